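#' Blood viscosity from hematocrit and total plasma protein
#'
#' Linear regression estimate of whole-blood dynamic viscosity:
#' \deqn{\mu\ [\mathrm{cPoise}] = 0.12\,\mathrm{hct}\,[\%] +
#'   0.17\,\mathrm{tpp} - 2.07.}
#' The protein term has two unit dialects. Taken literally in g/L the
#' formula yields viscosities around 14 cPoise for normal blood, well above
#' the physiological 3-10 cPoise range; with total protein expressed in
#' g/dL (the conventional clinical unit, numerically one tenth) the output
#' is physiological. Both dialects are implemented behind an explicit flag;
#' the default is `"g_dL"`. Supply `total_protein` in the unit named by
#' `dialect`.
#'
#' @param hematocrit volume percent, in (0, 100).
#' @param total_protein total plasma protein, in the `dialect` unit.
#' @param dialect `"g_dL"` (default) or `"g_L"`.
#' @return dynamic viscosity, cPoise.
#' @examples
#' viscosity_from_blood(40, 7)           # g/dL dialect: 3.92 cPoise
#' viscosity_from_blood(40, 70, "g_L")   # literal g/L dialect: 14.63 cPoise
#' @export
viscosity_from_blood <- function(hematocrit, total_protein,
                                 dialect = c("g_dL", "g_L")) {
  dialect <- match.arg(dialect)
  if (any(hematocrit <= 0) || any(hematocrit >= 100))
    stop("hematocrit must be in (0, 100) percent")
  if (any(total_protein <= 0)) stop("total protein must be positive")
  mu <- 0.12 * hematocrit + 0.17 * total_protein - 2.07
  if (any(mu <= 0))
    stop("nonphysical viscosity (<= 0 cPoise) from the supplied inputs")
  mu
}

#' Blood properties container
#'
#' @param viscosity dynamic viscosity, cPoise.
#' @param density fluid density, g/cm^3; fixed at 1.0 in this model.
#' @param hematocrit,total_protein optional provenance fields.
#' @return object of class `blood_properties`.
#' @export
blood_properties <- function(viscosity, density = 1.0,
                             hematocrit = NA_real_, total_protein = NA_real_) {
  if (viscosity <= 0) stop("viscosity must be positive")
  if (density != 1.0) stop("density is fixed at 1.0 g/cm^3 in this model")
  structure(list(viscosity = viscosity, density = density,
                 hematocrit = hematocrit, total_protein = total_protein),
            class = "blood_properties")
}
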