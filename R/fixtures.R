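#' Packaged 20-patient TOF cohort
#'
#' Demographics, blood pressures, ascending aortic diameters (AAD), aortic
#' Z scores and blood viscosities for a cohort of 20 Tetralogy of Fallot
#' patients, split evenly into nondilated and dilated groups by Z score.
#' This is the reference dataset the statistics stage reproduces exactly.
#'
#' @return data.frame with columns `id`, `group`, `age` (years), `sex`,
#'   `height` (cm), `weight` (kg), `sbp`, `dbp` (mmHg), `aad` (mm),
#'   `z_score`, `viscosity` (cPoise).
#' @examples
#' head(tof_cohort())
#' @export
tof_cohort <- function() {
  path <- system.file("extdata", "tof_cohort.csv", package = "aortafsi",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$group <- factor(df$group, levels = c("nondilated", "dilated"))
  df
}

#' Packaged per-patient simulated hemodynamic metrics for the TOF cohort
#'
#' Per-patient inlet/mean velocity, max/mean displacement and max/mean
#' maximal-principal-stress values in the ascending aorta at the diastolic
#' and systolic instants, for the [tof_cohort()] patients. Values are
#' stored rank-ordered (ascending) within each group; they are not linked
#' to patient ids.
#'
#' @return long-format data.frame with columns `metric`, `phase`, `units`,
#'   `group`, `rank`, `value`.
#' @examples
#' m <- tof_metrics()
#' unique(m$metric)
#' @export
tof_metrics <- function() {
  path <- system.file("extdata", "tof_metrics.csv", package = "aortafsi",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$group <- factor(df$group, levels = c("nondilated", "dilated"))
  df
}
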