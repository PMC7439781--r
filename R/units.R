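#' Unit conversions
#'
#' Pressure conversions between mmHg and kPa used throughout the package.
#' The conversion factor is fixed at 1 mmHg = 0.133322 kPa so that all
#' modules agree bit-for-bit.
#'
#' @param x numeric vector of pressures.
#' @return numeric vector in the target unit.
#' @examples
#' mmhg_to_kpa(80)
#' kpa_to_mmhg(mmhg_to_kpa(120))
#' @export
mmhg_to_kpa <- function(x) x * 0.133322

#' @rdname mmhg_to_kpa
#' @export
kpa_to_mmhg <- function(x) x / 0.133322

# internal: kPa -> Pa (g mm^-1 s^-2), the unit system of the flow solver
.kpa_to_pa <- function(x) x * 1000
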