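#' Normalised aortic pressure waveform template
#'
#' A two-phase analytic template for the aortic pressure trace over one
#' cardiac cycle, normalised to `[0, 1]`: a sinusoidal systolic upstroke and
#' partial decline over `[0, t_sys]` ending at a dicrotic-notch level, then
#' an exponential diastolic decay that reaches the diastolic minimum exactly
#' at end-cycle, so the sampled curve is periodic (first sample equals last).
#' The shape is parametric and swappable; any user curve with min 0 and
#' max 1 can be passed to [scale_waveform()] instead.
#'
#' @param n number of samples (the grid has `n` points including both
#'   endpoints).
#' @param t_sys systolic fraction of the cycle, default 0.35.
#' @param tau diastolic decay constant as a fraction of the cycle.
#' @return numeric vector of `n` samples on the uniform grid over one cycle,
#'   min 0, max 1, first equal to last.
#' @export
waveform_template <- function(n = 201, t_sys = 0.35, tau = 0.35) {
  stopifnot(n >= 21, t_sys > 0, t_sys < 1, tau > 0)
  tt <- seq(0, 1, length.out = n)
  # systole: sin rising from 0, peaking inside [0, t_sys], ending at the notch
  half_period <- 8 / 7 * t_sys
  notch <- sin(pi * t_sys / half_period)
  p <- ifelse(tt <= t_sys,
              sin(pi * tt / half_period),
              {
                E <- exp(-(1 - t_sys) / tau)
                notch * (exp(-(tt - t_sys) / tau) - E) / (1 - E)
              })
  p <- (p - min(p)) / (max(p) - min(p))
  p[n] <- p[1]
  p
}

#' Scale a normalised waveform to patient blood pressure
#'
#' Affine map of a normalised template (min 0, max 1) onto the patient's
#' diastolic/systolic pressure range:
#' \eqn{p(t) = \mathrm{DBP} + (\mathrm{SBP} - \mathrm{DBP})\,\tilde p(t)}.
#' The result is a periodic pressure trace whose maximum is exactly SBP and
#' minimum exactly DBP.
#'
#' @param template numeric samples of the normalised curve on a uniform grid
#'   over one cycle (min 0, max 1, periodic), e.g. [waveform_template()].
#' @param sbp,dbp systolic and diastolic pressure, mmHg; `sbp > dbp > 0`.
#' @param period cardiac period T, s (default 0.8).
#' @return object of class `pressure_waveform`: list with `t` (s), `p`
#'   (mmHg), `period`, `sbp`, `dbp`.
#' @examples
#' wf <- scale_waveform(waveform_template(), sbp = 108, dbp = 62)
#' range(wf$p) # 62 108
#' @export
scale_waveform <- function(template, sbp, dbp, period = 0.8) {
  if (dbp <= 0 || sbp <= dbp) stop("need SBP > DBP > 0")
  if (abs(min(template)) > 1e-12 || abs(max(template) - 1) > 1e-12)
    stop("template must be normalised to min 0, max 1")
  if (abs(template[1] - template[length(template)]) > 1e-12)
    stop("template must be periodic (first sample = last sample)")
  n <- length(template)
  structure(
    list(t = seq(0, period, length.out = n),
         p = dbp + (sbp - dbp) * template,
         period = period, sbp = sbp, dbp = dbp),
    class = "pressure_waveform"
  )
}

#' @export
print.pressure_waveform <- function(x, ...) {
  cat(sprintf("pressure_waveform: %d samples over T = %.3g s, %.4g-%.4g mmHg\n",
              length(x$t), x$period, x$dbp, x$sbp))
  invisible(x)
}

# periodic linear interpolator p(t) in mmHg
.waveform_fun <- function(wf) {
  af <- stats::approxfun(wf$t, wf$p, rule = 2)
  Tp <- wf$period
  function(t) af(t %% Tp)
}

# shift a waveform down by a constant offset (mmHg); used for outlet traces.
# The result is a plain shifted copy; sbp/dbp fields follow the shift.
.shift_waveform <- function(wf, offset_mmhg) {
  out <- wf
  out$p <- wf$p - offset_mmhg
  out$sbp <- wf$sbp - offset_mmhg
  out$dbp <- wf$dbp - offset_mmhg
  out
}
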