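# Safeguarded scalar root-finding on f(x) = 0 over [lower, upper]:
# secant steps clipped to the current sign-change bracket, bisection
# fallback when the secant step leaves it or stalls. Records a trace.
.secant_safeguarded <- function(f, x1, lower, upper,
                                tol_rel, max_iter = 40, f_scale = 1) {
  trace <- data.frame(iteration = integer(), value = numeric(),
                      residual = numeric())
  note <- function(x, fx) trace[nrow(trace) + 1, ] <<- c(nrow(trace) + 1, x, fx)
  fl <- f(lower); note(lower, fl)
  if (abs(fl) <= tol_rel * f_scale)
    return(list(root = lower, residual = fl, converged = TRUE, trace = trace))
  fu <- f(upper); note(upper, fu)
  if (abs(fu) <= tol_rel * f_scale)
    return(list(root = upper, residual = fu, converged = TRUE, trace = trace))
  if (fl * fu > 0)
    return(list(root = NA_real_, residual = NA_real_, converged = FALSE,
                trace = trace,
                message = sprintf("no sign change on [%g, %g]", lower, upper)))
  a <- lower; fa <- fl
  b <- upper; fb <- fu
  x_prev <- lower; f_prev <- fl
  x_cur <- min(max(x1, a), b)
  if (x_cur == x_prev) x_cur <- (a + b) / 2
  for (it in seq_len(max_iter)) {
    fx <- f(x_cur); note(x_cur, fx)
    if (abs(fx) <= tol_rel * f_scale)
      return(list(root = x_cur, residual = fx, converged = TRUE, trace = trace))
    if (fa * fx < 0) { b <- x_cur; fb <- fx } else { a <- x_cur; fa <- fx }
    # secant proposal from the two most recent iterates
    x_new <- NA_real_
    if (f_prev != fx)
      x_new <- x_cur - fx * (x_cur - x_prev) / (fx - f_prev)
    if (is.na(x_new) || x_new <= a || x_new >= b)
      x_new <- (a + b) / 2
    f_prev <- fx; x_prev <- x_cur; x_cur <- x_new
    if ((b - a) < 1e-14 * max(1, abs(b))) break
  }
  fx <- f(x_cur); note(x_cur, fx)
  list(root = x_cur, residual = fx,
       converged = abs(fx) <= tol_rel * f_scale, trace = trace)
}

.calibration_result <- function(parameter, value, achieved_rel_error,
                                converged, trace, tolerance = 0.05) {
  structure(list(parameter = parameter, value = value,
                 achieved_rel_error = achieved_rel_error,
                 iterations = nrow(trace), converged = converged,
                 tolerance = tolerance, trace = trace),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration_result: %s = %.6g (%s, rel. error %.3g after %d evaluations)\n",
              x$parameter, x$value,
              if (x$converged) "converged" else "NOT converged",
              x$achieved_rel_error, x$iterations))
  invisible(x)
}

#' Preshrink: recover the zero-load geometry
#'
#' Imaged vessel geometry is acquired under load (at least diastolic
#' pressure), while stress-free simulation must start from the unknown
#' zero-load shape. The preshrink inverse construction scales the in vivo
#' radii uniformly by \eqn{(1 - s)}, restoring the wall thickness by
#' per-ring wall-area conservation (the incompressible inverse of the
#' inflation map), and adjusts the shrink rate `s` (initial value 5%)
#' until re-pressurising the candidate zero-load geometry to diastolic
#' pressure reproduces the in vivo lumen volume. The
#' root is resolved to `tol_rel` (default 1e-4) and the conventional 5%
#' relative-volume contract is then verified on the converged value, so a
#' converged result is never marginal.
#'
#' @param geometry the in vivo (diastolic) [vessel_geometry()].
#' @param dbp_mmhg diastolic pressure, mmHg.
#' @param params wall [material_params()].
#' @param v_target target in vivo lumen volume, mm^3; defaults to the
#'   volume of `geometry` (the CT measurement analog).
#' @param s_init initial shrink rate (fraction), default 0.05.
#' @param bracket search interval for `s`, default `c(0, 0.4)`.
#' @param lambda_z axial stretch.
#' @param tol_rel root tolerance on relative volume error.
#' @return list with `geometry` (zero-load [vessel_geometry()]) and
#'   `result` (a `calibration_result` for `s`, as a percentage).
#' @export
preshrink <- function(geometry, dbp_mmhg, params, v_target = NULL,
                      s_init = 0.05, bracket = c(0, 0.4), lambda_z = 1,
                      tol_rel = 1e-4) {
  if (dbp_mmhg < 0) stop("DBP must be nonnegative")
  if (is.null(v_target)) v_target <- lumen_volume(geometry)
  P <- mmhg_to_kpa(dbp_mmhg)
  # candidate zero-load geometry: radii scaled by (1 - s); thickness
  # restored by per-ring wall-area conservation (the incompressible
  # inverse of the inflation map at lambda_z = 1)
  candidate <- function(s) {
    a <- geometry$rings$inner_radius
    h <- geometry$rings$wall_thickness
    a0 <- (1 - s) * a
    h0 <- sqrt(a0^2 + (a + h)^2 - a^2) - a0
    vessel_geometry(geometry$rings$axial_position, a0, h0,
                    configuration = "zero_load",
                    tissue_density = geometry$tissue_density)
  }
  vol_at <- function(s) {
    solve_vessel(params, candidate(s), P, lambda_z)$summary$lumen_volume
  }
  f <- function(s) (vol_at(s) - v_target) / v_target
  sol <- .secant_safeguarded(f, s_init, bracket[1], bracket[2],
                             tol_rel = tol_rel)
  if (!sol$converged)
    stop("calibration failure in preshrink: ",
         if (!is.null(sol$message)) sol$message else "no convergence",
         " (", nrow(sol$trace), " evaluations)")
  s <- sol$root
  rel_err <- abs(f(s))
  res <- .calibration_result("shrink_rate_percent", 100 * s, rel_err,
                             converged = rel_err < 0.05, trace = sol$trace)
  list(geometry = candidate(s), result = res)
}

#' Calibrate the patient-specific stiffness ratio
#'
#' Personalises the wall material by scaling the four stress-dimensioned
#' constants by a single ratio `r` (see [scale_params()]) until the lumen
#' volume predicted at the given load matches a measured target volume.
#' Two constructions are supported through the arguments: apply the
#' systolic-diastolic pressure difference to the imaged diastolic geometry,
#' or apply the full systolic pressure to a recovered zero-load geometry.
#' The root in `log r` is resolved to `tol_rel` relative volume error and
#' the 5% contract is then verified.
#'
#' @param geometry reference [vessel_geometry()] for the solve.
#' @param params_init initial [material_params()] (the population baseline).
#' @param pressure_mmhg load applied to `geometry`, mmHg (e.g. SBP - DBP on
#'   a diastolic geometry, or SBP on a zero-load geometry).
#' @param v_target target lumen volume under load, mm^3.
#' @param bracket search interval for `r`, default `c(1e-2, 1e2)`.
#' @param lambda_z axial stretch.
#' @param tol_rel root tolerance on relative volume error.
#' @return list with `params` (calibrated [material_params()]) and
#'   `result` (a `calibration_result` for the ratio).
#' @export
calibrate_material <- function(geometry, params_init, pressure_mmhg, v_target,
                               bracket = c(1e-2, 1e2), lambda_z = 1,
                               tol_rel = 1e-4) {
  if (pressure_mmhg <= 0) stop("calibration pressure must be positive")
  v_ref <- lumen_volume(geometry)
  if (v_target <= v_ref)
    stop("infeasible target: target volume ", signif(v_target, 6),
         " mm^3 does not exceed the reference lumen volume ",
         signif(v_ref, 6), " mm^3")
  P <- mmhg_to_kpa(pressure_mmhg)
  f <- function(logr) {
    p <- scale_params(params_init, exp(logr))
    (solve_vessel(p, geometry, P, lambda_z)$summary$lumen_volume - v_target) /
      v_target
  }
  # stiffer wall -> smaller volume: f is decreasing in log r
  sol <- .secant_safeguarded(f, 0, log(bracket[1]), log(bracket[2]),
                             tol_rel = tol_rel)
  if (!sol$converged)
    stop("calibration failure in calibrate_material: ",
         if (!is.null(sol$message)) sol$message else "no convergence")
  r <- exp(sol$root)
  rel_err <- abs(sol$residual)
  res <- .calibration_result("stiffness_ratio", r, rel_err,
                             converged = rel_err < 0.05, trace = sol$trace)
  res$trace$value <- exp(res$trace$value)
  list(params = scale_params(params_init, r), result = res)
}

#' Calibrate the outlet pressure offset to a measured inlet velocity
#'
#' The outlet pressure trace is parameterised as the inlet trace shifted
#' down by a constant offset \eqn{\delta \ge 0} (mmHg). The offset is
#' adjusted until the cycle-averaged inlet velocity predicted by
#' [solve_flow()] matches the Doppler-measured mean inlet velocity. The
#' match is on the net (signed) cycle average: a compliant tube at
#' \eqn{\delta = 0} carries purely oscillatory storage flow with zero net
#' through-flow, so a vanishing measurement calibrates to \eqn{\delta = 0}.
#' The root is resolved to `tol_rel` relative velocity error and the 5%
#' contract verified on the converged offset.
#'
#' @param p_in inlet [scale_waveform()] trace.
#' @param measured_velocity Doppler mean inlet velocity, mm/s (> 0, or 0).
#' @param params wall [material_params()].
#' @param geometry reference [vessel_geometry()] for the tube law.
#' @param blood a [blood_properties()] object.
#' @param bracket offset interval, mmHg, default `c(0, 30)`.
#' @param n_cycles,n_x flow solver controls.
#' @param lambda_z axial stretch.
#' @param law optional precomputed [tube_law()]; built once here otherwise.
#' @param tol_rel root tolerance on relative velocity error.
#' @return list with `p_out` (the calibrated outlet `pressure_waveform`),
#'   `delta_mmhg`, and `result` (a `calibration_result`).
#' @export
calibrate_outlet <- function(p_in, measured_velocity, params, geometry, blood,
                             bracket = c(0, 30), n_cycles = 4, n_x = 12,
                             lambda_z = 1, law = NULL, tol_rel = 1e-3) {
  if (measured_velocity < 0) stop("measured velocity must be nonnegative")
  if (is.null(law))
    law <- tube_law(params, geometry, p_max_mmhg = 1.25 * max(p_in$p) + 10,
                    n_x = n_x, lambda_z = lambda_z)
  vel_at <- function(delta) {
    p_out <- .shift_waveform(p_in, delta)
    solve_flow(params, geometry, blood, p_in, p_out, n_cycles = n_cycles,
               n_x = n_x, law = law, lambda_z = lambda_z)$summary$mean_inlet_velocity
  }
  if (measured_velocity == 0) {
    res <- .calibration_result("outlet_offset_mmhg", 0, 0, TRUE,
                               data.frame(iteration = 1L, value = 0,
                                          residual = 0))
    return(list(p_out = .shift_waveform(p_in, 0), delta_mmhg = 0, result = res))
  }
  f <- function(delta) (vel_at(delta) - measured_velocity) / measured_velocity
  # velocity is monotone increasing in the offset; response is nearly
  # linear, so the secant converges in a few flow solves
  sol <- .secant_safeguarded(f, 0.02, bracket[1], bracket[2],
                             tol_rel = tol_rel)
  if (!sol$converged)
    stop("calibration failure in calibrate_outlet: ",
         if (!is.null(sol$message)) sol$message
         else sprintf("velocity %.4g mm/s unreachable for offsets in [%g, %g] mmHg",
                      measured_velocity, bracket[1], bracket[2]))
  delta <- sol$root
  rel_err <- abs(sol$residual)
  res <- .calibration_result("outlet_offset_mmhg", delta, rel_err,
                             converged = rel_err < 0.05, trace = sol$trace)
  list(p_out = .shift_waveform(p_in, delta), delta_mmhg = delta, result = res)
}

#' Write a calibration trace to CSV
#'
#' @param result a `calibration_result`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_calibration_trace <- function(result, path) {
  utils::write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}
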