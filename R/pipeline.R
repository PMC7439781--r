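#' Pipeline configuration
#'
#' Central configuration for the per-patient pipeline and the flow solver.
#' Round-trips through JSON serialisation unchanged (see
#' [write_run_config()]).
#'
#' @param period cardiac period T, s (default 0.8).
#' @param lambda_z axial pre-stretch (default 1: no axial tethering).
#' @param viscosity_dialect protein-unit dialect for
#'   [viscosity_from_blood()].
#' @param alpha decision threshold for the statistical gates.
#' @param gate_normality strict mode for [compare_groups()].
#' @param n_x,n_cycles flow solver controls.
#' @param waveform_n,t_sys,tau waveform template controls
#'   ([waveform_template()]).
#' @param material_mode `"sbp_zero_load"` (calibrate stiffness by applying
#'   full systolic pressure to the recovered zero-load geometry; the
#'   self-consistent default) or `"delta_p"` (apply the systolic-diastolic
#'   difference to the imaged diastolic geometry).
#' @param outer_passes maximum secant iterations on the coupled
#'   preshrink/stiffness fixed point in [run_patient()] (convergence is
#'   declared at 0.1% relative change of the ratio, usually 3-4
#'   iterations).
#' @param tol_volume root tolerance (relative volume error) for the
#'   preshrink and stiffness calibrations.
#' @param tol_velocity root tolerance (relative velocity error) for the
#'   outlet calibration.
#' @param seed optional integer seed recorded in reports.
#' @return object of class `run_config` (a validated list).
#' @export
run_config <- function(period = 0.8, lambda_z = 1,
                       viscosity_dialect = c("g_dL", "g_L"),
                       alpha = 0.05, gate_normality = FALSE,
                       n_x = 12, n_cycles = 4,
                       waveform_n = 201, t_sys = 0.35, tau = 0.35,
                       material_mode = c("sbp_zero_load", "delta_p"),
                       outer_passes = 8, tol_volume = 1e-4,
                       tol_velocity = 1e-3, seed = NULL) {
  viscosity_dialect <- match.arg(viscosity_dialect)
  material_mode <- match.arg(material_mode)
  stopifnot(period > 0, lambda_z > 0, alpha > 0, alpha < 1,
            n_x >= 4, n_cycles >= 2, waveform_n >= 21,
            t_sys > 0, t_sys < 1, tau > 0, outer_passes >= 1,
            tol_volume > 0, tol_velocity > 0)
  structure(list(period = period, lambda_z = lambda_z,
                 viscosity_dialect = viscosity_dialect, alpha = alpha,
                 gate_normality = gate_normality, n_x = n_x,
                 n_cycles = n_cycles, waveform_n = waveform_n,
                 t_sys = t_sys, tau = tau, material_mode = material_mode,
                 outer_passes = outer_passes, tol_volume = tol_volume,
                 tol_velocity = tol_velocity, seed = seed),
            class = "run_config")
}

#' Serialise / restore a run configuration
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `write_run_config` returns the path invisibly;
#'   `read_run_config` returns the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' Run the full per-patient pipeline
#'
#' Executes the personalisation chain for one patient: preshrink to the
#' zero-load geometry, stiffness-ratio calibration to the systolic CT
#' volume (alternated with re-preshrinking for `outer_passes` rounds, since
#' the zero-load shape itself depends on the wall stiffness), outlet-offset
#' calibration to the Doppler velocity, and final structural and flow
#' solves at the diastolic and systolic states, extracting the standard
#' metric set: inlet/mean velocity at the diastolic and systolic instants,
#' mean/max diastolic-to-systolic displacement, and mean/max maximal
#' principal stress per phase.
#'
#' A missing Doppler measurement skips outlet calibration and leaves the
#' velocity metrics `NA` with an explicit `outlet_calibrated = FALSE` flag.
#'
#' @param record one-row data.frame (or list) with at least `sbp`, `dbp`
#'   (mmHg) and `viscosity` (cPoise).
#' @param geometry the in vivo diastolic [vessel_geometry()].
#' @param measurements list or one-row data.frame with `v_diastolic`,
#'   `v_systolic` (mm^3) and optionally `doppler_velocity` (mm/s).
#' @param params_init baseline [material_params()].
#' @param config a [run_config()].
#' @param report_path optional path for a JSON per-patient report
#'   (metrics, calibration summaries and traces, config).
#' @return list with `metrics` (long data.frame: metric, phase, units,
#'   value), `params`, `zero_load` geometry, `calibrations` (list of
#'   `calibration_result`s), `outlet_calibrated`, `states` (the final
#'   diastolic/systolic `deformed_state`s).
#' @export
run_patient <- function(record, geometry, measurements,
                        params_init = material_params(), config = run_config(),
                        report_path = NULL) {
  record <- as.list(record)
  measurements <- as.list(measurements)
  if (is.null(measurements$v_diastolic) || is.na(measurements$v_diastolic) ||
      is.null(measurements$v_systolic) || is.na(measurements$v_systolic))
    stop("measurements must provide v_diastolic and v_systolic")
  # The zero-load shape depends on the wall stiffness and the calibrated
  # stiffness depends on the zero-load shape, so the two inverse stages
  # are coupled: the calibrated ratio is a fixed point r = g(r), where
  # g(r) preshrinks with stiffness r and recalibrates. Solved by secant
  # (superlinear; plain alternation contracts slowly).
  ps <- cm <- NULL
  eval_g <- function(r) {
    ps <<- preshrink(geometry, record$dbp, scale_params(params_init, r),
                     v_target = measurements$v_diastolic,
                     lambda_z = config$lambda_z, tol_rel = config$tol_volume)
    if (config$material_mode == "sbp_zero_load") {
      cm <<- calibrate_material(ps$geometry, params_init, record$sbp,
                                measurements$v_systolic,
                                lambda_z = config$lambda_z,
                                tol_rel = config$tol_volume)
    } else {
      cm <<- calibrate_material(geometry, params_init,
                                record$sbp - record$dbp,
                                measurements$v_systolic,
                                lambda_z = config$lambda_z,
                                tol_rel = config$tol_volume)
    }
    cm$result$value
  }
  r_prev <- 1
  h_prev <- eval_g(r_prev) - r_prev
  r_cur <- r_prev + h_prev      # = g(1)
  if (abs(h_prev) / r_prev >= 1e-3) {
    for (pass in seq_len(config$outer_passes)) {
      h_cur <- eval_g(r_cur) - r_cur
      if (abs(h_cur) / r_cur < 1e-3) break
      denom <- h_cur - h_prev
      step <- if (denom != 0) -h_cur * (r_cur - r_prev) / denom else h_cur
      r_prev <- r_cur
      h_prev <- h_cur
      r_cur <- max(r_cur + step, 0.01)
    }
  }
  params <- cm$params
  g0 <- ps$geometry
  st_d <- solve_vessel(params, g0, mmhg_to_kpa(record$dbp), config$lambda_z)
  st_s <- solve_vessel(params, g0, mmhg_to_kpa(record$sbp), config$lambda_z)
  disp <- displacement_metrics(st_d, st_s)

  outlet_calibrated <- FALSE
  co <- NULL
  vel <- c(inlet_dia = NA_real_, inlet_sys = NA_real_,
           mean_dia = NA_real_, mean_sys = NA_real_)
  if (!is.null(measurements$doppler_velocity) &&
      !is.na(measurements$doppler_velocity)) {
    tmpl <- waveform_template(config$waveform_n, config$t_sys, config$tau)
    p_in <- scale_waveform(tmpl, record$sbp, record$dbp, config$period)
    blood <- blood_properties(record$viscosity)
    law <- tube_law(params, g0, p_max_mmhg = 1.25 * record$sbp + 10,
                    n_x = config$n_x, lambda_z = config$lambda_z)
    co <- calibrate_outlet(p_in, measurements$doppler_velocity, params, g0,
                           blood, n_cycles = config$n_cycles,
                           n_x = config$n_x, lambda_z = config$lambda_z,
                           law = law, tol_rel = config$tol_velocity)
    fl <- solve_flow(params, g0, blood, p_in, co$p_out,
                     n_cycles = config$n_cycles, n_x = config$n_x,
                     law = law, lambda_z = config$lambda_z)
    s <- fl$summary
    vel <- c(inlet_dia = s$inlet_velocity_diastolic,
             inlet_sys = s$inlet_velocity_systolic,
             mean_dia = s$mean_velocity_diastolic,
             mean_sys = s$mean_velocity_systolic)
    outlet_calibrated <- TRUE
  }
  metrics <- data.frame(
    metric = c("inlet_velocity", "inlet_velocity", "mean_velocity",
               "mean_velocity", "max_displacement", "mean_displacement",
               "max_stress_p1", "mean_stress_p1", "max_stress_p1",
               "mean_stress_p1"),
    phase = c("diastolic", "systolic", "diastolic", "systolic",
              "systolic", "systolic", "diastolic", "diastolic",
              "systolic", "systolic"),
    units = c("mm/s", "mm/s", "mm/s", "mm/s", "mm", "mm",
              "kPa", "kPa", "kPa", "kPa"),
    value = c(vel[["inlet_dia"]], vel[["inlet_sys"]],
              vel[["mean_dia"]], vel[["mean_sys"]],
              disp[["max"]], disp[["mean"]],
              st_d$summary$max_stress_p1, st_d$summary$mean_stress_p1,
              st_s$summary$max_stress_p1, st_s$summary$mean_stress_p1))
  out <- list(metrics = metrics, params = params, zero_load = g0,
              calibrations = list(preshrink = ps$result,
                                  material = cm$result,
                                  outlet = if (!is.null(co)) co$result),
              outlet_calibrated = outlet_calibrated,
              states = list(diastolic = st_d, systolic = st_s))
  if (!is.null(report_path)) {
    rep <- list(
      config = unclass(config),
      metrics = metrics,
      outlet_calibrated = outlet_calibrated,
      calibrations = lapply(Filter(Negate(is.null), out$calibrations),
                            function(cr) unclass(cr)))
    jsonlite::write_json(rep, report_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", null = "null")
  }
  out
}

#' Run the pipeline over a cohort and compare the groups
#'
#' Applies [run_patient()] to every patient, assembles the per-patient
#' metric sets, splits the cohort by Z score when no `group` column is
#' present, and runs the two-sample protocol per metric/phase via
#' [build_results_tables()]. Failed patients are reported, not fatal,
#' unless a group drops below 2 usable patients.
#'
#' @param cohort data.frame of patient records (columns as [tof_cohort()],
#'   at least `id`, `sbp`, `dbp`, `viscosity`, `z_score`).
#' @param geometries named list of in vivo diastolic [vessel_geometry()]
#'   per patient id.
#' @param measurements data.frame with `id`, `v_diastolic`, `v_systolic`,
#'   optionally `doppler_velocity`.
#' @param params_init baseline [material_params()].
#' @param config a [run_config()].
#' @return list with `tables` (a `results_tables`), `metrics` (long
#'   data.frame with patient id and group), `patients` (per-patient
#'   [run_patient()] results), `errors` (named failure messages).
#' @export
run_cohort <- function(cohort, geometries, measurements,
                       params_init = material_params(),
                       config = run_config()) {
  if (nrow(cohort) == 0) stop("empty cohort")
  if (!"group" %in% names(cohort)) cohort <- split_by_zscore(cohort)
  patients <- list()
  errors <- character(0)
  all_metrics <- list()
  for (i in seq_len(nrow(cohort))) {
    id <- as.character(cohort$id[i])
    mi <- measurements[measurements$id == id, , drop = FALSE]
    res <- tryCatch(
      run_patient(cohort[i, ], geometries[[id]], mi, params_init, config),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[id] <- conditionMessage(res)
      next
    }
    patients[[id]] <- res
    m <- res$metrics
    m$id <- id
    m$group <- as.character(cohort$group[i])
    all_metrics[[id]] <- m
  }
  metrics <- do.call(rbind, all_metrics)
  if (is.null(metrics)) stop("no usable patients")
  usable <- table(unique(metrics[, c("id", "group")])$group)
  if (any(usable < 2))
    stop("fewer than 2 usable patients in a group: ",
         paste(names(usable), usable, collapse = ", "))
  metrics_ok <- metrics[!is.na(metrics$value), ]
  tables <- build_results_tables(metrics_ok, alpha = config$alpha,
                                 gate_normality = config$gate_normality)
  list(tables = tables, metrics = metrics, patients = patients,
       errors = errors)
}

#' Statistics-only entry: reproduce the reference tables from metrics
#'
#' Consumes a long per-patient metric table (e.g. [tof_metrics()]) and
#' runs the full two-sample protocol per metric/phase, without any
#' simulation. This is the exactly-reproducible surface of the pipeline.
#'
#' @param metrics long-format data.frame (`metric`, `phase`, `group`,
#'   `value`, optionally `units`).
#' @param alpha,gate_normality passed to [build_results_tables()].
#' @return a `results_tables` object.
#' @examples
#' tabs <- run_cohort_stats(tof_metrics())
#' tabs$tables[["mean_stress_p1.systolic"]]$comparison
#' @export
run_cohort_stats <- function(metrics, alpha = 0.05, gate_normality = FALSE) {
  build_results_tables(metrics, alpha = alpha,
                       gate_normality = gate_normality)
}
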