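#' Specification for a synthetic TOF-like cohort
#'
#' Defines the joint distribution a synthetic cohort is drawn from. The
#' per-group field distributions are independent truncated normals whose
#' default means and SDs are those of the packaged reference cohort
#' ([tof_cohort()] summary rows): two groups of 10 with the dilated group
#' given systematically larger Z scores, larger diameters and (through the
#' hidden stiffness ratio) softer walls. Hidden ground-truth parameters
#' (stiffness ratio, zero-load shrink, outlet offset) are drawn per patient
#' so that every calibration stage can be validated by recovery.
#'
#' @param n_per_group patients per group, >= 2.
#' @param seed mandatory integer seed.
#' @param volume_noise SD of the multiplicative volume-scale error shared
#'   by the diastolic and systolic CT volumes of one patient (default 2%:
#'   segmentation and scanner biases hit both phases of one acquisition
#'   alike).
#' @param volume_phase_noise SD of the independent per-phase volume error
#'   (default 0.3%). This component competes directly with the
#'   diastolic-to-systolic volume increment that carries the stiffness
#'   signal, so it must be far smaller than the shared scale error for the
#'   stiffness ratio to remain identifiable.
#' @param velocity_noise SD of the multiplicative Doppler velocity error
#'   (default 2%).
#' @param fields optional list overriding per-group field distributions;
#'   each entry `fields[[group]][[name]]` is `c(mean, sd, lower, upper)`.
#' @param ratio_meanlog named numeric: mean of `log` stiffness ratio per
#'   group; the dilated default `log(0.7)` encodes softer dilated walls.
#' @param ratio_sdlog SD of log stiffness ratio.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 10, seed,
                        volume_noise = 0.02, volume_phase_noise = 0.003,
                        velocity_noise = 0.02,
                        fields = NULL,
                        ratio_meanlog = c(nondilated = log(1.0),
                                          dilated = log(0.7)),
                        ratio_sdlog = 0.15) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_per_group < 2) stop("need n >= 2 per group")
  defaults <- list(
    nondilated = list(
      age = c(13.5, 6.1, 3, 60), height = c(143, 23, 80, 200),
      weight = c(36.3, 16.6, 10, 120), sbp = c(109, 16, 70, 200),
      dbp = c(66, 13, 35, 120), aad = c(25.68, 5.86, 12, 55),
      z_score = c(2.78, 1.27, -2, 5), hematocrit = c(42, 6, 20, 60),
      total_protein = c(7.2, 0.8, 4, 10)),
    dilated = list(
      age = c(11.6, 4.8, 3, 60), height = c(135, 24, 80, 200),
      weight = c(26.5, 12.0, 10, 120), sbp = c(107, 17, 70, 200),
      dbp = c(62, 11, 35, 120), aad = c(31.53, 6.38, 12, 55),
      z_score = c(8.30, 1.27, 5, 16), hematocrit = c(42, 6, 20, 60),
      total_protein = c(7.2, 0.8, 4, 10))
  )
  if (!is.null(fields))
    for (g in names(fields))
      defaults[[g]][names(fields[[g]])] <- fields[[g]]
  for (g in names(defaults))
    for (f in names(defaults[[g]])) {
      v <- defaults[[g]][[f]]
      if (v[2] < 0 || v[3] >= v[4] || v[1] < v[3] || v[1] > v[4])
        stop("infeasible bounds for field ", f, " in group ", g)
    }
  structure(list(n_per_group = n_per_group, seed = as.integer(seed),
                 volume_noise = volume_noise,
                 volume_phase_noise = volume_phase_noise,
                 velocity_noise = velocity_noise,
                 fields = defaults,
                 ratio_meanlog = ratio_meanlog, ratio_sdlog = ratio_sdlog),
            class = "cohort_spec")
}

# truncated normal by rejection; exact mean for sd = 0
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

# idealized ascending-aortic segment: linear taper over 60 mm with the
# mid-segment inner diameter equal to AAD, uniform 2 mm wall
.taper_geometry <- function(aad_mm, length_mm = 60, n_rings = 13,
                            taper = 0.10, wall = 2.0,
                            configuration = "diastolic") {
  z <- seq(0, length_mm, length.out = n_rings)
  r_mid <- aad_mm / 2
  r <- r_mid * (1 + taper / 2 - taper * z / length_mm)
  vessel_geometry(z, r, wall, configuration = configuration)
}

#' Generate a synthetic cohort with hidden ground truth
#'
#' Draws patient records per [cohort_spec()], derives blood viscosity from
#' the drawn hematocrit and total plasma protein via
#' [viscosity_from_blood()], builds an idealised tapered in vivo vessel
#' geometry per patient (mid-segment diameter = AAD), and draws the hidden
#' truth: per-patient stiffness ratio, zero-load shrink rate, and the
#' outlet offset implied by a physiological target mean inlet velocity.
#' Fully seed-reproducible.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `synthetic_cohort`: list with `cohort`
#'   (data.frame of patient records), `truth` (data.frame: id, ratio,
#'   shrink, delta_mmhg, u_target), `zero_load` (list of truth zero-load
#'   [vessel_geometry()] per patient), and `spec`.
#' @export
generate_cohort <- function(spec) {
  set.seed(spec$seed)
  groups <- c("nondilated", "dilated")
  recs <- list()
  for (g in groups) {
    fd <- spec$fields[[g]]
    n <- spec$n_per_group
    draw <- function(f) .rtruncnorm(n, fd[[f]][1], fd[[f]][2],
                                    fd[[f]][3], fd[[f]][4])
    sbp <- draw("sbp")
    dbp <- draw("dbp")
    # redraw diastolic values until a physiological pulse pressure holds
    for (k in seq_len(50)) {
      bad <- sbp < dbp + 15
      if (!any(bad)) break
      dbp[bad] <- .rtruncnorm(sum(bad), fd$dbp[1], fd$dbp[2],
                              fd$dbp[3], fd$dbp[4])
    }
    dbp <- pmin(dbp, sbp - 15)
    hct <- draw("hematocrit")
    tpp <- draw("total_protein")
    recs[[g]] <- data.frame(
      group = g, age = draw("age"),
      sex = sample(c("M", "F"), n, replace = TRUE,
                   prob = if (g == "nondilated") c(0.8, 0.2) else c(0.6, 0.4)),
      height = draw("height"), weight = draw("weight"),
      sbp = sbp, dbp = dbp, aad = draw("aad"), z_score = draw("z_score"),
      hematocrit = hct, total_protein = tpp,
      viscosity = viscosity_from_blood(hct, tpp))
  }
  cohort <- do.call(rbind, recs)
  cohort <- data.frame(id = sprintf("S%02d", seq_len(nrow(cohort))), cohort)
  rownames(cohort) <- NULL
  cohort$group <- factor(cohort$group, levels = groups)
  n_tot <- nrow(cohort)
  ratio <- exp(stats::rnorm(n_tot,
                            spec$ratio_meanlog[as.character(cohort$group)],
                            spec$ratio_sdlog))
  shrink <- stats::runif(n_tot, 0.03, 0.08)
  u_target <- .rtruncnorm(n_tot, 200, 40, 100, 350)
  zero_load <- vector("list", n_tot)
  delta <- numeric(n_tot)
  for (i in seq_len(n_tot)) {
    nominal <- .taper_geometry(cohort$aad[i])
    zero_load[[i]] <- .scale_geometry(nominal, 1 - shrink[i],
                                      configuration = "zero_load")
    # outlet offset implied by the target velocity, Poiseuille estimate
    a_mid <- cohort$aad[i] / 2
    A_mid <- pi * a_mid^2
    mu <- cohort$viscosity[i] * 1e-3
    delta[i] <- kpa_to_mmhg(u_target[i] * 8 * pi * mu * 60 / A_mid / 1000)
  }
  names(zero_load) <- cohort$id
  structure(
    list(cohort = cohort,
         truth = data.frame(id = cohort$id, group = cohort$group,
                            ratio = ratio, shrink = shrink,
                            delta_mmhg = delta, u_target = u_target),
         zero_load = zero_load, spec = spec),
    class = "synthetic_cohort"
  )
}

#' Synthesise CT-volume and Doppler-velocity measurements
#'
#' Runs the forward model from the hidden truth of a
#' [generate_cohort()] result: for each patient, the truth zero-load
#' geometry is pressurised with the truth-scaled material to diastolic and
#' systolic pressure (giving the CT lumen-volume analogs and the in vivo
#' diastolic geometry), and, optionally, the pulsatile flow with the truth
#' outlet offset gives the Doppler mean-inlet-velocity analog.
#' Multiplicative Gaussian noise at the spec's levels is applied to all
#' three measurements. Patients whose forward model fails are flagged and
#' excluded, not silently dropped.
#'
#' @param gen a [generate_cohort()] result.
#' @param params_init baseline [material_params()] the truth ratios scale.
#' @param include_flow logical; synthesise the Doppler velocity (the
#'   expensive stage). When `FALSE`, `doppler_velocity` is `NA`.
#' @param config a [run_config()] for the flow solver controls.
#' @return list with `measurements` (data.frame: id, v_diastolic,
#'   v_systolic, doppler_velocity), `invivo` (list of in vivo diastolic
#'   [vessel_geometry()] per patient), `excluded` (named character vector
#'   of failure messages).
#' @export
synthesize_measurements <- function(gen, params_init = material_params(),
                                    include_flow = TRUE,
                                    config = run_config()) {
  spec <- gen$spec
  set.seed(spec$seed + 1L)
  n <- nrow(gen$cohort)
  meas <- data.frame(id = gen$cohort$id,
                     v_diastolic = NA_real_, v_systolic = NA_real_,
                     doppler_velocity = NA_real_)
  invivo <- vector("list", n)
  names(invivo) <- gen$cohort$id
  excluded <- character(0)
  tmpl <- waveform_template(config$waveform_n, config$t_sys, config$tau)
  for (i in seq_len(n)) {
    rec <- gen$cohort[i, ]
    tr <- gen$truth[i, ]
    res <- tryCatch({
      params <- scale_params(params_init, tr$ratio)
      g0 <- gen$zero_load[[i]]
      st_d <- solve_vessel(params, g0, mmhg_to_kpa(rec$dbp), config$lambda_z)
      st_s <- solve_vessel(params, g0, mmhg_to_kpa(rec$sbp), config$lambda_z)
      if (st_s$summary$lumen_volume <= st_d$summary$lumen_volume)
        stop("non-monotone inflation")
      u <- NA_real_
      if (include_flow) {
        p_in <- scale_waveform(tmpl, rec$sbp, rec$dbp, config$period)
        p_out <- .shift_waveform(p_in, tr$delta_mmhg)
        blood <- blood_properties(rec$viscosity)
        fl <- solve_flow(params, g0, blood, p_in, p_out,
                         n_cycles = config$n_cycles, n_x = config$n_x,
                         lambda_z = config$lambda_z)
        u <- fl$summary$mean_inlet_velocity
      }
      list(v_d = st_d$summary$lumen_volume,
           v_s = st_s$summary$lumen_volume,
           u = u,
           geom = vessel_geometry(st_d$rings$axial_position,
                                  st_d$rings$inner_radius,
                                  st_d$rings$wall_thickness,
                                  configuration = "diastolic"))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded[gen$cohort$id[i]] <- conditionMessage(res)
      next
    }
    scale_err <- stats::rnorm(1, 0, spec$volume_noise)
    meas$v_diastolic[i] <- res$v_d *
      (1 + scale_err + stats::rnorm(1, 0, spec$volume_phase_noise))
    meas$v_systolic[i] <- res$v_s *
      (1 + scale_err + stats::rnorm(1, 0, spec$volume_phase_noise))
    if (include_flow)
      meas$doppler_velocity[i] <- res$u *
        (1 + stats::rnorm(1, 0, spec$velocity_noise))
    invivo[[i]] <- res$geom
  }
  list(measurements = meas, invivo = invivo, excluded = excluded)
}
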