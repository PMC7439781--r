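#' Pressure-area law of the compliant vessel
#'
#' Precomputes, per axial cell of the flow grid, the lumen cross-section
#' area as a function of internal pressure by repeated incompressible
#' thick-wall inflation of the local ring. This is the structural half of
#' the fluid-structure coupling: the flow solver never re-solves the wall,
#' it interpolates this tabulated law. Building the law once and reusing it
#' across flow solves (e.g. inside outlet calibration) is the intended
#' pattern.
#'
#' @param params a [material_params()] object.
#' @param geometry a [vessel_geometry()] giving the unstressed reference.
#' @param p_max_mmhg upper end of the tabulated pressure range, mmHg; must
#'   exceed every pressure the flow solver will see.
#' @param n_x number of axial cells.
#' @param n_p number of pressure grid points.
#' @param lambda_z axial stretch.
#' @return object of class `tube_law`: cell centers `x` (mm), `dx`,
#'   pressure grid (Pa), area matrix `A` (n_p x n_x, mm^2) and
#'   interpolators.
#' @export
tube_law <- function(params, geometry, p_max_mmhg = 200, n_x = 12, n_p = 48,
                     lambda_z = 1) {
  rg <- geometry$rings
  L <- diff(range(rg$axial_position))
  dx <- L / n_x
  x <- min(rg$axial_position) + (seq_len(n_x) - 0.5) * dx
  r_ref <- stats::approx(rg$axial_position, rg$inner_radius, xout = x)$y
  h_ref <- stats::approx(rg$axial_position, rg$wall_thickness, xout = x)$y
  p_grid_kpa <- seq(0, mmhg_to_kpa(p_max_mmhg), length.out = n_p)
  A <- matrix(NA_real_, n_p, n_x)
  for (i in seq_len(n_x)) {
    a <- vapply(p_grid_kpa, function(p)
      .ring_radius(params, r_ref[i], r_ref[i] + h_ref[i], p, lambda_z),
      numeric(1))
    A[, i] <- pi * a^2
  }
  p_grid_pa <- .kpa_to_pa(p_grid_kpa)
  structure(
    list(x = x, dx = dx, length = L, n_x = n_x,
         r_ref = r_ref, h_ref = h_ref,
         p_grid = p_grid_pa, A = A, lambda_z = lambda_z,
         # per-cell inverse law p(A) and forward law A(p), linear interp on
         # the tabulated grid (monotone by construction)
         p_of_A = lapply(seq_len(n_x), function(i)
           stats::approxfun(A[, i], p_grid_pa, rule = 2)),
         A_of_p = lapply(seq_len(n_x), function(i)
           stats::approxfun(p_grid_pa, A[, i], rule = 2))),
    class = "tube_law"
  )
}

#' Quasi-1D pulsatile flow through the compliant vessel
#'
#' Integrates the one-dimensional mass and momentum balance of
#' incompressible flow in a distensible tube between prescribed inlet and
#' outlet pressure traces:
#' \deqn{\partial A/\partial t + \partial Q/\partial x = 0, \qquad
#'   \frac{\rho}{A}\,\partial Q/\partial t = -\partial p/\partial x
#'   - \frac{8\pi\mu Q}{A^2},}
#' with the local pressure-area relation supplied by [tube_law()] (the
#' fluid-structure coupling contract) and fully developed Poiseuille
#' friction. Convective acceleration is dropped (reduced model). The scheme
#' is a staggered-grid finite-volume update, conservative in area, with
#' semi-implicit friction and a CFL-limited time step from the tabulated
#' wave speed \eqn{c = \sqrt{A/(\rho\, dA/dp)}}. Runs `n_cycles` cardiac
#' cycles and returns the last one.
#'
#' With `rigid = TRUE` the cross-sections are frozen at the reference
#' geometry, the flow collapses to a single inertance-resistance balance
#' for the common flow rate, integrated exactly per step (exponential
#' update); in the steady constant-offset limit this reproduces Poiseuille
#' flow.
#'
#' @param params a [material_params()] object (ignored if `law` given).
#' @param geometry a [vessel_geometry()].
#' @param blood a [blood_properties()] object.
#' @param p_in,p_out inlet/outlet [scale_waveform()] traces sharing period
#'   and grid.
#' @param n_cycles number of cardiac cycles to integrate (default 5).
#' @param n_x axial cells (default 12).
#' @param law optional precomputed [tube_law()].
#' @param rigid logical; freeze the cross-sections.
#' @param lambda_z axial stretch for the tube law.
#' @param cfl CFL number (default 0.5).
#' @param wall_relaxation Kelvin-Voigt wall relaxation time, s (default
#'   5 ms, at the low end of reported large-artery wall viscoelastic
#'   relaxation times). A purely elastic tube between prescribed pressures
#'   is an undamped compliance-inertance oscillator whose ring-down far
#'   outlasts a few cardiac cycles; a small viscoelastic wall term damps it
#'   physically. Set 0 for a purely elastic wall.
#' @param max_steps_per_cycle refinement cap on the time step.
#' @return object of class `flow_state`: last-cycle time grid `t` (s),
#'   traces `inlet_velocity`, `outlet_velocity`, `mean_velocity` (mm/s),
#'   `Q_in`, `Q_out` (mm^3/s), `volume` (mm^3), and a `summary` list with
#'   cycle-averaged velocities, the instantaneous velocities at the
#'   systolic/diastolic instants (argmax/argmin of the inlet pressure),
#'   stroke volume, the cycle mass-balance error as a fraction of stroke
#'   volume, and the cycle-to-cycle periodicity error.
#' @export
solve_flow <- function(params, geometry, blood, p_in, p_out,
                       n_cycles = 5, n_x = 12, law = NULL, rigid = FALSE,
                       lambda_z = 1, cfl = 0.8, wall_relaxation = 0.005,
                       max_steps_per_cycle = 4e4) {
  if (abs(p_in$period - p_out$period) > 1e-12)
    stop("p_in and p_out must share the cardiac period")
  Tp <- p_in$period
  mu <- blood$viscosity * 1e-3          # cPoise -> Pa s
  rho <- blood$density * 1e-3           # g/cm^3 -> g/mm^3
  pin_f <- .waveform_fun(p_in)          # mmHg
  pout_f <- .waveform_fun(p_out)
  p_hi <- max(p_in$p, p_out$p)
  if (is.null(law)) {
    if (rigid) {
      rg <- geometry$rings
      L <- diff(range(rg$axial_position))
      n_xr <- n_x
      dx <- L / n_xr
      x <- min(rg$axial_position) + (seq_len(n_xr) - 0.5) * dx
      r_ref <- stats::approx(rg$axial_position, rg$inner_radius, xout = x)$y
      law <- list(x = x, dx = dx, length = L, n_x = n_xr,
                  A0 = pi * r_ref^2)
    } else {
      law <- tube_law(params, geometry, p_max_mmhg = 1.25 * p_hi + 10,
                      n_x = n_x, lambda_z = lambda_z)
    }
  }
  n_x <- law$n_x
  dx <- law$dx

  if (rigid) {
    A0 <- if (!is.null(law$A0)) law$A0 else law$A[1, ]
    return(.solve_flow_rigid(A0, dx, rho, mu, pin_f, pout_f, Tp, n_cycles))
  }

  # CFL from the tabulated wave speed at the top of the pressure range
  dAdp <- apply(law$A, 2, function(col) diff(col) / diff(law$p_grid))
  A_hi <- law$A[nrow(law$A), ]
  c_max <- max(sqrt(A_hi / (rho * pmin(apply(dAdp, 2, min), Inf))))
  n_steps <- ceiling(Tp / (cfl * dx / c_max))
  n_steps <- min(max(n_steps, 200), max_steps_per_cycle)
  dt <- Tp / n_steps

  mmhg <- 0.133322 * 1000               # mmHg -> Pa
  p <- rep(pin_f(0) * mmhg, n_x)        # cell-center pressures, Pa
  A <- vapply(seq_len(n_x), function(i) law$A_of_p[[i]](p[i]), numeric(1))
  # start from the quasi-steady Poiseuille through-flow for the cycle-mean
  # end-to-end gradient, with cross-sections at cycle-mean pressure: the
  # mean-flow mode relaxes on rho*A/(8*pi*mu) (seconds), far slower than a
  # few cardiac cycles, so it must be seeded rather than spun up
  tgrid <- seq(0, Tp, length.out = 257)[-257]
  p_mid <- (pin_f(tgrid) + pout_f(tgrid)) / 2 * mmhg
  dp_bar <- mean(pin_f(tgrid) - pout_f(tgrid)) * mmhg
  Ainv2 <- vapply(seq_len(n_x),
                  function(i) mean(law$A_of_p[[i]](p_mid)^-2), numeric(1))
  R_f0 <- 8 * pi * mu * dx * sum(Ainv2)
  Q <- rep(dp_bar / R_f0, n_x + 1)
  fric <- 8 * pi * mu
  tau_w <- wall_relaxation
  # per-cell compliance dA/dp at cycle-mean pressure (constant through the
  # step loop; only the damping magnitude depends on it)
  eps_p <- 5
  pm <- mean(p_mid)
  C_cell <- vapply(seq_len(n_x), function(i)
    (law$A_of_p[[i]](pm + eps_p) - law$A_of_p[[i]](pm - eps_p)) / (2 * eps_p),
    numeric(1))

  rec_u_in <- matrix(NA_real_, n_steps + 1, 2)   # last two cycles
  rec_u_out <- rec_umean <- rec_Qin <- rec_Qout <- rec_V <- rec_u_in
  total_steps <- n_cycles * n_steps
  rec_from <- total_steps - 2 * n_steps          # record last two cycles
  for (step in 0:(total_steps - 1)) {
    t_now <- step * dt
    # record state at the start of the step
    if (step >= rec_from) {
      k <- step - rec_from
      cyc <- k %/% n_steps + 1
      idx <- k %% n_steps + 1
      u_cells <- 0.5 * (Q[-1] + Q[-(n_x + 1)]) / A
      rec_u_in[idx, cyc] <- Q[1] / A[1]
      rec_u_out[idx, cyc] <- Q[n_x + 1] / A[n_x]
      rec_umean[idx, cyc] <- sum(u_cells * A) / sum(A)
      rec_Qin[idx, cyc] <- Q[1]
      rec_Qout[idx, cyc] <- Q[n_x + 1]
      rec_V[idx, cyc] <- sum(A) * dx
      if (idx == 1 && cyc > 1) {  # also close the previous cycle
        rec_u_in[n_steps + 1, cyc - 1] <- rec_u_in[1, cyc]
        rec_u_out[n_steps + 1, cyc - 1] <- rec_u_out[1, cyc]
        rec_umean[n_steps + 1, cyc - 1] <- rec_umean[1, cyc]
        rec_Qin[n_steps + 1, cyc - 1] <- rec_Qin[1, cyc]
        rec_Qout[n_steps + 1, cyc - 1] <- rec_Qout[1, cyc]
        rec_V[n_steps + 1, cyc - 1] <- rec_V[1, cyc]
      }
    }
    pb_in <- pin_f(t_now) * mmhg
    pb_out <- pout_f(t_now) * mmhg
    # interface areas and pressure gradients (ghost half-cells at the ends)
    A_f <- c(A[1], 0.5 * (A[-1] + A[-n_x]), A[n_x])
    dpdx <- c((p[1] - pb_in) / (dx / 2),
              diff(p) / dx,
              (pb_out - p[n_x]) / (dx / 2))
    rhs <- Q - dt * A_f / rho * dpdx
    diag_v <- 1 + dt * fric / (rho * A_f)
    if (tau_w > 0) {
      # Kelvin-Voigt wall viscoelasticity: the momentum balance sees
      # p_el + tau_w dp_el/dt; with dp_el/dt = -(dQ/dx)/C from mass
      # conservation this is a diffusion of Q, treated implicitly
      # (tridiagonal) because its explicit stability limit is far below
      # the CFL step
      k <- dt * A_f * tau_w / (rho * dx^2)
      lower <- upper <- rep(0, n_x + 1)
      j <- 2:n_x
      lower[j] <- -k[j] / C_cell[j - 1]
      upper[j] <- -k[j] / C_cell[j]
      diag_v[j] <- diag_v[j] + k[j] * (1 / C_cell[j - 1] + 1 / C_cell[j])
      # boundary rows: dp/dt at the ends is the prescribed trace rate
      dpin_dt <- (pin_f(t_now + dt) - pin_f(t_now)) / dt * mmhg
      dpout_dt <- (pout_f(t_now + dt) - pout_f(t_now)) / dt * mmhg
      diag_v[1] <- diag_v[1] + 2 * k[1] / C_cell[1]
      upper[1] <- -2 * k[1] / C_cell[1]
      rhs[1] <- rhs[1] + dt * 2 * A_f[1] * tau_w / (rho * dx) * dpin_dt
      nn <- n_x + 1
      diag_v[nn] <- diag_v[nn] + 2 * k[nn] / C_cell[n_x]
      lower[nn] <- -2 * k[nn] / C_cell[n_x]
      rhs[nn] <- rhs[nn] - dt * 2 * A_f[nn] * tau_w / (rho * dx) * dpout_dt
      Q <- .thomas(lower, diag_v, upper, rhs)
    } else {
      Q <- rhs / diag_v
    }
    A <- A - dt * diff(Q) / dx
    if (any(A <= 0)) stop("structural range error: negative area at step ", step)
    for (i in seq_len(n_x)) p[i] <- law$p_of_A[[i]](A[i])
  }
  # close the final cycle with one more state evaluation
  u_cells <- 0.5 * (Q[-1] + Q[-(n_x + 1)]) / A
  rec_u_in[n_steps + 1, 2] <- Q[1] / A[1]
  rec_u_out[n_steps + 1, 2] <- Q[n_x + 1] / A[n_x]
  rec_umean[n_steps + 1, 2] <- sum(u_cells * A) / sum(A)
  rec_Qin[n_steps + 1, 2] <- Q[1]
  rec_Qout[n_steps + 1, 2] <- Q[n_x + 1]
  rec_V[n_steps + 1, 2] <- sum(A) * dx

  tt <- seq(0, Tp, length.out = n_steps + 1)
  .flow_state(tt, dt, pin_f, rec_u_in, rec_u_out, rec_umean,
              rec_Qin, rec_Qout, rec_V, n_steps)
}

# tridiagonal solve (Thomas algorithm); lower[1] and upper[n] unused
.thomas <- function(lower, diag_v, upper, rhs) {
  n <- length(rhs)
  cp <- numeric(n)
  dp <- numeric(n)
  cp[1] <- upper[1] / diag_v[1]
  dp[1] <- rhs[1] / diag_v[1]
  for (i in 2:n) {
    m <- diag_v[i] - lower[i] * cp[i - 1]
    cp[i] <- upper[i] / m
    dp[i] <- (rhs[i] - lower[i] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# rigid-tube limit: single flow rate, inertance-resistance ODE integrated
# with an exact exponential update per step
.solve_flow_rigid <- function(A0, dx, rho, mu, pin_f, pout_f, Tp, n_cycles) {
  n_x <- length(A0)
  L_in <- rho * sum(dx / A0)            # inertance
  R_f <- 8 * pi * mu * sum(dx / A0^2)   # resistance
  n_steps <- 2000
  dt <- Tp / n_steps
  mmhg <- 0.133322 * 1000
  ef <- exp(-R_f * dt / L_in)
  # exact periodic steady state of the linear inertance-resistance ODE:
  # one warmup cycle from rest gives the cycle map Q_T = alpha*Q_0 + beta
  Q <- 0
  for (step in 0:(n_steps - 1)) {
    dp <- (pin_f(step * dt) - pout_f(step * dt)) * mmhg
    Q <- Q * ef + dp / R_f * (1 - ef)
  }
  alpha <- ef^n_steps
  Q <- Q / (1 - alpha)
  rec_Q <- matrix(NA_real_, n_steps + 1, 2)
  total <- max(n_cycles - 1, 2) * n_steps
  rec_from <- total - 2 * n_steps
  for (step in 0:(total - 1)) {
    if (step >= rec_from) {
      k <- step - rec_from
      rec_Q[k %% n_steps + 1, k %/% n_steps + 1] <- Q
    }
    dp <- (pin_f(step * dt) - pout_f(step * dt)) * mmhg
    Q <- Q * ef + dp / R_f * (1 - ef)
  }
  rec_Q[n_steps + 1, 2] <- Q
  rec_Q[n_steps + 1, 1] <- rec_Q[1, 2]
  tt <- seq(0, Tp, length.out = n_steps + 1)
  Vtot <- sum(A0) * dx
  u_in <- rec_Q / A0[1]
  u_out <- rec_Q / A0[n_x]
  umean <- rec_Q * n_x * dx / Vtot      # volume-weighted mean of Q/A
  .flow_state(tt, dt, pin_f, u_in, u_out, umean, rec_Q, rec_Q,
              rec_Q * 0 + Vtot, n_steps)
}

.flow_state <- function(tt, dt, pin_f, u_in, u_out, umean,
                        Qin, Qout, V, n_steps) {
  pin_trace <- pin_f(tt)
  i_sys <- which.max(pin_trace)
  i_dia <- which.min(pin_trace)
  last <- 2
  # trapezoid cycle averages over the closed last cycle
  cyc_avg <- function(v) {
    n <- length(v)
    sum((v[-1] + v[-n]) / 2) / (n - 1)
  }
  stroke <- sum(pmax((Qin[-1, last] + Qin[-nrow(Qin), last]) / 2, 0)) * dt
  net_in <- cyc_avg(Qin[, last] - Qout[, last]) * (tt[length(tt)] - tt[1])
  dV <- V[nrow(V), last] - V[1, last]
  scale_u <- max(abs(u_in), 1e-12)
  periodicity <- max(abs(u_in[, 2] - u_in[, 1])) / scale_u
  structure(
    list(t = tt, dt = dt,
         inlet_velocity = u_in[, last],
         outlet_velocity = u_out[, last],
         mean_velocity = umean[, last],
         Q_in = Qin[, last], Q_out = Qout[, last],
         volume = V[, last],
         inlet_pressure = pin_trace,
         summary = list(
           mean_inlet_velocity = cyc_avg(u_in[, last]),
           mean_mean_velocity = cyc_avg(umean[, last]),
           inlet_velocity_systolic = u_in[i_sys, last],
           inlet_velocity_diastolic = u_in[i_dia, last],
           mean_velocity_systolic = umean[i_sys, last],
           mean_velocity_diastolic = umean[i_dia, last],
           stroke_volume = stroke,
           mass_balance_error = if (stroke > 0)
             abs(net_in - dV) / stroke else abs(net_in - dV),
           periodicity_error = periodicity,
           n_steps_per_cycle = n_steps)),
    class = "flow_state"
  )
}

#' @export
print.flow_state <- function(x, ...) {
  s <- x$summary
  cat(sprintf("flow_state: %d steps/cycle\n", s$n_steps_per_cycle))
  cat(sprintf("  inlet velocity: cycle mean %.4g mm/s, systolic %.4g, diastolic %.4g\n",
              s$mean_inlet_velocity, s$inlet_velocity_systolic,
              s$inlet_velocity_diastolic))
  cat(sprintf("  mean velocity:  cycle mean %.4g mm/s, systolic %.4g, diastolic %.4g\n",
              s$mean_mean_velocity, s$mean_velocity_systolic,
              s$mean_velocity_diastolic))
  cat(sprintf("  stroke volume %.4g mm^3; mass balance error %.3g; periodicity %.3g\n",
              s$stroke_volume, s$mass_balance_error, s$periodicity_error))
  invisible(x)
}
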