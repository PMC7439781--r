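#' Axisymmetric vessel geometry
#'
#' A vessel is represented as an ordered stack of axisymmetric rings, each
#' with an axial position (mm), inner radius (mm) and wall thickness (mm).
#' The `configuration` label records which mechanical state the radii
#' describe: the zero-load (unpressurised) state, or the in vivo diastolic
#' or systolic state. Wall thickness defaults to 2 mm, the uniform value
#' used when patient-specific wall thickness cannot be imaged.
#'
#' @param axial_position strictly increasing numeric vector, mm.
#' @param inner_radius positive numeric vector, mm.
#' @param wall_thickness positive numeric vector or scalar, mm.
#' @param configuration one of `"zero_load"`, `"diastolic"`, `"systolic"`.
#' @param tissue_density solid density, g/cm^3. Recorded for completeness;
#'   the quasi-static structural reduction drops inertia, so it does not
#'   enter the solve.
#' @return an object of class `vessel_geometry`.
#' @examples
#' geom <- vessel_geometry(seq(0, 60, by = 5), inner_radius = 12.5)
#' lumen_volume(geom)
#' @export
vessel_geometry <- function(axial_position, inner_radius, wall_thickness = 2.0,
                            configuration = c("zero_load", "diastolic", "systolic"),
                            tissue_density = 1.06) {
  configuration <- match.arg(configuration)
  n <- length(axial_position)
  if (n < 2) stop("need at least 2 rings")
  if (any(diff(axial_position) <= 0))
    stop("axial positions must be strictly increasing")
  inner_radius <- rep_len(inner_radius, n)
  wall_thickness <- rep_len(wall_thickness, n)
  if (any(inner_radius <= 0)) stop("inner radii must be positive")
  if (any(wall_thickness <= 0)) stop("wall thickness must be positive")
  structure(
    list(rings = data.frame(axial_position = axial_position,
                            inner_radius = inner_radius,
                            wall_thickness = wall_thickness),
         configuration = configuration,
         tissue_density = tissue_density),
    class = "vessel_geometry"
  )
}

#' @export
print.vessel_geometry <- function(x, ...) {
  r <- x$rings
  cat(sprintf("vessel_geometry: %d rings over %.1f mm (%s configuration)\n",
              nrow(r), diff(range(r$axial_position)), x$configuration))
  cat(sprintf("  inner radius %.2f-%.2f mm, wall %.2f-%.2f mm\n",
              min(r$inner_radius), max(r$inner_radius),
              min(r$wall_thickness), max(r$wall_thickness)))
  invisible(x)
}

#' Lumen volume by frustum quadrature
#'
#' Volume enclosed by the inner surface, computed ring-to-ring as conical
#' frusta: \eqn{V = \sum \pi \Delta z (r_1^2 + r_1 r_2 + r_2^2)/3}. Exact
#' for piecewise-linear radius profiles, in particular for straight
#' cylinders.
#'
#' @param geometry a [vessel_geometry()], or a numeric vector of inner radii
#'   with `axial_position` supplied.
#' @param axial_position optional axial grid when `geometry` is a vector.
#' @return volume in mm^3.
#' @export
lumen_volume <- function(geometry, axial_position = NULL) {
  if (inherits(geometry, "vessel_geometry")) {
    r <- geometry$rings$inner_radius
    z <- geometry$rings$axial_position
  } else {
    r <- geometry
    z <- axial_position
    if (is.null(z)) stop("axial_position required for a bare radius vector")
  }
  dz <- diff(z)
  r1 <- r[-length(r)]
  r2 <- r[-1]
  sum(pi * dz * (r1^2 + r1 * r2 + r2^2) / 3)
}

# uniform radial rescale of all ring radii (thickness preserved)
.scale_geometry <- function(geometry, factor,
                            configuration = geometry$configuration) {
  vessel_geometry(geometry$rings$axial_position,
                  geometry$rings$inner_radius * factor,
                  geometry$rings$wall_thickness,
                  configuration = configuration,
                  tissue_density = geometry$tissue_density)
}

# 16-point Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch)
.gauss_legendre <- function(n = 16) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  E <- eigen(J, symmetric = TRUE)
  ord <- order(E$values)
  list(x = E$values[ord], w = 2 * E$vectors[1, ord]^2)
}

.GL16 <- .gauss_legendre(16)

# Pressure integral for an incompressible inflation of one ring:
# reference radii A..B, deformed inner radius a, axial stretch lz.
# r(R)^2 = a^2 + (R^2 - A^2)/lz;  P = int_A^B dtheta(r/R) * R/(lz r^2) dR (kPa)
.ring_pressure <- function(params, A, B, a, lambda_z, quad = .GL16) {
  R <- (B - A) / 2 * quad$x + (A + B) / 2
  w <- (B - A) / 2 * quad$w
  r2 <- a^2 + (R^2 - A^2) / lambda_z
  lt <- sqrt(r2) / R
  d <- stress_difference(params, lt, lambda_z)
  sum(w * d$dtheta * R / (lambda_z * r2))
}

# deformed inner radius of one ring: root of the pressure integral
.ring_radius <- function(params, A, B, pressure, lambda_z) {
  if (pressure == 0 && lambda_z == 1) return(A)
  f <- function(a) .ring_pressure(params, A, B, a, lambda_z) - pressure
  lo <- 0.5 * A
  hi <- 1.05 * A
  flo <- f(lo)
  fhi <- f(hi)
  while (flo * fhi > 0 && hi < 6 * A) {
    lo <- hi
    flo <- fhi
    hi <- hi * 1.25
    fhi <- f(hi)
  }
  if (flo * fhi > 0)
    stop(sprintf(
      "no convergence: pressure %.4g kPa outside material range (bracket %.3g-%.3g mm, residuals %.3g / %.3g)",
      pressure, lo, hi, flo, fhi))
  stats::uniroot(f, c(lo, hi), tol = 1e-10 * A)$root
}

#' Inflate one thick-walled ring
#'
#' Solves the incompressible inflation-extension of a single thick-walled
#' ring under internal gauge pressure. The incompressible map
#' \eqn{r(R)^2 = a^2 + (R^2 - A^2)/\lambda_z} reduces quasi-static radial
#' equilibrium to a single scalar equation for the deformed inner radius
#' \eqn{a}:
#' \deqn{P = \int_a^b (\sigma_{\theta\theta} - \sigma_{rr}) \frac{dr}{r},}
#' evaluated by 16-point Gauss-Legendre quadrature over the reference wall
#' and solved to 1e-10 relative tolerance. The transmural radial stress is
#' reconstructed by integrating the equilibrium equation inward from the
#' traction-free outer surface, so \eqn{\sigma_{rr}(b) = 0} and
#' \eqn{\sigma_{rr}(a) = -P}. Principal axes coincide with the cylindrical
#' axes in this reduction, so the maximal principal stress at each sample is
#' `max(sigma_rr, sigma_tt, sigma_zz)`.
#'
#' @param params a [material_params()] object.
#' @param ref_inner_radius reference inner radius A, mm.
#' @param thickness reference wall thickness, mm.
#' @param pressure internal gauge pressure, kPa (>= 0).
#' @param lambda_z axial stretch, default 1 (no axial pre-stretch).
#' @return list with `inner_radius` (deformed, mm), `outer_radius`,
#'   `pressure`, and `samples`: a data.frame of quadrature samples with
#'   reference radius `R`, deformed radius `r`, stretches, stresses
#'   `sigma_rr`, `sigma_tt`, `sigma_zz` (kPa) and `stress_p1`.
#' @export
inflate_ring <- function(params, ref_inner_radius, thickness, pressure,
                         lambda_z = 1) {
  if (pressure < 0) stop("pressure must be a nonnegative gauge pressure")
  if (lambda_z <= 0) stop("invalid kinematics: lambda_z must be positive")
  A <- ref_inner_radius
  B <- A + thickness
  a <- .ring_radius(params, A, B, pressure, lambda_z)
  quad <- .GL16
  # transmural samples: both wall surfaces plus the 16 interior Gauss nodes
  R <- c(A, (B - A) / 2 * quad$x + (A + B) / 2, B)
  w <- c(0, (B - A) / 2 * quad$w, 0)
  r <- sqrt(a^2 + (R^2 - A^2) / lambda_z)
  lt <- r / R
  d <- stress_difference(params, lt, lambda_z)
  # sigma_rr(R_k) = -int_{R_k}^{B} dtheta * R/(lz r^2) dR, fresh 16-pt rule
  # per subinterval so boundary values hold to quadrature accuracy
  sig_rr <- vapply(R, function(Rk) {
    if (Rk >= B) return(0)
    Rq <- (B - Rk) / 2 * quad$x + (Rk + B) / 2
    wq <- (B - Rk) / 2 * quad$w
    r2q <- a^2 + (Rq^2 - A^2) / lambda_z
    dq <- stress_difference(params, sqrt(r2q) / Rq, lambda_z)
    -sum(wq * dq$dtheta * Rq / (lambda_z * r2q))
  }, numeric(1))
  sig_tt <- sig_rr + d$dtheta
  sig_zz <- sig_rr + d$dz
  samples <- data.frame(
    R = R, r = r, weight = w,
    lambda_theta = lt, lambda_z = lambda_z,
    sigma_rr = sig_rr, sigma_tt = sig_tt, sigma_zz = sig_zz,
    stress_p1 = pmax(sig_rr, sig_tt, sig_zz)
  )
  list(inner_radius = a,
       outer_radius = sqrt(a^2 + (B^2 - A^2) / lambda_z),
       pressure = pressure,
       lambda_z = lambda_z,
       samples = samples)
}

#' Solve the vessel wall under uniform internal pressure
#'
#' Ring-by-ring incompressible inflation of the whole vessel via
#' [inflate_ring()], followed by summary metrics: per-ring deformed radii,
#' radial displacement of every wall sample relative to the reference
#' geometry, transmural stress samples, mean/max displacement, mean/max
#' maximal principal stress (plain average over all rings and quadrature
#' points), and the deformed lumen volume by frustum quadrature.
#'
#' @param params a [material_params()] object.
#' @param geometry a [vessel_geometry()] (its radii are taken as the
#'   unstressed reference configuration for this solve).
#' @param pressure internal gauge pressure, kPa.
#' @param lambda_z axial stretch, default 1.
#' @return an object of class `deformed_state`: list with `rings`
#'   (data.frame: axial_position, reference and deformed inner radius,
#'   deformed thickness), `samples` (all transmural samples with ring
#'   index), `summary` (mean/max displacement mm, mean/max stress-P1 kPa,
#'   lumen_volume mm^3), plus the inputs.
#' @export
solve_vessel <- function(params, geometry, pressure, lambda_z = 1) {
  rg <- geometry$rings
  sols <- vector("list", nrow(rg))
  for (i in seq_len(nrow(rg))) {
    sols[[i]] <- tryCatch(
      inflate_ring(params, rg$inner_radius[i], rg$wall_thickness[i],
                   pressure, lambda_z),
      error = function(e) stop("ring ", i, ": ", conditionMessage(e)))
  }
  a_def <- vapply(sols, `[[`, numeric(1), "inner_radius")
  b_def <- vapply(sols, `[[`, numeric(1), "outer_radius")
  samples <- do.call(rbind, lapply(seq_along(sols), function(i) {
    s <- sols[[i]]$samples
    s$ring <- i
    s$displacement <- s$r - s$R
    s
  }))
  vol <- lumen_volume(a_def, rg$axial_position)
  structure(
    list(
      rings = data.frame(axial_position = rg$axial_position,
                         ref_inner_radius = rg$inner_radius,
                         inner_radius = a_def,
                         wall_thickness = b_def - a_def),
      samples = samples,
      pressure = pressure,
      lambda_z = lambda_z,
      reference = geometry,
      summary = list(
        mean_displacement = mean(abs(samples$displacement)),
        max_displacement = max(abs(samples$displacement)),
        mean_stress_p1 = mean(samples$stress_p1),
        max_stress_p1 = max(samples$stress_p1),
        lumen_volume = vol
      )
    ),
    class = "deformed_state"
  )
}

#' @export
print.deformed_state <- function(x, ...) {
  s <- x$summary
  cat(sprintf("deformed_state at %.3g kPa (%.1f mmHg): %d rings\n",
              x$pressure, kpa_to_mmhg(x$pressure), nrow(x$rings)))
  cat(sprintf("  displacement mean %.4g / max %.4g mm; stress-P1 mean %.4g / max %.4g kPa\n",
              s$mean_displacement, s$max_displacement,
              s$mean_stress_p1, s$max_stress_p1))
  cat(sprintf("  lumen volume %.5g mm^3\n", s$lumen_volume))
  invisible(x)
}

#' Displacement between two deformed configurations
#'
#' Radial displacement magnitudes of every wall sample point between two
#' states solved from the same reference geometry (e.g. diastolic to
#' systolic). Returns the mean and maximum over all samples.
#'
#' @param state_low,state_high [solve_vessel()] results sharing a reference.
#' @return named numeric vector `c(mean, max)`, mm.
#' @export
displacement_metrics <- function(state_low, state_high) {
  if (nrow(state_low$rings) != nrow(state_high$rings) ||
      nrow(state_low$samples) != nrow(state_high$samples))
    stop("incompatible states: ring/sample counts differ")
  d <- abs(state_high$samples$r - state_low$samples$r)
  c(mean = mean(d), max = max(d))
}
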