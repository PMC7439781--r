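test_that("unpressurised ring is undeformed and stress-free", {
  mp <- material_params()
  sol <- inflate_ring(mp, 12, 2, pressure = 0)
  expect_equal(sol$inner_radius, 12)
  expect_equal(max(abs(sol$samples$sigma_rr)), 0)
  expect_equal(max(abs(sol$samples$sigma_tt)), 0)
  expect_equal(max(abs(sol$samples$sigma_zz)), 0)
})

test_that("inflated ring satisfies the pressure integral and tractions", {
  mp <- material_params()
  P <- mmhg_to_kpa(95)
  sol <- inflate_ring(mp, 12, 2, P)
  # fixed-point residual: the pressure integral at the returned radius
  P_back <- aortafsi:::.ring_pressure(mp, 12, 14, sol$inner_radius, 1)
  expect_lt(abs(P_back / P - 1), 1e-8)
  # traction boundary conditions at the wall surfaces
  s <- sol$samples
  expect_lt(abs(s$sigma_rr[1] + P), 1e-6)
  expect_lt(abs(s$sigma_rr[nrow(s)]), 1e-6)
  # radial equilibrium: d(sigma_rr)/dr = (sigma_tt - sigma_rr)/r between
  # adjacent transmural samples, to quadrature accuracy
  for (k in seq_len(nrow(s) - 1)) {
    lhs <- s$sigma_rr[k + 1] - s$sigma_rr[k]
    dth <- (s$sigma_tt - s$sigma_rr) / s$r
    rhs <- (dth[k] + dth[k + 1]) / 2 * (s$r[k + 1] - s$r[k])
    expect_lt(abs(lhs - rhs), 0.05 * max(1, abs(lhs)))
  }
})

test_that("wall is incompressible and response monotone in pressure", {
  mp <- material_params()
  lz <- 1.1
  A <- 11; h <- 2; B <- A + h
  prev <- 0
  for (P in mmhg_to_kpa(c(20, 60, 100, 140))) {
    sol <- inflate_ring(mp, A, h, P, lambda_z = lz)
    a <- sol$inner_radius
    b <- sol$outer_radius
    # deformed wall area x lambda_z = reference wall area
    expect_lt(abs((b^2 - a^2) * lz / (B^2 - A^2) - 1), 1e-8)
    expect_gt(a, prev)
    prev <- a
  }
})

test_that("thin-walled isotropic ring reproduces the Laplace law", {
  iso <- material_params(c1 = 50, c2 = 20, D1 = 1e-6, D2 = 3.5,
                         K1 = 0, K2 = 12.6, check_stability = FALSE)
  a_ref <- 10; h_ref <- 0.1
  P <- 0.2 # kPa, small
  sol <- inflate_ring(iso, a_ref, h_ref, P)
  s <- sol$samples
  # volume-weighted transmural mean hoop stress vs P a / h (deformed)
  w <- s$weight * s$R / s$r
  mean_hoop <- sum(w * s$sigma_tt) / sum(w)
  laplace <- P * sol$inner_radius / (sol$outer_radius - sol$inner_radius)
  expect_lt(abs(mean_hoop / laplace - 1), 0.01)
})

test_that("vessel solve aggregates rings with symmetry and exact volumes", {
  mp <- material_params()
  cyl <- cylinder_geometry(radius = 10, length = 60, n_rings = 7)
  expect_equal(lumen_volume(cyl), pi * 100 * 60, tolerance = 1e-12)
  st0 <- solve_vessel(mp, cyl, 0)
  expect_equal(st0$summary$lumen_volume, pi * 100 * 60, tolerance = 1e-12)

  st <- solve_vessel(mp, cyl, mmhg_to_kpa(80))
  # uniform cylinder: every ring identical (radii and transmural profiles)
  expect_lt(diff(range(st$rings$inner_radius)), 1e-10)
  ring_max <- tapply(abs(st$samples$displacement), st$samples$ring, max)
  expect_lt(diff(range(ring_max)), 1e-10)
  expect_gte(st$summary$max_displacement, st$summary$mean_displacement)
})

test_that("stress summaries converge under axial refinement", {
  mp <- material_params()
  tapered <- function(n) {
    z <- seq(0, 60, length.out = n)
    vessel_geometry(z, 13 - 0.04 * z, 2)
  }
  P <- mmhg_to_kpa(100)
  s1 <- solve_vessel(mp, tapered(8), P)$summary
  s2 <- solve_vessel(mp, tapered(16), P)$summary
  expect_lt(abs(s2$mean_stress_p1 / s1$mean_stress_p1 - 1), 0.02)
  expect_lt(abs(s2$max_stress_p1 / s1$max_stress_p1 - 1), 0.02)
})

test_that("displacement metrics are exact for simple fields", {
  mp <- material_params()
  cyl <- cylinder_geometry()
  st_a <- solve_vessel(mp, cyl, mmhg_to_kpa(60))
  expect_equal(unname(displacement_metrics(st_a, st_a)), c(0, 0))

  st_b <- st_a
  st_b$samples$r <- st_a$samples$r + 0.1
  expect_equal(unname(displacement_metrics(st_a, st_b)), c(0.1, 0.1),
               tolerance = 1e-12)

  st_c <- solve_vessel(mp, cylinder_geometry(n_rings = 9), mmhg_to_kpa(60))
  expect_error(displacement_metrics(st_a, st_c), "incompatible")

  # bookkeeping oracle: metrics equal direct recomputation from stored radii
  st_d <- solve_vessel(mp, cyl, mmhg_to_kpa(100))
  m <- displacement_metrics(st_a, st_d)
  d <- abs(st_d$samples$r - st_a$samples$r)
  expect_equal(unname(m), c(mean(d), max(d)))
})

test_that("geometry constructor validates and scales", {
  expect_error(vessel_geometry(c(0, 0, 10), 10), "increasing")
  expect_error(vessel_geometry(c(0, 10), -1), "positive")
  g <- vessel_geometry(c(0, 30, 60), c(10, 11, 12))
  gs <- aortafsi:::.scale_geometry(g, 0.95)
  expect_equal(gs$rings$inner_radius, c(10, 11, 12) * 0.95)
  expect_equal(gs$rings$wall_thickness, g$rings$wall_thickness)
})
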