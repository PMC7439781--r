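test_that("strain invariants match the defining formulas", {
  iv <- strain_invariants(diag(3), c(1, 0, 0))
  expect_equal(unname(iv), c(3, 3, 1))

  C <- diag(c(1.44, 1, 0.694444))
  iv <- strain_invariants(C, c(1, 0, 0))
  expect_equal(iv[["I1"]], 3.134444, tolerance = 1e-12)
  expect_equal(iv[["I4"]], 1.44, tolerance = 1e-12)
  expect_equal(unname(iv), unname(brute_invariants(C, c(1, 0, 0))),
               tolerance = 1e-12)

  # eigenvalue oracle for volume-preserving deformations
  set.seed(11)
  for (k in 1:10) {
    X <- random_unimodular()
    C <- t(X) %*% X
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    iv <- strain_invariants(C, c(0, 1, 0))
    expect_equal(iv[["I1"]], sum(ev), tolerance = 1e-10)
    expect_equal(iv[["I2"]], ev[1] * ev[2] + ev[1] * ev[3] + ev[2] * ev[3],
                 tolerance = 1e-10)
  }
})

test_that("strain invariants are frame-indifferent and reject bad kinematics", {
  set.seed(12)
  C <- t(random_unimodular()) %*% random_unimodular()
  C <- (C + t(C)) / 2
  n <- c(0, 1, 0)
  iv <- strain_invariants(C, n)
  for (k in 1:5) {
    Q <- random_rotation()
    expect_equal(strain_invariants(Q %*% C %*% t(Q), drop(Q %*% n)), iv,
                 tolerance = 1e-9)
  }
  bad <- diag(3)
  bad[1, 2] <- 0.5
  expect_error(strain_invariants(bad, n), "symmetric")
  expect_error(strain_invariants(diag(c(1, 1, -1)), n), "positive definite")
})

test_that("strain energy evaluates the four-term expression", {
  mp <- material_params()
  expect_identical(strain_energy(mp, diag(3)), 0)

  C <- diag(c(1.44, 1, 0.694444))
  iv <- strain_invariants(C, c(1, 0, 0))
  expect_equal(strain_energy(material_params(fiber_direction = c(1, 0, 0)), C),
               brute_energy(mp, iv[["I1"]], iv[["I2"]], iv[["I4"]]),
               tolerance = 1e-12)

  # linearity in the stress-dimensioned constants
  for (r in c(0.25, 2, 7.5)) {
    expect_equal(strain_energy(scale_params(mp, r), C),
                 r * strain_energy(mp, C), tolerance = 1e-12)
  }
  # exponential overflow is reported, not returned as Inf
  expect_error(strain_energy(mp, diag(c(400, 1, 1 / 400))), "out-of-range")
})

test_that("stress differences match finite differences of the energy", {
  mp <- material_params()
  d0 <- stress_difference(mp, 1, 1)
  expect_equal(d0$dtheta, 0, tolerance = 1e-12)
  expect_equal(d0$dz, 0, tolerance = 1e-12)

  for (lt in seq(0.8, 1.3, by = 0.1)) {
    for (lz in c(0.8, 1, 1.15, 1.3)) {
      an <- stress_difference(mp, lt, lz)
      fd <- fd_stress_difference(mp, lt, lz)
      scale <- max(abs(unlist(an)), 1)
      expect_lt(abs(an$dtheta - fd[["dtheta"]]) / scale, 1e-5)
      expect_lt(abs(an$dz - fd[["dz"]]) / scale, 1e-5)
    }
  }
  expect_error(stress_difference(mp, -1, 1), "positive")
})

test_that("single-ratio scaling acts on the stress-dimensioned constants only", {
  mp <- material_params()
  same <- scale_params(mp, 1)
  expect_equal(same[c("c1", "c2", "D1", "D2", "K1", "K2")],
               mp[c("c1", "c2", "D1", "D2", "K1", "K2")])
  p2 <- scale_params(mp, 2)
  expect_equal(p2$c1, -1050.32)
  expect_equal(p2$K1, 66.8)
  expect_equal(p2$D2, mp$D2)
  expect_equal(p2$K2, mp$K2)
  d1 <- stress_difference(mp, 1.12, 1.05)
  d2 <- stress_difference(p2, 1.12, 1.05)
  expect_equal(d2$dtheta, 2 * d1$dtheta, tolerance = 1e-14)
  expect_equal(d2$dz, 2 * d1$dz, tolerance = 1e-14)
  expect_error(scale_params(mp, 0), "positive")
  expect_error(scale_params(mp, -1), "positive")
})

test_that("uniaxial stability check warns on destabilised parameter sets", {
  expect_true(is_uniaxially_stable(material_params()))
  expect_warning(
    material_params(c1 = -525.16, D1 = 50, K1 = 0.1),
    "incremental uniaxial stiffness")
  expect_silent(material_params())
})

test_that("baseline fitting recovers parameters from uniaxial data", {
  truth <- material_params()
  l <- seq(1.0, 1.25, length.out = 25)
  sig <- aortafsi:::.uniaxial_stress(truth, l)
  dat <- data.frame(stretch = l, stress = sig)
  init <- scale_params(truth, 1.25)
  fit <- fit_baseline_params(dat, init = init)
  expect_gt(fit$r_squared, 0.999)
  for (f in c("c1", "c2", "D1", "K1"))
    expect_lt(abs(fit$params[[f]] / truth[[f]] - 1), 0.01)

  expect_error(fit_baseline_params(data.frame(stretch = l, stress = 0 * l)),
               "degenerate")
  expect_error(fit_baseline_params(dat[1:4, ]), "at least 6")

  set.seed(3)
  noisy <- data.frame(stretch = l, stress = sig * (1 + rnorm(25, 0, 0.1)))
  fitn <- fit_baseline_params(noisy, init = init)
  expect_lt(fitn$r_squared, 1)
  resid <- noisy$stress - aortafsi:::.uniaxial_stress(fitn$params, l)
  expect_lt(abs(cor(resid, l)), 0.5)
})
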