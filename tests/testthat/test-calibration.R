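test_that("preshrink recovers a manufactured zero-load geometry", {
  mp <- material_params()
  true_zero <- cylinder_geometry(radius = 11.5, length = 60, n_rings = 7)
  dbp <- 70
  st <- solve_vessel(mp, true_zero, mmhg_to_kpa(dbp))
  invivo <- vessel_geometry(st$rings$axial_position, st$rings$inner_radius,
                            st$rings$wall_thickness,
                            configuration = "diastolic")
  ps <- preshrink(invivo, dbp, mp)
  expect_true(ps$result$converged)
  expect_lt(ps$result$achieved_rel_error, 0.05)
  expect_lt(max(abs(ps$geometry$rings$inner_radius /
                      true_zero$rings$inner_radius - 1)), 0.01)
  # re-evaluate the contract from scratch
  v <- solve_vessel(mp, ps$geometry, mmhg_to_kpa(dbp))$summary$lumen_volume
  expect_lt(abs(v / lumen_volume(invivo) - 1), 0.05)
})

test_that("preshrink limits: no load and rigid wall need no shrink", {
  mp <- material_params()
  geom <- cylinder_geometry(radius = 12, configuration = "diastolic")
  ps0 <- preshrink(geom, 0, mp)
  expect_equal(ps0$result$value, 0)

  rigid <- scale_params(mp, 1e6)
  psr <- preshrink(geom, 80, rigid)
  expect_lt(psr$result$value, 0.5) # shrink in percent
})

test_that("stiffness-ratio calibration recovers hidden ratios bidirectionally", {
  mp <- material_params()
  g0 <- cylinder_geometry(radius = 11, length = 60, n_rings = 7)
  sbp <- 110
  for (r_true in c(1.3, 0.5)) {
    v_target <- solve_vessel(scale_params(mp, r_true), g0,
                             mmhg_to_kpa(sbp))$summary$lumen_volume
    cm <- calibrate_material(g0, mp, sbp, v_target)
    expect_true(cm$result$converged)
    expect_lt(abs(cm$result$value / r_true - 1), 0.02)
  }
  # target at baseline stiffness returns ratio 1
  v1 <- solve_vessel(mp, g0, mmhg_to_kpa(sbp))$summary$lumen_volume
  cm1 <- calibrate_material(g0, mp, sbp, v1)
  expect_lt(abs(cm1$result$value - 1), 0.02)
  # target below the reference volume is infeasible
  expect_error(calibrate_material(g0, mp, sbp, lumen_volume(g0) * 0.9),
               "infeasible")
})

test_that("outlet calibration recovers a hidden offset and responds to viscosity", {
  mp <- material_params()
  g0 <- cylinder_geometry(radius = 10, length = 60, n_rings = 3)
  tmpl <- waveform_template()
  p_in <- scale_waveform(tmpl, 108, 62)
  blood <- blood_properties(4)
  law <- tube_law(mp, g0, p_max_mmhg = 1.25 * 108 + 10, n_x = 8)
  delta_true <- 0.03
  u_meas <- solve_flow(mp, g0, blood, p_in,
                       aortafsi:::.shift_waveform(p_in, delta_true),
                       n_cycles = 3, n_x = 8,
                       law = law)$summary$mean_inlet_velocity
  co <- calibrate_outlet(p_in, u_meas, mp, g0, blood, n_cycles = 3,
                         n_x = 8, law = law)
  expect_true(co$result$converged)
  expect_lt(co$result$achieved_rel_error, 0.05)
  expect_lt(abs(co$delta_mmhg / delta_true - 1), 0.05)

  co0 <- calibrate_outlet(p_in, 0, mp, g0, blood, law = law)
  expect_equal(co0$delta_mmhg, 0)

  # doubling viscosity needs a larger offset for the same measurement
  co2 <- calibrate_outlet(p_in, u_meas, mp, g0, blood_properties(8),
                          n_cycles = 3, n_x = 8, law = law)
  expect_gt(co2$delta_mmhg, co$delta_mmhg)
})

test_that("calibration is deterministic and traces are written", {
  mp <- material_params()
  geom <- cylinder_geometry(radius = 12, configuration = "diastolic")
  a <- preshrink(geom, 75, mp)
  b <- preshrink(geom, 75, mp)
  expect_identical(a$result$value, b$result$value)
  expect_identical(a$result$trace, b$result$trace)
  path <- withr::local_tempfile(fileext = ".csv")
  write_calibration_trace(a$result, path)
  tr <- read.csv(path)
  expect_equal(nrow(tr), nrow(a$result$trace))
  expect_named(tr, c("iteration", "value", "residual"))
})
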