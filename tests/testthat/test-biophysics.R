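test_that("drug conductance fold follows the Hill relation", {
  drug <- drug_model(ec50 = 1e-6, hill = 1, g_max_fold = 5)
  expect_identical(conductance_fold(drug, 0), 1)
  expect_equal(conductance_fold(drug, 1e-6), 3)           # midpoint
  expect_equal(conductance_fold(drug, 1), 5, tolerance = 1e-5)  # saturation
  # monotone nondecreasing over a wide sweep, any hill
  for (h in c(0.5, 1, 2.3)) {
    d <- drug_model(ec50 = 3e-7, hill = h, g_max_fold = 8)
    folds <- conductance_fold(d, 10^seq(-10, -3, length.out = 50))
    expect_true(all(diff(folds) >= 0))
    expect_gte(min(folds), 1)
    expect_lte(max(folds), 8)
  }
  expect_error(conductance_fold(drug, -1), "nonnegative")
})

test_that("rectification scales only the drug-added conductance", {
  drug <- drug_model(ec50 = 1e-6, g_max_fold = 5, rectification = 0.5)
  g0 <- hemisphere_folds(drug, 0)
  expect_equal(unname(g0), c(1, 1))  # ohmic at zero dose
  gs <- hemisphere_folds(drug, 1e-3)  # near saturation
  expect_equal(unname(gs[1]), conductance_fold(drug, 1e-3))
  expect_equal(unname(gs[2]), 1 + (gs[[1]] - 1) * 0.5)
})

test_that("induced potential follows the cosine polarization pattern", {
  cc <- cell_model()
  fd <- field_geometry()
  pp <- pulse_protocol()
  # perpendicular to the field: no polarization
  expect_lt(abs(induced_delta_v(cc, fd, pp, pi / 2, t = 90)), 1e-12)
  # antisymmetry between cathode- and anode-facing poles
  v0 <- induced_delta_v(cc, fd, pp, 0, t = 90)
  vpi <- induced_delta_v(cc, fd, pp, pi, t = 90)
  expect_equal(v0, -vpi, tolerance = 1e-12)
  expect_gt(v0, 0)  # cathode-facing side depolarizes
  expect_error(induced_delta_v(cc, fd, pp, 0, t = -1), "nonnegative")
})

test_that("plateau potential obeys Ohm's law in the conductance fold", {
  cc <- cell_model()
  fd <- field_geometry()
  # sample late enough in a long pulse that charging is complete
  pp <- pulse_protocol(phase_duration = 400, plateau_sample_time = 350)
  v1 <- induced_delta_v(cc, fd, pp, 0.4, g_fold = 1, t = 350)
  for (g in c(1.25, 2, 5, 10)) {
    vg <- induced_delta_v(cc, fd, pp, 0.4, g_fold = g, t = 350)
    expect_lt(abs(vg * g - v1), 1e-9)
  }
  # halving resistance halves the plateau potential
  v2 <- induced_delta_v(cc, fd, pp, 0.4, g_fold = 2, t = 350)
  expect_lt(abs(v2 / v1 - 0.5), 1e-9)
})

test_that("plateau potential is linear in the pulse amplitude", {
  cc <- cell_model()
  fd <- field_geometry()
  amps <- c(0.25, 0.5, 1, 2)
  vs <- vapply(amps, function(a) {
    pp <- pulse_protocol(amplitude = a)
    induced_delta_v(cc, fd, pp, 0.7, t = 90)
  }, numeric(1))
  expect_equal(vs / vs[3], amps, tolerance = 1e-12)
})

test_that("conductance speeds up charging (tau_eff = tau_m / g)", {
  cc <- cell_model(tau_m = 10)
  fd <- field_geometry()
  pp <- pulse_protocol(phase_duration = 100, plateau_sample_time = 90)
  t_early <- 5
  v1 <- induced_delta_v(cc, fd, pp, 0, g_fold = 1, t = t_early)
  v4 <- induced_delta_v(cc, fd, pp, 0, g_fold = 4, t = t_early)
  # at equal early time the higher-conductance membrane is further along
  # its (smaller) plateau: ratio exceeds the pure Ohm factor 1/4
  expect_gt(v4 / v1, 1 / 4)
  expect_equal(v4, 35 * (1 / 4) * (1 - exp(-t_early * 4 / 10)),
               tolerance = 1e-12)
})

test_that("biphasic pulses flip polarity in the second phase", {
  cc <- cell_model()
  fd <- field_geometry()
  pp <- pulse_protocol(shape = "biphasic", phase_duration = 50,
                       plateau_sample_time = 45)
  v_first <- induced_delta_v(cc, fd, pp, 0, t = 45)
  v_second <- induced_delta_v(cc, fd, pp, 0, t = 95)
  expect_equal(v_first, -v_second, tolerance = 1e-12)
  expect_error(induced_delta_v(cc, fd, pp, 0, t = 150), "duration")
})

test_that("whole-cell average polarization is null for a symmetric cell", {
  cc <- cell_model()
  fd <- field_geometry(c(1, 2))
  pp <- pulse_protocol()
  expect_lt(abs(whole_cell_mean_dv(cc, fd, pp, t = 90)), 1e-9)
  # cathode-facing hemisphere alone depolarizes
  expect_gt(whole_cell_mean_dv(cc, fd, pp, t = 90,
                               arc = c(-pi / 2, pi / 2)), 0)
  # no stimulus, no signal
  pp0 <- pulse_protocol(amplitude = 0)
  expect_identical(whole_cell_mean_dv(cc, fd, pp0, t = 90), 0)
})

test_that("model constructors validate their invariants", {
  expect_error(cell_model(radius = -1), "radius")
  expect_error(cell_model(tau_m = 0), "tau_m")
  expect_error(drug_model(ec50 = 0), "ec50")
  expect_error(drug_model(ec50 = 1e-6, hill = -1), "hill")
  expect_error(pulse_protocol(plateau_sample_time = 200), "plateau_sample_time")
  expect_error(field_geometry(c(0, 0)), "nonzero")
  expect_equal(sqrt(sum(field_geometry(c(3, 4))$direction^2)), 1)
  expect_error(camera_model(bit_depth = 10), "bit_depth")
})

test_that("antagonist model closes the agonist response window", {
  ag <- drug_model(ec50 = 1e-6, g_max_fold = 5)
  ant <- antagonist_model(ag, agonist_conc = 2e-5, ic50 = 1e-6)
  g_alone <- conductance_fold(ag, 2e-5)
  expect_equal(conductance_fold(ant, 0), g_alone)
  expect_equal(conductance_fold(ant, 1e-6), 1 + (g_alone - 1) / 2)
  expect_lt(conductance_fold(ant, 1e-2), 1.01)
})
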