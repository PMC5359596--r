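sample_4pl <- function(bottom, top, ec50, hill,
                       conc = 10^seq(-8, -4.5, by = 0.5)) {
  tibble::tibble(concentration = conc,
                 response = logistic4(conc, bottom, top, ec50, hill))
}

test_that("noiseless 4PL samples recover all four parameters", {
  pts <- sample_4pl(1, 5, 1e-6, 1)
  fit <- fit_crc(pts)
  expect_rel_equal(fit$bottom, 1, 1e-6)
  expect_rel_equal(fit$top, 5, 1e-6)
  expect_rel_equal(fit$ec50, 1e-6, 1e-6)
  expect_rel_equal(fit$hill, 1, 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-10)
  expect_equal(fit$direction, "ascending")
  # a steeper, descending curve
  pts2 <- sample_4pl(4.8, 1.1, 3e-7, 1.7)
  fit2 <- fit_crc(pts2)
  expect_rel_equal(fit2$ec50, 3e-7, 1e-5)
  expect_rel_equal(fit2$hill, 1.7, 1e-5)
  expect_equal(fit2$direction, "descending")
})

test_that("the 4PL midpoint identity holds exactly", {
  expect_equal(logistic4(1e-6, 1, 5, 1e-6, 1.3), 3, tolerance = 1e-15)
  fit <- fit_crc(sample_4pl(1, 5, 1e-6, 1))
  expect_equal(predict(fit, fit$ec50), (fit$top + fit$bottom) / 2,
               tolerance = 1e-12)
})

test_that("flat responses yield the no-EC50 control outcome", {
  pts <- tibble::tibble(concentration = default_series(),
                        response = rep(1, 8))
  fit <- fit_crc(pts)
  expect_true(fit$flat)
  expect_true(is.na(fit$ec50))
  expect_equal(fit$direction, "flat")
  expect_output(print(fit), "flat curve, no EC50")
})

test_that("the fit requires enough distinct nonzero concentrations", {
  pts <- sample_4pl(1, 5, 1e-6, 1, conc = c(1e-7, 1e-6, 1e-5))
  expect_error(fit_crc(pts), "4 distinct nonzero")
})

test_that("EC50 rescales with concentration units, fit quality unchanged", {
  pts <- sample_4pl(1, 4, 2e-7, 1.2)
  f1 <- fit_crc(pts)
  pts_nM <- dplyr::mutate(pts, concentration = concentration * 1e9)
  f2 <- fit_crc(pts_nM)
  expect_rel_equal(f2$ec50, f1$ec50 * 1e9, 1e-6)
  expect_equal(f2$hill, f1$hill, tolerance = 1e-6)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-8)
})

test_that("out-of-range EC50s are censored, not extrapolated", {
  pts <- sample_4pl(1, 5, 1e-10, 1)  # EC50 far below tested range
  fit <- fit_crc(pts, flat_tol = 0.01)
  expect_equal(fit$censored, "low")
})

test_that("weighting by 1/SE^2 downweights noisy wells", {
  pts <- sample_4pl(1, 5, 1e-6, 1)
  pts$se <- rep(0.02, nrow(pts))
  pts$response[4] <- pts$response[4] + 1  # corrupt one well...
  pts$se[4] <- 10                         # ...with a huge SE
  fit_w <- fit_crc(pts, weights = "se")
  fit_u <- fit_crc(pts, weights = "none")
  expect_lt(abs(fit_w$ec50 - 1e-6) / 1e-6, 0.02)
  expect_gt(abs(fit_u$ec50 - 1e-6) / 1e-6,
            abs(fit_w$ec50 - 1e-6) / 1e-6)
})

test_that("the constrained-bottom mode pins the control asymptote", {
  pts <- sample_4pl(1, 5, 1e-6, 1)
  fit <- fit_crc(pts, bottom_fixed = 1)
  expect_identical(fit$bottom, 1)
  expect_rel_equal(fit$ec50, 1e-6, 1e-6)
})

test_that("tidy and glance report the 4PL parameters", {
  fit <- fit_crc(sample_4pl(1, 5, 1e-6, 1))
  td <- tidy(fit)
  expect_setequal(td$term, c("bottom", "top", "ec50", "hill"))
  gl <- glance(fit)
  expect_rel_equal(gl$ec50, 1e-6, 1e-6)
  expect_false(gl$flat)
})

test_that("Min-Max normalization is affine-invariant on [0, 1]", {
  expect_equal(minmax_normalize(c(1, 3, 5)), c(0, 0.5, 1))
  v <- c(0, 0.25, 1)
  expect_equal(minmax_normalize(v), v)
  expect_equal(minmax_normalize(3 * v + 10), v)
  expect_error(minmax_normalize(rep(2, 5)), "degenerate")
})

test_that("antagonist runs return IC50 or an inactive call", {
  ag <- drug_model(ec50 = 1e-6, g_max_fold = 5)
  conc <- 10^seq(-9, -4, by = 0.5)
  make_run <- function(ic50) {
    ant <- antagonist_model(ag, agonist_conc = 2e-5, ic50 = ic50)
    tibble::tibble(concentration = c(0, 0, conc),
                   response = conductance_fold(ant, c(0, 0, conc)))
  }
  run <- make_run(1e-6)
  res <- ic50_from_antagonist_run(run)
  expect_equal(res$call, "active")
  expect_rel_equal(res$ic50, 1e-6, 0.01)  # noiseless: near-exact
  expect_equal(res$fit$direction, "descending")
  # zero-potency antagonist: no inhibition
  inert <- tibble::tibble(concentration = c(0, 0, conc),
                          response = c(rep(conductance_fold(ag, 2e-5),
                                           2 + length(conc))))
  expect_equal(ic50_from_antagonist_run(inert)$call, "inactive")
  # infinite potency: fully inhibited everywhere -> below range
  dead <- tibble::tibble(concentration = c(0, 0, conc),
                         response = c(rep(conductance_fold(ag, 2e-5), 2),
                                      rep(1, length(conc))))
  expect_equal(ic50_from_antagonist_run(dead)$call, "out_of_range_low")
  # anchors are mandatory; so is a >= 3 decade span
  expect_error(ic50_from_antagonist_run(run[-(1:2), ]), "anchor")
  expect_error(ic50_from_antagonist_run(
    dplyr::filter(run, concentration %in% c(0, 1e-6, 3.16e-6, 1e-5))),
    "decades")
})

test_that("simulated antagonist plate recovers the configured IC50", {
  ag <- drug_model(ec50 = 1e-6, g_max_fold = 5)
  ant <- antagonist_model(ag, agonist_conc = 2e-5, ic50 = 1e-6)
  conc <- c(0, 10^seq(-8, -4, length.out = 7))
  plate <- plate_map(conc, areas_per_well = 3, seed = 12)
  sim <- sim_params(frame_dim = c(128, 128), n_cells = 3,
                    radius_range = c(18, 24))
  ps <- simulate_plate(plate, ant, sim = sim)
  an <- analyze_plate(ps, fit_curve = FALSE)
  pts <- tibble::tibble(concentration = an$wells$concentration,
                        response = an$wells$gd_gc_mean,
                        se = an$wells$gd_gc_se)
  res <- ic50_from_antagonist_run(pts)
  expect_equal(res$call, "active")
  expect_lt(abs(res$ic50 - 1e-6) / 1e-6, 0.25)
})
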