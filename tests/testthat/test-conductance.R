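make_pairs <- function(x, y) {
  structure(tibble::tibble(row = seq_along(x), col = seq_along(x),
                           x = x, y = y),
            class = c("pixel_pairs", "tbl_df", "tbl", "data.frame"))
}

area_maps <- function(rec, b = 4) {
  mask <- build_shape_mask(bin_image(rec$f_pre_ref, b))
  list(ref = compute_dff(bin_image(rec$f_pre_ref, b),
                         bin_image(rec$f_plateau_ref, b), mask),
       test = compute_dff(bin_image(rec$f_pre_test, b),
                          bin_image(rec$f_plateau_test, b), mask, "test"))
}

test_that("pixel pairing joins common pixels and drops exclusions", {
  rec <- simulate_area_fold(1)
  m <- area_maps(rec)
  pr <- pair_pixels(m$ref, m$test)
  expect_equal(pr$x, pr$y, tolerance = 1e-12)  # identity passage
  # disjoint exclusions: pairs = mask minus the union
  drop_pixels <- function(map, i) {
    structure(map[-i, ], class = class(map),
              mask_id = attr(map, "mask_id"), n_mask = attr(map, "n_mask"))
  }
  pr2 <- pair_pixels(drop_pixels(m$ref, 1:3), drop_pixels(m$test, 4:5))
  expect_equal(nrow(pr2), nrow(pr) - 5)
  # different masks refuse to pair
  other <- m$test
  attr(other, "mask_id") <- c(n = 1, sum_row = 0, sum_col = 0)
  expect_error(pair_pixels(m$ref, other), "mask mismatch")
})

test_that("noiseless pairs at g_fold = 2 fall on y = x/2", {
  rec <- simulate_area_fold(2)
  m <- area_maps(rec)
  pr <- pair_pixels(m$ref, m$test)
  on_line <- abs(pr$x) > 0.002
  expect_lt(max(abs(pr$y[on_line] - 0.5 * pr$x[on_line])), 1e-9)
})

test_that("slope fitting matches closed-form least squares", {
  x <- seq(-0.05, 0.05, length.out = 200)
  x <- x[abs(x) > 0.002]
  fit <- fit_slope(make_pairs(x, 0.5 * x))
  expect_equal(fit$slope_all, 0.5, tolerance = 1e-12)
  expect_equal(fit$slope_se, 0, tolerance = 1e-12)
  expect_equal(fit$slope_neg, 0.5, tolerance = 1e-12)
  expect_equal(fit$slope_pos, 0.5, tolerance = 1e-12)
  fit1 <- fit_slope(make_pairs(x, x))
  expect_equal(fit1$slope_all, 1, tolerance = 1e-12)
  # noisy recovery within 3 stderr of the closed-form oracle
  set.seed(31)
  xn <- runif(1e4, -0.06, 0.06)
  yn <- 0.3 * xn + rnorm(1e4, sd = 0.1 * abs(xn))
  keep <- abs(xn) >= 0.002
  oracle <- sum(xn[keep] * yn[keep]) / sum(xn[keep]^2)
  fitn <- fit_slope(make_pairs(xn, yn))
  expect_equal(fitn$slope_all, oracle, tolerance = 1e-12)
  expect_lt(abs(fitn$slope_all - 0.3), 3 * fitn$slope_se)
})

test_that("slope is scale-invariant and respects the deadband", {
  set.seed(5)
  x <- runif(500, -0.05, 0.05)
  y <- 0.4 * x + rnorm(500, sd = 0.002)
  f1 <- fit_slope(make_pairs(x, y))
  f2 <- fit_slope(make_pairs(7 * x, 7 * y), x_deadband = 7 * 0.002)
  expect_equal(f1$slope_all, f2$slope_all, tolerance = 1e-12)
  # all pairs inside the deadband: no information
  expect_error(fit_slope(make_pairs(runif(100, -1e-3, 1e-3),
                                    runif(100, -1e-3, 1e-3))),
               "insufficient responsive")
  expect_error(fit_slope(make_pairs(numeric(0), numeric(0))),
               "insufficient responsive")
})

test_that("Theil-Sen fallback resists heavy-tailed contamination", {
  set.seed(77)
  x <- runif(400, 0.005, 0.05) * sample(c(-1, 1), 400, replace = TRUE)
  y <- 0.5 * x
  y[1:40] <- y[1:40] + 0.5  # 10% gross outliers
  ls <- fit_slope(make_pairs(x, y))
  ts <- fit_slope(make_pairs(x, y), method = "theil-sen")
  expect_gt(abs(ls$slope_all - 0.5), abs(ts$slope_all - 0.5))
  expect_equal(ts$slope_all, 0.5, tolerance = 0.02)
})

test_that("free-intercept diagnostic is available behind a flag", {
  x <- seq(-0.05, 0.05, length.out = 101)
  x <- x[abs(x) > 0.002]
  fit <- fit_slope(make_pairs(x, 0.3 * x + 0.001), intercept = TRUE)
  expect_equal(fit$slope_free, 0.3, tolerance = 1e-9)
  expect_equal(fit$intercept, 0.001, tolerance = 1e-9)
})

test_that("rectification index flags asymmetric drug action", {
  x <- c(seq(-0.05, -0.005, length.out = 60),
         seq(0.005, 0.05, length.out = 60))
  y <- ifelse(x < 0, 0.2 * x, 0.4 * x)
  fit <- fit_slope(make_pairs(x, y))
  expect_equal(rectification_index(fit), 2, tolerance = 1e-9)
  # ohmic control
  fit0 <- fit_slope(make_pairs(x, 0.7 * x))
  expect_equal(rectification_index(fit0), 1, tolerance = 1e-9)
  # underpopulated side -> undefined
  xp <- seq(0.005, 0.05, length.out = 80)
  fitp <- fit_slope(make_pairs(xp, 0.5 * xp), min_side = 25)
  expect_true(is.na(rectification_index(fitp)))
})

test_that("simulated rectifying drug shows index > 1 at saturation", {
  rec <- simulate_area_fold(5, rectification = 0.5)
  m <- area_maps(rec)
  fit <- fit_slope(pair_pixels(m$ref, m$test))
  # depol side: g = 5 -> slope 0.2; hyper side: g = 3 -> slope 1/3
  expect_gt(rectification_index(fit), 1.3)
  expect_equal(fit$slope_neg, 0.2, tolerance = 0.02)
  expect_equal(fit$slope_pos, 1 / 3, tolerance = 0.03)
})

test_that("conductance ratio is the reciprocal slope", {
  expect_equal(to_conductance(0.5), 2)
  expect_equal(to_conductance(1), 1)
  # ~20% residual resistance maps to 5-fold conductance
  expect_equal(to_conductance(0.2), 5)
  expect_error(to_conductance(-0.1), "nonphysical")
  expect_equal(to_resistance(to_conductance(0.37)), 0.37, tolerance = 1e-12)
})

test_that("resting-potential shifts barely move the slope", {
  rec0 <- simulate_area_fold(2, sim = noiseless_params())
  rec5 <- simulate_area_fold(2, sim = noiseless_params(v_rest_offset = 5))
  f0 <- fit_slope(do.call(pair_pixels, unname(area_maps(rec0))))
  f5 <- fit_slope(do.call(pair_pixels, unname(area_maps(rec5))))
  expect_lt(abs(f5$slope_all - f0$slope_all) / f0$slope_all, 0.01)
})

test_that("tidy and glance summaries expose the fit", {
  x <- seq(-0.05, 0.05, length.out = 101)
  x <- x[abs(x) > 0.002]
  fit <- fit_slope(make_pairs(x, 0.25 * x))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "slope_all"], 0.25, tolerance = 1e-12)
  gl <- glance(fit)
  expect_equal(gl$gd_gc, 4, tolerance = 1e-9)
  expect_equal(gl$n_pairs, length(x))
})
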