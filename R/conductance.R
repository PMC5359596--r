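#' Pair reference and test dF/F values pixel by pixel
#'
#' Joins the reference- and test-passage [compute_dff()] maps of one sampling
#' area on their common mask pixels: `x` is the reference value
#' (dFc/F_Rc) and `y` the test value (dFd/F_Rd) of the same pixel. Pixels
#' excluded in either passage drop out of both. Under Ohm's law at the pulse
#' plateau the pairs fall on the line `y = (Rd/Rc) x`.
#'
#' @param ref,test `dff_map` objects built on the same [build_shape_mask()].
#' @return A tibble of class `pixel_pairs` with columns `row`, `col`, `x`,
#'   `y`; attribute `n_mask` carries the common mask size.
#' @export
pair_pixels <- function(ref, test) {
  stopifnot(inherits(ref, "dff_map"), inherits(test, "dff_map"))
  if (!identical(attr(ref, "mask_id"), attr(test, "mask_id"))) {
    abort("mask mismatch: reference and test maps use different masks")
  }
  pairs <- inner_join(
    tibble(row = ref$row, col = ref$col, x = ref$dff),
    tibble(row = test$row, col = test$col, y = test$dff),
    by = c("row", "col"))
  structure(pairs, class = c("pixel_pairs", class(pairs)),
            n_mask = attr(ref, "n_mask"))
}

slope_through_origin <- function(x, y) {
  sxx <- sum(x * x)
  b <- sum(x * y) / sxx
  n <- length(x)
  se <- if (n > 1) sqrt(sum((y - b * x)^2) / (n - 1) / sxx) else NA_real_
  list(slope = b, se = se, n = n)
}

theil_sen_origin <- function(x, y, max_n = 500) {
  if (length(x) > max_n) {
    idx <- round(seq(1, length(x), length.out = max_n))
    x <- x[idx]; y <- y[idx]
  }
  median(y / x)
}

#' Fit the paired-pixel scatter slope (Rd/Rc)
#'
#' Least-squares regression of test on reference dF/F through the origin:
#' the Ohm relation `y = (Rd/Rc) x` has no offset term, so the intercept is
#' fixed at zero by default. Pairs with `|x| < x_deadband` are dropped first:
#' unresponsive pixels near the origin carry no slope information and only
#' add noise. The slope is also fitted separately on the depolarizing
#' (`x < 0`, with a dye that dims on depolarization) and hyperpolarizing
#' (`x > 0`) subsets; unequal split slopes are the signature of channel
#' rectification.
#'
#' @param pairs A [pair_pixels()] result (or tibble with `x`, `y`).
#' @param x_deadband Half-width of the excluded band around `x = 0`.
#' @param min_pairs Minimum retained pairs for the overall fit.
#' @param min_side Minimum pairs per sign-restricted subset; below it the
#'   split slope is `NA`.
#' @param method `"ls"` (default, linear regression) or `"theil-sen"`, a
#'   robust pairwise-median fallback for heavy-tailed noise.
#' @param intercept If `TRUE`, additionally fit a free-intercept diagnostic
#'   line (reported as `intercept`/`slope_free`; the primary slope is
#'   unchanged).
#' @return An object of class `slope_fit`: list with `slope_all`,
#'   `slope_se`, `slope_neg`, `slope_pos`, `n_pairs`, `n_neg`, `n_pos`,
#'   `method`, and optionally the free-intercept diagnostics.
#' @export
fit_slope <- function(pairs, x_deadband = 0.002, min_pairs = 50,
                      min_side = 25, method = c("ls", "theil-sen"),
                      intercept = FALSE) {
  method <- match.arg(method)
  x <- pairs$x
  y <- pairs$y
  keep <- is.finite(x) & is.finite(y) & abs(x) >= x_deadband
  x <- x[keep]; y <- y[keep]
  if (length(x) < min_pairs) {
    abort("insufficient responsive pixels for slope fit")
  }
  fit <- slope_through_origin(x, y)
  slope_all <- if (method == "theil-sen") theil_sen_origin(x, y) else
    fit$slope
  neg <- x < 0
  pos <- x > 0
  slope_neg <- if (sum(neg) >= min_side) {
    if (method == "theil-sen") theil_sen_origin(x[neg], y[neg]) else
      slope_through_origin(x[neg], y[neg])$slope
  } else NA_real_
  slope_pos <- if (sum(pos) >= min_side) {
    if (method == "theil-sen") theil_sen_origin(x[pos], y[pos]) else
      slope_through_origin(x[pos], y[pos])$slope
  } else NA_real_
  out <- list(slope_all = slope_all, slope_se = fit$se,
              slope_neg = slope_neg, slope_pos = slope_pos,
              n_pairs = fit$n, n_neg = sum(neg), n_pos = sum(pos),
              x_deadband = x_deadband, method = method)
  if (intercept) {
    cf <- coef(stats::lm(y ~ x))
    out$intercept <- unname(cf[1])
    out$slope_free <- unname(cf[2])
  }
  structure(out, class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf(
    "<slope_fit> Rd/Rc = %.4f (se %.2g, n = %d); depol %.4f / hyper %.4f [%s]\n",
    x$slope_all, x$slope_se, x$n_pairs, x$slope_neg, x$slope_pos, x$method))
  invisible(x)
}

#' @export
tidy.slope_fit <- function(x, ...) {
  tibble(term = c("slope_all", "slope_neg", "slope_pos"),
         estimate = c(x$slope_all, x$slope_neg, x$slope_pos),
         std.error = c(x$slope_se, NA_real_, NA_real_))
}

#' @export
glance.slope_fit <- function(x, ...) {
  tibble(slope_all = x$slope_all, slope_se = x$slope_se,
         slope_neg = x$slope_neg, slope_pos = x$slope_pos,
         rect_index = x$slope_pos / x$slope_neg,
         gd_gc = 1 / x$slope_all, n_pairs = x$n_pairs)
}

#' Rectification index from split scatter slopes
#'
#' Ratio of the hyperpolarizing-side to the depolarizing-side slope,
#' `slope_pos / slope_neg`. A value of 1 indicates an ohmic drug effect;
#' values above 1 mean the drug-opened conductance is larger under
#' depolarization (the outward-rectification signature: resistance drops
#' more on the depolarizing side, so that side's slope is smaller).
#'
#' @param fit A [fit_slope()] result.
#' @return The index, or `NA` (with a message attribute) when either split
#'   slope is undefined.
#' @export
rectification_index <- function(fit) {
  stopifnot(inherits(fit, "slope_fit"))
  if (!is.finite(fit$slope_neg) || !is.finite(fit$slope_pos)) {
    return(structure(NA_real_, reason = "split slope undefined"))
  }
  fit$slope_pos / fit$slope_neg
}

#' Conductance ratio from a resistance-ratio slope
#'
#' Ohm's law with a constant test current: the scatter slope estimates
#' Rd/Rc, and conductance is the reciprocal of resistance, so
#' `Gd/Gc = 1 / (Rd/Rc)`. A slope of ~0.2 (resistance reduced to ~20% of
#' control) maps to a 5-fold conductance increase.
#'
#' @param fit A [fit_slope()] result, or a positive numeric slope.
#' @return The conductance ratio Gd/Gc.
#' @export
to_conductance <- function(fit) {
  slope <- if (inherits(fit, "slope_fit")) fit$slope_all else as.numeric(fit)
  if (!all(is.finite(slope)) || any(slope <= 0)) {
    abort("nonphysical slope: Rd/Rc must be positive")
  }
  1 / slope
}

#' Resistance ratio from a conductance ratio
#'
#' Inverse of [to_conductance()]; the two are mutually inverse.
#' @param gd_gc Positive conductance ratio(s).
#' @return Rd/Rc.
#' @export
to_resistance <- function(gd_gc) {
  if (any(gd_gc <= 0)) abort("nonphysical conductance ratio")
  1 / gd_gc
}
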