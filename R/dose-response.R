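#' Four-parameter logistic response function
#'
#' `f(c) = bottom + (top - bottom) / (1 + (ec50 / c)^hill)`, evaluated
#' internally on log10 concentration. At `c = ec50` the response is exactly
#' the asymptote midpoint `(top + bottom) / 2`. Ascending curves have
#' `top > bottom` (conductance readout); descending curves (resistance
#' readout, or antagonist inhibition) simply swap the asymptote roles.
#'
#' @param conc Concentration(s), M (> 0).
#' @param bottom,top Low- and high-concentration asymptotes.
#' @param ec50 Half-maximal concentration, M.
#' @param hill Hill coefficient (> 0).
#' @return Response value(s).
#' @export
logistic4 <- function(conc, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (log10(ec50) - log10(conc))))
}

#' Fit a concentration-response curve (4PL)
#'
#' Fits the four-parameter logistic of [logistic4()] to per-well responses
#' (Gd/Gc, or Rd/Rc for resistance-mode "inverse sigmoid" curves - the same
#' model with the asymptote roles swapped) against log10 concentration by
#' Levenberg-Marquardt nonlinear least squares. Points are weighted by
#' `1 / se^2` when standard errors over sampling areas are available.
#'
#' A response range smaller than `flat_tol` is the control-experiment
#' outcome: no concentration dependence, no EC50 (`flat = TRUE`). A fitted
#' EC50 outside the tested concentration range is reported with a censoring
#' flag rather than trusted as an extrapolation.
#'
#' @param points Tibble with columns `concentration` (M) and `response`;
#'   optional `se` (standard error across sampling areas). At least 4
#'   distinct nonzero concentrations are required.
#' @param weights `"se"` (default; falls back to unweighted when `se` is
#'   absent or degenerate) or `"none"`.
#' @param flat_tol Response range below which the curve is declared flat.
#' @param hill_bounds Bounds on the Hill coefficient, stabilizing sparse
#'   designs.
#' @param bottom_fixed Optional fixed low-dose asymptote (e.g. 1 to pin the
#'   control conductance ratio); default leaves it free.
#' @return An object of class `crc_fit` with elements `bottom`, `top`,
#'   `ec50`, `hill`, `r_squared`, `direction` (`"ascending"`/`"descending"`),
#'   `flat`, `censored` (`"none"`, `"low"`, `"high"`), `converged`, the data
#'   and residuals. Methods: [tidy()], [glance()], `predict()`, `print()`,
#'   [autoplot()].
#' @export
fit_crc <- function(points, weights = c("se", "none"), flat_tol = 0.1,
                    hill_bounds = c(0.3, 5), bottom_fixed = NULL) {
  weights <- match.arg(weights)
  stopifnot(all(c("concentration", "response") %in% names(points)))
  pts <- as_tibble(points)
  pts <- pts[is.finite(pts$concentration) & is.finite(pts$response), ]
  nz <- pts[pts$concentration > 0, ]
  if (length(unique(nz$concentration)) < 4) {
    abort("need >= 4 distinct nonzero concentrations")
  }
  rng <- range(nz$response)
  new_fit <- function(...) {
    structure(list(..., data = nz, flat_tol = flat_tol), class = "crc_fit")
  }
  if (diff(rng) < flat_tol) {
    return(new_fit(bottom = mean(nz$response), top = mean(nz$response),
                   ec50 = NA_real_, hill = NA_real_, r_squared = NA_real_,
                   direction = "flat", flat = TRUE, censored = "none",
                   converged = TRUE, std_errors = NULL,
                   fitted = rep(mean(nz$response), nrow(nz)),
                   residuals = nz$response - mean(nz$response)))
  }
  lc <- log10(nz$concentration)
  o <- order(lc)
  resp_lo <- mean(nz$response[lc == min(lc)])
  resp_hi <- mean(nz$response[lc == max(lc)])
  start_bottom <- resp_lo
  start_top <- resp_hi
  mid <- (resp_lo + resp_hi) / 2
  start_lec50 <- lc[o][which.min(abs(nz$response[o] - mid))]
  w <- rep(1, nrow(nz))
  if (weights == "se" && "se" %in% names(nz) &&
      all(is.finite(nz$se)) && all(nz$se > 0)) {
    w <- 1 / nz$se^2
  }
  lo_l <- min(lc) - 2
  hi_l <- max(lc) + 2
  df <- data.frame(lc = lc, response = nz$response, w = w)
  ctrl <- nls.lm.control(maxiter = 1024, ftol = 1e-15, ptol = 1e-15)
  fit <- tryCatch({
    if (is.null(bottom_fixed)) {
      nlsLM(response ~ bottom + (top - bottom) /
              (1 + 10^(hill * (lec50 - lc))),
            data = df, weights = df$w,
            start = list(bottom = start_bottom, top = start_top,
                         lec50 = start_lec50, hill = 1),
            lower = c(-Inf, -Inf, lo_l, hill_bounds[1]),
            upper = c(Inf, Inf, hi_l, hill_bounds[2]),
            control = ctrl)
    } else {
      b0 <- bottom_fixed
      nlsLM(response ~ b0 + (top - b0) / (1 + 10^(hill * (lec50 - lc))),
            data = df, weights = df$w,
            start = list(top = start_top, lec50 = start_lec50, hill = 1),
            lower = c(-Inf, lo_l, hill_bounds[1]),
            upper = c(Inf, hi_l, hill_bounds[2]),
            control = ctrl)
    }
  }, error = function(e) {
    abort(paste0("CRC fit did not converge: ", conditionMessage(e)))
  })
  cf <- coef(fit)
  bottom <- if (is.null(bottom_fixed)) unname(cf["bottom"]) else bottom_fixed
  top <- unname(cf["top"])
  lec50 <- unname(cf["lec50"])
  hill <- unname(cf["hill"])
  fitted_v <- logistic4(nz$concentration, bottom, top, 10^lec50, hill)
  res <- nz$response - fitted_v
  r2 <- 1 - sum(res^2) / sum((nz$response - mean(nz$response))^2)
  censored <- if (lec50 < min(lc)) "low" else if (lec50 > max(lc)) "high"
    else "none"
  se_tab <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) NULL)
  new_fit(bottom = bottom, top = top, ec50 = 10^lec50, hill = hill,
          r_squared = r2,
          direction = if (top >= bottom) "ascending" else "descending",
          flat = FALSE, censored = censored, converged = TRUE,
          std_errors = se_tab, fitted = fitted_v, residuals = res)
}

#' @export
print.crc_fit <- function(x, ...) {
  if (x$flat) {
    cat("<crc_fit> flat curve, no EC50 (response range below",
        x$flat_tol, ")\n")
  } else {
    cat(sprintf(
      "<crc_fit> %s 4PL: EC50 = %.4g M, hill = %.3f, bottom = %.3f, top = %.3f, R-Sq = %.4f%s\n",
      x$direction, x$ec50, x$hill, x$bottom, x$top, x$r_squared,
      if (x$censored != "none") paste0(" [EC50 censored ", x$censored,
                                       " of tested range]") else ""))
  }
  invisible(x)
}

#' @export
predict.crc_fit <- function(object, conc, ...) {
  if (object$flat) return(rep(object$bottom, length(conc)))
  logistic4(conc, object$bottom, object$top, object$ec50, object$hill)
}

#' @export
tidy.crc_fit <- function(x, ...) {
  if (x$flat) {
    return(tibble(term = "level", estimate = x$bottom,
                  std.error = NA_real_))
  }
  se <- x$std_errors
  get_se <- function(nm) if (!is.null(se) && nm %in% names(se))
    unname(se[nm]) else NA_real_
  # delta method for EC50 from the log10 parameterization
  ec50_se <- log(10) * x$ec50 * get_se("lec50")
  tibble(term = c("bottom", "top", "ec50", "hill"),
         estimate = c(x$bottom, x$top, x$ec50, x$hill),
         std.error = c(get_se("bottom"), get_se("top"), ec50_se,
                       get_se("hill")))
}

#' @export
glance.crc_fit <- function(x, ...) {
  tibble(ec50 = x$ec50, hill = x$hill, bottom = x$bottom, top = x$top,
         r_squared = x$r_squared, direction = x$direction, flat = x$flat,
         censored = x$censored, n = nrow(x$data), converged = x$converged)
}

#' Min-Max normalization of fitted curve values
#'
#' Rescales values affinely to `[0, 1]`; used only to overlay fitted curves
#' from different plates on a common axis, never before fitting. Invariant
#' to any positive affine transform of the input.
#'
#' @param v Numeric values with `max(v) > min(v)`.
#' @return Normalized values in `[0, 1]`.
#' @export
minmax_normalize <- function(v) {
  r <- range(v, na.rm = TRUE)
  if (!all(is.finite(r)) || r[2] <= r[1]) {
    abort("degenerate normalization: constant input")
  }
  (v - r[1]) / (r[2] - r[1])
}

#' IC50 from an antagonist run at a fixed agonist challenge
#'
#' Analyzes a run in which the antagonist is administered before the test
#' passage and every well receives the same agonist challenge: conductance
#' ratios fall from the agonist-alone level toward control as antagonist
#' concentration rises, giving a descending 4PL whose midpoint is the IC50.
#' Wells with zero antagonist provide the agonist-alone anchor defining the
#' response window. When the maximal inhibition at the highest tested
#' concentration is below 50% of that window the compound is called
#' inactive; an IC50 apparently below the lowest tested concentration is
#' flagged out of range rather than extrapolated.
#'
#' @param points Tibble with `concentration` (antagonist, M; include 0 rows
#'   for the agonist-alone anchors), `response` (Gd/Gc), optional `se`.
#' @param baseline Control conductance ratio (no agonist), default 1.
#' @param span_decades Minimum antagonist concentration span required,
#'   decades.
#' @param flat_tol Passed to [fit_crc()].
#' @return A list of class `ic50_call`: `call` (`"active"`, `"inactive"`, or
#'   `"out_of_range_low"`), `ic50`, `max_inhibition`, `window`, and the
#'   underlying `crc_fit` when one was fitted.
#' @export
ic50_from_antagonist_run <- function(points, baseline = 1,
                                     span_decades = 3, flat_tol = 0.1) {
  stopifnot(all(c("concentration", "response") %in% names(points)))
  anchors <- points$response[points$concentration == 0]
  if (length(anchors) == 0) {
    abort("missing agonist-alone anchor wells (zero antagonist)")
  }
  nz <- points[points$concentration > 0, ]
  if (nrow(nz) == 0) abort("no antagonist concentrations")
  span <- log10(max(nz$concentration) / min(nz$concentration))
  if (span < span_decades) {
    abort(sprintf("antagonist concentrations span %.1f decades (< %g)",
                  span, span_decades))
  }
  r0 <- mean(anchors)
  window <- r0 - baseline
  if (window <= 0) abort("agonist-alone response does not exceed baseline")
  top_conc <- max(nz$concentration)
  r_top <- mean(nz$response[nz$concentration == top_conc])
  max_inh <- (r0 - r_top) / window
  out <- list(ic50 = NA_real_, max_inhibition = max_inh, window = window,
              agonist_alone = r0, fit = NULL)
  if (max_inh < 0.5) {
    out$call <- "inactive"
    return(structure(out, class = "ic50_call"))
  }
  if (diff(range(nz$response)) < flat_tol) {
    # fully inhibited at every tested concentration
    out$call <- "out_of_range_low"
    return(structure(out, class = "ic50_call"))
  }
  fit <- fit_crc(nz, flat_tol = flat_tol)
  out$fit <- fit
  out$ic50 <- fit$ec50
  out$call <- if (fit$censored == "low") "out_of_range_low" else "active"
  structure(out, class = "ic50_call")
}

#' @export
print.ic50_call <- function(x, ...) {
  cat(sprintf("<ic50_call> %s; IC50 = %.4g M; max inhibition %.0f%% of window\n",
              x$call, x$ic50, 100 * x$max_inhibition))
  invisible(x)
}
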