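#' Z factor of assay separation
#'
#' Screening separation statistic of Zhang:
#' `Z = 1 - 3 (sd_p + sd_n) / |mean_p - mean_n|`, using sample (n-1)
#' standard deviations. Applied to the lowest- and highest-concentration
#' responses it is the Z factor; applied to control wells (min- vs
#' max-signal controls) it is the Z' factor. Invariant under any common
#' affine rescaling of both groups; tends to 1 as both spreads vanish.
#'
#' @param positives,negatives Numeric response vectors, at least 2 values
#'   each.
#' @return The Z (or Z') factor, a dimensionless value <= 1.
#' @export
#' @examples
#' z_factor(rnorm(8, 1, 0.05), rnorm(8, 0, 0.05))
z_factor <- function(positives, negatives) {
  if (length(positives) < 2 || length(negatives) < 2) {
    abort("need at least 2 values per group")
  }
  mu_p <- mean(positives); mu_n <- mean(negatives)
  if (mu_p == mu_n) abort("no separation: equal group means")
  1 - 3 * (sd(positives) + sd(negatives)) / abs(mu_p - mu_n)
}

#' Per-concentration coefficient of variation across replicate curves
#'
#' @param data Tibble with columns `concentration` and `response`, replicate
#'   responses stacked (>= 2 per concentration).
#' @return A tibble with `concentration`, `n`, `mean`, `sd`, `cv` (percent)
#'   and `flagged` (zero-mean points, excluded from [cv_max()]).
#' @export
cv_profile <- function(data) {
  stopifnot(all(c("concentration", "response") %in% names(data)))
  out <- data |>
    group_by(.data$concentration) |>
    summarise(n = dplyr::n(), mean = mean(.data$response),
              sd = sd(.data$response), .groups = "drop")
  if (any(out$n < 2)) abort("need >= 2 replicates per concentration")
  out |>
    mutate(flagged = abs(.data$mean) < .Machine$double.eps^0.5,
           cv = ifelse(.data$flagged, NA_real_,
                       100 * .data$sd / abs(.data$mean)))
}

#' Maximum coefficient of variation over concentrations
#'
#' `CV = 100 * sd / mean` across replicate curves at each concentration; the
#' reported statistic is the maximum over concentrations (NIH intra-plate
#' consistency criterion: CV_max < 20%). Scale-invariant. Concentrations
#' with zero mean are flagged and excluded from the maximum.
#'
#' @inheritParams cv_profile
#' @return CV_max in percent.
#' @export
cv_max <- function(data) {
  prof <- cv_profile(data)
  vals <- prof$cv[!prof$flagged]
  if (length(vals) == 0) abort("all concentrations flagged (zero mean)")
  max(vals)
}

#' EC50 fold change across replicate curves
#'
#' `max(ec50) / min(ec50)` (>= 1), the NIH consistency measure of EC50
#' variation across replicate curves (criterion: fold change < 2).
#'
#' @param ec50s Numeric vector of at least 2 positive EC50s.
#' @return The fold change.
#' @export
ec50_fold_change <- function(ec50s) {
  if (length(ec50s) < 2) abort("need >= 2 EC50s")
  if (any(!is.finite(ec50s) | ec50s <= 0)) {
    abort("all EC50s must be positive")
  }
  max(ec50s) / min(ec50s)
}

#' Summary statistics of replicate EC50s
#'
#' Mean and geometric-mean EC50, the max/min fold change, and the maximum
#' relative deviation from the mean (an alternative fold-change reading for
#' which values below 1 are possible).
#'
#' @inheritParams ec50_fold_change
#' @return A one-row tibble: `n`, `mean_ec50`, `geomean_ec50`,
#'   `fold_change`, `max_rel_dev`.
#' @export
ec50_summary <- function(ec50s) {
  fc <- ec50_fold_change(ec50s)
  m <- mean(ec50s)
  tibble(n = length(ec50s), mean_ec50 = m,
         geomean_ec50 = exp(mean(log(ec50s))), fold_change = fc,
         max_rel_dev = max(abs(ec50s - m)) / m)
}

#' Intra- and inter-plate consistency report
#'
#' Applies the NIH screening-consistency criteria to replicate
#' concentration-response curves: per plate, the maximum coefficient of
#' variation of responses over concentrations (CV_max < 20%), the EC50
#' max/min fold change across the plate's curves (< 2), and the Z' factor
#' between the lowest- and highest-concentration responses (> 0.4); across
#' plates, the fold change of plate-mean EC50s.
#'
#' @param curves Tibble of curve points with columns `plate`, `curve`,
#'   `concentration`, `response`.
#' @param ec50s Optional tibble with columns `plate`, `curve`, `ec50`. When
#'   omitted, each curve is fitted with [fit_crc()].
#' @param thresholds Named list of pass thresholds (`cv_max`, percent;
#'   `fold_change`; `z_prime`).
#' @return A list of class `qc_report`: `per_plate` (tibble with the three
#'   statistics and pass flags per plate) and `inter_plate` (one-row tibble
#'   with mean of plate-mean EC50s, inter-plate fold change and max relative
#'   deviation).
#' @export
consistency_report <- function(curves, ec50s = NULL,
                               thresholds = list(cv_max = 20,
                                                 fold_change = 2,
                                                 z_prime = 0.4)) {
  stopifnot(all(c("plate", "curve", "concentration", "response") %in%
                  names(curves)))
  if (is.null(ec50s)) {
    ec50s <- curves |>
      group_by(.data$plate, .data$curve) |>
      summarise(ec50 = fit_crc(pick(dplyr::everything()))$ec50,
                .groups = "drop")
  }
  per_plate <- curves |>
    group_by(.data$plate) |>
    group_modify(function(d, key) {
      cvm <- cv_max(d)
      cmin <- min(d$concentration)
      cmax <- max(d$concentration)
      zp <- z_factor(d$response[d$concentration == cmax],
                     d$response[d$concentration == cmin])
      tibble(n_curves = length(unique(d$curve)), cv_max = cvm, z_prime = zp)
    }) |>
    ungroup()
  plate_ec50 <- ec50s |>
    group_by(.data$plate) |>
    summarise(mean_ec50 = mean(.data$ec50),
              fold_change = if (dplyr::n() >= 2)
                ec50_fold_change(.data$ec50) else NA_real_,
              .groups = "drop")
  per_plate <- left_join(per_plate, plate_ec50, by = "plate") |>
    mutate(pass_cv = .data$cv_max < thresholds$cv_max,
           pass_fold = is.na(.data$fold_change) |
             .data$fold_change < thresholds$fold_change,
           pass_z_prime = .data$z_prime > thresholds$z_prime)
  inter <- if (nrow(plate_ec50) >= 2) {
    s <- ec50_summary(plate_ec50$mean_ec50)
    tibble(n_plates = nrow(plate_ec50),
           mean_of_plate_means = s$mean_ec50,
           fold_change = s$fold_change, max_rel_dev = s$max_rel_dev,
           pass_fold = s$fold_change < thresholds$fold_change)
  } else {
    tibble(n_plates = nrow(plate_ec50),
           mean_of_plate_means = mean(plate_ec50$mean_ec50),
           fold_change = NA_real_, max_rel_dev = NA_real_, pass_fold = NA)
  }
  structure(list(per_plate = per_plate, inter_plate = inter,
                 thresholds = thresholds),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Per-plate consistency (thresholds: CV_max <",
      x$thresholds$cv_max, "%, fold change <", x$thresholds$fold_change,
      ", Z' >", x$thresholds$z_prime, ")\n")
  print(as.data.frame(x$per_plate), row.names = FALSE, digits = 4)
  cat("\nInter-plate:\n")
  print(as.data.frame(x$inter_plate), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Overall pass flag of a QC report
#'
#' @param x A [consistency_report()] result.
#' @return `TRUE` when every per-plate and inter-plate criterion passes.
#' @export
qc_pass <- function(x) {
  stopifnot(inherits(x, "qc_report"))
  all(x$per_plate$pass_cv, x$per_plate$pass_fold, x$per_plate$pass_z_prime,
      x$inter_plate$pass_fold %in% c(TRUE, NA))
}
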