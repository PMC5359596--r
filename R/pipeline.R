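#' Analysis parameters for the imaging pipeline
#'
#' Collects the tunable parameters of the frame-to-slope pipeline. Defaults
#' follow the platform's robust configuration: 4X binning before dF/F,
#' relative object threshold, a 3-pixel membrane ring, and a small deadband
#' excluding unresponsive pixels from the slope fit.
#'
#' @param bin_factor Binning factor applied to raw counts before dF/F.
#' @param max_shift Registration search radius, raw pixels.
#' @param object_threshold,ring_depth,robust_quantile,smooth_size,min_component
#'   Shape-mask parameters, see [build_shape_mask()].
#' @param f_floor,dff_limit dF/F exclusion rules, see [compute_dff()].
#' @param x_deadband,min_pairs,min_side,slope_method Slope-fit parameters,
#'   see [fit_slope()].
#' @return A list of class `analysis_params`.
#' @export
analysis_params <- function(bin_factor = 4, max_shift = 5,
                            object_threshold = 0.2, ring_depth = 3,
                            robust_quantile = 0.995, smooth_size = 3,
                            min_component = 9, f_floor = 2000,
                            dff_limit = 0.5, x_deadband = 0.002,
                            min_pairs = 50, min_side = 25,
                            slope_method = "ls") {
  structure(
    list(bin_factor = as.integer(bin_factor),
         max_shift = as.integer(max_shift),
         object_threshold = object_threshold, ring_depth = ring_depth,
         robust_quantile = robust_quantile, smooth_size = smooth_size,
         min_component = min_component, f_floor = f_floor,
         dff_limit = dff_limit, x_deadband = x_deadband,
         min_pairs = min_pairs, min_side = min_side,
         slope_method = slope_method),
    class = "analysis_params"
  )
}

#' Analyze one sampling area
#'
#' Runs the full per-area pipeline on a [simulate_passage_pair()] record (or
#' an equivalent list of four frames): register the test passage onto the
#' reference by integer-shift cross-correlation, bin all frames, build the
#' shape mask from the binned reference resting frame, compute both
#' passages' dF/F maps over that common mask, pair pixels, and fit the
#' scatter slope.
#'
#' @param record A `passage_pair` (list with `f_pre_ref`, `f_plateau_ref`,
#'   `f_pre_test`, `f_plateau_test`).
#' @param params An [analysis_params()].
#' @param keep_pairs Keep the pixel pairs in the result (for plotting).
#' @return A one-row tibble: registration shift, pair count, `slope_all`,
#'   `slope_se`, `slope_neg`, `slope_pos`, `rect_index`, `gd_gc`, plus a
#'   `pairs` list-column when `keep_pairs = TRUE`.
#' @export
analyze_area <- function(record, params = analysis_params(),
                         keep_pairs = FALSE) {
  shift <- register_frames(record$f_pre_ref, record$f_pre_test,
                           max_shift = params$max_shift)
  test_pre <- translate_frame(record$f_pre_test, -shift[1], -shift[2])
  test_plat <- translate_frame(record$f_plateau_test, -shift[1], -shift[2])
  b <- params$bin_factor
  ref_pre_b <- bin_image(record$f_pre_ref, b)
  ref_plat_b <- bin_image(record$f_plateau_ref, b)
  test_pre_b <- bin_image(test_pre, b)
  test_plat_b <- bin_image(test_plat, b)
  mask <- build_shape_mask(ref_pre_b,
                           object_threshold = params$object_threshold,
                           ring_depth = params$ring_depth,
                           robust_quantile = params$robust_quantile,
                           smooth_size = params$smooth_size,
                           min_component = params$min_component)
  dff_ref <- compute_dff(ref_pre_b, ref_plat_b, mask, "reference",
                         f_floor = params$f_floor,
                         dff_limit = params$dff_limit)
  dff_test <- compute_dff(test_pre_b, test_plat_b, mask, "test",
                          f_floor = params$f_floor,
                          dff_limit = params$dff_limit)
  pairs <- pair_pixels(dff_ref, dff_test)
  fit <- fit_slope(pairs, x_deadband = params$x_deadband,
                   min_pairs = params$min_pairs,
                   min_side = params$min_side,
                   method = params$slope_method)
  out <- tibble(
    shift_row = shift[1], shift_col = shift[2],
    n_mask = nrow(mask), n_pairs = fit$n_pairs,
    slope_all = fit$slope_all, slope_se = fit$slope_se,
    slope_neg = fit$slope_neg, slope_pos = fit$slope_pos,
    rect_index = as.numeric(rectification_index(fit)),
    gd_gc = to_conductance(fit))
  if (keep_pairs) out$pairs <- list(pairs)
  out
}

#' Analyze a simulated (or loaded) plate
#'
#' Maps [analyze_area()] over every sampling area of a [simulate_plate()]
#' result (or of [read_plate()] output), isolating per-area failures,
#' aggregates per-well statistics (mean and standard error of the per-area
#' conductance ratios Gd/Gc), and - unless the plate is flat - fits the
#' concentration-response curve on the per-well means weighted by their
#' standard errors.
#'
#' @param sim A `plate_sim` tibble.
#' @param params An [analysis_params()].
#' @param fit_curve Fit the CRC on the per-well summary (default `TRUE`).
#' @param keep_pairs Passed to [analyze_area()].
#' @param flat_tol Passed to [fit_crc()].
#' @return A list of class `plate_analysis`: `areas` (per-area tibble with
#'   an `ok` flag and failure notes), `wells` (per-well summary), `crc`
#'   (a `crc_fit` or `NULL`), `z_prime` (Z' between lowest- and
#'   highest-concentration per-area Gd/Gc, when defined), `params`, and
#'   provenance (`config_hash`, `seed`).
#' @export
analyze_plate <- function(sim, params = analysis_params(), fit_curve = TRUE,
                          keep_pairs = FALSE, flat_tol = 0.1) {
  stopifnot(is.data.frame(sim), "record" %in% names(sim))
  res <- map(sim$record, function(rec) {
    tryCatch(
      cbind(analyze_area(rec, params, keep_pairs = keep_pairs),
            tibble(ok = TRUE, note = NA_character_)),
      error = function(e) {
        tibble(shift_row = NA_integer_, shift_col = NA_integer_,
               n_mask = NA_integer_, n_pairs = NA_integer_,
               slope_all = NA_real_, slope_se = NA_real_,
               slope_neg = NA_real_, slope_pos = NA_real_,
               rect_index = NA_real_, gd_gc = NA_real_,
               ok = FALSE, note = conditionMessage(e))
      })
  })
  areas <- bind_cols(
    sim[, c("well", "well_index", "area", "concentration", "seed")],
    list_rbind(res))
  if (!any(areas$ok)) abort("all sampling areas failed analysis")
  wells <- areas |>
    filter(.data$ok) |>
    group_by(.data$well, .data$well_index, .data$concentration) |>
    summarise(n_areas = dplyr::n(),
              slope_mean = mean(.data$slope_all),
              gd_gc_mean = mean(.data$gd_gc),
              gd_gc_se = sd(.data$gd_gc) / sqrt(dplyr::n()),
              rect_index_mean = mean(.data$rect_index),
              .groups = "drop") |>
    arrange(.data$well_index)
  crc <- NULL
  if (fit_curve) {
    pts <- tibble(concentration = wells$concentration,
                  response = wells$gd_gc_mean, se = wells$gd_gc_se)
    crc <- tryCatch(fit_crc(pts, flat_tol = flat_tol),
                    error = function(e) NULL)
  }
  z_prime <- {
    cmin <- min(wells$concentration)
    cmax <- max(wells$concentration)
    lo <- areas$gd_gc[areas$ok & areas$concentration == cmin]
    hi <- areas$gd_gc[areas$ok & areas$concentration == cmax]
    if (cmax > cmin && length(lo) >= 2 && length(hi) >= 2 &&
        mean(lo) != mean(hi)) z_factor(hi, lo) else NA_real_
  }
  structure(list(areas = areas, wells = wells, crc = crc, z_prime = z_prime,
                 params = params,
                 config_hash = attr(sim, "config_hash"),
                 config = attr(sim, "config")),
            class = "plate_analysis")
}

#' @export
print.plate_analysis <- function(x, ...) {
  cat(sprintf("<plate_analysis> %d/%d areas analyzed, %d wells\n",
              sum(x$areas$ok), nrow(x$areas), nrow(x$wells)))
  print(as.data.frame(x$wells), row.names = FALSE, digits = 4)
  if (!is.null(x$crc)) print(x$crc)
  if (is.finite(x$z_prime)) cat(sprintf("Z' (min vs max conc): %.3f\n",
                                        x$z_prime))
  invisible(x)
}

#' @export
glance.plate_analysis <- function(x, ...) {
  base <- tibble(n_areas_ok = sum(x$areas$ok), n_areas = nrow(x$areas),
                 n_wells = nrow(x$wells), z_prime = x$z_prime)
  if (!is.null(x$crc)) bind_cols(base, glance(x$crc)) else base
}

#' Score recovery of ground truth from an analyzed plate
#'
#' Compares the analysis of a simulated plate against the simulator's
#' ground truth: per-well conductance fold versus recovered mean Gd/Gc, and
#' (when both sides have one) configured versus fitted EC50 and Hill
#' coefficient. The configuration hash of the analysis must match the
#' simulation it came from.
#'
#' @param analysis A [analyze_plate()] result.
#' @param sim The `plate_sim` the analysis was computed from.
#' @return A tibble with columns `quantity`, `truth`, `estimate`,
#'   `rel_error`.
#' @export
score_recovery <- function(analysis, sim) {
  stopifnot(inherits(analysis, "plate_analysis"))
  if (!identical(analysis$config_hash, attr(sim, "config_hash"))) {
    abort("manifest mismatch: analysis does not derive from this simulation")
  }
  truth_fold <- map_dbl(sim$record, function(r) r$truth$g_fold)
  truth <- tibble(well = sim$well, area = sim$area, g_fold = truth_fold) |>
    group_by(.data$well) |>
    summarise(g_fold = mean(.data$g_fold), .groups = "drop")
  wells <- left_join(analysis$wells, truth, by = "well")
  out <- tibble(
    quantity = paste0("g_fold_", wells$well),
    truth = wells$g_fold,
    estimate = wells$gd_gc_mean)
  cfg <- analysis$config
  if (!is.null(analysis$crc) && !analysis$crc$flat &&
      !is.null(cfg$drug$ec50)) {
    out <- bind_rows(out, tibble(
      quantity = c("ec50", "hill"),
      truth = c(cfg$drug$ec50, cfg$drug$hill),
      estimate = c(analysis$crc$ec50, analysis$crc$hill)))
  }
  out$rel_error <- abs(out$estimate - out$truth) / abs(out$truth)
  out
}
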