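#' Per-pixel fractional fluorescence change over a shape mask
#'
#' Computes `dF/F_R = (F_S - F_R) / F_R` for every mask pixel, where `F_R`
#' is the pre-pulse (resting) frame and `F_S` the plateau frame of one
#' passage. Normalizing each passage to its own resting frame cancels dye
#' bleaching and any global illumination change between passages. Pixels are
#' excluded (and counted) when the resting value is at or below the floor,
#' when either frame is non-finite (e.g. registration fill), or when the
#' value falls outside the plausibility window `|dF/F| > dff_limit`. An area
#' with more than half of its mask excluded is unusable.
#'
#' @param pre,plateau Binned, registered frames (numeric matrices of equal
#'   dimensions matching the mask provenance).
#' @param mask A [build_shape_mask()] result (built on the reference
#'   passage's resting frame and shared by both passages).
#' @param passage Passage tag, `"reference"` or `"test"`.
#' @param f_floor Minimum admissible resting value, counts.
#' @param dff_limit Plausibility bound on `|dF/F|`.
#' @return A tibble of class `dff_map` with columns `row`, `col` (0-based)
#'   and `dff`, restricted to retained pixels. Attributes: `passage`,
#'   `n_mask`, `n_excluded` (list by reason), and the originating `mask`.
#' @export
compute_dff <- function(pre, plateau, mask, passage = "reference",
                        f_floor = 2000, dff_limit = 0.5) {
  stopifnot(inherits(mask, "shape_mask"), all(dim(pre) == dim(plateau)))
  ij <- cbind(mask$row + 1L, mask$col + 1L)
  f_r <- pre[ij]
  f_s <- plateau[ij]
  bad_floor <- !is.finite(f_r) | !is.finite(f_s) | f_r <= f_floor
  dff <- rep(NA_real_, length(f_r))
  dff[!bad_floor] <- (f_s[!bad_floor] - f_r[!bad_floor]) / f_r[!bad_floor]
  bad_window <- !bad_floor & abs(dff) > dff_limit
  keep <- !bad_floor & !bad_window
  if (sum(keep) < 0.5 * nrow(mask)) {
    abort("unusable area: more than 50% of mask pixels excluded")
  }
  out <- tibble(row = mask$row[keep], col = mask$col[keep], dff = dff[keep])
  structure(out, class = c("dff_map", class(out)),
            passage = passage, n_mask = nrow(mask),
            n_excluded = list(floor = sum(bad_floor),
                              window = sum(bad_window)),
            mask_id = mask_signature(mask))
}

mask_signature <- function(mask) {
  c(n = nrow(mask), sum_row = sum(mask$row), sum_col = sum(mask$col),
    dim = attr(mask, "provenance")$dim)
}

#' Frequency distribution of dF/F values
#'
#' Histogram of a [compute_dff()] map with bins symmetric about zero (zero is
#' a bin center), the representation used to visualize how responses cluster
#' toward zero as channel-opening drug concentrations rise.
#'
#' @param map A `dff_map` (or any numeric vector of dF/F values).
#' @param bin_width Bin width in dF/F units (> 0).
#' @return A tibble of class `dff_histogram` with bin `mid` points and
#'   `count`; counts sum to the number of included pixels.
#' @export
dff_histogram <- function(map, bin_width = 0.005) {
  if (bin_width <= 0) abort("`bin_width` must be > 0")
  v <- if (is.data.frame(map)) map$dff else as.numeric(map)
  if (length(v) == 0) abort("empty dF/F map")
  idx <- round(v / bin_width)
  rng <- range(idx)
  mids <- seq(rng[1], rng[2]) * bin_width
  counts <- tabulate(idx - rng[1] + 1L, nbins = rng[2] - rng[1] + 1L)
  out <- tibble(mid = mids, count = as.integer(counts))
  structure(out, class = c("dff_histogram", class(out)),
            bin_width = bin_width,
            passage = attr(map, "passage") %||% NA_character_)
}
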