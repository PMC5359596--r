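#' Build the membrane-ring shape mask
#'
#' Selects the analyzed pixels of a (binned) resting frame in two steps
#' mirroring the platform's shape-mask rule: (1) *cell recognition* -
#' pixels above `object_threshold` times a robust intensity maximum, after
#' light uniform smoothing; (2) *membrane confinement* - of those, keep the
#' ring within `ring_depth` pixels of the object boundary (foreground minus
#' its morphological erosion by a disc of radius `ring_depth`). Connected
#' components smaller than `min_component` pixels are dropped as debris.
#'
#' The mask is built once from the reference passage's resting frame and
#' reused for the test passage, so reference and test dF/F values are paired
#' within the same individual pixels.
#'
#' @param resting_frame Binned resting (pre-pulse) frame, numeric matrix.
#' @param object_threshold Fraction (0, 1) of the robust maximum intensity
#'   above which a pixel belongs to a cell.
#' @param ring_depth Ring depth in (binned) pixels (>= 1).
#' @param robust_quantile Quantile used as the robust maximum (guards against
#'   hot pixels).
#' @param smooth_size Side of the uniform smoothing kernel (odd; 1 = none).
#' @param min_component Minimum connected-component size kept, pixels.
#' @param min_mask Minimum total mask size; below it the area is not
#'   analyzable.
#' @return A tibble of class `shape_mask` with 0-based `row`, `col`
#'   coordinates (sorted), carrying its construction parameters as the
#'   `provenance` attribute.
#' @export
build_shape_mask <- function(resting_frame, object_threshold = 0.2,
                             ring_depth = 3, robust_quantile = 0.995,
                             smooth_size = 3, min_component = 9,
                             min_mask = 25) {
  if (object_threshold <= 0 || object_threshold >= 1) {
    abort("`object_threshold` must be in (0, 1)")
  }
  if (ring_depth < 1) abort("`ring_depth` must be >= 1")
  frame <- resting_frame
  frame[!is.finite(frame)] <- 0
  if (smooth_size > 1) {
    kern <- matrix(1 / smooth_size^2, smooth_size, smooth_size)
    frame <- filter2(frame, kern, boundary = "replicate")
  }
  cut <- object_threshold * quantile(frame, robust_quantile, names = FALSE)
  fg <- frame > cut
  if (!any(fg)) abort("no cells detected: empty foreground")
  fg_num <- matrix(as.numeric(fg), nrow(fg), ncol(fg))
  brush <- makeBrush(2L * as.integer(ring_depth) + 1L, shape = "disc")
  core <- erode(fg_num, brush) > 0.5
  ring <- fg & !core
  # drop small debris components (8-connectivity)
  labels <- bwlabel(matrix(as.numeric(ring), nrow(ring), ncol(ring)))
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= min_component)
  ring <- ring & matrix(labels %in% keep, nrow(ring), ncol(ring))
  idx <- which(ring, arr.ind = TRUE)
  if (nrow(idx) < min_mask) abort("insufficient mask: too few ring pixels")
  mask <- tibble(row = as.integer(idx[, 1] - 1L),
                 col = as.integer(idx[, 2] - 1L))
  mask <- arrange(mask, .data$row, .data$col)
  structure(mask, class = c("shape_mask", class(mask)),
            provenance = list(object_threshold = object_threshold,
                              ring_depth = ring_depth,
                              robust_quantile = robust_quantile,
                              smooth_size = smooth_size,
                              min_component = min_component,
                              dim = dim(resting_frame)))
}

#' Export a shape mask as a binary image matrix
#'
#' @param mask A [build_shape_mask()] result.
#' @param dim Image dimensions; defaults to the provenance dimensions.
#' @return A 0/1 matrix suitable for [tiff::writeTIFF()] or [png::writePNG()].
#' @export
mask_to_image <- function(mask, dim = attr(mask, "provenance")$dim) {
  img <- matrix(0, dim[1], dim[2])
  img[cbind(mask$row + 1L, mask$col + 1L)] <- 1
  img
}
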