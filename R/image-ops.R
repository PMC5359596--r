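#' Estimate the rigid integer shift between two frames
#'
#' Brute-force normalized cross-correlation over all integer shifts within
#' `±max_shift` on both axes, on the overlapping region of the two frames.
#' Returns the shift `(drow, dcol)` such that
#' `test[r, c] ~ reference[r - drow, c - dcol]`; translating the test frame
#' by the negated shift (see [translate_frame()]) re-registers it onto the
#' reference. Ties are broken toward the smaller shift, lexicographically on
#' `(|drow| + |dcol|, drow, dcol)`.
#'
#' @param reference,test Numeric matrices of identical dimensions.
#' @param max_shift Maximum absolute shift searched per axis (>= 0).
#' @return Integer vector `(drow, dcol)`.
#' @export
#' @examples
#' ref <- matrix(rnorm(400), 20, 20)
#' tst <- translate_frame(ref, 3, -2, fill = 0)
#' register_frames(ref, tst, max_shift = 5)
register_frames <- function(reference, test, max_shift = 5) {
  stopifnot(is.matrix(reference), is.matrix(test),
            all(dim(reference) == dim(test)))
  if (max_shift < 0) abort("`max_shift` must be >= 0")
  if (sd(reference, na.rm = TRUE) == 0 || sd(test, na.rm = TRUE) == 0) {
    abort("unregistrable: flat (zero-variance) frame")
  }
  if (max_shift == 0) return(c(0L, 0L))
  nr <- nrow(reference); nc <- ncol(reference)
  cand <- expand.grid(dr = -max_shift:max_shift, dc = -max_shift:max_shift)
  cand <- cand[order(abs(cand$dr) + abs(cand$dc), cand$dr, cand$dc), ]
  best <- -Inf
  best_shift <- c(0L, 0L)
  for (i in seq_len(nrow(cand))) {
    dr <- cand$dr[i]; dc <- cand$dc[i]
    r_ref <- max(1, 1 + dr):min(nr, nr + dr)
    c_ref <- max(1, 1 + dc):min(nc, nc + dc)
    a <- reference[r_ref - dr, c_ref - dc]
    b <- test[r_ref, c_ref]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 9) next
    score <- suppressWarnings(cor(a[ok], b[ok]))
    if (is.finite(score) && score > best) {
      best <- score
      best_shift <- c(as.integer(dr), as.integer(dc))
    }
  }
  if (!is.finite(best)) abort("unregistrable: no valid overlap")
  best_shift
}

#' Translate a frame by an integer shift
#'
#' Moves the frame content by `(drow, dcol)`: the output satisfies
#' `out[r, c] = frame[r - drow, c - dcol]`. Pixels with no source are set to
#' `fill` (default `NA`, which downstream binning and dF/F computation treat
#' as unusable).
#'
#' @param frame Numeric matrix.
#' @param drow,dcol Integer shift.
#' @param fill Value for uncovered pixels.
#' @return Matrix of the same dimensions.
#' @export
translate_frame <- function(frame, drow, dcol, fill = NA_real_) {
  nr <- nrow(frame); nc <- ncol(frame)
  out <- matrix(fill, nr, nc)
  r_dst <- max(1, 1 + drow):min(nr, nr + drow)
  c_dst <- max(1, 1 + dcol):min(nc, nc + dcol)
  if (length(r_dst) > 0 && length(c_dst) > 0) {
    out[r_dst, c_dst] <- frame[r_dst - drow, c_dst - dcol]
  }
  out
}

#' Bin an image by block averaging
#'
#' Averages non-overlapping `factor x factor` blocks of raw counts (the
#' noise-reduction step applied before any dF/F computation). Trailing rows
#' and columns that do not fill a block are cropped. Blocks containing
#' non-finite pixels (e.g. from registration fill) propagate `NA`.
#'
#' @param frame Numeric matrix.
#' @param factor Integer binning factor (>= 1).
#' @return Matrix of dimensions `floor(dim(frame) / factor)`.
#' @export
#' @examples
#' bin_image(matrix(1:4, 2, 2), 2)  # 2.5
bin_image <- function(frame, factor) {
  if (length(factor) != 1 || factor < 1 || factor != round(factor)) {
    abort("`factor` must be a positive integer")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(frame)
  nr <- (nrow(frame) %/% factor) * factor
  nc <- (ncol(frame) %/% factor) * factor
  if (nr < factor || nc < factor) abort("frame smaller than one block")
  m <- frame[seq_len(nr), seq_len(nc), drop = FALSE]
  # rows: average factor-sized row groups, then the same on columns
  m1 <- matrix(colMeans(matrix(m, nrow = factor)), nrow = nr %/% factor)
  m2 <- matrix(colMeans(matrix(t(m1), nrow = factor)), nrow = nc %/% factor)
  t(m2)
}
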