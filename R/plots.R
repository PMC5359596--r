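#' @export
autoplot.dff_histogram <- function(object, ...) {
  ggplot(object, aes(x = .data$mid, y = .data$count)) +
    geom_step() +
    labs(x = expression(Delta * F / F[R]), y = "Pixel count") +
    theme_minimal()
}

#' Overlay reference and test dF/F distributions
#'
#' Frequency-polygon overlay of the reference- and test-passage dF/F
#' histograms of one sampling area; with an effective channel opener the
#' test distribution collapses toward zero.
#'
#' @param ref,test `dff_map` objects of the two passages.
#' @param bin_width Histogram bin width.
#' @return A ggplot object.
#' @export
plot_dff_distributions <- function(ref, test, bin_width = 0.005) {
  h1 <- dff_histogram(ref, bin_width)
  h2 <- dff_histogram(test, bin_width)
  d <- bind_rows(mutate(as_tibble(h1), passage = "reference"),
                 mutate(as_tibble(h2), passage = "test"))
  ggplot(d, aes(x = .data$mid, y = .data$count, colour = .data$passage)) +
    geom_step() +
    scale_colour_manual(values = c(reference = "#2166ac", test = "#b2182b")) +
    labs(x = expression(Delta * F / F[R]), y = "Pixel count",
         colour = NULL) +
    theme_minimal()
}

#' @export
autoplot.pixel_pairs <- function(object, slope = NULL, ...) {
  p <- ggplot(object, aes(x = .data$x, y = .data$y)) +
    geom_point(alpha = 0.3, size = 0.6, colour = "#2166ac") +
    geom_hline(yintercept = 0, linewidth = 0.2) +
    geom_vline(xintercept = 0, linewidth = 0.2) +
    labs(x = expression(Delta * F[c] / F[Rc]),
         y = expression(Delta * F[d] / F[Rd])) +
    theme_minimal()
  if (!is.null(slope)) {
    p <- p + geom_abline(slope = slope, intercept = 0, colour = "#b2182b",
                         linewidth = 0.8)
  }
  p
}

#' @export
autoplot.crc_fit <- function(object, n_curve = 200, ...) {
  d <- object$data
  p <- ggplot(d, aes(x = .data$concentration, y = .data$response)) +
    geom_point() +
    scale_x_log10() +
    labs(x = "Concentration (M)", y = "Gd/Gc") +
    theme_minimal()
  if ("se" %in% names(d)) {
    p <- p + geom_errorbar(aes(ymin = .data$response - .data$se,
                               ymax = .data$response + .data$se),
                           width = 0.05)
  }
  if (!object$flat) {
    cc <- 10^seq(log10(min(d$concentration)), log10(max(d$concentration)),
                 length.out = n_curve)
    curve <- tibble(concentration = cc, response = predict(object, cc))
    p <- p + geom_line(data = curve, colour = "#b2182b")
  }
  p
}

#' Overlay normalized concentration-response curves
#'
#' Min-Max normalizes each fitted curve (after fitting, for display only)
#' and overlays them on a common semilogarithmic axis - the representation
#' used to compare replicate plates.
#'
#' @param fits Named list of `crc_fit` objects (non-flat).
#' @param n_curve Points per curve.
#' @return A ggplot object.
#' @export
plot_crc_overlay <- function(fits, n_curve = 200) {
  stopifnot(length(fits) >= 1)
  if (is.null(names(fits))) names(fits) <- paste0("curve", seq_along(fits))
  d <- imap(fits, function(f, nm) {
    if (f$flat) return(NULL)
    cc <- 10^seq(log10(min(f$data$concentration)),
                 log10(max(f$data$concentration)), length.out = n_curve)
    tibble(curve = nm, concentration = cc,
           response = minmax_normalize(predict(f, cc)))
  })
  d <- list_rbind(d[!map_lgl(d, is.null)])
  ggplot(d, aes(x = .data$concentration, y = .data$response,
                colour = .data$curve)) +
    geom_line() +
    scale_x_log10() +
    labs(x = "Concentration (M)", y = "Normalized response (Min-Max)",
         colour = NULL) +
    theme_minimal()
}
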