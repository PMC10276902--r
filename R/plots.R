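#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a genome-wide wavelet power spectrum
#'
#' Wavelet variance against scale (log2 axis, map units), with jackknife
#' intervals where available; the among-chromosome and scaling components are
#' shown as labelled points beyond the largest scale.
#'
#' @param object A `gnom_var_decomp` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gnom_var_decomp <- function(object, ...) {
  d <- tidy(object)
  wav <- d[!is.na(d$level), ]
  ggplot2::ggplot(wav, ggplot2::aes(x = .data$scale_map, y = .data$variance)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                           width = 0.15, na.rm = TRUE) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "scale (map units)", y = "wavelet variance") +
    ggplot2::theme_minimal()
}

#' Plot a genome-wide wavelet correlation decomposition
#'
#' Per-scale wavelet correlations (points, with jackknife intervals) and each
#' scale's contribution to the overall correlation (bars).
#'
#' @param object A `gnom_cor_decomp` object.
#' @param what `"correlation"` or `"contribution"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gnom_cor_decomp <- function(object, what = c("correlation", "contribution"),
                                     ...) {
  what <- match.arg(what)
  d <- tidy(object)
  wav <- d[!is.na(d$level), ]
  if (what == "correlation") {
    ggplot2::ggplot(wav, ggplot2::aes(x = .data$scale_map, y = .data$correlation)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                             width = 0.15, na.rm = TRUE) +
      ggplot2::geom_point(na.rm = TRUE) +
      ggplot2::scale_x_continuous(trans = "log2") +
      ggplot2::labs(x = "scale (map units)", y = "wavelet correlation") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(wav, ggplot2::aes(x = factor(signif(.data$scale_map, 3)),
                                      y = .data$contribution)) +
      ggplot2::geom_col() +
      ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
      ggplot2::labs(x = "scale (map units)", y = "contribution to correlation") +
      ggplot2::theme_minimal()
  }
}

#' Power-spectrum plot for one or more signals
#'
#' Convenience wrapper: computes [gnom_var_decomp()] for each signal in a
#' named list and overlays their spectra.
#'
#' @param signals A named list of `chrom`/`pos`/`value` data frames (or a
#'   single data frame).
#' @param estimator Passed to [gnom_var_decomp()].
#' @return A ggplot.
#' @export
plot_power_spectrum <- function(signals, estimator = "unbiased") {
  if (is.data.frame(signals)) signals <- list(signal = signals)
  d <- purrr::map_dfr(signals, function(s) {
    tidy(gnom_var_decomp(s, estimator = estimator, jackknife = FALSE))
  }, .id = "signal")
  d <- d[!is.na(d$level), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$scale_map, y = .data$variance,
                                  colour = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "scale (map units)", y = "wavelet variance") +
    ggplot2::theme_minimal()
}
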