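#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a genome-wide variance decomposition
#'
#' @param x A `gnom_var_decomp` object.
#' @param ... Unused.
#' @return A plain tibble, one row per component.
#' @export
tidy.gnom_var_decomp <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  attr(out, "total_variance") <- NULL
  attr(out, "resolution") <- NULL
  attr(out, "estimator") <- NULL
  attr(out, "statistic") <- NULL
  out
}

#' @rdname tidy.gnom_var_decomp
#' @export
tidy.gnom_cor_decomp <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  attr(out, "correlation") <- NULL
  attr(out, "resolution") <- NULL
  attr(out, "estimator") <- NULL
  attr(out, "statistic") <- NULL
  out
}

#' One-row summary of a variance decomposition
#'
#' @param x A `gnom_var_decomp` object.
#' @param ... Unused.
#' @return Tibble with total variance, number of wavelet scales, number of
#'   chromosomes, and the estimator used.
#' @export
glance.gnom_var_decomp <- function(x, ...) {
  tibble::tibble(
    total_variance = attr(x, "total_variance"),
    n_scales = sum(!is.na(x$level)),
    n_chrom = max(x$n_chrom),
    resolution = attr(x, "resolution"),
    estimator = attr(x, "estimator")
  )
}

#' One-row summary of a correlation decomposition
#'
#' @param x A `gnom_cor_decomp` object.
#' @param ... Unused.
#' @return Tibble with the reconstructed overall correlation, number of
#'   scales, chromosomes, and the estimator used.
#' @export
glance.gnom_cor_decomp <- function(x, ...) {
  tibble::tibble(
    correlation = attr(x, "correlation"),
    n_scales = sum(!is.na(x$level)),
    n_chrom = max(x$n_chrom),
    resolution = attr(x, "resolution"),
    estimator = attr(x, "estimator")
  )
}
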