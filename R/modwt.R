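#' Haar maximal-overlap discrete wavelet transform of a gridded signal
#'
#' Decomposes an evenly spaced signal into Haar wavelet coefficients at dyadic
#' scales using the maximal-overlap discrete wavelet transform (MODWT). Unlike
#' the decimated transform, the MODWT places a wavelet at every position, so
#' each level carries a full-length coefficient vector and the decomposition is
#' shift-covariant. Filters follow the Percival-Walden MODWT normalization
#' (level-1 wavelet filter (1/2, -1/2), level-j coefficients rescaled by
#' 2^-j), under which the squared coefficients partition the signal variance
#' exactly (see [wavelet_variance()]).
#'
#' Circular (periodic) convolution is used; coefficients whose filter support
#' wraps the chromosome end are flagged as boundary coefficients and can be
#' excluded downstream for unbiased variance estimation.
#'
#' @param signal Either a numeric vector, or a data frame with columns
#'   `chrom`, `pos`, `value` holding one chromosome on an even grid.
#' @param max_level Optional cap on the number of levels. The natural maximum
#'   is `floor(log2(L))` for a signal of length `L`; larger requests are capped
#'   with a warning.
#' @return An object of class `haar_modwt`: a list with the coefficient matrix
#'   `W` (`L` rows, one column per level), the level-J scaling coefficients
#'   `V`, the per-level count of boundary coefficients, and bookkeeping fields
#'   (`L`, `levels`, `resolution`, `chromosome`, `x_mean`, `x_var`).
#' @examples
#' d <- modwt_haar(sin(seq_len(128) / 8))
#' wavelet_variance(d)
#' @export
modwt_haar <- function(signal, max_level = NULL) {
  if (is.data.frame(signal)) {
    stopifnot(all(c("pos", "value") %in% names(signal)))
    chrom <- if ("chrom" %in% names(signal)) as.character(signal$chrom[1]) else NA_character_
    if ("chrom" %in% names(signal) && length(unique(signal$chrom)) > 1L) {
      stop("modwt_haar() operates on a single chromosome; got ",
           length(unique(signal$chrom)), ". See gnom_var_decomp() for genome-wide use.")
    }
    x <- as.numeric(signal$value)
    res <- .grid_resolution(signal$pos)
  } else {
    chrom <- NA_character_
    x <- as.numeric(signal)
    res <- 1
  }
  L <- length(x)
  if (L < 2L) stop("signal must have length >= 2")
  if (anyNA(x) || any(!is.finite(x))) stop("signal values must be finite; gaps are an interpolation concern")
  J <- floor(log2(L))
  if (!is.null(max_level)) {
    if (max_level < 1L) stop("max_level must be >= 1")
    if (max_level > J) {
      warning("max_level ", max_level, " exceeds floor(log2(L)) = ", J, "; capped")
    }
    J <- min(J, as.integer(max_level))
  }
  W <- matrix(0, nrow = L, ncol = J)
  V <- x
  idx <- seq_len(L)
  for (j in seq_len(J)) {
    shift <- 2^(j - 1L)
    lag <- ((idx - 1L - shift) %% L) + 1L
    Vlag <- V[lag]
    W[, j] <- (V - Vlag) / 2
    V <- (V + Vlag) / 2
  }
  n_boundary <- pmin(L, 2^seq_len(J) - 1L)
  structure(
    list(
      W = W, V = V, L = L, levels = seq_len(J),
      n_boundary = n_boundary,
      resolution = res, chromosome = chrom,
      x_mean = mean(x), x_var = mean((x - mean(x))^2)
    ),
    class = "haar_modwt"
  )
}

#' @export
print.haar_modwt <- function(x, ...) {
  cat("Haar MODWT:", x$L, "points,", length(x$levels), "levels",
      if (!is.na(x$chromosome)) paste0("(", x$chromosome, ")"), "\n")
  invisible(x)
}

# Non-boundary coefficient indices at level j: the level-j equivalent filter
# spans 2^j points ending at i, so i = 1 .. 2^j - 1 wrap the chromosome start.
.nonboundary_idx <- function(L, j) {
  first <- 2^j
  if (first > L) integer(0) else seq.int(first, L)
}

#' Inverse Haar MODWT
#'
#' Reconstructs the signal from a [modwt_haar()] decomposition. The MODWT
#' analysis operator has an exact left inverse (its transpose), so the round
#' trip is exact to numerical precision.
#'
#' @param decomp A `haar_modwt` object.
#' @return Numeric vector of length `L`.
#' @export
imodwt_haar <- function(decomp) {
  stopifnot(inherits(decomp, "haar_modwt"))
  L <- decomp$L
  idx <- seq_len(L)
  V <- decomp$V
  for (j in rev(decomp$levels)) {
    shift <- 2^(j - 1L)
    lead <- ((idx - 1L + shift) %% L) + 1L
    W <- decomp$W[, j]
    V <- (V + V[lead]) / 2 + (W - W[lead]) / 2
  }
  V
}

# Per-level second-moment machinery shared by variance/covariance/correlation.
# Returns sums and counts so genome-wide pooling can reweight chromosomes.
.level_products <- function(dx, dy, estimator) {
  J <- length(dx$levels)
  prod_mat <- dx$W * dy$W
  if (estimator == "biased") {
    n <- rep(dx$L, J)
    sums <- colSums(prod_mat)
  } else {
    n <- integer(J)
    sums <- numeric(J)
    for (j in seq_len(J)) {
      keep <- .nonboundary_idx(dx$L, j)
      n[j] <- length(keep)
      sums[j] <- sum(prod_mat[keep, j])
    }
  }
  list(sum = sums, n = n)
}

.check_pair <- function(dx, dy) {
  stopifnot(inherits(dx, "haar_modwt"), inherits(dy, "haar_modwt"))
  if (dx$L != dy$L) stop("decompositions have mismatched lengths: ", dx$L, " vs ", dy$L)
  if (length(dx$levels) != length(dy$levels)) stop("decompositions have mismatched level counts")
  invisible(TRUE)
}

#' Wavelet variance (power spectrum) of one chromosome
#'
#' Averages squared MODWT coefficients at each scale. The `biased` estimator
#' averages over all `L` coefficients and is energy-exact: the per-scale
#' variances plus the scaling variance sum to the population variance of the
#' signal. The `unbiased` estimator (default, as used for reporting) excludes
#' boundary coefficients whose support wraps the chromosome end.
#'
#' The scale reported for level `j` is `2^j` grid units (`scale_map` converts
#' to map units via the grid resolution). The scaling variance is the variance
#' of the level-J smooth coefficients about the grand mean; it is the leftover
#' component present whenever `L` is not a power of two.
#'
#' @param decomp A `haar_modwt` object.
#' @param estimator `"unbiased"` (boundary coefficients removed) or `"biased"`
#'   (all coefficients; exact energy decomposition).
#' @return A tibble of class `scale_spectrum` with columns `component`
#'   (`"wavelet"` or `"scaling"`), `level`, `scale`, `scale_map`, `variance`,
#'   `n_coef`; the total signal variance is attached as attribute
#'   `total_variance`. Levels with no non-boundary coefficients are reported
#'   with `NA` variance.
#' @export
wavelet_variance <- function(decomp, estimator = c("unbiased", "biased")) {
  estimator <- match.arg(estimator)
  lp <- .level_products(decomp, decomp, estimator)
  v <- ifelse(lp$n > 0, lp$sum / lp$n, NA_real_)
  scaling <- mean((decomp$V - decomp$x_mean)^2)
  out <- tibble::tibble(
    component = c(rep("wavelet", length(decomp$levels)), "scaling"),
    level = c(decomp$levels, NA_integer_),
    scale = c(2^decomp$levels, NA_real_),
    scale_map = c(2^decomp$levels * decomp$resolution, NA_real_),
    variance = c(v, scaling),
    n_coef = c(lp$n, decomp$L)
  )
  attr(out, "total_variance") <- decomp$x_var
  attr(out, "estimator") <- estimator
  class(out) <- c("scale_spectrum", class(out))
  out
}

#' Per-scale wavelet covariance between two signals on one chromosome
#'
#' Averages products of the two signals' MODWT coefficients at each scale.
#' With the `biased` estimator the per-scale covariances plus the scaling
#' covariance sum exactly to the population covariance of the two signals.
#'
#' @param dx,dy `haar_modwt` objects for the same chromosome (equal length and
#'   levels).
#' @inheritParams wavelet_variance
#' @return A tibble with columns `component`, `level`, `scale`, `scale_map`,
#'   `covariance`, `n_coef`.
#' @export
wavelet_covariance <- function(dx, dy, estimator = c("unbiased", "biased")) {
  estimator <- match.arg(estimator)
  .check_pair(dx, dy)
  lp <- .level_products(dx, dy, estimator)
  cv <- ifelse(lp$n > 0, lp$sum / lp$n, NA_real_)
  scaling <- mean((dx$V - dx$x_mean) * (dy$V - dy$x_mean))
  tibble::tibble(
    component = c(rep("wavelet", length(dx$levels)), "scaling"),
    level = c(dx$levels, NA_integer_),
    scale = c(2^dx$levels, NA_real_),
    scale_map = c(2^dx$levels * dx$resolution, NA_real_),
    covariance = c(cv, scaling),
    n_coef = c(lp$n, dx$L)
  )
}

#' Per-scale wavelet correlation between two signals on one chromosome
#'
#' Correlation of the two signals' MODWT coefficients at each scale,
#' `cov / sqrt(var_x * var_y)`. Scales at which either signal has zero
#' wavelet variance are undefined and reported as `NA` (not zero).
#'
#' @inheritParams wavelet_covariance
#' @return A tibble with columns `component`, `level`, `scale`, `scale_map`,
#'   `correlation`, `n_coef`.
#' @export
wavelet_correlation <- function(dx, dy, estimator = c("unbiased", "biased")) {
  estimator <- match.arg(estimator)
  .check_pair(dx, dy)
  cv <- .level_products(dx, dy, estimator)
  vx <- .level_products(dx, dx, estimator)
  vy <- .level_products(dy, dy, estimator)
  denom <- sqrt(vx$sum * vy$sum)
  rho <- ifelse(cv$n > 0 & denom > 0, cv$sum / denom, NA_real_)
  sc_x <- mean((dx$V - dx$x_mean)^2)
  sc_y <- mean((dy$V - dy$x_mean)^2)
  sc_cov <- mean((dx$V - dx$x_mean) * (dy$V - dy$x_mean))
  sc_rho <- if (sc_x > 0 && sc_y > 0) sc_cov / sqrt(sc_x * sc_y) else NA_real_
  tibble::tibble(
    component = c(rep("wavelet", length(dx$levels)), "scaling"),
    level = c(dx$levels, NA_integer_),
    scale = c(2^dx$levels, NA_real_),
    scale_map = c(2^dx$levels * dx$resolution, NA_real_),
    correlation = c(rho, sc_rho),
    n_coef = c(cv$n, dx$L)
  )
}

# Resolution of an even grid, with a tolerance check for evenness.
.grid_resolution <- function(pos, tol = 1e-6) {
  d <- diff(pos)
  if (length(d) == 0L) stop("grid must have >= 2 positions")
  res <- stats::median(d)
  if (res <= 0) stop("positions must be strictly increasing")
  if (any(abs(d - res) > tol * res)) {
    stop("positions are not evenly spaced; interpolate_to_grid() first")
  }
  res
}
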