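# Shared fixture builders and independent oracles.

# white-noise grid signal on one or more chromosomes
mk_signal <- function(L, chrom = "chr1", res = 1, value = NULL) {
  tibble::tibble(
    chrom = chrom,
    pos = (seq_len(L) - 1) * res,
    value = value %||% stats::rnorm(L)
  )
}

mk_multi <- function(Ls, res = 1) {
  dplyr::bind_rows(lapply(seq_along(Ls), function(i) {
    mk_signal(Ls[i], chrom = paste0("chr", i), res = res)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(L^2) direct-summation MODWT oracle: inner products of the signal with
# explicitly constructed, circularly shifted Haar wavelet vectors. The level-j
# wavelet ending at position i takes +2^-j on the 2^(j-1) positions up to i
# and -2^-j on the preceding 2^(j-1) positions (circularly).
direct_haar_modwt <- function(x, j) {
  L <- length(x)
  h <- 2^(j - 1)
  vapply(seq_len(L), function(i) {
    psi <- numeric(L)
    psi[((i - seq_len(h)) %% L) + 1] <- 2^-j
    psi[((i - h - seq_len(h)) %% L) + 1] <- -(2^-j)
    sum(x * psi)
  }, numeric(1))
}

# population (denominator n) variance/covariance
pvar <- function(x) mean((x - mean(x))^2)
pcov <- function(x, y) mean((x - mean(x)) * (y - mean(y)))
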