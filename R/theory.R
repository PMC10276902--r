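#' Expected neutral wavelet variance of the ancestry proportion
#'
#' Closed-form coalescent expectation of the Haar MODWT wavelet variance of
#' the population ancestry-proportion signal after `t` generations of neutral
#' Wright-Fisher drift with recombination, following a single admixture pulse
#' at fraction `alpha`.
#'
#' The expectation follows from the spatial covariance of the ancestry
#' frequency. For two loci separated by `d` Morgans, trace one lineage per
#' locus backward: within a gamete the two loci split onto the parent's two
#' haplotypes with probability `(1 - exp(-2d)) / 2` (Haldane's map function,
#' matching Poisson crossovers without interference), and lineages in
#' different haplotypes coalesce into one with probability `1/2N(t)` per
#' generation. If the lineages reach the founding generation in the same
#' founder haplotype both loci share one pure ancestry; founding with an exact
#' count of `alpha * 2N(0)` introgressed haplotypes gives
#' `Cov(d) = alpha * (1 - alpha) * (f(d) - (1 - f(d)) / (2N(0) - 1))`,
#' with `f(d)` the same-founder-haplotype probability from the two-state
#' chain. At `d = 0` this reduces to the single-locus drift law
#' `alpha * (1 - alpha) * (1 - (1 - 1/2N)^t)`, and at `t = 0` it vanishes for
#' all `d`. The expected wavelet variance at level `j` is the covariance
#' summed against the autocorrelation of the level-`j` MODWT Haar filter
#' (an exact triangular form), and equals the expectation of the unbiased
#' (boundary-free) estimator.
#'
#' @param two_n Population size trajectory in haploid genomes: scalar, or
#'   vector `2N(t)` for `t = 0..generations`.
#' @param generations Generations of drift since the admixture pulse (>= 0).
#' @param levels Wavelet levels `j` to evaluate (scale `2^j` grid units).
#' @param resolution Grid step in Morgans.
#' @param alpha Admixture fraction.
#' @return Tibble with columns `level`, `scale`, `scale_map`, `variance`.
#' @examples
#' expected_neutral_wavelet_variance(200, 10, levels = 1:8, resolution = 2^-10)
#' @export
expected_neutral_wavelet_variance <- function(two_n, generations, levels,
                                              resolution, alpha = 0.5) {
  stopifnot(all(levels >= 1), all(levels == floor(levels)), resolution > 0,
            generations >= 0, alpha > 0, alpha < 1)
  if (length(two_n) == 1L) two_n <- rep(two_n, generations + 1L)
  stopifnot(length(two_n) == generations + 1L, all(two_n >= 2))
  jmax <- max(levels)
  lags <- 0:(2^jmax - 1)
  cc <- .ancestry_freq_cov(lags * resolution, two_n, generations, alpha)
  v <- vapply(levels, function(j) {
    M <- 2^j
    tau <- 0:(M - 1)
    A <- ifelse(tau <= M / 2, (M - 3 * tau) / M^2, (tau - M) / M^2)
    A[1] * cc[1] + 2 * sum(A[-1] * cc[tau[-1] + 1])
  }, numeric(1))
  tibble::tibble(level = as.integer(levels), scale = 2^levels,
                 scale_map = 2^levels * resolution, variance = v)
}

# Covariance of the neutral ancestry frequency between loci separated by d
# Morgans, after `generations` of drift under trajectory two_n (t = 0..T).
.ancestry_freq_cov <- function(d, two_n, generations, alpha) {
  r <- (1 - exp(-2 * d)) / 2
  # two-state lineage chain: C = same gamete/haplotype, A = different
  pC <- rep(1 / two_n[generations + 1L], length(d))
  pA <- 1 - pC
  for (g in rev(seq_len(generations))) {
    coal <- 1 / two_n[g] # size of generation g - 1 (1-based index g)
    pC_new <- pC * (1 - r) + pA * coal
    pA <- pC * r + pA * (1 - coal)
    pC <- pC_new
  }
  alpha * (1 - alpha) * (pC - pA / (two_n[1] - 1))
}
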