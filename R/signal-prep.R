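#' Diploid ancestry dosage from genotype posteriors
#'
#' Converts per-site posterior probabilities of diploid ancestry genotypes
#' (homozygous for ancestry A, heterozygous, homozygous for the other
#' ancestry) into the expected frequency of the A allele within the diploid:
#' `p_hat = P(AA) + P(Aa) / 2`.
#'
#' @param track Data frame with columns `chrom`, `pos`, `pAA`, `pAa`, `paa`.
#' @param tol Tolerance for each posterior triple summing to 1.
#' @return Tibble with columns `chrom`, `pos`, `value`; values lie in [0, 1].
#' @examples
#' diploid_dosage(tibble::tibble(chrom = "chr1", pos = c(100, 200),
#'                               pAA = c(1, 0.2), pAa = c(0, 0.6), paa = c(0, 0.2)))
#' @export
diploid_dosage <- function(track, tol = 1e-6) {
  stopifnot(all(c("chrom", "pos", "pAA", "pAa", "paa") %in% names(track)))
  p <- cbind(track$pAA, track$pAa, track$paa)
  if (any(p < 0 | p > 1)) {
    bad <- which(apply(p < 0 | p > 1, 1, any))[1]
    stop("posterior probabilities outside [0,1] at ", track$chrom[bad],
         ":", track$pos[bad])
  }
  s <- rowSums(p)
  off <- which(abs(s - 1) > tol)
  if (length(off) > 0L) {
    stop("posterior triple does not sum to 1 (", format(s[off[1]]), ") at ",
         track$chrom[off[1]], ":", track$pos[off[1]])
  }
  tibble::tibble(
    chrom = track$chrom, pos = track$pos,
    value = track$pAA + track$pAa / 2
  )
}

#' Interpolate an irregular track onto an even grid
#'
#' Places grid points every `resolution` map units starting at the first
#' observed position of each chromosome and ending at or before the last, then
#' fills values by linear interpolation between flanking observations
#' (`method = "linear"`, suited to proportions and dosages) or by carrying the
#' nearest preceding observation forward (`method = "step"`, suited to
#' piecewise-constant signals such as haploid ancestry state). No
#' extrapolation occurs beyond the observed range.
#'
#' @param track Data frame with columns `chrom`, `pos`, `value`; positions
#'   strictly increasing within each chromosome.
#' @param resolution Grid step, in the track's map units (e.g. 50e3 bp or
#'   2^-12 Morgans).
#' @param method `"linear"` or `"step"`.
#' @return Tibble with columns `chrom`, `pos`, `value` on the even grid.
#' @export
interpolate_to_grid <- function(track, resolution, method = c("linear", "step")) {
  method <- match.arg(method)
  stopifnot(all(c("chrom", "pos", "value") %in% names(track)), resolution > 0)
  track %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::group_modify(function(df, key) {
      pos <- df$pos
      span <- pos[length(pos)] - pos[1]
      if (span < resolution) {
        stop("resolution ", resolution, " exceeds track span ", span,
             " on chromosome ", key$chrom)
      }
      if (is.unsorted(pos, strictly = TRUE)) {
        stop("positions must be strictly increasing (chromosome ", key$chrom, ")")
      }
      grid <- pos[1] + resolution * seq(0L, floor(span / resolution))
      val <- switch(method,
        linear = stats::approx(pos, df$value, xout = grid, method = "linear")$y,
        step = df$value[findInterval(grid, pos)]
      )
      tibble::tibble(pos = grid, value = val)
    }) %>%
    dplyr::ungroup()
}

#' Convert physical positions to genetic-map positions
#'
#' Replaces physical (bp) coordinates with cumulative genetic distance in
#' Morgans from the chromosome start, using a piecewise-constant recombination
#' map. Intervals are half-open `[start, end)`; rank order of positions is
#' preserved.
#'
#' @param track Data frame with columns `chrom`, `pos` (bp), `value`.
#' @param rec_map Data frame with columns `chrom`, `start`, `end`, `rate`;
#'   contiguous, non-overlapping intervals covering the track positions.
#' @param units Units of `rate`: `"Morgan_per_bp"` or `"cM_per_Mb"`.
#' @return Tibble `chrom`, `pos` (Morgans), `value`.
#' @export
physical_to_genetic <- function(track, rec_map,
                                units = c("Morgan_per_bp", "cM_per_Mb")) {
  units <- match.arg(units)
  stopifnot(all(c("chrom", "pos", "value") %in% names(track)),
            all(c("chrom", "start", "end", "rate") %in% names(rec_map)))
  if (any(rec_map$rate < 0)) stop("recombination rates must be >= 0")
  # cM/Mb -> Morgan/bp: 1 cM/Mb = 1e-2 Morgan / 1e6 bp = 1e-8 Morgan/bp
  conv <- if (units == "cM_per_Mb") 1e-8 else 1
  track %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::group_modify(function(df, key) {
      m <- rec_map[as.character(rec_map$chrom) == as.character(key$chrom), , drop = FALSE]
      if (nrow(m) == 0L) stop("no recombination map for chromosome ", key$chrom)
      m <- m[order(m$start), , drop = FALSE]
      .check_map_contiguous(m, key$chrom)
      if (any(df$pos < m$start[1]) || any(df$pos > m$end[nrow(m)])) {
        stop("positions outside recombination map coverage on chromosome ", key$chrom)
      }
      cum <- c(0, cumsum(m$rate * conv * (m$end - m$start)))
      k <- findInterval(df$pos, m$start)
      gen <- cum[k] + m$rate[k] * conv * (df$pos - m$start[k])
      tibble::tibble(pos = gen, value = df$value)
    }) %>%
    dplyr::ungroup()
}

.check_map_contiguous <- function(m, chrom) {
  if (nrow(m) > 1L && any(abs(m$start[-1] - m$end[-nrow(m)]) > 1e-9)) {
    stop("recombination map intervals not contiguous on chromosome ", chrom)
  }
  invisible(TRUE)
}

#' Rescale a population-scaled (rho = 2*Ne*r) recombination map to Morgans
#'
#' LD-based recombination maps report rates in units of the population-scaled
#' recombination rate rho = 2*Ne*r. Given independent crossover-map genetic
#' lengths for each chromosome, the scalar 2*Ne is estimated as the slope of a
#' through-the-origin regression of cumulative rho lengths on crossover-map
#' lengths, and the map rates are divided by it. Because LD maps contain
#' extreme outliers, per-interval rho rates above `truncate_at` are capped at
#' that value (winsorized) before the regression.
#'
#' @param rec_map Data frame `chrom`, `start`, `end`, `rate` with `rate` in
#'   rho per bp.
#' @param chrom_genetic_lengths Named numeric vector (or two-column data frame
#'   `chrom`, `morgans`) of crossover-map genetic lengths, in Morgans.
#' @param truncate_at Optional cap on per-interval rho rates (same units as
#'   `rate`); `NULL` disables truncation.
#' @return List with elements `map` (the converted map, rates in Morgans per
#'   bp) and `two_ne` (the estimated 2*Ne).
#' @export
rho_map_to_morgans <- function(rec_map, chrom_genetic_lengths, truncate_at = NULL) {
  stopifnot(all(c("chrom", "start", "end", "rate") %in% names(rec_map)))
  if (is.data.frame(chrom_genetic_lengths)) {
    gl <- stats::setNames(chrom_genetic_lengths$morgans,
                          as.character(chrom_genetic_lengths$chrom))
  } else {
    gl <- chrom_genetic_lengths
  }
  chroms <- unique(as.character(rec_map$chrom))
  if (length(chroms) < 2L) {
    stop("need at least 2 chromosomes to regress rho lengths on genetic lengths")
  }
  if (!all(chroms %in% names(gl))) {
    stop("missing crossover-map genetic length for chromosome(s): ",
         paste(setdiff(chroms, names(gl)), collapse = ", "))
  }
  m <- rec_map
  if (!is.null(truncate_at)) m$rate <- pmin(m$rate, truncate_at)
  rho_len <- vapply(chroms, function(ch) {
    mm <- m[as.character(m$chrom) == ch, , drop = FALSE]
    sum(mm$rate * (mm$end - mm$start))
  }, numeric(1))
  g <- gl[chroms]
  two_ne <- sum(g * rho_len) / sum(g^2)
  if (!is.finite(two_ne) || two_ne <= 0) stop("2Ne estimate is not positive")
  m$rate <- m$rate / two_ne
  list(map = tibble::as_tibble(m), two_ne = unname(two_ne))
}

#' Log-transform a non-negative rate signal
#'
#' Replaces values by `log(value + offset)`. Recombination-rate signals can be
#' strongly right-skewed (particularly finely resolved LD-based maps), and
#' analyses of their wavelet structure are often run on the log scale. The
#' default offset, half the smallest positive value, keeps zero rates finite
#' while leaving well-separated positive values essentially untouched.
#'
#' @param signal Data frame with a `value` column (e.g. a gridded rate track).
#' @param offset Added before taking logs. Default: half the smallest positive
#'   value in the signal. Use 0 only for strictly positive signals.
#' @return The input with `value` replaced by its log transform.
#' @export
log_transform_rates <- function(signal, offset = NULL) {
  stopifnot("value" %in% names(signal))
  v <- signal$value
  if (any(v < 0)) stop("rates must be >= 0")
  if (is.null(offset)) {
    pos <- v[v > 0]
    if (length(pos) == 0L) stop("all rates are zero; cannot choose a log offset")
    offset <- min(pos) / 2
  }
  if (any(v + offset <= 0)) stop("value + offset must be positive (zero rate with offset 0?)")
  signal$value <- log(v + offset)
  signal
}
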