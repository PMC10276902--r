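#' A deterministic heterogeneous recombination map for simulations
#'
#' Builds a piecewise-constant recombination map with smooth broad- and
#' medium-scale rate variation along each chromosome, the ingredient needed
#' for selection to generate ancestry-recombination correlations when
#' selected loci are placed uniformly on the physical map. Rates follow a
#' fixed log-sinusoidal profile (phase-shifted between chromosomes) and each
#' chromosome is rescaled to its target genetic length, so the map is fully
#' reproducible without consuming random numbers.
#'
#' @param genetic_lengths Target genetic length per chromosome, Morgans.
#' @param length_bp Physical length per chromosome (recycled).
#' @param n_intervals Number of constant-rate intervals per chromosome.
#' @return Tibble `chrom`, `start`, `end`, `rate` with rate in Morgans/bp.
#' @export
heterogeneous_rec_map <- function(genetic_lengths = c(chr1 = 1, chr2 = 0.8),
                                  length_bp = 1e8, n_intervals = 32) {
  if (is.null(names(genetic_lengths))) {
    names(genetic_lengths) <- paste0("chr", seq_along(genetic_lengths))
  }
  length_bp <- rep_len(length_bp, length(genetic_lengths))
  rows <- lapply(seq_along(genetic_lengths), function(c) {
    k <- seq_len(n_intervals) - 0.5
    prof <- exp(0.9 * sin(2 * pi * k / n_intervals + (c - 1) * pi / 3) +
                  0.4 * sin(6 * pi * k / n_intervals + 1 + c))
    step <- length_bp[c] / n_intervals
    rate <- prof * genetic_lengths[[c]] / (sum(prof) * step)
    tibble::tibble(
      chrom = names(genetic_lengths)[c],
      start = (seq_len(n_intervals) - 1) * step,
      end = seq_len(n_intervals) * step,
      rate = rate
    )
  })
  dplyr::bind_rows(rows)
}

#' Recombination-rate signal on the genetic-map grid
#'
#' Evaluates the local recombination rate at evenly spaced genetic-map
#' positions: the grid point at genetic position `g` takes the rate of the
#' physical interval containing `g`. This is the predictor signal paired with
#' ancestry proportion in correlation decompositions.
#'
#' @param rec_map Data frame `chrom`, `start`, `end`, `rate` (Morgans/bp).
#' @param resolution Grid step in Morgans.
#' @return Tibble `chrom`, `pos` (Morgans), `value` (rate in Morgans/bp).
#' @export
rec_rate_signal <- function(rec_map, resolution = 2^-10) {
  stopifnot(all(c("chrom", "start", "end", "rate") %in% names(rec_map)))
  chroms <- unique(as.character(rec_map$chrom))
  rows <- lapply(chroms, function(ch) {
    m <- rec_map[as.character(rec_map$chrom) == ch, , drop = FALSE]
    m <- m[order(m$start), , drop = FALSE]
    cum <- c(0, cumsum(m$rate * (m$end - m$start)))
    total <- cum[length(cum)]
    grid <- resolution * seq(0L, floor(total / resolution))
    # interval containing each genetic position (last interval for the end point)
    k <- pmin(findInterval(grid, cum, rightmost.closed = TRUE), nrow(m))
    k[k < 1L] <- 1L
    tibble::tibble(chrom = ch, pos = grid, value = m$rate[k])
  })
  dplyr::bind_rows(rows)
}

#' Matched selection-scenario simulation runs
#'
#' Convenience driver reproducing the canonical timing-of-selection
#' experiments: `continuous` selection from the pulse onward, `early` (first
#' 10 generations only), `late` (onset after 500 neutral generations),
#' `reversal` (direction flips after 100 generations to favor the introgressed
#' ancestry), plus a matched-seed `neutral` control. Selected loci are placed
#' uniformly on the physical map, so regions of low recombination carry more
#' selected loci per Morgan and selection builds a positive correlation
#' between introgressed ancestry and recombination rate.
#'
#' @param two_n Population size (haploid genomes), scalar.
#' @param alpha Admixture fraction.
#' @param s Total selection coefficient (> 0).
#' @param n_loci Number of selected loci.
#' @param generations Generations to simulate.
#' @param record_generations Generations to snapshot (default final).
#' @param rec_map Recombination map; default [heterogeneous_rec_map()].
#' @param resolution Output grid step, Morgans.
#' @param seed Integer seed shared across scenarios (matched runs).
#' @param scenarios Subset of `c("continuous", "early", "late", "reversal")`.
#' @return Tibble with columns `scenario`, `generation`, `chrom`, `pos`,
#'   `ancestry` (introgressed proportion) and `rec_rate` (Morgans/bp at the
#'   same grid point); includes the `neutral` control.
#' @export
run_selection_scenarios <- function(two_n = 1000, alpha = 0.5, s = 1,
                                    n_loci = 500, generations = 20,
                                    record_generations = NULL,
                                    rec_map = heterogeneous_rec_map(),
                                    resolution = 2^-10, seed = NULL,
                                    scenarios = c("continuous", "early", "late",
                                                  "reversal")) {
  stopifnot(s > 0)
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  record_generations <- record_generations %||% generations
  T <- generations
  schedules <- list(
    neutral = list(s = 0, sched = 0),
    continuous = list(s = s, sched = rep(1, T)),
    early = list(s = s, sched = c(rep(1, min(10, T)), rep(0, max(0, T - 10)))),
    late = list(s = s, sched = c(rep(0, min(500, T)), rep(1, max(0, T - 500)))),
    reversal = list(s = s, sched = c(rep(1, min(100, T)), rep(-1, max(0, T - 100))))
  )
  rec_sig <- rec_rate_signal(rec_map, resolution)
  runs <- lapply(c("neutral", scenarios), function(sc) {
    spec <- schedules[[sc]]
    cfg <- sim_config(
      alpha = alpha, two_n = two_n, generations = T,
      selection = selection_regime(s = spec$s, schedule = spec$sched,
                                   n_loci = n_loci, placement = "physical"),
      rec_map = rec_map, resolution = resolution, seed = seed
    )
    snaps <- simulate_admixture(cfg, record_generations = record_generations)
    purrr::map_dfr(snaps, function(st) {
      sig <- ancestry_proportion_signal(st, resolution = resolution)
      out <- dplyr::inner_join(
        dplyr::rename(sig, ancestry = "value"),
        dplyr::rename(rec_sig, rec_rate = "value"),
        by = c("chrom", "pos")
      )
      out$generation <- st$generation
      out$scenario <- sc
      out
    })
  })
  dplyr::bind_rows(runs)[, c("scenario", "generation", "chrom", "pos",
                             "ancestry", "rec_rate")]
}
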