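#' Selection regime for the linear fitness model
#'
#' Specifies time-varying genome-wide selection against (or for) introgressed
#' ancestry. Fitness of individual `i` is `w_i = 1 - p_i * s * schedule(t)`,
#' where `p_i` is the fraction of selected loci at which the individual
#' carries introgressed alleles (diploid dosage averaged over the two
#' haplotypes), `s` the total selection coefficient, and `schedule(t)` a
#' per-generation multiplier in `[-1, 1]` (`+1` active, `0` off, `-1`
#' reversed, favoring introgressed ancestry). Fitness is clamped at zero.
#'
#' @param s Total selection coefficient (>= 0). With `s = 1` an F1 hybrid
#'   (`p = 0.5`) has relative fitness 0.5.
#' @param schedule Numeric vector of per-generation multipliers; recycled or
#'   zero-padded to the number of generations simulated. Default `1`
#'   (continuous selection).
#' @param n_loci Number of selected loci to place (ignored if `loci` given).
#' @param loci Optional list (one element per chromosome) of selected-locus
#'   positions in Morgans; if `NULL`, `n_loci` loci are placed at simulation
#'   time, uniformly at random on the genetic map by default or on the
#'   physical map when `placement = "physical"` and a recombination map is
#'   part of the configuration.
#' @param placement `"genetic"` or `"physical"` locus placement.
#' @return An object of class `selection_regime`.
#' @export
selection_regime <- function(s = 0, schedule = 1, n_loci = 0, loci = NULL,
                             placement = c("genetic", "physical")) {
  placement <- match.arg(placement)
  stopifnot(s >= 0, all(abs(schedule) <= 1), n_loci >= 0)
  structure(list(s = s, schedule = schedule, n_loci = n_loci, loci = loci,
                 placement = placement),
            class = "selection_regime")
}

#' Linear hybrid fitness
#'
#' The fitness model used by the simulator: `w = 1 - p * s * multiplier`,
#' clamped below at zero, where `p` is the individual's introgressed-allele
#' fraction at the selected loci.
#'
#' @param p Introgressed-allele fraction(s) in [0, 1].
#' @param s Total selection coefficient.
#' @param multiplier Selection schedule multiplier (default 1, active
#'   selection against introgressed ancestry).
#' @return Relative fitness value(s).
#' @examples
#' hybrid_fitness(0.5, s = 1) # F1 hybrid under full selection
#' @export
hybrid_fitness <- function(p, s, multiplier = 1) {
  stopifnot(all(p >= 0 & p <= 1), s >= 0, all(abs(multiplier) <= 1))
  pmax(0, 1 - p * s * multiplier)
}

#' Simulation configuration
#'
#' Collects everything a simulation run needs. Population size is a
#' trajectory `2N(t)` for generations `t = 0..generations` (scalars are
#' recycled); generation 0 is the founding mixture of pure haplotypes.
#'
#' @param chrom_lengths Genetic lengths of chromosomes in Morgans (ignored if
#'   `rec_map` supplied, in which case lengths come from the map).
#' @param alpha Admixture fraction: initial proportion of introgressed
#'   haplotypes, in (0, 1).
#' @param two_n Population size in haploid genomes (2N): a scalar, or a
#'   vector of length `generations + 1` giving `2N(t)`, `t = 0..generations`.
#'   Sizes must be even.
#' @param generations Number of Wright-Fisher generations to run (>= 1).
#' @param selection A [selection_regime()].
#' @param rec_map Optional recombination map (`chrom`, `start`, `end`, `rate`
#'   in Morgans/bp) used for physical-map locus placement and for the
#'   recombination-rate signal.
#' @param resolution Output grid step in Morgans for ancestry signals.
#' @param seed Optional integer seed, recorded in all outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = 1, alpha = 0.5, two_n = 200,
                       generations = 10, selection = selection_regime(),
                       rec_map = NULL, resolution = 2^-10, seed = NULL) {
  stopifnot(alpha > 0, alpha < 1, generations >= 1)
  if (!is.null(rec_map)) {
    chrom_lengths <- vapply(split(rec_map, rec_map$chrom)[unique(as.character(rec_map$chrom))],
                            function(m) sum(m$rate * (m$end - m$start)), numeric(1))
  } else {
    names(chrom_lengths) <- names(chrom_lengths) %||% paste0("chr", seq_along(chrom_lengths))
  }
  if (length(two_n) == 1L) two_n <- rep(two_n, generations + 1L)
  stopifnot(length(two_n) == generations + 1L, all(two_n >= 2), all(two_n %% 2 == 0))
  stopifnot(inherits(selection, "selection_regime"))
  structure(list(chrom_lengths = chrom_lengths, alpha = alpha, two_n = two_n,
                 generations = generations, selection = selection,
                 rec_map = rec_map, resolution = resolution, seed = seed),
            class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Place selected loci per the regime; returns list of per-chromosome sorted
# positions in Morgans.
.place_sel_loci <- function(config) {
  reg <- config$selection
  len <- config$chrom_lengths
  if (!is.null(reg$loci)) {
    stopifnot(length(reg$loci) == length(len))
    return(lapply(reg$loci, sort))
  }
  if (reg$n_loci == 0L) return(lapply(len, function(l) numeric(0)))
  if (reg$placement == "physical") {
    if (is.null(config$rec_map)) stop("physical locus placement requires a rec_map")
    maps <- split(config$rec_map, config$rec_map$chrom)[names(len)]
    bp <- vapply(maps, function(m) max(m$end) - min(m$start), numeric(1))
    n_per <- stats::rmultinom(1, reg$n_loci, bp / sum(bp))[, 1]
    out <- vector("list", length(len))
    for (c in seq_along(len)) {
      m <- maps[[c]][order(maps[[c]]$start), , drop = FALSE]
      p_bp <- min(m$start) + sort(stats::runif(n_per[c])) * (max(m$end) - min(m$start))
      cum <- c(0, cumsum(m$rate * (m$end - m$start)))
      k <- findInterval(p_bp, m$start)
      out[[c]] <- cum[k] + m$rate[k] * (p_bp - m$start[k])
    }
    out
  } else {
    n_per <- stats::rmultinom(1, reg$n_loci, len / sum(len))[, 1]
    lapply(seq_along(len), function(c) sort(stats::runif(n_per[c], 0, len[[c]])))
  }
}

#' Run the Wright-Fisher admixture simulation
#'
#' Forward simulation of ancestry junctions in a hybrid population. Generation
#' 0 consists of `alpha * 2N(0)` pure introgressed and the remainder pure
#' recipient haplotypes, paired randomly into diploids. Each subsequent
#' generation samples parents with probability proportional to the linear
#' fitness `w = 1 - p * s * schedule(t)` (uniformly when selection is off) and
#' forms gametes with `Poisson(map length)` crossovers placed uniformly on the
#' genetic map, with independent assortment across chromosomes.
#'
#' @param config A [sim_config()].
#' @param record_generations Generations at which to snapshot the population
#'   (default: the final generation only).
#' @return A list of `admix_population` snapshots (named by generation), each
#'   holding junction lists, leftmost-segment ancestries, chromosome lengths,
#'   the generation index, and the selected-locus positions used.
#' @export
simulate_admixture <- function(config, record_generations = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  record_generations <- sort(unique(record_generations %||% config$generations))
  stopifnot(all(record_generations >= 0), all(record_generations <= config$generations))

  sel <- config$selection
  loci <- .place_sel_loci(config)
  # scalar schedules recycle to every generation; vectors are zero-padded
  sched <- if (length(sel$schedule) == 1L) {
    rep(sel$schedule, config$generations)
  } else {
    c(sel$schedule, rep(0, config$generations))[seq_len(config$generations)]
  }

  # founding: exactly round(alpha * 2N0) introgressed haplotypes, shuffled
  n0 <- config$two_n[1]
  n_int <- round(config$alpha * n0)
  anc0 <- sample(c(rep(1L, n_int), rep(0L, n0 - n_int)))
  C <- length(config$chrom_lengths)
  state <- list(
    junctions = replicate(C, replicate(n0, numeric(0), simplify = FALSE), simplify = FALSE),
    left = replicate(C, anc0, simplify = FALSE)
  )

  snapshots <- list()
  wrap <- function(st, gen) {
    structure(list(junctions = st$junctions, left = st$left,
                   chrom_lengths = config$chrom_lengths, generation = gen,
                   alpha = config$alpha, sel_loci = loci, seed = config$seed),
              class = "admix_population")
  }
  if (0 %in% record_generations) snapshots[["0"]] <- wrap(state, 0L)
  done <- 0L
  for (g in record_generations[record_generations > 0]) {
    span <- seq.int(done + 1L, g)
    res <- .wf_generations(state$junctions, state$left,
                           unname(config$chrom_lengths),
                           as.integer(config$two_n[span + 1L]),
                           sched[span], sel$s, loci)
    state <- list(junctions = res$junctions, left = res$left)
    snapshots[[as.character(g)]] <- wrap(state, g)
    done <- g
  }
  snapshots
}

#' @export
print.admix_population <- function(x, ...) {
  cat("Admixed population: generation", x$generation, "-",
      length(x$left[[1]]), "haplotypes,", length(x$chrom_lengths),
      "chromosome(s) of", paste(signif(x$chrom_lengths, 3), collapse = ", "),
      "Morgans\n")
  invisible(x)
}

#' Ancestry-proportion signal from a population snapshot
#'
#' At each genetic-map grid point, the fraction of haplotypes whose covering
#' ancestry tract is introgressed. Grid points are placed every `resolution`
#' Morgans from the chromosome start.
#'
#' @param state An `admix_population` snapshot from [simulate_admixture()].
#' @param resolution Grid step in Morgans.
#' @param sample_haplotypes Optional number of haplotypes to subsample
#'   (without replacement) to emulate a finite study sample; default all.
#' @return Tibble `chrom`, `pos`, `value` with values in [0, 1].
#' @export
ancestry_proportion_signal <- function(state, resolution = 2^-10,
                                       sample_haplotypes = NULL) {
  stopifnot(inherits(state, "admix_population"), resolution > 0)
  lens <- state$chrom_lengths
  chroms <- names(lens)
  H <- length(state$left[[1]])
  keep <- seq_len(H)
  if (!is.null(sample_haplotypes)) {
    stopifnot(sample_haplotypes >= 1, sample_haplotypes <= H)
    keep <- sample(H, sample_haplotypes)
  }
  rows <- lapply(seq_along(lens), function(c) {
    if (resolution > lens[[c]] && lens[[c]] > 0) {
      stop("resolution ", resolution, " exceeds chromosome length ", lens[[c]],
           " (", chroms[c], ")")
    }
    grid <- if (lens[[c]] == 0) 0 else resolution * seq(0L, floor(lens[[c]] / resolution))
    freq <- .anc_frequency(state$junctions[[c]][keep], state$left[[c]][keep], grid)
    tibble::tibble(chrom = chroms[c], pos = grid, value = freq)
  })
  dplyr::bind_rows(rows)
}

#' Ancestry tract lengths in a population snapshot
#'
#' Enumerates the maximal single-ancestry segments of every haplotype. The
#' tract length distribution is what the wavelet power spectrum of haploid
#' ancestry state summarizes: long tracts load broad scales, short tracts
#' fine scales.
#'
#' @param state An `admix_population` snapshot.
#' @return Tibble with columns `haplotype`, `chrom`, `start`, `end`,
#'   `ancestry`, `length` (all positions in Morgans).
#' @export
tract_length_summary <- function(state) {
  stopifnot(inherits(state, "admix_population"))
  lens <- state$chrom_lengths
  rows <- lapply(seq_along(lens), function(c) {
    juncs <- state$junctions[[c]]
    lefts <- state$left[[c]]
    nj <- lengths(juncs)
    len <- lens[[c]]
    # breakpoints per haplotype: 0, junctions, chromosome end
    starts <- unlist(lapply(juncs, function(j) c(0, j)), use.names = FALSE)
    ends <- unlist(lapply(juncs, function(j) c(j, len)), use.names = FALSE)
    hap <- rep.int(seq_along(juncs), nj + 1L)
    seg <- sequence(nj + 1L) - 1L # 0-based segment index within haplotype
    tibble::tibble(
      haplotype = hap, chrom = names(lens)[c],
      start = starts, end = ends,
      ancestry = bitwXor(rep.int(lefts, nj + 1L), seg %% 2L)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$length <- out$end - out$start
  out
}

#' Mean introgressed ancestry of a snapshot
#'
#' Genome-wide mean, weighting chromosomes by genetic length (tract mass).
#'
#' @param state An `admix_population` snapshot.
#' @return Scalar in [0, 1].
#' @export
mean_ancestry <- function(state) {
  tr <- tract_length_summary(state)
  if (all(tr$length == 0)) {
    # zero-length (single-locus) chromosomes: average point ancestry
    sig <- ancestry_proportion_signal(state, resolution = 1)
    return(mean(sig$value))
  }
  sum(tr$length * tr$ancestry) / sum(tr$length)
}

#' Selected-locus introgression dosage of one individual
#'
#' Fraction of selected loci at which an individual (a pair of haplotypes)
#' carries introgressed alleles, averaged over its two haplotypes — the `p`
#' of the linear fitness model.
#'
#' @param state An `admix_population` snapshot with selected loci recorded.
#' @param individual Individual index (haplotypes `2k - 1` and `2k`).
#' @return Scalar in [0, 1].
#' @export
individual_sel_dosage <- function(state, individual = 1) {
  stopifnot(inherits(state, "admix_population"))
  k <- individual
  hA <- lapply(state$junctions, function(jc) jc[[2 * k - 1]])
  hB <- lapply(state$junctions, function(jc) jc[[2 * k]])
  lA <- vapply(state$left, function(l) l[2 * k - 1], integer(1))
  lB <- vapply(state$left, function(l) l[2 * k], integer(1))
  .sel_locus_dosage(hA, lA, hB, lB, state$sel_loci)
}
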