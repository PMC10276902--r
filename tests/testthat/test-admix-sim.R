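test_that("the linear fitness model has the right endpoints and clamps at zero", {
  expect_equal(hybrid_fitness(0, 1), 1)
  expect_equal(hybrid_fitness(1, 1), 0)
  expect_equal(hybrid_fitness(0.5, 1), 0.5)
  # reversal favors introgressed ancestry; clamping keeps fitness non-negative
  expect_equal(hybrid_fitness(0.5, 1, multiplier = -1), 1.5)
  expect_equal(hybrid_fitness(1, 2), 0)
})

test_that("founding generation is an exact alpha mixture of pure haplotypes", {
  cfg <- sim_config(chrom_lengths = 1, alpha = 0.3, two_n = 100,
                    generations = 1, seed = 401)
  st0 <- simulate_admixture(cfg, record_generations = 0)[["0"]]
  expect_equal(sum(st0$left[[1]]), 30)
  expect_true(all(lengths(st0$junctions[[1]]) == 0))
  tr <- tract_length_summary(st0)
  expect_true(all(tr$length == 1)) # full-chromosome tracts
  sig <- ancestry_proportion_signal(st0, 2^-4)
  expect_true(all(sig$value == 0.3))
})

test_that("neutral simulation conserves mean ancestry near alpha", {
  set.seed(402)
  nrep <- 60
  m <- replicate(nrep, {
    cfg <- sim_config(chrom_lengths = 0.5, alpha = 0.5, two_n = 1000,
                      generations = 5)
    mean_ancestry(simulate_admixture(cfg)[[1]])
  })
  expect_lt(abs(mean(m) - 0.5), 3 * sd(m) / sqrt(nrep))
})

test_that("simulation snapshots are deterministic under a seed", {
  cfg <- sim_config(chrom_lengths = 1, two_n = 200, generations = 10, seed = 403)
  a <- simulate_admixture(cfg)
  b <- simulate_admixture(cfg)
  expect_identical(a, b)
  siga <- ancestry_proportion_signal(a[[1]], 2^-8)
  sigb <- ancestry_proportion_signal(b[[1]], 2^-8)
  expect_identical(siga, sigb)
})

test_that("tract structure is a valid alternating junction representation", {
  cfg <- sim_config(chrom_lengths = c(a = 1, b = 0.5), two_n = 100,
                    generations = 20, seed = 404)
  st <- simulate_admixture(cfg)[[1]]
  for (c in 1:2) {
    for (h in seq_along(st$junctions[[c]])) {
      j <- st$junctions[[c]][[h]]
      if (length(j) > 0) {
        expect_true(all(diff(j) > 0))
        expect_true(all(j > 0 & j < st$chrom_lengths[[c]]))
      }
    }
  }
  tr <- tract_length_summary(st)
  # tracts tile each haplotype exactly and alternate ancestry
  tot <- tapply(tr$length, list(tr$haplotype, tr$chrom), sum)
  expect_equal(unname(tot[, "a"]), rep(1, 100), tolerance = 1e-12)
  expect_equal(unname(tot[, "b"]), rep(0.5, 100), tolerance = 1e-12)
  one <- tr[tr$haplotype == 1 & tr$chrom == "a", ]
  if (nrow(one) > 1) expect_true(all(abs(diff(one$ancestry)) == 1))
})

test_that("junctions accrue at roughly t * 2a(1-a) per Morgan in a large population", {
  set.seed(405)
  t <- 10
  cfg <- sim_config(chrom_lengths = 1, alpha = 0.5, two_n = 4000,
                    generations = t)
  st <- simulate_admixture(cfg)[[1]]
  njunc <- mean(lengths(st$junctions[[1]]))
  expect_lt(abs(njunc - t * 2 * 0.25) / (t * 2 * 0.25), 0.1)
})

test_that("a bottleneck freezes junction accrual relative to a constant population", {
  set.seed(406)
  t <- 60
  run <- function(twoN) {
    cfg <- sim_config(chrom_lengths = 1, two_n = twoN, generations = t)
    mean(lengths(simulate_admixture(cfg)[[1]]$junctions[[1]]))
  }
  small <- mean(replicate(5, run(20)))
  big <- mean(replicate(5, run(2000)))
  expect_lt(small, big)
})

test_that("drift law holds at an unlinked marker", {
  set.seed(407)
  nrep <- 400
  tt <- 10
  f <- replicate(nrep, {
    cfg <- sim_config(chrom_lengths = 0, two_n = 100, generations = tt)
    mean_ancestry(simulate_admixture(cfg)[[1]])
  })
  truth <- 0.25 * (1 - (1 - 1 / 100)^tt)
  se <- sd((f - 0.5)^2) / sqrt(nrep)
  expect_lt(abs(mean((f - 0.5)^2) - truth), 3 * se)
})

test_that("selection reduces introgressed ancestry relative to matched neutral runs", {
  set.seed(408)
  wins <- replicate(20, {
    seed <- sample.int(1e6, 1)
    m <- vapply(c(0, 1), function(s) {
      cfg <- sim_config(chrom_lengths = 1, two_n = 400, generations = 10,
                        selection = selection_regime(s = s, n_loci = 100),
                        seed = seed)
      mean_ancestry(simulate_admixture(cfg)[[1]])
    }, numeric(1))
    m[2] < m[1]
  })
  expect_gte(sum(wins), 19)
})

test_that("selected-locus dosage and fitness expose the F1 case", {
  # an F1 individual: one pure introgressed + one pure recipient haplotype
  cfg <- sim_config(chrom_lengths = 1, two_n = 2, generations = 1,
                    selection = selection_regime(s = 1, n_loci = 50), seed = 409)
  st0 <- simulate_admixture(cfg, record_generations = 0)[["0"]]
  # force the two founder haplotypes of individual 1 to be 1 and 0
  st0$left[[1]] <- c(1L, 0L)
  expect_equal(individual_sel_dosage(st0, 1), 0.5)
  expect_equal(hybrid_fitness(individual_sel_dosage(st0, 1), s = 1), 0.5)
})

test_that("total extinction of viable parents is reported", {
  cfg <- sim_config(chrom_lengths = 1, alpha = 0.5, two_n = 4, generations = 2,
                    selection = selection_regime(s = 1, n_loci = 10), seed = 410)
  st0 <- simulate_admixture(cfg, record_generations = 0)[["0"]]
  # all-introgressed population with S = 1 has fitness 0 everywhere
  st0$left[[1]] <- rep(1L, 4)
  expect_error(
    .wf_generations(st0$junctions, st0$left, unname(st0$chrom_lengths),
                    4L, 1, 1, st0$sel_loci),
    "extinct"
  )
})

test_that("ancestry signal validates resolution and supports subsampling", {
  cfg <- sim_config(chrom_lengths = 0.5, two_n = 50, generations = 3, seed = 411)
  st <- simulate_admixture(cfg)[[1]]
  expect_error(ancestry_proportion_signal(st, resolution = 1), "exceeds")
  set.seed(1)
  sub <- ancestry_proportion_signal(st, 2^-6, sample_haplotypes = 10)
  expect_true(all(sub$value %in% ((0:10) / 10)))
})

test_that("neutral theory reduces to the drift law and vanishes at t = 0", {
  # zero-distance covariance equals the single-locus drift law
  for (tt in c(1, 5, 50)) {
    cc <- admixwave:::.ancestry_freq_cov(0, rep(100, tt + 1), tt, 0.5)
    expect_equal(cc, 0.25 * (1 - (1 - 1 / 100)^tt), tolerance = 1e-12)
  }
  th0 <- expected_neutral_wavelet_variance(200, 0, 1:5, 2^-8)
  expect_true(all(th0$variance == 0))
})

test_that("theory matches simulated spectra for a small neutral system", {
  set.seed(412)
  nrep <- 120
  res <- 2^-8
  sims <- replicate(nrep, {
    cfg <- sim_config(chrom_lengths = 1, two_n = 200, generations = 10)
    st <- simulate_admixture(cfg)[[1]]
    v <- wavelet_variance(modwt_haar(ancestry_proportion_signal(st, res)))
    v$variance[v$component == "wavelet"][1:7]
  })
  th <- expected_neutral_wavelet_variance(200, 10, 1:7, res)$variance
  se <- apply(sims, 1, sd) / sqrt(nrep)
  expect_true(all(abs(rowMeans(sims) - th) < 3 * se))
})

test_that("bottleneck theory exceeds constant-N theory at broad scales", {
  res <- 2^-10
  bn <- c(rep(200, 11), rep(20000, 990))
  cn <- rep(20000, 1001)
  thb <- expected_neutral_wavelet_variance(bn, 1000, 1:10, res)
  thc <- expected_neutral_wavelet_variance(cn, 1000, 1:10, res)
  expect_true(all(thb$variance[8:10] > thc$variance[8:10]))
})

test_that("scenario driver produces matched runs with the requested schedules", {
  runs <- run_selection_scenarios(two_n = 200, s = 1, n_loci = 50,
                                  generations = 12, seed = 413,
                                  scenarios = c("continuous", "early"))
  expect_setequal(unique(runs$scenario), c("neutral", "continuous", "early"))
  expect_true(all(runs$generation == 12))
  expect_true(all(runs$ancestry >= 0 & runs$ancestry <= 1))
  expect_true(all(runs$rec_rate > 0))
  # selection removed introgressed ancestry relative to the neutral control
  m <- tapply(runs$ancestry, runs$scenario, mean)
  expect_lt(m["continuous"], m["neutral"])
})
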