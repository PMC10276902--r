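test_that("identical constant chromosomes give an all-zero decomposition", {
  sig <- mk_multi(c(64, 64))
  sig$value <- 1.5
  d <- gnom_var_decomp(sig)
  expect_lt(max(abs(d$variance)), 1e-14)
})

test_that("opposite constant chromosomes put all variance among chromosomes", {
  sig <- mk_multi(c(64, 64))
  sig$value <- rep(c(1, -1), each = 64)
  d <- gnom_var_decomp(sig, estimator = "biased")
  expect_lt(max(abs(d$variance[d$scale != "chrom"])), 1e-14)
  expect_equal(d$contribution[d$scale == "chrom"], 1)
  expect_equal(d$variance[d$scale == "chrom"], 1) # weighted variance of +-1 means
})

test_that("genome decomposition equals a hand-coded length-weighted average", {
  set.seed(301)
  sig <- mk_multi(c(256, 256, 64))
  d <- gnom_var_decomp(sig, estimator = "unbiased", jackknife = FALSE)
  # direct recomputation
  per <- lapply(split(sig, sig$chrom), function(s) {
    s <- s[order(s$pos), ]
    wavelet_variance(modwt_haar(s$value), "unbiased")
  })
  Ls <- c(chr1 = 256, chr2 = 256, chr3 = 64)
  w <- Ls / sum(Ls)
  for (j in 1:8) {
    vj <- vapply(per, function(v) {
      out <- v$variance[v$component == "wavelet"][j]
      if (is.na(out) || length(out) == 0) NA_real_ else out
    }, numeric(1))
    p <- !is.na(vj)
    expect_equal(d$variance[d$level == j & !is.na(d$level)],
                 sum(w[p] * vj[p]) / sum(w[p]), tolerance = 1e-12)
    expect_equal(d$n_chrom[which(!is.na(d$level))[j]], sum(p))
  }
  # scales 7 and 8 exist only on the two long chromosomes
  expect_equal(d$n_chrom[d$level %in% 7:8 & !is.na(d$level)], c(2, 2))
  # zero-inclusion rule: contribution uses zero for the short chromosome
  tot <- attr(d, "total_variance")
  v7 <- vapply(per[1:2], function(v) v$variance[v$component == "wavelet"][7], numeric(1))
  expect_equal(d$contribution[d$level == 7 & !is.na(d$level)],
               sum(w[1:2] * v7) / tot, tolerance = 1e-12)
})

test_that("biased full decomposition reconstructs pooled variance; proportions sum to 1", {
  set.seed(302)
  for (Ls in list(c(100, 255), c(128, 300, 90))) {
    sig <- mk_multi(Ls)
    sig$value <- sig$value + rep(rnorm(length(Ls), sd = 2), Ls) # chromosome shifts
    d <- gnom_var_decomp(sig, estimator = "biased")
    expect_lt(abs(attr(d, "total_variance") - pvar(sig$value)), 1e-8)
    expect_equal(sum(d$contribution), 1, tolerance = 1e-12)
  }
})

test_that("duplicating every chromosome leaves point estimates unchanged", {
  set.seed(303)
  sig <- mk_multi(c(128, 64))
  dup <- sig
  dup$chrom <- paste0(dup$chrom, "_copy")
  both <- dplyr::bind_rows(sig, dup)
  d1 <- gnom_var_decomp(sig, jackknife = FALSE)
  d2 <- gnom_var_decomp(both, jackknife = FALSE)
  expect_equal(d2$variance, d1$variance, tolerance = 1e-12)
  expect_equal(d2$contribution, d1$contribution, tolerance = 1e-12)
})

test_that("inconsistent resolutions across chromosomes are rejected", {
  sig <- dplyr::bind_rows(mk_signal(32, "c1", res = 1), mk_signal(32, "c2", res = 2))
  expect_error(gnom_var_decomp(sig), "resolution")
})

test_that("correlation decomposition reconstructs the Pearson correlation", {
  set.seed(304)
  # single chromosome, biased: exact identity against the direct oracle
  for (k in 1:20) {
    L <- sample(c(100, 200, 257), 1)
    x <- mk_signal(L)
    y <- x
    y$value <- runif(1, -2, 2) * x$value + rnorm(L, sd = runif(1, 0.1, 2))
    dc <- gnom_cor_decomp(x, y, estimator = "biased", jackknife = FALSE)
    expect_lt(abs(attr(dc, "correlation") - cor(x$value, y$value)), 1e-8)
  }
  # multi-chromosome with chromosome mean differences
  x <- mk_multi(c(128, 200, 64))
  x$value <- x$value + rep(c(1, -1, 0.5), c(128, 200, 64))
  y <- x
  y$value <- 0.4 * x$value + rnorm(nrow(x))
  dc <- gnom_cor_decomp(x, y, estimator = "biased", jackknife = FALSE)
  expect_lt(abs(attr(dc, "correlation") - cor(x$value, y$value)), 1e-8)
})

test_that("y = x gives unit correlations with contributions summing to 1", {
  set.seed(305)
  x <- mk_multi(c(128, 64))
  dc <- gnom_cor_decomp(x, x, estimator = "biased", jackknife = FALSE)
  wav <- !is.na(dc$level)
  expect_true(all(abs(dc$correlation[wav] - 1) < 1e-10, na.rm = TRUE))
  expect_equal(sum(dc$contribution), 1, tolerance = 1e-8)
})

test_that("independent signals give near-zero reconstructed correlation", {
  set.seed(306)
  nrep <- 30
  overall <- replicate(nrep, {
    x <- mk_multi(rep(512, 10))
    y <- mk_multi(rep(512, 10))
    attr(gnom_cor_decomp(x, y, estimator = "biased", jackknife = FALSE),
         "correlation")
  })
  expect_lt(abs(mean(overall)), 3 * sd(overall) / sqrt(nrep))
})

test_that("variance explained: self-prediction gives R2 = 1, noise near 0", {
  set.seed(307)
  x <- mk_multi(c(256, 128))
  r2 <- variance_explained_by_predictor(x, x)
  expect_true(all(abs(r2$r_squared - 1) < 1e-10, na.rm = TRUE))
  # independent predictor: pooled n = 5000 coefficients at level 1
  xx <- mk_multi(rep(513, 10))
  pp <- mk_multi(rep(513, 10))
  r2n <- variance_explained_by_predictor(xx, pp)
  expect_lt(r2n$r_squared[r2n$level == 1], 0.01)
})

test_that("variance explained supports multiple predictors", {
  set.seed(308)
  p1 <- mk_multi(c(256, 256))
  p2 <- mk_multi(c(256, 256))
  x <- p1
  x$value <- 0.5 * p1$value + 0.5 * p2$value + rnorm(512, sd = 0.1)
  r2_both <- variance_explained_by_predictor(x, list(a = p1, b = p2))
  r2_one <- variance_explained_by_predictor(x, p1)
  expect_true(all(r2_both$r_squared >= r2_one$r_squared - 1e-8, na.rm = TRUE))
  expect_gt(r2_both$r_squared[1], 0.9)
})

test_that("weighted jackknife reduces to the ordinary jackknife with equal weights", {
  v <- c(2.1, 3.4, 1.9, 2.8, 3.0)
  jk <- jackknife_ci(v)
  loo <- vapply(seq_along(v), function(i) mean(v[-i]), numeric(1))
  ps <- length(v) * mean(v) - (length(v) - 1) * loo
  se_ord <- sqrt(stats::var(ps) / length(v))
  expect_equal(jk$estimate, mean(v))
  expect_equal(jk$se, se_ord, tolerance = 1e-12)
  expect_equal(jk$ci_hi - jk$estimate, stats::qnorm(0.975) * se_ord, tolerance = 1e-12)
})

test_that("jackknife degenerates and omissions follow the block-count rules", {
  # identical statistic on every block: zero SE, degenerate interval
  jk0 <- jackknife_ci(rep(2.5, 4), weights = c(1, 2, 3, 4))
  expect_equal(jk0$se, 0)
  expect_equal(jk0$ci_lo, 2.5)
  expect_equal(jk0$ci_hi, 2.5)
  # fewer than 3 blocks: interval omitted
  jk2 <- jackknife_ci(c(1, 2), weights = c(1, 2))
  expect_true(is.na(jk2$se) && is.na(jk2$ci_lo))
  # inside decompositions: 2 chromosomes -> no CI anywhere
  set.seed(309)
  d <- gnom_var_decomp(mk_multi(c(64, 64)))
  expect_true(all(is.na(d$ci_lo)))
})

test_that("jackknife intervals cover the known white-noise variance", {
  set.seed(310)
  nrep <- 150
  truth <- 2^-3 # level-3 white-noise wavelet variance, sigma = 1
  cover <- logical(nrep)
  for (i in seq_len(nrep)) {
    d <- gnom_var_decomp(mk_multi(rep(128, 8)), estimator = "unbiased")
    row <- which(d$level == 3)
    cover[i] <- d$ci_lo[row] <= truth && truth <= d$ci_hi[row]
  }
  expect_gte(mean(cover), 0.9)
})
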