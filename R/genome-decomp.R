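#' Genome-wide wavelet variance decomposition
#'
#' Applies the Haar MODWT to each chromosome of a gridded signal and combines
#' per-scale wavelet variances into a genome-wide decomposition. Chromosomes
#' differ in length, so two averages are formed at each scale: the raw
#' magnitude (`variance`) is a chromosome-length-weighted mean over only those
#' chromosomes on which the scale exists, while the proportion of total
#' genomic variance (`contribution`) assigns zero to chromosomes lacking the
#' scale before weighting, so that contributions over all components sum to
#' one. Two extra components complete the decomposition: `chrom`, the
#' length-weighted variance of chromosome mean values (the among-chromosome
#' part not visible to within-chromosome wavelets), and `scaling`, the
#' aggregated leftover smooth variance from chromosome lengths that are not
#' powers of two.
#'
#' With `estimator = "biased"` the decomposition is exact: the components sum
#' to the population variance of the pooled signal. The default `"unbiased"`
#' estimator removes boundary coefficients, making per-scale magnitudes
#' unbiased at the cost of contributions being approximate.
#'
#' @param data Data frame with columns `chrom`, `pos`, `value`; each
#'   chromosome must be on the same even grid spacing.
#' @param estimator `"unbiased"` or `"biased"` (see [wavelet_variance()]).
#' @param jackknife Compute weighted delete-one-chromosome jackknife
#'   confidence intervals for per-scale variances? Intervals are omitted (`NA`)
#'   at scales present on fewer than 3 chromosomes.
#' @param conf_level Confidence level for jackknife intervals.
#' @return A tibble of class `gnom_var_decomp` with one row per scale plus
#'   `chrom` and `scaling` rows: columns `scale` (label), `level`, `scale_map`
#'   (scale in map units), `variance`, `contribution`, `n_chrom`, `ci_lo`,
#'   `ci_hi`. Attributes: `total_variance`, `resolution`, `estimator`.
#' @examples
#' sig <- tibble::tibble(
#'   chrom = rep(c("chr1", "chr2"), each = 128),
#'   pos = rep(seq(0, 127) * 0.001, 2),
#'   value = stats::rnorm(256)
#' )
#' gnom_var_decomp(sig)
#' @export
gnom_var_decomp <- function(data, estimator = c("unbiased", "biased"),
                            jackknife = TRUE, conf_level = 0.95) {
  estimator <- match.arg(estimator)
  per <- .per_chrom_decomp(data)
  res <- per$resolution
  decomps <- per$decomps
  n_chr <- length(decomps)
  Lvec <- vapply(decomps, function(d) d$L, numeric(1))
  w <- Lvec / sum(Lvec)
  Jmax <- max(vapply(decomps, function(d) max(d$levels), numeric(1)))

  # per-chromosome per-level variances (rows = chrom, cols = level), NA = absent
  vmat <- matrix(NA_real_, nrow = n_chr, ncol = Jmax)
  for (i in seq_len(n_chr)) {
    lp <- .level_products(decomps[[i]], decomps[[i]], estimator)
    vmat[i, seq_along(lp$sum)] <- ifelse(lp$n > 0, lp$sum / lp$n, NA_real_)
  }
  scaling_i <- vapply(decomps, function(d) mean((d$V - d$x_mean)^2), numeric(1))
  means_i <- vapply(decomps, function(d) d$x_mean, numeric(1))

  # raw magnitude: weighted mean over chromosomes where the scale exists
  present <- !is.na(vmat)
  raw <- vapply(seq_len(Jmax), function(j) {
    p <- present[, j]
    if (!any(p)) return(NA_real_)
    sum(w[p] * vmat[p, j]) / sum(w[p])
  }, numeric(1))
  n_at_scale <- colSums(present)

  # zero-filled weighted means feed the proportion-of-total decomposition
  vz <- vmat
  vz[!present] <- 0
  zf <- as.numeric(w %*% vz)
  scaling_avg <- sum(w * scaling_i)
  grand <- sum(w * means_i)
  among <- sum(w * (means_i - grand)^2)
  total <- sum(zf) + scaling_avg + among
  contribution <- if (total > 0) c(zf, among, scaling_avg) / total else
    rep(NA_real_, Jmax + 2L)

  ci <- matrix(NA_real_, nrow = Jmax + 2L, ncol = 2L)
  if (jackknife && n_chr >= 3L) {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    for (j in seq_len(Jmax)) {
      p <- which(present[, j])
      if (length(p) >= 3L) {
        loo <- vapply(p, function(drop) {
          keep <- setdiff(p, drop)
          sum(w[keep] * vmat[keep, j]) / sum(w[keep])
        }, numeric(1))
        se <- .wjack_se(raw[j], loo, Lvec[p])
        ci[j, ] <- raw[j] + c(-1, 1) * z * se
      }
    }
    loo_among <- vapply(seq_len(n_chr), function(drop) {
      keep <- setdiff(seq_len(n_chr), drop)
      wk <- w[keep] / sum(w[keep])
      gk <- sum(wk * means_i[keep])
      sum(wk * (means_i[keep] - gk)^2)
    }, numeric(1))
    ci[Jmax + 1L, ] <- among + c(-1, 1) * z * .wjack_se(among, loo_among, Lvec)
    loo_sc <- vapply(seq_len(n_chr), function(drop) {
      keep <- setdiff(seq_len(n_chr), drop)
      sum(w[keep] * scaling_i[keep]) / sum(w[keep])
    }, numeric(1))
    ci[Jmax + 2L, ] <- scaling_avg + c(-1, 1) * z * .wjack_se(scaling_avg, loo_sc, Lvec)
  }

  out <- tibble::tibble(
    scale = c(as.character(2^seq_len(Jmax)), "chrom", "scaling"),
    level = c(seq_len(Jmax), NA_integer_, NA_integer_),
    scale_map = c(2^seq_len(Jmax) * res, NA_real_, NA_real_),
    variance = c(raw, among, scaling_avg),
    contribution = contribution,
    n_chrom = c(n_at_scale, n_chr, n_chr),
    ci_lo = ci[, 1],
    ci_hi = ci[, 2]
  )
  attr(out, "total_variance") <- total
  attr(out, "resolution") <- res
  attr(out, "estimator") <- estimator
  attr(out, "statistic") <- "variance"
  class(out) <- c("gnom_var_decomp", class(out))
  out
}

#' Genome-wide wavelet correlation decomposition of two signals
#'
#' Decomposes the overall correlation between two gridded genomic signals
#' (e.g. local ancestry proportion and recombination rate) into contributions
#' from dyadic scales, `Cor(x, y) = sum_lambda c_lambda * rho_lambda`, plus
#' among-chromosome and scaling terms. At each scale the correlation
#' `rho_lambda` is computed from MODWT coefficients pooled across chromosomes
#' with chromosome-length weights; the weight `c_lambda` is the geometric mean
#' of the two signals' proportions of variance at that scale, the choice under
#' which the decomposition reconstructs the direct Pearson correlation exactly
#' when biased estimators are used.
#'
#' @param x,y Data frames with columns `chrom`, `pos`, `value` on matching
#'   grids (same chromosomes, positions, and resolution).
#' @inheritParams gnom_var_decomp
#' @param weight_mean `"geometric"` (default; exact reconstruction) or
#'   `"arithmetic"` mean of the two per-scale variance proportions for
#'   `c_lambda`.
#' @return A tibble of class `gnom_cor_decomp` with one row per scale plus
#'   `chrom` and `scaling` rows: columns `scale`, `level`, `scale_map`,
#'   `correlation` (`rho_lambda`), `weight` (`c_lambda`), `contribution`,
#'   `n_chrom`, `ci_lo`, `ci_hi`. Attribute `correlation` holds the overall
#'   reconstructed genome-wide correlation.
#' @export
gnom_cor_decomp <- function(x, y, estimator = c("unbiased", "biased"),
                            weight_mean = c("geometric", "arithmetic"),
                            jackknife = TRUE, conf_level = 0.95) {
  estimator <- match.arg(estimator)
  weight_mean <- match.arg(weight_mean)
  px <- .per_chrom_decomp(x)
  py <- .per_chrom_decomp(y)
  if (!identical(names(px$decomps), names(py$decomps))) {
    stop("x and y must cover the same chromosomes in the same order")
  }
  if (abs(px$resolution - py$resolution) > 1e-9 * px$resolution) {
    stop("x and y are on different grid resolutions")
  }
  res <- px$resolution
  dx <- px$decomps
  dy <- py$decomps
  n_chr <- length(dx)
  for (i in seq_len(n_chr)) .check_pair(dx[[i]], dy[[i]])
  Lvec <- vapply(dx, function(d) d$L, numeric(1))
  w <- Lvec / sum(Lvec)
  Jmax <- max(vapply(dx, function(d) max(d$levels), numeric(1)))

  # per-chromosome per-level mean products; NA where scale absent
  fill <- function(f) {
    m <- matrix(NA_real_, nrow = n_chr, ncol = Jmax)
    for (i in seq_len(n_chr)) {
      lp <- f(i)
      m[i, seq_along(lp$sum)] <- ifelse(lp$n > 0, lp$sum / lp$n, NA_real_)
    }
    m
  }
  cv <- fill(function(i) .level_products(dx[[i]], dy[[i]], estimator))
  vx <- fill(function(i) .level_products(dx[[i]], dx[[i]], estimator))
  vy <- fill(function(i) .level_products(dy[[i]], dy[[i]], estimator))
  present <- !is.na(vx)

  pool <- function(m, zero_fill = FALSE) {
    vapply(seq_len(Jmax), function(j) {
      p <- present[, j]
      if (!any(p)) return(if (zero_fill) 0 else NA_real_)
      if (zero_fill) sum(w[p] * m[p, j]) else sum(w[p] * m[p, j]) / sum(w[p])
    }, numeric(1))
  }
  cv_p <- pool(cv); vx_p <- pool(vx); vy_p <- pool(vy)
  rho <- ifelse(!is.na(vx_p) & !is.na(vy_p) & vx_p > 0 & vy_p > 0,
                cv_p / sqrt(vx_p * vy_p), NA_real_)

  # zero-filled totals for contribution weights
  cv_z <- pool(cv, zero_fill = TRUE)
  vx_z <- pool(vx, zero_fill = TRUE)
  vy_z <- pool(vy, zero_fill = TRUE)
  sc <- function(dd) vapply(dd, function(d) mean((d$V - d$x_mean)^2), numeric(1))
  sc_cov_i <- vapply(seq_len(n_chr), function(i) {
    mean((dx[[i]]$V - dx[[i]]$x_mean) * (dy[[i]]$V - dy[[i]]$x_mean))
  }, numeric(1))
  scx <- sum(w * sc(dx)); scy <- sum(w * sc(dy)); sccov <- sum(w * sc_cov_i)
  mx <- vapply(dx, function(d) d$x_mean, numeric(1))
  my <- vapply(dy, function(d) d$x_mean, numeric(1))
  gx <- sum(w * mx); gy <- sum(w * my)
  amx <- sum(w * (mx - gx)^2); amy <- sum(w * (my - gy)^2)
  amcov <- sum(w * (mx - gx) * (my - gy))
  Vx <- sum(vx_z) + scx + amx
  Vy <- sum(vy_z) + scy + amy

  prop <- function(vz, V) if (V > 0) vz / V else rep(NA_real_, length(vz))
  cx <- prop(vx_z, Vx); cyp <- prop(vy_z, Vy)
  c_lam <- switch(weight_mean,
    geometric = sqrt(cx * cyp),
    arithmetic = (cx + cyp) / 2
  )
  rho_z <- ifelse(vx_z > 0 & vy_z > 0, cv_z / sqrt(vx_z * vy_z), NA_real_)
  contrib <- ifelse(is.na(rho_z), 0, c_lam * rho_z)

  sc_rho <- if (scx > 0 && scy > 0) sccov / sqrt(scx * scy) else NA_real_
  sc_c <- switch(weight_mean,
    geometric = sqrt((scx / Vx) * (scy / Vy)),
    arithmetic = (scx / Vx + scy / Vy) / 2
  )
  sc_contrib <- if (is.na(sc_rho)) 0 else sc_c * sc_rho
  am_rho <- if (amx > 0 && amy > 0) amcov / sqrt(amx * amy) else NA_real_
  am_c <- switch(weight_mean,
    geometric = sqrt((amx / Vx) * (amy / Vy)),
    arithmetic = (amx / Vx + amy / Vy) / 2
  )
  am_contrib <- if (is.na(am_rho)) 0 else am_c * am_rho

  ci <- matrix(NA_real_, nrow = Jmax + 2L, ncol = 2L)
  if (jackknife && n_chr >= 3L) {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    for (j in seq_len(Jmax)) {
      p <- which(present[, j])
      if (length(p) >= 3L && !is.na(rho[j])) {
        loo <- vapply(p, function(drop) {
          keep <- setdiff(p, drop)
          cvk <- sum(w[keep] * cv[keep, j])
          vxk <- sum(w[keep] * vx[keep, j])
          vyk <- sum(w[keep] * vy[keep, j])
          if (vxk > 0 && vyk > 0) cvk / sqrt(vxk * vyk) else NA_real_
        }, numeric(1))
        if (!anyNA(loo)) {
          se <- .wjack_se(rho[j], loo, Lvec[p])
          ci[j, ] <- rho[j] + c(-1, 1) * z * se
        }
      }
    }
  }

  out <- tibble::tibble(
    scale = c(as.character(2^seq_len(Jmax)), "chrom", "scaling"),
    level = c(seq_len(Jmax), NA_integer_, NA_integer_),
    scale_map = c(2^seq_len(Jmax) * res, NA_real_, NA_real_),
    correlation = c(rho, am_rho, sc_rho),
    weight = c(c_lam, am_c, sc_c),
    contribution = c(contrib, am_contrib, sc_contrib),
    n_chrom = c(colSums(present), n_chr, n_chr),
    ci_lo = ci[, 1],
    ci_hi = ci[, 2]
  )
  attr(out, "correlation") <- sum(out$contribution, na.rm = TRUE)
  attr(out, "resolution") <- res
  attr(out, "estimator") <- estimator
  attr(out, "statistic") <- "correlation"
  class(out) <- c("gnom_cor_decomp", class(out))
  out
}

#' Per-scale variance explained by predictor signals
#'
#' Regresses the wavelet coefficients of a response signal on those of one or
#' more predictor signals, scale by scale, pooling non-boundary coefficients
#' across chromosomes. Because wavelet coefficients are zero-mean by
#' construction, the regression has no intercept. The squared multiple
#' correlation per scale estimates the proportion of variance at that scale
#' attributable to the predictors (e.g. ancestry on recombination rate, where
#' any systematic relationship is taken to reflect selection).
#'
#' @param x Response signal: data frame with `chrom`, `pos`, `value`.
#' @param predictors A single predictor data frame in the same format, or a
#'   named list of them for multiple regression.
#' @inheritParams gnom_var_decomp
#' @return Tibble with columns `level`, `scale`, `scale_map`, `r_squared`,
#'   `n_coef`. Scales with fewer than 3 pooled coefficient pairs have `NA`.
#' @export
variance_explained_by_predictor <- function(x, predictors,
                                            estimator = c("unbiased", "biased")) {
  estimator <- match.arg(estimator)
  if (is.data.frame(predictors)) predictors <- list(predictors)
  px <- .per_chrom_decomp(x)
  pp <- lapply(predictors, .per_chrom_decomp)
  for (p in pp) {
    if (!identical(names(p$decomps), names(px$decomps))) {
      stop("predictor must cover the same chromosomes as the response")
    }
  }
  dx <- px$decomps
  Jmax <- max(vapply(dx, function(d) max(d$levels), numeric(1)))
  rows <- lapply(seq_len(Jmax), function(j) {
    yy <- list(); XX <- list()
    for (i in seq_along(dx)) {
      if (j > max(dx[[i]]$levels)) next
      keep <- if (estimator == "unbiased") .nonboundary_idx(dx[[i]]$L, j) else seq_len(dx[[i]]$L)
      if (length(keep) == 0L) next
      yy[[length(yy) + 1L]] <- dx[[i]]$W[keep, j]
      XX[[length(XX) + 1L]] <- vapply(pp, function(p) p$decomps[[i]]$W[keep, j],
                                      numeric(length(keep)))
    }
    yv <- unlist(yy)
    n <- length(yv)
    if (n < 3L) {
      return(tibble::tibble(level = j, scale = 2^j,
                            scale_map = 2^j * px$resolution,
                            r_squared = NA_real_, n_coef = n))
    }
    X <- do.call(rbind, lapply(XX, function(m) matrix(m, ncol = length(pp))))
    fit <- stats::lm.fit(X, yv)
    r2 <- 1 - sum(fit$residuals^2) / sum(yv^2)
    tibble::tibble(level = j, scale = 2^j, scale_map = 2^j * px$resolution,
                   r_squared = r2, n_coef = n)
  })
  dplyr::bind_rows(rows)
}

#' Weighted delete-one-block jackknife confidence interval
#'
#' Delete-one jackknife over blocks (chromosomes) with unequal block weights,
#' for a genome-wide statistic formed as the weighted mean of per-block
#' statistics. Uses block-length-weighted pseudovalues; with equal weights it
#' reduces to the ordinary delete-one jackknife. The interval is z-based,
#' centered on the full-sample estimate.
#'
#' @param values Per-block statistic values.
#' @param weights Block weights (e.g. chromosome lengths). Default equal.
#' @param conf_level Confidence level.
#' @return One-row tibble: `estimate`, `se`, `ci_lo`, `ci_hi`, `n_blocks`.
#'   With fewer than 3 blocks the interval (and se) is omitted as `NA`.
#' @export
jackknife_ci <- function(values, weights = NULL, conf_level = 0.95) {
  values <- as.numeric(values)
  g <- length(values)
  if (is.null(weights)) weights <- rep(1, g)
  stopifnot(length(weights) == g, all(weights > 0))
  wn <- weights / sum(weights)
  est <- sum(wn * values)
  if (g < 3L) {
    return(tibble::tibble(estimate = est, se = NA_real_,
                          ci_lo = NA_real_, ci_hi = NA_real_, n_blocks = g))
  }
  loo <- vapply(seq_len(g), function(i) {
    sum(wn[-i] * values[-i]) / sum(wn[-i])
  }, numeric(1))
  se <- .wjack_se(est, loo, weights)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(estimate = est, se = se,
                 ci_lo = est - z * se, ci_hi = est + z * se, n_blocks = g)
}

# Weighted jackknife standard error (Busing et al. 1999 delete-one form):
# theta = full-sample estimate, loo = leave-one-out estimates, m = block sizes.
.wjack_se <- function(theta, loo, m) {
  g <- length(loo)
  n <- sum(m)
  h <- n / m
  theta_J <- g * theta - sum((1 - m / n) * loo)
  tau <- h * theta - (h - 1) * loo
  sqrt(sum((tau - theta_J)^2 / (h - 1)) / g)
}

# Split a (chrom, pos, value) frame into per-chromosome MODWT decompositions,
# checking that every chromosome shares one grid resolution.
.per_chrom_decomp <- function(data) {
  stopifnot(is.data.frame(data), all(c("chrom", "pos", "value") %in% names(data)))
  if (nrow(data) < 2L) stop("need at least 2 observations")
  chroms <- unique(as.character(data$chrom))
  decomps <- vector("list", length(chroms))
  names(decomps) <- chroms
  res <- NA_real_
  for (ch in chroms) {
    sub <- data[as.character(data$chrom) == ch, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    r <- .grid_resolution(sub$pos)
    if (is.na(res)) {
      res <- r
    } else if (abs(r - res) > 1e-6 * res) {
      stop("inconsistent grid resolutions across chromosomes: ", res, " vs ", r,
           " (chromosome ", ch, ")")
    }
    d <- modwt_haar(sub$value)
    d$chromosome <- ch
    d$resolution <- r
    decomps[[ch]] <- d
  }
  list(decomps = decomps, resolution = res)
}
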