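# Inter-model comparison statistics: distribution summaries, Bland-Altman
# limits of agreement, Spearman rank correlation, polynomial relation fits,
# Wilcoxon signed-rank and Fisher-Pitman permutation tests, and validation
# of a raster against point measurements.

#' Distribution summary in the layout of the exposure tables
#'
#' @param x numeric vector, n >= 1.
#' @return list with `n`, `mean`, `sd` (sample SD, n-1 denominator; 0 with
#'   `sd_undefined = TRUE` for a single value), `min`, `p5`, `median`, `p95`,
#'   `max`. Percentiles use linear interpolation.
#' @export
summarize_distribution <- function(x) {
  abort_if(length(x) < 1L, "need at least one value")
  q <- stats::quantile(x, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  sd_undef <- length(x) == 1L
  list(n = length(x), mean = mean(x),
       sd = if (sd_undef) 0 else stats::sd(x), sd_undefined = sd_undef,
       min = min(x), p5 = q[1L], median = q[2L], p95 = q[3L], max = max(x))
}

#' Bland-Altman agreement between two paired series
#'
#' Differences are `b - a`; the limits of agreement are the mean difference
#' plus/minus twice the sample SD of the differences.
#'
#' @param a,b equal-length paired numeric vectors, n >= 2.
#' @return list with `n`, `mean_diff`, `sd_diff`, `loa_low`, `loa_high` and
#'   the per-pair `diffs`.
#' @export
bland_altman <- function(a, b) {
  abort_if(length(a) != length(b) || length(a) < 2L,
           "need equal-length paired vectors with n >= 2")
  d <- b - a
  m <- mean(d)
  s <- stats::sd(d)
  list(n = length(d), mean_diff = m, sd_diff = s,
       loa_low = m - 2 * s, loa_high = m + 2 * s, diffs = d)
}

#' Polynomial relation between two model estimates
#'
#' Least-squares fits of `b` on polynomials of `a` of degree 1 to
#' `max_degree`. The selected "best" degree is the lowest degree whose
#' R-squared gain over the previous degree exceeds `gain_threshold`
#' (degree 1 is the baseline).
#'
#' @param a,b paired numeric vectors with `n > max_degree + 1`.
#' @param max_degree highest polynomial degree tried.
#' @param gain_threshold minimum R-squared improvement to accept a higher
#'   degree.
#' @return list with `r_squared` (named by degree), `best_degree` and
#'   `coefficients` of the selected fit (intercept first).
#' @export
polynomial_relation <- function(a, b, max_degree = 3, gain_threshold = 0.01) {
  abort_if(length(a) != length(b) || length(a) <= max_degree + 1L,
           "need paired vectors with n > max_degree + 1")
  r2 <- numeric(max_degree)
  fits <- vector("list", max_degree)
  for (d in seq_len(max_degree)) {
    fits[[d]] <- stats::lm(b ~ stats::poly(a, d, raw = TRUE))
    r2[d] <- summary(fits[[d]])$r.squared
  }
  best <- 1L
  for (d in seq_len(max_degree)[-1L]) {
    if (r2[d] - r2[d - 1L] > gain_threshold) best <- d else break
  }
  list(r_squared = stats::setNames(r2, paste0("degree_", seq_len(max_degree))),
       best_degree = best,
       coefficients = unname(stats::coef(fits[[best]])))
}

#' Spearman rank correlation
#'
#' Pearson correlation of the ranks, with average ranks on ties.
#'
#' @param a,b paired numeric vectors.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(a, b) {
  abort_if(length(a) != length(b) || length(a) < 2L,
           "need equal-length paired vectors with n >= 2")
  stats::cor(rank(a, ties.method = "average"),
             rank(b, ties.method = "average"))
}

#' Two-sided Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (all-zero pairs give p = 1 with a warning).
#' The exact signed-rank null distribution is used for n <= 25 without ties
#' in the absolute differences; otherwise a normal approximation with
#' continuity and tie correction.
#'
#' @param a,b paired numeric vectors.
#' @return list with `statistic` (V, sum of positive ranks), `n_nonzero`,
#'   `p_value` and `method` ("exact" or "normal").
#' @export
wilcoxon_signed_rank <- function(a, b) {
  abort_if(length(a) != length(b) || length(a) < 1L,
           "need equal-length paired vectors")
  d <- b - a
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; p-value defined as 1")
    return(list(statistic = NA_real_, n_nonzero = 0L, p_value = 1,
                method = "degenerate"))
  }
  r <- rank(abs(d), ties.method = "average")
  V <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25L && !ties) {
    p <- if (V > n * (n + 1) / 4) {
      2 * stats::psignrank(V - 1, n, lower.tail = FALSE)
    } else {
      2 * stats::psignrank(V, n)
    }
    return(list(statistic = V, n_nonzero = n, p_value = min(1, p),
                method = "exact"))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (V - mu - 0.5 * sign(V - mu)) / sqrt(sigma2)
  list(statistic = V, n_nonzero = n,
       p_value = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Fisher-Pitman permutation test for paired samples
#'
#' Monte-Carlo permutation test obtained by randomly swapping the members of
#' each pair. The default statistic targets a difference in spread,
#' `|SD(a) - SD(b)|`, matching its use for comparing the variability of
#' model estimates; any other exchangeable statistic can be plugged in.
#' The p-value is `(1 + #{perm >= observed}) / (1 + n_perm)`.
#'
#' @param a,b paired numeric vectors, n >= 2.
#' @param n_perm number of random permutations.
#' @param seed integer seed for the permutation draws.
#' @param statistic function of `(a, b)` returning a scalar; larger = more
#'   extreme.
#' @return list with `statistic` (observed), `p_value`, `n_perm`.
#' @export
fisher_pitman <- function(a, b, n_perm = 9999, seed = 1L,
                          statistic = function(a, b) abs(stats::sd(a) -
                                                           stats::sd(b))) {
  abort_if(length(a) != length(b) || length(a) < 2L,
           "need equal-length paired vectors with n >= 2")
  obs <- statistic(a, b)
  rng <- local_seed(seed, "fisher_pitman")
  on.exit(rng(), add = TRUE)
  n <- length(a)
  perm_stats <- numeric(n_perm)
  swap <- matrix(stats::runif(n * n_perm) < 0.5, nrow = n)
  for (k in seq_len(n_perm)) {
    s <- swap[, k]
    ak <- ifelse(s, b, a)
    bk <- ifelse(s, a, b)
    perm_stats[k] <- statistic(ak, bk)
  }
  list(statistic = obs,
       p_value = (1 + sum(perm_stats >= obs)) / (1 + n_perm),
       n_perm = n_perm)
}

#' Validate a raster against point measurements
#'
#' Unadjusted R-squared of a linear regression of the measured values on the
#' grid-cell values at the measurement sites.
#'
#' @param grid a [concentration_grid()].
#' @param sites data.frame with columns `x`, `y` (metres) and `measured`
#'   (ug/m3); at least 3 sites.
#' @return R-squared in `[0, 1]`.
#' @export
validate_against_points <- function(grid, sites) {
  abort_if(!is.data.frame(sites) ||
             !all(c("x", "y", "measured") %in% names(sites)),
           "sites must have columns x, y, measured")
  abort_if(nrow(sites) < 3L, "need at least 3 measurement sites")
  modeled <- grid_value_at(grid, sites$x, sites$y)
  abort_if(stats::var(modeled) == 0,
           "grid values at the sites have zero variance; R^2 undefined")
  summary(stats::lm(sites$measured ~ modeled))$r.squared
}

#' Pairwise comparison of per-subject model estimates
#'
#' Computes, for every model pair in a [compute_exposure()] table, the
#' Bland-Altman difference statistics, Spearman correlation, best polynomial
#' relation, Wilcoxon signed-rank p and Fisher-Pitman (spread) p.
#'
#' @param exposure data.frame from [compute_exposure()] covering >= 2 models.
#' @param value column compared (default `time_weighted`).
#' @param n_perm,seed forwarded to [fisher_pitman()].
#' @return data.frame of class `comparison_result`, one row per ordered model
#'   pair (B - A): `model_a`, `model_b`, `n`, `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `spearman_rho`, `fit_degree`, `fit_r_squared`,
#'   `wilcoxon_p`, `fisher_pitman_p`.
#' @export
compare_models <- function(exposure, value = "time_weighted",
                           n_perm = 1999, seed = 1L) {
  abort_if(!value %in% names(exposure), paste("no column", value))
  models <- unique(exposure$model_name)
  abort_if(length(models) < 2L, "need estimates from at least two models")
  wide <- lapply(models, function(m) {
    sub <- exposure[exposure$model_name == m, ]
    sub[[value]][order(sub$subject_id)]
  })
  names(wide) <- models
  rows <- list()
  for (i in seq_along(models)) {
    for (j in seq_along(models)) {
      if (j <= i) next
      a <- wide[[i]]; b <- wide[[j]]
      ba <- bland_altman(a, b)
      pr <- polynomial_relation(a, b,
                                max_degree = max(1L, min(3L, ba$n - 2L)))
      rows[[length(rows) + 1L]] <- data.frame(
        model_a = models[i], model_b = models[j], n = ba$n,
        mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
        loa_low = ba$loa_low, loa_high = ba$loa_high,
        spearman_rho = spearman_rho(a, b),
        fit_degree = pr$best_degree,
        fit_r_squared = unname(pr$r_squared[pr$best_degree]),
        wilcoxon_p = wilcoxon_signed_rank(a, b)$p_value,
        fisher_pitman_p = fisher_pitman(a, b, n_perm = n_perm,
                                        seed = seed)$p_value)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_result", "data.frame")
  out
}
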