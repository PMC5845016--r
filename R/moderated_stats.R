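## Empirical-Bayes moderated one-sample t-test for SILAC log2 ratios.
##
## Model: per-feature sample variances s2_g on df_g degrees of freedom are
## shrunk toward a global prior (d0, s02) estimated across all features by
## moment matching on log sample variances: if s2 | sigma2 ~ sigma2 * chi^2_df/df
## and 1/sigma2 ~ (1/s02) * chi^2_d0/d0, then
##   E log(s2)   = log(sigma2) + digamma(df/2) - log(df/2)
##   Var log(s2) = trigamma(df/2)                       (sampling)
##               + trigamma(d0/2)                       (between-feature)
## so the excess of the observed variance of the adjusted log variances over
## the mean sampling variance identifies trigamma(d0/2); the mean identifies
## s02. The posterior variance is the df-weighted blend
##   s2_tilde = (d0*s02 + df*s2) / (d0 + df)
## and the moderated t is mean / sqrt(s2_tilde / n) on df + d0 degrees of
## freedom.

#' Invert the trigamma function
#'
#' Solves \code{trigamma(x) = y} for \code{x > 0} by Newton iteration on the
#' convex decreasing function, used to recover the prior degrees of freedom
#' from the matched log-variance moment.
#'
#' @param y positive value.
#' @return \code{x} with \code{trigamma(x) == y} (to ~1e-12 relative).
#' @export
trigamma_inverse <- function(y) {
  if (!is.finite(y)) return(if (y > 0) 0 else Inf)
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:64) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-12) break
  }
  x
}

#' Fit the empirical-Bayes variance model to a log-ratio matrix
#'
#' @param mat numeric matrix, features x replicates, log2 ratios, \code{NA}
#'   allowed. At least two features need \code{>= 2} observations.
#' @param var_floor variances below this are raised to it before the
#'   log-variance moment fit (guards \code{log(0)}).
#' @param d0_override optional fixed prior df (e.g. \code{0} for the
#'   no-shrinkage ordinary t limit, \code{Inf} for full pooling); skips
#'   hyperparameter estimation.
#' @param posterior_only if \code{TRUE}, features seen in a single replicate
#'   (df = 0) are still assigned a moderated t using the prior alone; by
#'   default they are flagged and left untested.
#' @return object of class \code{"ebayes_fit"}: per-feature \code{n_obs},
#'   \code{mean_log2}, \code{s2}, \code{df}, \code{s2_tilde},
#'   \code{df_total}, \code{t_mod}, \code{p_two}, \code{flagged}; global
#'   \code{d0}, \code{s02}.
#' @export
fit_ebayes <- function(mat, var_floor = 1e-8, d0_override = NULL,
                       posterior_only = FALSE) {
  mat <- as.matrix(mat)
  n_obs <- rowSums(!is.na(mat))
  mean_log2 <- rowMeans(mat, na.rm = TRUE)
  mean_log2[n_obs == 0L] <- NA_real_
  s2 <- apply(mat, 1L, function(v) stats::var(v[!is.na(v)]))
  s2[n_obs < 2L] <- NA_real_
  df <- pmax(n_obs - 1L, 0L)

  est <- df >= 1L & !is.na(s2)
  if (sum(est) < 2L)
    stopf("need at least 2 features with >= 2 observations to fit the variance prior")
  if (all(s2[est] <= 0) && var_floor <= 0)
    stopf("all sample variances are zero; the variance prior (d0 = Inf, s02 = 0) is ill-posed — apply a positive variance floor")

  s2f <- pmax(s2[est], var_floor)
  dfe <- df[est]
  z <- log(s2f)
  e <- z - digamma(dfe / 2) + log(dfe / 2)
  if (is.null(d0_override)) {
    emean <- mean(e)
    n <- length(e)
    evar <- mean((e - emean)^2) * n / (n - 1L)
    excess <- evar - mean(trigamma(dfe / 2))
    if (excess > 0) {
      d0 <- 2 * trigamma_inverse(excess)
      s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s02 <- exp(emean)
    }
  } else {
    d0 <- d0_override
    s02 <- if (is.finite(d0) && d0 > 0)
      exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)) else exp(mean(e))
  }

  s2w <- pmax(s2, var_floor)
  if (is.finite(d0)) {
    s2_tilde <- (d0 * s02 + df * s2w) / (d0 + df)
    s2_tilde[df == 0L] <- if (d0 > 0) s02 else NA_real_
  } else {
    s2_tilde <- rep(s02, length(s2w))
  }
  df_total <- df + d0
  flagged <- df == 0L
  t_mod <- mean_log2 / sqrt(s2_tilde / pmax(n_obs, 1L))
  p_two <- 2 * stats::pt(-abs(t_mod), df = df_total)
  if (!posterior_only) {
    t_mod[flagged] <- NA_real_
    p_two[flagged] <- NA_real_
  }
  t_mod[n_obs == 0L] <- NA_real_
  p_two[n_obs == 0L] <- NA_real_

  structure(list(n_obs = n_obs, mean_log2 = mean_log2, s2 = s2, df = df,
                 d0 = d0, s02 = s02, s2_tilde = s2_tilde,
                 df_total = df_total, t_mod = t_mod, p_two = p_two,
                 flagged = flagged),
            class = "ebayes_fit")
}

#' @export
print.ebayes_fit <- function(x, ...) {
  cat(sprintf("<ebayes_fit> %d features; prior d0 = %.4g, s02 = %.4g\n",
              length(x$t_mod), x$d0, x$s02))
  invisible(x)
}

#' Moderated one-sample test on one contrast of a ratio table
#'
#' Tests, per feature, whether the mean log2 ratio of the given contrast
#' differs from zero, with empirical-Bayes variance moderation across
#' features.
#'
#' @param x a \code{ratio_table} (\code{silac_site_table} or
#'   \code{pulldown_table}).
#' @param contrast condition label to test.
#' @param alternative \code{"two.sided"}, \code{"less"} or \code{"greater"}.
#' @param ... passed to \code{\link{fit_ebayes}}.
#' @return data.frame with feature id, \code{n_obs}, \code{mean_log2},
#'   \code{t_mod}, \code{p}, \code{q} (BH-adjusted over testable features).
#' @export
moderated_one_sample_test <- function(x, contrast,
                                      alternative = c("two.sided", "less", "greater"),
                                      ...) {
  alternative <- match.arg(alternative)
  m <- ratio_matrix(x, contrast)
  fit <- fit_ebayes(m, ...)
  p <- switch(alternative,
              two.sided = fit$p_two,
              less = stats::pt(fit$t_mod, df = fit$df_total),
              greater = stats::pt(fit$t_mod, df = fit$df_total, lower.tail = FALSE))
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- bh_adjust(p[ok])
  out <- data.frame(id = rownames(m), n_obs = fit$n_obs,
                    mean_log2 = fit$mean_log2, t_mod = fit$t_mod,
                    p = p, q = q, stringsAsFactors = FALSE)
  names(out)[1L] <- attr(x, "id_col")
  attr(out, "fit") <- fit
  attr(out, "contrast") <- contrast
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values \code{q_i = min_j {min(1, m p_(j) / j) : p_(j) >= p_(i)}}.
#'
#' @param p numeric vector of p-values in [0,1].
#' @return vector of q-values, same order as \code{p}.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0,1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

test_result <- function(statistic, p_value, method, estimate = NULL) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 estimate = estimate), class = "uvphos_test")
}

#' @export
print.uvphos_test <- function(x, ...) {
  cat(sprintf("<%s test> statistic = %.4g, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  invisible(x)
}

#' Wilcoxon rank-sum test
#'
#' Exact null enumeration for small samples without ties
#' (\code{n_x + n_y <= 12}); otherwise the normal approximation with
#' mid-rank tie correction and optional \code{+/- 0.5} continuity correction.
#'
#' @param x,y numeric samples.
#' @param continuity apply the continuity correction in the normal
#'   approximation (default \code{TRUE}).
#' @param alternative \code{"two.sided"}, \code{"less"} or \code{"greater"}.
#' @return a test-result object with the rank-sum statistic \code{W} and the
#'   p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, continuity = TRUE,
                              alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y)) <= 12L
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = continuity))
  test_result(unname(ht$statistic), ht$p.value, "wilcoxon")
}

#' Siegel-Tukey test for differences in spread
#'
#' Assigns alternating extreme ranks to the pooled sorted sample (1 to the
#' smallest, 2-3 to the largest two, 4-5 to the next smallest two, ...),
#' averages ranks over tied values, then applies the Wilcoxon rank-sum test
#' to the resulting scores. A sample drawn from the wider distribution
#' collects the low extreme ranks. When the pooled size is odd the single
#' middle observation is dropped (classical convention).
#'
#' @param x,y numeric samples.
#' @param alternative as in \code{\link{wilcoxon_rank_sum}}; \code{"less"}
#'   means \code{x} has systematically lower Siegel-Tukey scores, i.e.
#'   larger spread.
#' @return a test-result object.
#' @export
siegel_tukey <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  pooled <- c(x, y)
  grp <- rep(c("x", "y"), c(length(x), length(y)))
  N <- length(pooled)
  ord <- order(pooled)
  if (N %% 2L == 1L) {
    mid <- ord[(N + 1L) %/% 2L]
    keep <- seq_len(N) != mid
    pooled <- pooled[keep]; grp <- grp[keep]
    N <- N - 1L
    ord <- order(pooled)
  }
  st <- siegel_tukey_ranks(N)
  rank_by_sortpos <- st
  scores <- numeric(N)
  scores[ord] <- rank_by_sortpos
  # mid-ranks over tied data values
  for (v in unique(pooled[duplicated(pooled)]))
    scores[pooled == v] <- mean(scores[pooled == v])
  wilcoxon_rank_sum(scores[grp == "x"], scores[grp == "y"],
                    alternative = alternative)
}

## Alternating extreme-rank pattern for a pooled sample of even size N:
## position i (1 = smallest) -> Siegel-Tukey rank.
siegel_tukey_ranks <- function(N) {
  ranks <- integer(N)
  lo <- 1L; hi <- N; r <- 1L
  take_lo <- TRUE; first <- TRUE
  while (lo <= hi) {
    k <- if (first) 1L else 2L
    first <- FALSE
    if (take_lo) {
      for (i in seq_len(min(k, hi - lo + 1L))) { ranks[lo] <- r; lo <- lo + 1L; r <- r + 1L }
    } else {
      for (i in seq_len(min(k, hi - lo + 1L))) { ranks[hi] <- r; hi <- hi - 1L; r <- r + 1L }
    }
    take_lo <- !take_lo
  }
  ranks
}

#' Spearman rank correlation test
#'
#' Rho on mid-ranks; exact p by permutation enumeration for \code{n <= 9}
#' without ties, otherwise the t-approximation.
#'
#' @param x,y numeric vectors of equal length.
#' @return a test-result object with \code{estimate} = rho.
#' @export
spearman <- function(x, y) {
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  exact <- !ties && length(x) <= 9L
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact))
  test_result(unname(ht$statistic), ht$p.value, "spearman",
              estimate = unname(ht$estimate))
}
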