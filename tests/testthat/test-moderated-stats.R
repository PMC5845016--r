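# The empirical-Bayes moderated t: hyperparameters by log-variance moment
# matching, posterior variance blending, and the shrinkage properties that
# define it.

ebayes_fixture <- matrix(c( 0.10, 0.30, 0.20,
                            1.50, 1.20, 1.80,
                           -0.40, -0.10, -0.25,
                            0.05, 0.00, 0.90,
                            2.00, 2.10, 1.95,
                           -1.00, -1.60, -1.30), nrow = 6, byrow = TRUE)

test_that("hyperparameters match the independent bisection oracle and frozen values", {
  fit <- fit_ebayes(ebayes_fixture)
  orc <- oracle_ebayes(ebayes_fixture)
  expect_equal(fit$d0, orc$d0, tolerance = 1e-8)
  expect_equal(fit$s02, orc$s02, tolerance = 1e-8)
  # frozen values, computed once from the oracle
  expect_equal(fit$d0, 4.9766892387, tolerance = 1e-7)
  expect_equal(fit$s02, 0.0537133893, tolerance = 1e-7)
  expect_equal(fit$t_mod,
               c(1.70701084, 10.26053295, -2.04658134, 1.64143652,
                 17.46753909, -8.89246189),
               tolerance = 1e-6)
  # and on larger random matrices with heterogeneous variances
  set.seed(201)
  for (i in 1:3) {
    sg <- sqrt(0.05 * 2 / rchisq(150, df = 2))
    m <- matrix(rnorm(150 * 3, 0, rep(sg, 3)), ncol = 3)
    f <- fit_ebayes(m); o <- oracle_ebayes(m)
    expect_equal(f$d0, o$d0, tolerance = 1e-6)
    expect_equal(f$s02, o$s02, tolerance = 1e-6)
  }
})

test_that("hyperparameters agree with limma's squeezeVar on the same variances", {
  s2 <- apply(ebayes_fixture, 1, var)
  sq <- limma::squeezeVar(s2, df = 2)
  fit <- fit_ebayes(ebayes_fixture)
  expect_equal(fit$d0, sq$df.prior, tolerance = 1e-8)
  expect_equal(fit$s02, sq$var.prior, tolerance = 1e-8)
  expect_equal(unname(fit$s2_tilde), unname(sq$var.post), tolerance = 1e-8)
})

test_that("homogeneous variances give d0 = Inf and a z-like statistic", {
  m <- matrix(c(1, 2, 3,
                2, 3, 4,
                0, 1, 2,
                5, 6, 7), nrow = 4, byrow = TRUE)  # identical s2 = 1
  fit <- fit_ebayes(m)
  expect_identical(fit$d0, Inf)
  expect_equal(unname(fit$s2_tilde), rep(fit$s02, 4))
  expect_equal(unname(fit$t_mod), rowMeans(m) / sqrt(fit$s02 / 3))
})

test_that("d0 = 0 override recovers the ordinary one-sample t", {
  set.seed(5)
  m <- matrix(rnorm(30), 10, 3)
  fit <- fit_ebayes(m, d0_override = 0)
  t_ord <- apply(m, 1, function(v) t.test(v)$statistic)
  p_ord <- apply(m, 1, function(v) t.test(v)$p.value)
  expect_equal(unname(fit$t_mod), unname(t_ord), tolerance = 1e-12)
  expect_equal(unname(fit$p_two), unname(p_ord), tolerance = 1e-12)
})

test_that("shrinkage ordering and monotonicity in s2 hold", {
  set.seed(77)
  for (i in 1:5) {
    sg <- sqrt(0.1 * 3 / rchisq(80, df = 3))
    m <- matrix(rnorm(80 * 3, 0.2, rep(sg, 3)), ncol = 3)
    fit <- fit_ebayes(m)
    lo <- pmin(fit$s02, fit$s2) - 1e-12
    hi <- pmax(fit$s02, fit$s2) + 1e-12
    expect_true(all(fit$s2_tilde >= lo & fit$s2_tilde <= hi))
  }
  # same mean, increasing s2 -> |t| non-increasing
  base <- c(-1, 0, 1)
  m <- rbind(1 + 0.5 * base, 1 + 1.0 * base, 1 + 2.0 * base, 1 + 4.0 * base)
  fit <- fit_ebayes(m)
  expect_true(all(diff(abs(fit$t_mod)) <= 1e-12))
})

test_that("degenerate inputs are handled per contract", {
  expect_error(fit_ebayes(matrix(0, 3, 2), var_floor = 0), "variance floor")
  # with the default floor the all-zero matrix is well-posed and t = 0
  fit <- fit_ebayes(matrix(0, 3, 2))
  expect_equal(unname(fit$t_mod), rep(0, 3))
  expect_error(fit_ebayes(matrix(1:2, 1, 2)), "at least 2 features")
  # single-replicate features are flagged and untested by default
  m <- matrix(rnorm(20), 10, 2)
  m[1, 2] <- NA
  fit2 <- fit_ebayes(m)
  expect_true(fit2$flagged[1])
  expect_true(is.na(fit2$t_mod[1]))
  fit3 <- fit_ebayes(m, posterior_only = TRUE)
  expect_false(is.na(fit3$t_mod[1]))
  expect_equal(fit3$df_total[1], fit3$d0)
})

test_that("type-I error at p < 0.01 is calibrated under the null", {
  set.seed(11)
  m <- matrix(rnorm(1e4 * 2, 0, 0.35), ncol = 2)
  fit <- fit_ebayes(m)
  rate <- mean(fit$p_two < 0.01)
  ci <- 0.01 + c(-1, 1) * qnorm(0.995) * sqrt(0.01 * 0.99 / 1e4)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("moderation beats the ordinary t in power at two replicates", {
  set.seed(303)
  n <- 4000
  sg <- sqrt(0.1 * 4 / rchisq(n, df = 4))
  eff <- ifelse(runif(n) < 0.1, 1.5, 0)
  m <- matrix(rnorm(n * 2, eff, rep(sg, 2)), ncol = 2)
  fit <- fit_ebayes(m)
  p_ord <- apply(m, 1, function(v) t.test(v)$p.value)
  pow_mod <- mean(fit$p_two[eff > 0] < 0.01)
  pow_ord <- mean(p_ord[eff > 0] < 0.01)
  expect_gt(pow_mod, pow_ord)
})

test_that("moderated_one_sample_test reports zero-mean features as null", {
  m <- matrix(c(0, 0, 1, -1, 2, 2.5), nrow = 3, byrow = TRUE)
  x <- make_site_table(list("UV/mock" = m))
  res <- moderated_one_sample_test(x, "UV/mock")
  expect_equal(res$t_mod[1:2], c(0, 0))
  expect_equal(res$p[1:2], c(1, 1))
  expect_error(moderated_one_sample_test(x, "nope"), "absent")
})

test_that("BH adjustment matches the step-up formula and its invariances", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.04), 0.04)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0,1\\]")
  set.seed(8)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  o <- sample(50)
  expect_equal(bh_adjust(p[o]), q[o])
})
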