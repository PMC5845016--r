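# Hierarchical regulation calling: UV direction, p38/MK dependency,
# S/TQ flags and the summary-fraction arithmetic.

test_that("an all-zero ratio matrix yields only non-significant calls", {
  x <- make_site_table(list("UV/mock" = matrix(0, 5, 2)))
  calls <- call_uv_regulation(x)
  expect_true(all(calls$uv_direction == "ns"))
})

test_that("direction follows sign and significance of the mean log2 ratio", {
  set.seed(1)
  m <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
             c(2.0, 2.1), c(-1.8, -2.2))
  x <- make_site_table(list("UV/mock" = m))
  calls <- call_uv_regulation(x)
  expect_equal(calls$uv_direction[21], "up")
  expect_lt(calls$p_uv[21], 0.01)
  expect_equal(calls$uv_direction[22], "down")
  expect_true(all(calls$uv_direction[1:20] == "ns"))
})

test_that("sites below the localization cutoff are excluded from testing", {
  m <- matrix(c(2, 2.1, 2, 2.1, 0, 0.1, 0, -0.1), 4, 2, byrow = TRUE)
  x <- make_site_table(list("UV/mock" = m))
  x$features$localization_prob <- c(0.99, 0.5, 0.99, 0.99)
  calls <- call_uv_regulation(x)
  expect_true(is.na(calls$uv_direction[2]))
  expect_true(is.na(calls$dependency[2]))
  expect_equal(calls$uv_direction[1], "up")
})

test_that("identical inhibitor and UV ratios give zero dependent sites", {
  set.seed(2)
  m <- matrix(rnorm(20, 1, 0.3), 10, 2)
  x <- make_site_table(list("UV/mock" = m, "p38i+UV/mock" = m))
  calls <- call_uv_regulation(x)
  calls <- call_dependency(x, calls, "p38i+UV/mock")
  expect_false(any(calls$dependency == "p38_dependent", na.rm = TRUE))
})

test_that("a strong negative inhibitor shift on an up site is called dependent", {
  set.seed(3)
  n <- 30
  uv <- matrix(rnorm(2 * n, 0, 0.3), n, 2)
  uv[1, ] <- c(2.0, 2.2)                    # UV-induced
  inh <- uv + matrix(rnorm(2 * n, 0, 0.05), n, 2)
  inh[1, ] <- uv[1, ] - 1.4                 # effect erased by inhibition
  x <- make_site_table(list("UV/mock" = uv, "p38i+UV/mock" = inh))
  calls <- call_uv_regulation(x)
  calls <- call_dependency(x, calls, "p38i+UV/mock")
  expect_equal(calls$dependency[1], "p38_dependent")
  expect_lt(calls$p_p38[1], 0.01)
})

test_that("calls partition the tested sites and respect the hierarchy", {
  cfg <- sim_config(seed = 8, n_sites = 4000)
  out <- simulate_phospho_experiment(cfg)
  calls <- call_uv_regulation(out$table)
  calls <- call_dependency(out$table, calls, "p38i+UV/mock")
  calls <- call_dependency(out$table, calls, "MKi+UV/mock", level = "mk")
  tested <- !is.na(calls$uv_direction)
  expect_equal(sum(calls$uv_direction[tested] %in% c("up", "down", "ns")),
               sum(tested))
  up <- tested & calls$uv_direction == "up"
  expect_true(all(calls$dependency[tested & !up] == "na"))
  expect_equal(sum(calls$dependency[up] %in% c("p38_dependent", "p38_independent")),
               sum(up))
  dep <- up & calls$dependency == "p38_dependent"
  expect_true(all(calls$mk_dependency[tested & !dep] == "na"))
})

test_that("lowering alpha never increases call counts", {
  cfg <- sim_config(seed = 9, n_sites = 3000)
  out <- simulate_phospho_experiment(cfg)
  c1 <- call_uv_regulation(out$table, alpha = 0.01)
  c2 <- call_uv_regulation(out$table, alpha = 0.001)
  for (d in c("up", "down"))
    expect_lte(sum(c2$uv_direction == d, na.rm = TRUE),
               sum(c1$uv_direction == d, na.rm = TRUE))
})

test_that("planted fractions are recovered at study scale with bounded FDR", {
  cfg <- sim_config(seed = 101)
  out <- simulate_phospho_experiment(cfg)
  calls <- call_uv_regulation(out$table)
  calls <- call_dependency(out$table, calls, "p38i+UV/mock")
  up <- !is.na(calls$uv_direction) & calls$uv_direction == "up"
  truth <- out$truth
  # truth-scored: nearly every planted site is recovered, with bounded FDR
  sensitivity <- mean(up[truth$uv_up])
  expect_gt(sensitivity, 0.95)
  fdr <- mean(!truth$uv_up[up])
  expect_lte(fdr, 0.15)
  dep_frac <- mean(calls$dependency[up] == "p38_dependent")
  se_dep <- sqrt(0.26 * 0.74 / sum(up))
  expect_lt(abs(dep_frac - 0.26), 3 * se_dep)
})

test_that("S/TQ flags require an S/T center followed by glutamine", {
  expect_true(flag_stq("AAAAAASQAAAAA"))
  expect_true(flag_stq("AAAAAATQAAAAA"))
  expect_false(flag_stq("AAAAAAYQAAAAA"))
  expect_false(flag_stq("AAAAAASAAAAAA"))
})

test_that("summary fractions reproduce the published percentage labels", {
  fr <- summarize_fractions(list(total = 13091, up = 538, down = 153,
                                 dep = 138, stq_up = 89, mk_dep = NULL,
                                 interactors = 384, dep_interactors = 108))
  g <- function(nm, col) fr[[col]][fr$name == nm]
  expect_equal(g("up_of_total", "pct_trunc1"), 4.1)
  expect_equal(g("down_of_total", "pct_round1"), 1.2)
  expect_equal(g("dep_of_up", "pct_trunc1"), 25.6)
  expect_equal(g("stq_of_up", "pct_int"), 17)
  expect_equal(g("interactor_dep", "pct_int"), 28)
})
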