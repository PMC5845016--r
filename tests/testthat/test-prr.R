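# Promoter-release ratio: window signals, eligibility filters, differential
# release and metagene profiles.

plus_gene <- function(tss = 5000, len = 10000, id = "g1") {
  data.frame(gene_id = id, chrom = "chrS", strand = "+", start = tss,
             end = tss + len, tss = tss, tes = tss + len, length = len,
             stringsAsFactors = FALSE)
}

test_that("uniform coverage gives window-independent signal and PRR = 0", {
  tr <- flat_track(3, 20000, "mock", 1)
  g <- plus_gene()
  s1 <- compute_window_signal(tr, g[1, ], c(-300, 1000))
  s2 <- compute_window_signal(tr, g[1, ], c(1000, 3000))
  expect_equal(s1, s2)
  prr <- compute_prr(list(tr), g, window_spec(tss_min_signal = 0))
  expect_equal(prr$summary$mock, 0)
})

test_that("a doubled downstream window gives PRR = 1 up to the pseudocount", {
  len <- 20000
  cov <- rep(0, len)
  cov[(5000 - 300 + 1):(5000 + 1000)] <- 50
  cov[(5000 + 1000 + 1):(5000 + 3000)] <- 100
  tr <- coverage_track(list(chrS = cov), "mock", 1)
  prr <- compute_prr(list(tr), plus_gene(), window_spec())
  expect_equal(prr$summary$mock, 1, tolerance = 0.01)
})

test_that("minus-strand windows mirror the plus-strand construction", {
  len <- 30000
  cov_p <- rep(0, len)
  cov_p[(5000 - 300 + 1):(5000 + 1000)] <- 7
  cov_p[(5000 + 1000 + 1):(5000 + 3000)] <- 21
  tr_p <- coverage_track(list(chrS = cov_p), "mock", 1)
  gp <- plus_gene(tss = 5000, len = 10000)

  tss_m <- 25000
  cov_m <- rep(0, len)
  cov_m[(tss_m - 1000 + 2):(tss_m + 300 + 1)] <- 7      # TSS window, mirrored
  cov_m[(tss_m - 3000 + 2):(tss_m - 1000 + 1)] <- 21    # downstream, mirrored
  tr_m <- coverage_track(list(chrS = cov_m), "mock", 1)
  gm <- data.frame(gene_id = "g2", chrom = "chrS", strand = "-",
                   start = tss_m - 10000 + 1, end = tss_m + 1, tss = tss_m,
                   tes = tss_m - 10000, length = 10000, stringsAsFactors = FALSE)
  for (w in list(c(-300, 1000), c(1000, 3000)))
    expect_equal(compute_window_signal(tr_m, gm[1, ], w),
                 compute_window_signal(tr_p, gp[1, ], w))
})

test_that("PRR is invariant to sequencing depth", {
  set.seed(41)
  cov <- rpois(20000, 5)
  g <- plus_gene()
  tr1 <- coverage_track(list(chrS = cov), "mock", 1)
  tr2 <- coverage_track(list(chrS = cov * 5), "mock", 1)
  p1 <- compute_prr(list(tr1), g, window_spec(tss_min_signal = 0))
  p2 <- compute_prr(list(tr2), g, window_spec(tss_min_signal = 0))
  expect_equal(p1$summary$mock, p2$summary$mock)
})

test_that("length and TSS-signal filters gate eligibility monotonically", {
  cfg <- sim_config(seed = 55, n_genes = 30, gene_length_range = c(1500, 12000))
  out <- simulate_polii_coverage(cfg)
  prr <- compute_prr(out$tracks, out$genes)
  short <- out$genes$length <= 3000
  expect_false(any(prr$eligible[out$genes$gene_id[short]]))
  # raising the TSS threshold never adds genes
  hi <- compute_prr(out$tracks, out$genes, window_spec(tss_min_signal = 50))
  expect_true(all(prr$eligible[hi$eligible]))
  expect_error(compute_prr(out$tracks, out$genes,
                           window_spec(tss_min_signal = 1e9)),
               "no gene")
})

test_that("identical condition tracks give zero differential release", {
  set.seed(47)
  cov1 <- rpois(20000, 4); cov2 <- rpois(20000, 4)
  g <- plus_gene()
  tracks <- list(coverage_track(list(chrS = cov1), "mock", 1),
                 coverage_track(list(chrS = cov2), "mock", 2),
                 coverage_track(list(chrS = cov1), "UV", 1),
                 coverage_track(list(chrS = cov2), "UV", 2))
  prr <- compute_prr(tracks, rbind(plus_gene(), plus_gene(tss = 14000, id = "g2")),
                     window_spec(tss_min_signal = 0))
  d <- differential_prr(prr, "mock", "UV")
  expect_equal(d$delta_prr, rep(0, 2))
  expect_true(all(d$call == "ns"))
  expect_equal(attr(d, "global_test")$p_value, 1)
})

test_that("planted release shifts are recovered with the published asymmetry", {
  cfg <- sim_config(seed = 61, n_genes = 500)
  out <- simulate_polii_coverage(cfg)
  prr <- compute_prr(out$tracks, out$genes, untreated_condition = "mock")
  d <- differential_prr(prr, "mock", "UV")
  released <- out$truth$gene_id[out$truth$released]
  est <- d$delta_prr[d$gene_id %in% released]
  expect_lt(abs(mean(est) - 1), 0.1)
  expect_gt(sum(d$call == "up"), 5 * max(sum(d$call == "down"), 1))
  expect_lt(attr(d, "global_test")$p_value, 0.01)
})

test_that("metagene profiles are strand-oriented and peak at the TSS bump", {
  len <- 30000
  cov <- rep(0, len)
  cov[5001] <- 1000                      # delta bump exactly at the + TSS
  tr <- coverage_track(list(chrS = cov), "mock", 1)
  prof <- metagene_profile(tr, plus_gene(), span = 2000, bins = 100)
  expect_equal(which.max(prof$signal), 51)   # bin [0, 40)

  flat <- metagene_profile(flat_track(2, len, "mock", 1), plus_gene(),
                           span = 2000, bins = 100)
  expect_equal(length(unique(round(flat$signal, 9))), 1)

  # mirrored minus-strand bump reproduces the plus-only profile
  cov2 <- cov
  cov2[25001] <- 1000
  tr2 <- coverage_track(list(chrS = cov2), "mock", 1,
                        library_size = tr$library_size)
  gm <- data.frame(gene_id = "gm", chrom = "chrS", strand = "-",
                   start = 15001, end = 25001, tss = 25000, tes = 15000,
                   length = 10000, stringsAsFactors = FALSE)
  prof2 <- metagene_profile(tr2, rbind(plus_gene(), gm), span = 2000, bins = 100)
  expect_equal(prof2$signal, prof$signal)
})
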