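# Position-frequency counting, iceLogo enrichment, fixed-motif matching and
# the 14-3-3 binding-motif scorer.

test_that("position counts tally residues and padding separately", {
  mc <- count_position_frequencies(rep("ALARQASAAAAAA", 10))
  expect_equal(mc$n_windows, 10)
  expect_equal(mc$counts["L", "-5"], 10)
  expect_equal(mc$counts["R", "-3"], 10)
  expect_equal(unname(colSums(mc$counts) + mc$padding), rep(10, 13))

  padded <- count_position_frequencies(c("______ASAAAAA"))
  expect_equal(unname(padded$padding["-6"]), 1)
  expect_equal(sum(padded$counts[, "-6"]), 0)
  expect_error(count_position_frequencies("ASQA"), "odd")
})

test_that("frequencies sum to one over fully occupied positions", {
  set.seed(12)
  w <- replicate(50, paste(c(sample(c("A", "C", "D"), 6, TRUE), "S",
                             sample(c("A", "C", "D"), 6, TRUE)), collapse = ""))
  mc <- count_position_frequencies(w)
  f <- sweep(mc$counts, 2, mc$n_windows - mc$padding, "/")
  expect_equal(unname(colSums(f)), rep(1, 13))
})

test_that("iceLogo z follows the binomial reference model", {
  fg <- count_position_frequencies(rep("AAAAAASQAAAAA", 100))
  # background with uniform 1/20 frequency at every flank position
  set.seed(3)
  bgw <- replicate(2000, paste(c(sample(AA20_test(), 6, TRUE), "S",
                                 sample(AA20_test(), 6, TRUE)), collapse = ""))
  bg <- count_position_frequencies(bgw)
  res <- icelogo_enrichment(fg, bg)
  cell <- res[res$position == 1 & res$residue == "Q", ]
  f_bg <- cell$freq_bg
  expect_equal(cell$z, (1 - f_bg) / sqrt(f_bg * (1 - f_bg) / 100))
  expect_gt(cell$z, 30)
  expect_true(cell$significant)
})

test_that("identical foreground and background give null enrichment", {
  mc <- count_position_frequencies(rep(c("ALARQASAAAAAA", "AAAAAATQAAAAA"), 10))
  res <- icelogo_enrichment(mc, mc)
  expect_true(all(res$diff == 0))
  expect_false(any(res$significant))
  expect_error(icelogo_enrichment(count_position_frequencies(character(0)), mc),
               "empty foreground")
})

test_that("a foreground drawn from the background flags ~alpha of cells", {
  set.seed(44)
  all_w <- random_aa_windows(12000)
  fg <- count_position_frequencies(all_w[1:2000])
  bg <- count_position_frequencies(all_w)
  res <- icelogo_enrichment(fg, bg, alpha = 0.05)
  testable <- res$freq_bg > 0 & res$freq_bg < 1
  rate <- mean(res$significant[testable])
  se <- sqrt(0.05 * 0.95 / sum(testable))
  expect_lt(abs(rate - 0.05), 4 * se)
})

test_that("fixed-motif matchers implement the published consensi", {
  expect_true(match_motif("ALARQASAAAAAA", motif_lxrqxst()))
  expect_false(match_motif("AAAAAASAAAAAA", motif_lxrqxst()))
  expect_true(match_motif("AAARAASADADIA", motif_rxxstxdxdi()))
  expect_false(match_motif("AAARAASADADAA", motif_rxxstxdxdi()))
  expect_true(match_motif("AAAAAASQAAAAA", motif_stq()))
  expect_error(motif_spec("bad", "Q"), "S/T/Y")
})

test_that("the S/TQ motif matcher agrees with flag_stq on random windows", {
  set.seed(19)
  w <- random_aa_windows(500)
  expect_equal(match_motif(w, motif_stq()), flag_stq(w))
})

test_that("iceLogo on simulator output ranks the injected MK motif cells first", {
  cfg <- sim_config(seed = 5)
  out <- simulate_phospho_experiment(cfg)
  w <- out$table$features$sequence_window
  res <- icelogo_enrichment(count_position_frequencies(w[out$truth$mk_dep]),
                            count_position_frequencies(w))
  top3 <- res[order(-abs(res$z)), ][1:3, ]
  key <- paste(top3$position, top3$residue)
  expect_setequal(key, c("-5 L", "-3 R", "-2 Q"))
  expect_true(all(top3$significant))
})

test_that("14-3-3 scoring recognizes the canonical modes and the NELFE S115 context", {
  modeI <- predict_14_3_3("AAARSASAPAAAA")
  expect_equal(modeI$mode, "mode-I")
  expect_true(modeI$positive)
  # S115 context of the crystallized NELFE phosphopeptide
  s115 <- predict_14_3_3("PFQRSISADDDLQ")
  expect_true(s115$positive)
  expect_equal(s115$mode, "relaxed-anchor")
  expect_false(predict_14_3_3("AAAAAASAAAAAA")$positive)
  expect_error(predict_14_3_3("AAAAAAYAAAAAA"), "S/T center")
})
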