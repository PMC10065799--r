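test_that("log2 fold change is computed on raw mean enrichments", {
  expect_equal(variant_log2fc(c(4, 4, 4), c(1, 1, 1)), 2)
  expect_equal(variant_log2fc(c(2, 3), c(2, 3)), 0)
  expect_equal(variant_log2fc(c(4.0, 4.2, 3.8), c(1.0, 1.1, 0.9)),
               log2(4 / 1))
  expect_error(variant_log2fc(c(0, 0), c(1, 1)), "positive")
})

test_that("the replicate test matches a textbook Welch computation", {
  v <- c(4.0, 4.2, 3.8); r <- c(1.0, 1.1, 0.9)
  expect_equal(variant_test(v, r), oracle_welch_p(v, r), tolerance = 1e-12)
  expect_lt(variant_test(v, r), 0.05)

  v2 <- c(1.0, 3.0); r2 <- c(2.0, 2.1)
  expect_equal(variant_test(v2, r2), oracle_welch_p(v2, r2), tolerance = 1e-12)
  expect_gt(variant_test(v2, r2), 0.05)

  # degenerate zero-spread identical samples: p = 1 by convention
  expect_equal(variant_test(c(2, 2, 2), c(2, 2, 2)), 1)
  expect_error(variant_test(1, c(1, 2)), "2 replicates")
})

test_that("tyrosine-gain/loss mutations are flagged", {
  expect_true(tyrosine_change("AAAAYYAAAAA", "AAAAAYAAAAA"))   # adds a Tyr
  expect_false(tyrosine_change("CAAAAYAAAAA", "AAAAAYAAAAA"))  # A->C
  expect_true(tyrosine_change("AAAAAYAFAAA", "AAAAAYAYAAA"))   # Y->F at +2
  expect_error(tyrosine_change("AAAAAAAAAAA", "AAAAAYAAAAA"), "central")
})

test_that("the five-step filter annotates reasons in order and calls hits", {
  mk_effect <- function(p, Ev, Er, tyr = FALSE, reads = 200) {
    structure(data.frame(pair_name = "p", variant = "AAAAAYAAAAC",
                         reference = "AAAAAYAAAAA",
                         mean_E_variant = Ev, sd_E_variant = 0.1,
                         mean_E_reference = Er, sd_E_reference = 0.1,
                         log2fc = log2(Ev / Er), p_value = p,
                         mean_reads_variant = reads,
                         mean_reads_reference = reads, tyr_change = tyr,
                         stringsAsFactors = FALSE),
              class = c("variant_effects", "data.frame"))
  }
  th <- filter_thresholds()

  # manual rule walk: passes all five filters
  hit <- apply_filters(mk_effect(0.01, 4, 1), th)
  expect_equal(hit$verdict, "hit")
  expect_equal(hit$reason_codes, "")

  expect_equal(apply_filters(mk_effect(0.01, 1.8, 1.2), th)$reason_codes,
               "small_fold_change")
  expect_equal(apply_filters(mk_effect(0.01, 1.2, 0.5), th)$reason_codes,
               "both_low_activity")
  expect_equal(apply_filters(mk_effect(0.2, 4, 1), th)$reason_codes,
               "not_significant")
  expect_equal(apply_filters(mk_effect(0.01, 4, 1, tyr = TRUE), th)$reason_codes,
               "tyr_change")
  expect_equal(apply_filters(mk_effect(0.01, 4, 1, reads = 20), th)$reason_codes,
               "low_reads")
  # multiple failures accumulate in evaluation order
  multi <- apply_filters(mk_effect(0.2, 1.4, 1.2, reads = 10), th)
  expect_equal(multi$reason_codes,
               "not_significant,small_fold_change,both_low_activity,low_reads")

  # symmetric fold change: a 4-fold *loss* also passes step 2
  expect_equal(apply_filters(mk_effect(0.01, 1, 4), th)$verdict, "hit")
})

test_that("tightening any threshold never increases the hit count", {
  eff <- simulate_null_variant_screen(n_pairs = 60, n_reps = 4,
                                      depth = 6e4, seed = 71)
  n_hits <- function(th) sum(apply_filters(eff, th)$verdict == "hit")
  base <- filter_thresholds()
  h0 <- n_hits(base)
  expect_lte(n_hits(filter_thresholds(min_fold = 3)), h0)
  expect_lte(n_hits(filter_thresholds(min_reads = 200)), h0)
  expect_lte(n_hits(filter_thresholds(alpha = 0.01)), h0)
  # pure function: same inputs give identical verdicts
  expect_identical(apply_filters(eff, base), apply_filters(eff, base))
})

test_that("variant effect tables wire replicates, counts and flags together", {
  eff <- simulate_null_variant_screen(n_pairs = 20, n_reps = 3,
                                      depth = 4e4, seed = 72)
  expect_equal(nrow(eff), 20L)
  expect_true(all(is.finite(eff$log2fc)))
  expect_true(all(eff$p_value > 0 & eff$p_value <= 1))
  expect_true(all(eff$mean_reads_variant > 0))
  # no true effects: log2fc should hover near zero on average
  expect_lt(abs(mean(eff$log2fc)), 0.2)
})
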