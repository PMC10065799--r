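test_that("position counts place each residue in its (row, column) cell", {
  m <- position_counts(records_from_peptides("AAAAAYAAAAA"), "nostop")
  expect_equal(dim(m), c(21L, 11L))
  expect_equal(rownames(m)[21], "*")
  expect_equal(unname(unclass(m)["A", ]), c(rep(1L, 5), 0L, rep(1L, 5)))
  expect_equal(unname(unclass(m)["Y", "0"]), 1L)
  expect_equal(sum(m), 11L)

  # one-Amber mode: the '*' lands at position -3 only
  rec <- translate_regions(paste0("GCTGCT", "TAG", "GCTGCT", "TAT",
                                  strrep("GCT", 5)))
  m1 <- position_counts(rec, "one_amber")
  expect_equal(unname(unclass(m1)["*", ]),
               c(0L, 0L, 1L, rep(0L, 8)))

  expect_error(position_counts(records_from_peptides("AA*AAYAAAAA"), "nostop"),
               "nostop")
})

test_that("matrix tally matches the naive double-loop oracle", {
  set.seed(51)
  peps <- random_peptides(10000)
  m <- position_counts(records_from_peptides(peps), "nostop")
  expect_equal(unclass(m), oracle_position_counts(peps), ignore_attr = TRUE)
  # every column accounts for every peptide; '*' row empty in nostop mode
  expect_true(all(colSums(m) == length(peps)))
  expect_true(all(unclass(m)["*", ] == 0L))
})

test_that("frequencies divide by column totals", {
  peps <- c(rep("AAAAAYAAAAA", 3), "CCCCCYCCCCC")
  f <- position_frequencies(position_counts(records_from_peptides(peps),
                                            "nostop"))
  expect_equal(unname(unclass(f)["A", "-5"]), 0.75)
  expect_equal(unname(unclass(f)["C", "-5"]), 0.25)
  expect_true(all(abs(colSums(f) - 1) < 1e-12))

  set.seed(52)
  m <- position_counts(records_from_peptides(random_peptides(500)), "nostop")
  f <- position_frequencies(m)
  expect_equal(unclass(f), sweep(unclass(m), 2, colSums(m), `/`),
               ignore_attr = TRUE)
})

test_that("log2 enrichment of identical samples is zero; ratios are exact", {
  set.seed(53)
  recs <- records_from_peptides(random_peptides(2000))
  f <- position_frequencies(position_counts(recs, "nostop"))
  e <- position_enrichment(f, f, pseudo_freq = 0)
  vals <- unclass(e)[!is.na(unclass(e))]
  expect_true(all(vals == 0))
  # forced arithmetic: f_sel 0.4 vs f_in 0.1 is +2
  fs <- unclass(f); fi <- unclass(f)
  fs["A", 1] <- 0.4; fi["A", 1] <- 0.1
  fs <- pepdisplay:::new_position_matrix(fs, "frequency", "nostop")
  fi <- pepdisplay:::new_position_matrix(fi, "frequency", "nostop")
  e <- position_enrichment(fs, fi, pseudo_freq = 0)
  expect_equal(unname(unclass(e)["A", 1]), 2)
  # mode/shape guards
  f_full <- position_frequencies(position_counts(recs, "full"))
  expect_error(position_enrichment(fs, f_full), "mode mismatch")
})

test_that("in-mode undefined cells are missing", {
  set.seed(54)
  recs <- records_from_peptides(random_peptides(300))
  f <- position_frequencies(position_counts(recs, "nostop"))
  e <- position_enrichment(f, f)
  expect_true(all(is.na(unclass(e)["*", ])))
  expect_true(all(is.na(unclass(e)[setdiff(rownames(e), "Y"), "0"])))
  expect_false(is.na(unclass(e)["Y", "0"]))
})

test_that("replicate averaging is cell-wise and ignores missing cells", {
  set.seed(55)
  mats <- replicate(3, random_log2_matrix(), simplify = FALSE)
  avg <- average_matrices(mats)
  expect_equal(unclass(avg),
               (unclass(mats[[1]]) + unclass(mats[[2]]) + unclass(mats[[3]])) / 3,
               ignore_attr = TRUE)
  expect_identical(unclass(average_matrices(mats[1])), unclass(mats[[1]]),
                   ignore_attr = TRUE)
  # +1 and -1 average to 0; NA in one replicate is ignored, not propagated
  m1 <- unclass(mats[[1]]); m2 <- unclass(mats[[2]])
  m1["A", 1] <- 1; m2["A", 1] <- -1
  m1["C", 2] <- NA; m2["C", 2] <- 4
  pm <- function(m) pepdisplay:::new_position_matrix(m, "log2_enrichment", "full")
  avg <- average_matrices(list(pm(m1), pm(m2)))
  expect_equal(unname(unclass(avg)["A", 1]), 0)
  expect_equal(unname(unclass(avg)["C", 2]), 4)
})

test_that("matrix CSV round-trips through write/read", {
  m <- random_log2_matrix()
  f <- tempfile(fileext = ".csv")
  write_position_matrix(m, f)
  expect_match(readLines(f, n = 1), "layer=log2_enrichment")
  m2 <- read_position_matrix(f)
  expect_equal(unclass(m2), unclass(m), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(m2, "mode"), attr(m, "mode"))
})
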