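test_that("NNS sampling respects the degenerate codon structure", {
  lib <- sample_nns_library(2000, seed = 81)
  expect_true(all(nchar(lib) == 33L))
  # central codon is always TAT
  expect_true(all(substr(lib, 16, 18) == "TAT"))
  # every degenerate codon's third base is G or C
  third_pos <- c(3, 6, 9, 12, 15, 21, 24, 27, 30, 33)
  for (p in third_pos)
    expect_true(all(substr(lib, p, p) %in% c("G", "C")))
})

test_that("NNS Amber statistics match the closed form", {
  n <- 50000
  lib <- sample_nns_library(n, seed = 82)
  has_tag <- vapply(seq(1, 31, by = 3), function(s) substr(lib, s, s + 2) == "TAG",
                    logical(n))
  frac <- mean(rowSums(has_tag) > 0)
  p <- 1 - (31 / 32)^10
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(frac - p), 3 * se)
})

test_that("identical seeds reproduce the simulation byte-for-byte", {
  tm <- random_truth_matrix(seed = 83)
  truth <- screen_truth(tm, depth_input = 2000, depth_selected = 2000,
                        seed = 83)
  s1 <- simulate_screen(truth, n_library = 1000)
  s2 <- simulate_screen(truth, n_library = 1000)
  expect_identical(s1$input, s2$input)
  expect_identical(s1$selected, s2$selected)
  # a different seed changes the draw
  s3 <- simulate_screen(screen_truth(tm, depth_input = 2000,
                                     depth_selected = 2000, seed = 84),
                        n_library = 1000)
  expect_false(identical(s1$selected$sequence, s3$selected$sequence))
})

test_that("simulated reads carry the flanks and trim back to the library", {
  fs <- flank_spec()
  tm <- random_truth_matrix(seed = 85)
  truth <- screen_truth(tm, depth_input = 500, depth_selected = 500, seed = 85)
  sim <- simulate_screen(truth, n_library = 300)
  tr <- trim_reads(sim$input, fs)
  expect_equal(tr$stats$discarded, 0L)
  expect_true(all(nchar(tr$regions$dna) == 33L))
})

test_that("complete premature termination removes stops from selected reads", {
  tm <- random_truth_matrix(seed = 86)
  truth <- screen_truth(tm, depth_input = 5000, depth_selected = 5000,
                        amber_termination_prob = 1, seed = 86)
  sim <- simulate_screen(truth, n_library = 5000)
  sel <- process_sample(sim$selected)
  expect_true(all(sel$records$n_stop == 0L))
  # ... while the input still contains them
  inp <- process_sample(sim$input)
  expect_gt(sum(inp$records$n_stop > 0L), 0L)
})

test_that("a strong single-cell preference is recovered in rank order", {
  tm <- random_truth_matrix(seed = 87)
  base <- unclass(tm) * 0
  base["I", "-1"] <- 2  # favour Ile at -1 and nothing else
  tm <- pepdisplay:::new_position_matrix(base, "log2_enrichment", "truth")
  truth <- screen_truth(tm, selection_strength = 2, depth_input = 4e4,
                        depth_selected = 4e4, amber_termination_prob = 0,
                        seed = 87)
  sim <- simulate_screen(truth, n_library = 4e4)
  sm <- screen_matrix(sim$input, sim$selected, mode = "nostop")
  col <- unclass(sm$log2_matrix)[AA20, "-1"]
  expect_gt(col["I"], 0)
  expect_equal(names(which.max(col)), "I")
})

test_that("oligo design preserves the peptide and removes forbidden sites", {
  des <- design_library_oligos("GGGGGYGGGGG")
  expect_equal(translate_regions(des$dna)$peptide, "GGGGGYGGGGG")
  expect_true(des$forbidden_site_free)

  # most-frequent-codon seed for GASGA contains GGCC AGCGG TGGCC? build a
  # peptide whose naive reverse translation creates an SfiI site: G-Q-S-G-Q
  # seeds GGC CAG AGC GGC CAG which contains GGCCAGAGCGGCC
  pep <- "GQSGQYAAAAA"
  naive <- "GGCCAGAGCGGCCAG"
  expect_true(grepl("GGCC.{5}GGCC", naive))
  des <- design_library_oligos(pep)
  expect_true(des$forbidden_site_free)
  expect_false(grepl("GGCC.{5}GGCC", des$dna))
  expect_equal(translate_regions(des$dna)$peptide, pep)

  # AT-rich peptide: swaps push GC toward the lower bound when possible
  des_f <- design_library_oligos("FFFFFYFFFFF")
  naive_gc <- mean(strsplit(strrep("TTT", 11), "")[[1]] %in% c("G", "C"))
  expect_gte(des_f$gc_fraction, naive_gc)
  expect_true(des_f$gc_fraction >= 0.30 || !des_f$feasible)

  # re-translation preserves every design in a random batch
  set.seed(88)
  peps <- random_peptides(30)
  des <- design_library_oligos(peps)
  expect_equal(translate_regions(des$dna)$peptide, peps)
  expect_true(all(des$gc_fraction[des$feasible] >= 0.30 &
                    des$gc_fraction[des$feasible] <= 0.70))
})
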