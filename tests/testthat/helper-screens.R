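# Defined-library screen fixture: n_pairs variant/reference pairs with
# identical generative parameters (no true effects) screened in n_reps
# replicates, returning the fitted variant_effects table. Each replicate is
# an independent multinomial resampling of input and selected pools.
simulate_null_variant_screen <- function(n_pairs = 100, n_reps = 4,
                                         depth = 2e5, seed = 1) {
  set.seed(seed)
  peptides <- unique(random_peptides(3 * n_pairs))
  stopifnot(length(peptides) >= 2 * n_pairs)
  pairs <- data.frame(pair_name = sprintf("pair_%04d", seq_len(n_pairs)),
                      variant = peptides[seq_len(n_pairs)],
                      reference = peptides[n_pairs + seq_len(n_pairs)],
                      stringsAsFactors = FALSE)
  universe <- c(pairs$variant, pairs$reference)
  lib <- design_library_oligos(universe)
  tm <- random_truth_matrix()
  reps <- lapply(seq_len(n_reps), function(r) {
    truth <- screen_truth(tm, selection_strength = 0,
                          depth_input = depth, depth_selected = depth,
                          amber_termination_prob = 0, seed = seed + r)
    sim <- simulate_selection(lib$dna, truth)
    screen_enrichment(sim$input, sim$selected, universe = universe)
  })
  variant_effects(pairs, reps)
}
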