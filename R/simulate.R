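# Synonymous codons per amino acid, ordered by decreasing E. coli K-12 usage.
# The first codon of each entry is the most frequently used one and seeds
# reverse translation; later entries are tried, in order, when synonymous
# swaps are needed to fix GC content or remove forbidden motifs.
ECOLI_CODONS <- list(
  A = c("GCG", "GCC", "GCA", "GCT"),
  C = c("TGC", "TGT"),
  D = c("GAT", "GAC"),
  E = c("GAA", "GAG"),
  F = c("TTT", "TTC"),
  G = c("GGC", "GGT", "GGG", "GGA"),
  H = c("CAT", "CAC"),
  I = c("ATT", "ATC", "ATA"),
  K = c("AAA", "AAG"),
  L = c("CTG", "TTA", "TTG", "CTT", "CTC", "CTA"),
  M = "ATG",
  N = c("AAC", "AAT"),
  P = c("CCG", "CCA", "CCT", "CCC"),
  Q = c("CAG", "CAA"),
  R = c("CGC", "CGT", "CGG", "CGA", "AGA", "AGG"),
  S = c("AGC", "TCG", "TCT", "TCC", "AGT", "TCA"),
  T = c("ACC", "ACG", "ACT", "ACA"),
  V = c("GTG", "GTT", "GTC", "GTA"),
  W = "TGG",
  Y = c("TAT", "TAC")
)

# SfiI recognition site; N = any base. Sites must be absent from designed
# inserts because SfiI digestion is used to clone the library.
SFII_MOTIF <- "GGCCNNNNNGGCC"

#' Sample coding regions from the degenerate NNS library
#'
#' Each region is five NNS codons, the fixed central tyrosine codon TAT,
#' then five more NNS codons (N uniform over A/C/G/T, S uniform over G/C).
#' NNS encodes all 20 amino acids; the only reachable stop is the Amber
#' codon TAG, sampled at each degenerate position with probability 1/32.
#'
#' @param n number of regions to sample
#' @param seed optional RNG seed for reproducibility
#' @return character vector of `n` 33-nt coding regions
#' @export
#' @examples
#' sample_nns_library(3, seed = 1)
sample_nns_library <- function(n, seed = NULL) {
  stopifnot(n > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  base_n <- c("A", "C", "G", "T")
  base_s <- c("G", "C")
  codon <- function() paste0(sample(base_n, n, replace = TRUE),
                             sample(base_n, n, replace = TRUE),
                             sample(base_s, n, replace = TRUE))
  left <- Reduce(paste0, replicate(5, codon(), simplify = FALSE))
  right <- Reduce(paste0, replicate(5, codon(), simplify = FALSE))
  paste0(left, "TAT", right)
}

#' Ground-truth parameters for a simulated screen
#'
#' @param truth_matrix 21 x 11 log2 preference `position_matrix` (see
#'   [random_truth_matrix()]); its `*` row is conventionally zero, since
#'   premature termination at stop codons is modeled separately through
#'   `amber_termination_prob`
#' @param selection_strength Boltzmann selection strength (0 = neutral)
#' @param depth_input number of input-sample reads
#' @param depth_selected number of selected-sample reads
#' @param amber_termination_prob probability that a stop-containing peptide
#'   is removed from the selectable pool (1 = complete premature
#'   termination, as in an unsuppressed library; intermediate values emulate
#'   partial Amber suppression). Default 0.8.
#' @param seed RNG seed; the full simulation is reproducible given the seed
#' @return list of class `screen_truth`
#' @export
screen_truth <- function(truth_matrix, selection_strength = 1,
                         depth_input = 1e5, depth_selected = 1e5,
                         amber_termination_prob = 0.8, seed = 1L) {
  stopifnot(inherits(truth_matrix, "position_matrix"),
            selection_strength >= 0, depth_input > 0, depth_selected > 0,
            amber_termination_prob >= 0, amber_termination_prob <= 1)
  structure(list(truth_matrix = truth_matrix,
                 selection_strength = selection_strength,
                 depth_input = as.integer(depth_input),
                 depth_selected = as.integer(depth_selected),
                 amber_termination_prob = amber_termination_prob,
                 seed = as.integer(seed)),
            class = "screen_truth")
}

#' Random ground-truth log2 preference matrix
#'
#' Entries for the 20 amino-acid rows at the 10 variable positions are drawn
#' uniformly from `range`; the central column is zero (only Y occurs there)
#' and the `*` row is zero (premature termination is modeled separately).
#'
#' @param range range of the uniform draw, default `c(-2, 2)`
#' @param seed optional RNG seed
#' @return a `position_matrix` with layer `"log2_enrichment"`, mode `"truth"`
#' @export
random_truth_matrix <- function(range = c(-2, 2), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  width <- 11L
  m <- matrix(0, nrow = length(ROW_ORDER), ncol = width,
              dimnames = list(ROW_ORDER, position_labels(width)))
  centre <- central_index(width)
  variable <- setdiff(seq_len(width), centre)
  m[AA_ORDER, variable] <- runif(length(AA_ORDER) * length(variable),
                                 range[1L], range[2L])
  new_position_matrix(m, layer = "log2_enrichment", mode = "truth")
}

# Raw truth-matrix score of peptides that may contain '*': mean of the truth
# value of each residue over the variable positions (the '*' row scores stop
# residues; the central position is ignored).
truth_scores <- function(peptides, truth_matrix) {
  width <- ncol(truth_matrix)
  centre <- central_index(width)
  res <- residue_matrix(peptides, width)
  variable <- setdiff(seq_len(width), centre)
  vals <- vapply(variable, function(j) unclass(truth_matrix)[res[, j], j],
                 numeric(length(peptides)))
  if (length(peptides) == 1L) vals <- matrix(vals, nrow = 1L)
  rowSums(vals) / length(variable)
}

#' Simulate one round of selection over a peptide-coding library
#'
#' Input reads are drawn multinomially from the library (probabilities
#' `library_probs`, uniform by default). Selected reads are drawn with
#' probability proportional to
#' `library_probs * exp(selection_strength * score) * survival`, where
#' `score` is the peptide's mean truth-matrix value over variable positions
#' and `survival` is `1 - amber_termination_prob` for stop-containing
#' peptides (premature termination truncates the displayed peptide before
#' the scaffold, removing it from the selectable pool) and 1 otherwise.
#' Each emitted read is `5' flank + coding DNA + 3' flank`.
#'
#' @param library_dna character vector of 33-nt coding regions (the library
#'   pool; duplicates allowed)
#' @param truth a [screen_truth()]; its `seed` makes the draw reproducible
#' @param library_probs optional sampling weights over `library_dna`
#' @param flanks a [flank_spec()] supplying the attached flanks
#' @param .reseed internal: set to `FALSE` to continue the caller's RNG
#'   stream instead of re-seeding from `truth$seed`
#' @return list with `input` and `selected` read data frames (`read_id`,
#'   `sequence`, `quality` = `"I"`-filled), and `truth`
#' @export
simulate_selection <- function(library_dna, truth, library_probs = NULL,
                               flanks = flank_spec(), .reseed = TRUE) {
  stopifnot(inherits(truth, "screen_truth"), length(library_dna) > 0)
  if (.reseed) set.seed(truth$seed)
  peps <- translate_regions(library_dna)
  if (any(peps$status != "ok"))
    stop("library contains invalid coding regions (first: ",
         peps$dna[peps$status != "ok"][1L], ")")
  if (is.null(library_probs)) library_probs <- rep(1, length(library_dna))
  stopifnot(length(library_probs) == length(library_dna),
            all(library_probs >= 0))
  score <- truth_scores(peps$peptide, truth$truth_matrix)
  survival <- ifelse(peps$n_stop > 0L, 1 - truth$amber_termination_prob, 1)
  w_sel <- library_probs * exp(truth$selection_strength * score) * survival
  if (sum(w_sel) == 0) stop("selectable pool is empty")

  draw <- function(depth, probs, prefix) {
    counts <- as.integer(rmultinom(1L, depth, probs))
    idx <- rep.int(seq_along(library_dna), counts)
    seqs <- paste0(flanks$five_prime, library_dna[idx], flanks$three_prime)
    data.frame(read_id = sprintf("%s_%07d", prefix, seq_along(idx)),
               sequence = seqs,
               quality = strrep("I", nchar(seqs)),
               stringsAsFactors = FALSE)
  }
  input <- draw(truth$depth_input, library_probs / sum(library_probs), "input")
  selected <- draw(truth$depth_selected, w_sel / sum(w_sel), "selected")
  list(input = input, selected = selected, truth = truth)
}

#' Simulate a complete degenerate-library screen
#'
#' Samples an NNS library pool and runs [simulate_selection()] on it. The
#' pool size defaults to the input depth, emulating a library whose
#' diversity is on par with the sequencing depth, as is the case for a
#' million-member degenerate library.
#'
#' @param truth a [screen_truth()]
#' @param n_library library pool size (default `truth$depth_input`)
#' @param flanks a [flank_spec()]
#' @return as [simulate_selection()]
#' @export
simulate_screen <- function(truth, n_library = NULL, flanks = flank_spec()) {
  stopifnot(inherits(truth, "screen_truth"))
  if (is.null(n_library)) n_library <- truth$depth_input
  set.seed(truth$seed)
  pool <- sample_nns_library(n_library)
  simulate_selection(pool, truth, flanks = flanks, .reseed = FALSE)
}

#' Design library oligos encoding a defined peptide list
#'
#' Reverse-translates each peptide using the most frequently used codon in
#' E. coli, then greedily swaps synonymous codons (positions left to right,
#' codons in decreasing usage order) until the GC fraction lies within
#' `gc_bounds` and no forbidden motif remains, or no swap improves further.
#' The encoded peptide is preserved by construction. Infeasible peptides are
#' reported with diagnostics rather than dropped.
#'
#' @param peptides character vector of peptides over the 20-residue alphabet
#' @param gc_bounds GC-fraction bounds, default `c(0.30, 0.70)`
#' @param forbidden_motifs degenerate DNA motifs (N = any base) that must be
#'   absent; default the SfiI site `GGCCNNNNNGGCC`
#' @return data frame `peptide`, `dna`, `gc_fraction`, `forbidden_site_free`,
#'   `feasible`
#' @export
#' @examples
#' design_library_oligos("GGGGGYGGGGG")
design_library_oligos <- function(peptides, gc_bounds = c(0.30, 0.70),
                                  forbidden_motifs = SFII_MOTIF) {
  peptides <- toupper(peptides)
  bad <- !grepl(paste0("^[", paste(AA_ORDER, collapse = ""), "]+$"), peptides)
  if (any(bad))
    stop("peptide ", which(bad)[1L], " contains non-amino-acid symbols")
  motif_re <- paste0("(?=", gsub("N", ".", forbidden_motifs), ")")

  gc_frac <- function(dna) {
    b <- strsplit(dna, "")[[1L]]
    mean(b %in% c("G", "C"))
  }
  n_motif_hits <- function(dna) {
    sum(vapply(motif_re, function(re) {
      m <- gregexpr(re, dna, perl = TRUE)[[1L]]
      sum(m > 0L)
    }, numeric(1)))
  }
  # penalty: forbidden motifs dominate, then distance of GC outside bounds
  objective <- function(dna) {
    g <- gc_frac(dna)
    gc_pen <- max(0, gc_bounds[1L] - g, g - gc_bounds[2L])
    n_motif_hits(dna) + gc_pen
  }

  design_one <- function(pep) {
    res <- strsplit(pep, "")[[1L]]
    codons <- vapply(res, function(a) ECOLI_CODONS[[a]][1L], character(1))
    repeat {
      dna <- paste0(codons, collapse = "")
      obj <- objective(dna)
      if (obj == 0) break
      improved <- FALSE
      for (i in seq_along(codons)) {
        for (alt in ECOLI_CODONS[[res[i]]]) {
          if (alt == codons[i]) next
          cand <- codons
          cand[i] <- alt
          if (objective(paste0(cand, collapse = "")) < obj) {
            codons <- cand
            improved <- TRUE
            break
          }
        }
        if (improved) break
      }
      if (!improved) break
    }
    dna <- paste0(codons, collapse = "")
    g <- gc_frac(dna)
    data.frame(peptide = pep, dna = dna, gc_fraction = g,
               forbidden_site_free = n_motif_hits(dna) == 0L,
               feasible = objective(dna) == 0,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(peptides, design_one))
  rownames(out) <- NULL
  out
}
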