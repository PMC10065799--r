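#' Trim and translate one sample
#'
#' Runs flank trimming and translation on a set of merged reads, returning
#' the translated records plus the per-stage bookkeeping.
#'
#' @param reads data frame from [read_merged_reads()] (or a character vector
#'   of sequences)
#' @param flanks a [flank_spec()]
#' @param expected_length expected peptide length (default 11)
#' @return list with `trim` (a `trim_result`) and `records` (translated data
#'   frame from [translate_regions()])
#' @export
process_sample <- function(reads, flanks = flank_spec(),
                           expected_length = 11L) {
  tr <- trim_reads(reads, flanks)
  list(trim = tr,
       records = translate_regions(tr$regions, expected_length))
}

#' Recover a specificity matrix from selected/input read sets
#'
#' Full deconvolution for one replicate of a degenerate-library screen:
#' trim, translate, position-count both samples in the requested mode, and
#' return the log2-enrichment matrix of selected over input.
#'
#' @param input_reads merged reads of the unselected input sample
#' @param selected_reads merged reads of the selected sample
#' @param mode matrix mode, see [position_counts()]
#' @param flanks a [flank_spec()]
#' @param pseudo_freq see [position_enrichment()]
#' @param expected_length expected peptide length
#' @return list with `log2_matrix`, `input` and `selected` processed samples
#' @export
screen_matrix <- function(input_reads, selected_reads,
                          mode = c("nostop", "full", "one_amber"),
                          flanks = flank_spec(), pseudo_freq = 1e-4,
                          expected_length = 11L) {
  mode <- match.arg(mode)
  inp <- process_sample(input_reads, flanks, expected_length)
  sel <- process_sample(selected_reads, flanks, expected_length)
  fi <- position_frequencies(position_counts(inp$records, mode))
  fs <- position_frequencies(position_counts(sel$records, mode))
  list(log2_matrix = position_enrichment(fs, fi, pseudo_freq),
       input = inp, selected = sel)
}

#' Per-peptide enrichment for one replicate of a defined-library screen
#'
#' Trims, translates and counts both samples, then computes the enrichment
#' table over a fixed peptide universe (typically the defined library or the
#' union of pair peptides).
#'
#' @param input_reads merged reads of the input sample
#' @param selected_reads merged reads of the selected sample
#' @param universe optional peptide universe, see [enrichment_scores()]
#' @param flanks a [flank_spec()]
#' @param pseudocount see [enrichment_scores()]
#' @param expected_length expected peptide length
#' @return an `enrichment_table`
#' @export
screen_enrichment <- function(input_reads, selected_reads, universe = NULL,
                              flanks = flank_spec(), pseudocount = 0.5,
                              expected_length = 11L) {
  inp <- process_sample(input_reads, flanks, expected_length)
  sel <- process_sample(selected_reads, flanks, expected_length)
  enrichment_scores(count_peptides(sel$records),
                    count_peptides(inp$records),
                    pseudocount = pseudocount, universe = universe)
}
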