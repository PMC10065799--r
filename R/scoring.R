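#' Score peptides against a log2-enrichment matrix
#'
#' For each peptide, sums the log2-enrichment value of its residue at every
#' variable position (ignoring the fixed central tyrosine) and divides by
#' the number of scored positions (10 for the X5-Y-X5 geometry). Peptides
#' must match the matrix width, carry a central Y, and contain no stop
#' symbol; non-central tyrosines are allowed and scored from the Y row, as
#' natural phosphosite sequences frequently contain additional tyrosines.
#'
#' @param peptides character vector of peptides
#' @param matrix a `position_matrix` with layer `"log2_enrichment"`
#' @return numeric vector of raw scores (mean log2 enrichment per scored
#'   position)
#' @export
#' @examples
#' m <- matrix(0, 21, 11, dimnames = list(pepdisplay:::ROW_ORDER,
#'                                        position_labels(11)))
#' m["A", ] <- 1
#' m <- pepdisplay:::new_position_matrix(m, "log2_enrichment", "nostop")
#' score_peptides("AAAAAYAAAAA", m)  # 1.0
score_peptides <- function(peptides, matrix) {
  check_log2_matrix(matrix)
  width <- ncol(matrix)
  centre <- central_index(width)
  if (any(nchar(peptides) != width))
    stop("peptide length must be ", width, " to match the matrix")
  res <- residue_matrix(toupper(peptides), width)
  if (any(res == "*"))
    stop("peptides containing a stop symbol cannot be scored")
  if (any(res[, centre] != "Y"))
    stop("central residue must be Y (peptide ",
         which(res[, centre] != "Y")[1L], ")")
  bad <- !res %in% AA_ORDER
  if (any(bad))
    stop("unknown residue '", res[bad][1L], "' in peptide list")
  variable <- setdiff(seq_len(width), centre)
  vals <- vapply(variable, function(j) unclass(matrix)[res[, j], j],
                 numeric(length(peptides)))
  if (length(peptides) == 1L) vals <- base::matrix(vals, nrow = 1L)
  if (anyNA(vals)) {
    miss <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("matrix cell (", res[miss[1L], variable[miss[2L]]], ", ",
         colnames(matrix)[variable[miss[2L]]], ") is missing")
  }
  unname(rowSums(vals)) / length(variable)
}

#' Best- and worst-achievable raw scores of a matrix
#'
#' The best (worst) raw score is the mean over variable positions of the
#' column maxima (minima), excluding the stop row — the score of the
#' sequence assembled from the most (least) enriched residue at every
#' position.
#'
#' @param matrix a `position_matrix` with layer `"log2_enrichment"`
#' @return list with `best_raw` and `worst_raw`
#' @export
score_extremes <- function(matrix) {
  check_log2_matrix(matrix)
  width <- ncol(matrix)
  centre <- central_index(width)
  variable <- setdiff(seq_len(width), centre)
  m <- unclass(matrix)[AA_ORDER, variable, drop = FALSE]
  if (any(colSums(!is.na(m)) == 0L))
    stop("variable column(s) entirely missing: ",
         paste(colnames(m)[colSums(!is.na(m)) == 0L], collapse = ", "))
  # summed left-to-right then divided, matching score_peptides() bit-for-bit
  # so the best/worst sequences normalize to exactly 1 and 0
  list(best_raw = sum(apply(m, 2L, max, na.rm = TRUE)) / ncol(m),
       worst_raw = sum(apply(m, 2L, min, na.rm = TRUE)) / ncol(m))
}

#' Min-max normalize raw scores to the 0-1 scale
#'
#' Maps raw scores linearly so the worst achievable sequence scores 0 and
#' the best achievable sequence scores 1.
#'
#' @param raw numeric raw scores
#' @param extremes list from [score_extremes()]
#' @return normalized scores
#' @export
normalize_scores <- function(raw, extremes) {
  if (extremes$best_raw <= extremes$worst_raw)
    stop("degenerate matrix: best and worst scores coincide")
  (raw - extremes$worst_raw) / (extremes$best_raw - extremes$worst_raw)
}

#' Score a peptide list, reporting raw and normalized scores
#'
#' @param peptides character vector of peptides
#' @param matrix a log2-enrichment `position_matrix`
#' @return data frame `peptide`, `raw_score`, `normalized_score`
#' @export
score_table <- function(peptides, matrix) {
  raw <- score_peptides(peptides, matrix)
  ext <- score_extremes(matrix)
  data.frame(peptide = peptides, raw_score = raw,
             normalized_score = normalize_scores(raw, ext),
             stringsAsFactors = FALSE)
}

#' Consensus sequence implied by a specificity matrix
#'
#' Assembles the peptide taking, at each variable position, the residue with
#' the highest (or lowest, with `best = FALSE`) log2 enrichment, excluding
#' the stop row, with the fixed central tyrosine. With `exclude_tyr = TRUE`
#' tyrosine is also excluded at variable positions, as is done when designing
#' consensus substrates (variable-position tyrosines would confound a
#' phosphotyrosine readout).
#'
#' @param matrix a log2-enrichment `position_matrix`
#' @param best take the argmax residue (default); `FALSE` for the argmin
#' @param exclude_tyr exclude Y at variable positions (default FALSE)
#' @return a single peptide string
#' @export
consensus_sequence <- function(matrix, best = TRUE, exclude_tyr = FALSE) {
  check_log2_matrix(matrix)
  width <- ncol(matrix)
  centre <- central_index(width)
  rows <- if (exclude_tyr) setdiff(AA_ORDER, "Y") else AA_ORDER
  m <- unclass(matrix)[rows, , drop = FALSE]
  pick <- vapply(seq_len(width), function(j) {
    if (j == centre) return("Y")
    col <- m[, j]
    if (all(is.na(col))) stop("column ", colnames(matrix)[j], " is all missing")
    rows[if (best) which.max(col) else which.min(col)]
  }, character(1))
  paste0(pick, collapse = "")
}

#' Predicted effect of a variant relative to its reference
#'
#' Signed difference of normalized scores (variant minus reference); positive
#' values predict gain-of-function.
#'
#' @param variant variant peptide
#' @param reference reference peptide
#' @param matrix a log2-enrichment `position_matrix`
#' @return one-row data frame `variant`, `reference`, `delta_normalized`,
#'   `identical_pair`
#' @export
predict_variant_effect <- function(variant, reference, matrix) {
  ext <- score_extremes(matrix)
  sv <- normalize_scores(score_peptides(variant, matrix), ext)
  sr <- normalize_scores(score_peptides(reference, matrix), ext)
  same <- identical(toupper(variant), toupper(reference))
  if (same) warning("variant and reference peptides are identical")
  data.frame(variant = variant, reference = reference,
             delta_normalized = sv - sr, identical_pair = same,
             stringsAsFactors = FALSE)
}

check_log2_matrix <- function(matrix) {
  if (!inherits(matrix, "position_matrix"))
    stop("expected a position_matrix")
  if (attr(matrix, "layer") != "log2_enrichment")
    stop("expected a log2_enrichment matrix, got layer '",
         attr(matrix, "layer"), "'")
  invisible(matrix)
}
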