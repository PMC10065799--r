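#' Per-peptide frequencies in a sample
#'
#' The frequency of a peptide is its read count divided by the total number
#' of peptide-coding reads in the sample: f = n_peptide / n_total.
#'
#' @param counts a `peptide_counts` object with `n_total > 0`
#' @return named numeric vector of frequencies summing to 1
#' @export
peptide_frequency <- function(counts) {
  stopifnot(inherits(counts, "peptide_counts"))
  if (counts$n_total == 0L)
    stop("cannot compute frequencies: sample has no counted reads")
  counts$counts / counts$n_total
}

#' Selected-versus-input enrichment scores
#'
#' For each peptide, the enrichment score is the frequency in the selected
#' sample divided by the frequency in the input sample:
#' E = f_selected / f_input. The raw score is reported exactly as this ratio,
#' with no pseudocount; peptides absent from the input (or selected) sample
#' are flagged and their raw E is NA when that would divide by zero. The
#' `log2_enrichment` column is computed after adding `pseudocount` to both
#' raw counts and recomputing frequencies, so it stays finite at zero counts.
#'
#' @param selected `peptide_counts` for the selected (kinase-phosphorylated
#'   or SH2-bound) sample
#' @param input `peptide_counts` for the unselected input sample
#' @param pseudocount non-negative count added to both raw counts for the
#'   log2 column only (default 0.5)
#' @param universe optional character vector restricting the peptide universe
#'   (e.g. a defined library); default is the union of peptides in the two
#'   samples. Totals (`n_total`) are computed over this universe.
#' @return data frame of class `enrichment_table` with columns `peptide`,
#'   `n_input`, `n_selected`, `f_input`, `f_selected`, `enrichment`,
#'   `log2_enrichment`, `zero_input`, `zero_selected`; the pseudocount used
#'   is attached as attribute `pseudocount`
#' @export
#' @examples
#' inp <- count_peptides(rep(c("AAAAAYAAAAA", "CCCCCYCCCCC"), c(10, 90)))
#' sel <- count_peptides(rep(c("AAAAAYAAAAA", "CCCCCYCCCCC"), c(30, 70)))
#' enrichment_scores(sel, inp, pseudocount = 0)$enrichment  # 3.0, 0.778
enrichment_scores <- function(selected, input, pseudocount = 0.5,
                              universe = NULL) {
  stopifnot(inherits(selected, "peptide_counts"),
            inherits(input, "peptide_counts"))
  if (length(selected$counts) == 0L && length(input$counts) == 0L)
    stop("both samples are empty")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (is.null(universe))
    universe <- sort(union(names(selected$counts), names(input$counts)))
  get0i <- function(counts, u) {
    x <- counts[u]
    x[is.na(x)] <- 0L
    unname(x)
  }
  n_in <- get0i(input$counts, universe)
  n_sel <- get0i(selected$counts, universe)
  tot_in <- sum(n_in)
  tot_sel <- sum(n_sel)
  if (tot_in == 0L || tot_sel == 0L)
    stop("a sample has no reads within the peptide universe")
  f_in <- n_in / tot_in
  f_sel <- n_sel / tot_sel
  E <- ifelse(f_in > 0, f_sel / f_in, NA_real_)
  k <- length(universe)
  f_in_ps <- (n_in + pseudocount) / (tot_in + k * pseudocount)
  f_sel_ps <- (n_sel + pseudocount) / (tot_sel + k * pseudocount)
  log2E <- log2(f_sel_ps / f_in_ps)
  out <- data.frame(peptide = universe, n_input = n_in, n_selected = n_sel,
                    f_input = f_in, f_selected = f_sel, enrichment = E,
                    log2_enrichment = log2E,
                    zero_input = n_in == 0L, zero_selected = n_sel == 0L,
                    stringsAsFactors = FALSE)
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Aggregate enrichment tables across replicate screens
#'
#' Computes the per-peptide mean and sample standard deviation of the
#' enrichment score across replicates (screens are typically run in three to
#' five replicates and their scores averaged). A peptide missing from a
#' replicate's universe is treated as missing in that replicate, not as zero.
#'
#' @param tables list of `enrichment_table` objects (>= 1)
#' @param value_col which column to aggregate: `"enrichment"` (raw E,
#'   default) or `"log2_enrichment"` (pseudocounted log scale)
#' @return data frame with one row per peptide in the union universe:
#'   `peptide`, `n_replicates`, `mean_enrichment`, `sd_enrichment` (NA when a
#'   single replicate), `mean_n_input`, `mean_n_selected`, plus one
#'   `enrichment_r<i>` column per replicate
#' @export
aggregate_replicates <- function(tables,
                                 value_col = c("enrichment", "log2_enrichment")) {
  value_col <- match.arg(value_col)
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "enrichment_table")))
  universe <- sort(Reduce(union, lapply(tables, `[[`, "peptide")))
  k <- length(tables)
  pull <- function(tab, col) {
    x <- setNames(tab[[col]], tab$peptide)[universe]
    unname(x)
  }
  Em <- vapply(tables, pull, numeric(length(universe)), col = value_col)
  if (length(universe) == 1L) Em <- matrix(Em, nrow = 1L)
  n_in <- vapply(tables, pull, numeric(length(universe)), col = "n_input")
  n_sel <- vapply(tables, pull, numeric(length(universe)), col = "n_selected")
  if (length(universe) == 1L) {
    n_in <- matrix(n_in, nrow = 1L)
    n_sel <- matrix(n_sel, nrow = 1L)
  }
  out <- data.frame(
    peptide = universe,
    n_replicates = rowSums(!is.na(Em)),
    mean_enrichment = rowMeans(Em, na.rm = TRUE),
    sd_enrichment = apply(Em, 1L, function(x) {
      x <- x[!is.na(x)]
      if (length(x) >= 2L) sd(x) else NA_real_
    }),
    mean_n_input = rowMeans(n_in, na.rm = TRUE),
    mean_n_selected = rowMeans(n_sel, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  reps <- as.data.frame(Em)
  names(reps) <- paste0("enrichment_r", seq_len(k))
  cbind(out, reps)
}
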