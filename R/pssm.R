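#' Position-specific residue counts
#'
#' Tallies, for each of the 11 peptide positions (-5..+5), how many
#' qualifying peptides carry each residue there, producing a 21 x 11 counts
#' matrix: rows are the 20 amino acids in alphabetical one-letter order with
#' the stop symbol `*` as row 21; columns run -5..+5 left to right. Three
#' selection modes mirror the three counting analyses:
#' \describe{
#'   \item{nostop}{central tyrosine, no stop codons (standard specificity
#'     profile; the `*` row stays zero)}
#'   \item{full}{all valid 11-residue sequences (used to measure per-position
#'     stop-codon depletion)}
#'   \item{one_amber}{central tyrosine and exactly one TAG codon (Amber
#'     suppression: the `*` position carries the non-canonical amino acid)}
#' }
#'
#' @param records data frame from [translate_regions()]
#' @param mode `"nostop"`, `"full"`, or `"one_amber"`
#' @param sample_id optional label carried on the matrix
#' @return a `position_matrix` (integer matrix, layer `"counts"`)
#' @export
position_counts <- function(records, mode = c("nostop", "full", "one_amber"),
                            sample_id = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(records), "peptide" %in% names(records))
  keep <- switch(mode, nostop = records$nostop_ok, full = records$full_ok,
                 one_amber = records$one_amber_ok)
  peps <- records$peptide[keep]
  if (length(peps) == 0L)
    stop("no peptides qualify for mode '", mode, "'")
  width <- nchar(peps[1L])
  res <- residue_matrix(peps, width)
  m <- vapply(seq_len(width), function(j) {
    tab <- table(factor(res[, j], levels = ROW_ORDER))
    as.integer(tab)
  }, integer(length(ROW_ORDER)))
  dimnames(m) <- list(ROW_ORDER, position_labels(width))
  new_position_matrix(m, layer = "counts", mode = mode, sample_id = sample_id)
}

new_position_matrix <- function(m, layer, mode, sample_id = NULL) {
  structure(m, layer = layer, mode = mode, sample_id = sample_id,
            class = c("position_matrix", class(m)))
}

#' @export
print.position_matrix <- function(x, ...) {
  cat(sprintf("position_matrix [%s, mode=%s%s] %d x %d\n",
              attr(x, "layer"), attr(x, "mode"),
              if (!is.null(attr(x, "sample_id")))
                paste0(", sample=", attr(x, "sample_id")) else "",
              nrow(x), ncol(x)))
  print(unclass(x)[, , drop = FALSE], digits = 3)
  invisible(x)
}

#' Position-specific residue frequencies
#'
#' Divides each cell of a counts matrix by its column total, so every column
#' of the result sums to 1 over the counted residues.
#'
#' @param m a `position_matrix` with layer `"counts"`
#' @return a `position_matrix` with layer `"frequency"`
#' @export
position_frequencies <- function(m) {
  stopifnot(inherits(m, "position_matrix"), attr(m, "layer") == "counts")
  totals <- colSums(m)
  if (any(totals == 0))
    stop("column(s) with zero total counts: ",
         paste(colnames(m)[totals == 0], collapse = ", "))
  f <- sweep(unclass(m), 2L, totals, `/`)
  new_position_matrix(f, layer = "frequency", mode = attr(m, "mode"),
                      sample_id = attr(m, "sample_id"))
}

#' Position-specific log2 enrichment matrix
#'
#' Normalizes selected-sample residue frequencies against input-sample
#' frequencies and log2-transforms the ratio:
#' `log2((f_selected + pseudo_freq) / (f_input + pseudo_freq))`. Cells that
#' are undefined in the active mode (the `*` row in nostop mode; non-Y rows
#' of the central column whenever the mode fixes the central tyrosine) are
#' set to NA.
#'
#' @param selected frequency `position_matrix` from the selected sample
#' @param input frequency `position_matrix` from the input sample, same mode
#' @param pseudo_freq non-negative frequency added to numerator and
#'   denominator (default 1e-4) so unobserved residue/position cells stay
#'   finite at realistic sequencing depth
#' @return a `position_matrix` with layer `"log2_enrichment"`
#' @export
position_enrichment <- function(selected, input, pseudo_freq = 1e-4) {
  stopifnot(inherits(selected, "position_matrix"),
            inherits(input, "position_matrix"))
  if (attr(selected, "layer") != "frequency" ||
      attr(input, "layer") != "frequency")
    stop("both matrices must be frequency matrices")
  if (attr(selected, "mode") != attr(input, "mode"))
    stop("mode mismatch: ", attr(selected, "mode"), " vs ", attr(input, "mode"))
  if (!identical(dim(selected), dim(input)))
    stop("matrix shape mismatch")
  if (pseudo_freq < 0) stop("pseudo_freq must be >= 0")
  mode <- attr(selected, "mode")
  e <- log2((unclass(selected) + pseudo_freq) / (unclass(input) + pseudo_freq))
  centre <- central_index(ncol(e))
  if (mode %in% c("nostop", "one_amber")) {
    e[setdiff(ROW_ORDER, "Y"), centre] <- NA_real_
  }
  if (mode == "nostop") e["*", ] <- NA_real_
  if (mode == "one_amber") e["*", centre] <- NA_real_
  new_position_matrix(e, layer = "log2_enrichment", mode = mode,
                      sample_id = attr(selected, "sample_id"))
}

#' Cell-wise average of replicate log2-enrichment matrices
#'
#' Published specificity heatmaps are the average of replicate screens; this
#' averages on the log2 layer, ignoring missing cells.
#'
#' @param matrices list of `position_matrix` objects with identical mode and
#'   shape (>= 1)
#' @return a `position_matrix` of the same layer/mode
#' @export
average_matrices <- function(matrices) {
  stopifnot(length(matrices) >= 1L,
            all(vapply(matrices, inherits, logical(1), "position_matrix")))
  modes <- vapply(matrices, attr, character(1), "mode")
  if (length(unique(modes)) != 1L) stop("matrices have differing modes")
  dims <- vapply(matrices, dim, integer(2))
  if (any(dims != dims[, 1L])) stop("matrices have differing shapes")
  arr <- simplify2array(lapply(matrices, unclass))
  avg <- apply(arr, c(1L, 2L), function(x)
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
  dimnames(avg) <- dimnames(matrices[[1L]])
  new_position_matrix(avg, layer = attr(matrices[[1L]], "layer"),
                      mode = modes[1L])
}

#' Build replicate-averaged specificity matrices from translated samples
#'
#' Convenience wrapper chaining [position_counts()], [position_frequencies()]
#' and [position_enrichment()] for each selected/input replicate pair, then
#' averaging the per-replicate log2 matrices with [average_matrices()].
#'
#' @param selected_records list of translated data frames (selected sample,
#'   one per replicate)
#' @param input_records list of translated data frames (input sample),
#'   parallel to `selected_records`
#' @param mode matrix mode, see [position_counts()]
#' @param pseudo_freq see [position_enrichment()]
#' @return list with `replicates` (per-replicate log2 matrices) and
#'   `average` (their cell-wise mean)
#' @export
specificity_matrix <- function(selected_records, input_records,
                               mode = c("nostop", "full", "one_amber"),
                               pseudo_freq = 1e-4) {
  mode <- match.arg(mode)
  if (is.data.frame(selected_records)) selected_records <- list(selected_records)
  if (is.data.frame(input_records)) input_records <- list(input_records)
  stopifnot(length(selected_records) == length(input_records))
  reps <- mapply(function(sel, inp) {
    fs <- position_frequencies(position_counts(sel, mode))
    fi <- position_frequencies(position_counts(inp, mode))
    position_enrichment(fs, fi, pseudo_freq)
  }, selected_records, input_records, SIMPLIFY = FALSE)
  list(replicates = reps, average = average_matrices(reps))
}

#' Write a position matrix as labeled CSV
#'
#' The layer and mode are recorded in a `#`-prefixed header comment line,
#' followed by a 21-row by 11-column labeled table.
#'
#' @param m a `position_matrix`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_position_matrix <- function(m, path) {
  stopifnot(inherits(m, "position_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# layer=%s mode=%s", attr(m, "layer"), attr(m, "mode")),
             con)
  df <- data.frame(residue = rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a position matrix written by [write_position_matrix()]
#'
#' @param path CSV path
#' @return a `position_matrix`
#' @export
read_position_matrix <- function(path) {
  header <- readLines(path, n = 1L)
  layer <- sub(".*layer=(\\S+).*", "\\1", header)
  mode <- sub(".*mode=(\\S+).*", "\\1", header)
  df <- read.table(path, sep = ",", header = TRUE, skip = 1L,
                   check.names = FALSE, stringsAsFactors = FALSE,
                   comment.char = "")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  new_position_matrix(m, layer = layer, mode = mode)
}
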