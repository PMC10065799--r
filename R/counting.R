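#' Count peptide abundances in one sample
#'
#' Exact multiset count over translated records: every read contributes one
#' count to its peptide (the display protocol has no UMIs). When a mode
#' filter is given, only records passing that classification contribute to
#' both the counts and the total, so downstream frequencies are normalized to
#' the number of peptide-coding reads that pass the active filter.
#'
#' @param records data frame from [translate_regions()], or a character
#'   vector of peptides (taken as-is, no filtering possible unless `none`)
#' @param mode_filter `"none"` (all `ok` records), `"nostop"`, `"full"`, or
#'   `"one_amber"` — see [classify_peptides()]
#' @param sample_id optional sample label carried on the result
#' @return an object of class `peptide_counts`: list with `sample_id`,
#'   `counts` (named integer vector, names are peptides), `n_total`
#' @export
#' @examples
#' pc <- count_peptides(c("AAAAAYAAAAA", "AAAAAYAAAAA", "CCCCCYCCCCC"))
#' pc$counts
count_peptides <- function(records,
                           mode_filter = c("none", "nostop", "full", "one_amber"),
                           sample_id = NULL) {
  mode_filter <- match.arg(mode_filter)
  if (is.character(records)) {
    if (mode_filter != "none")
      stop("mode filtering requires translated records, not bare peptides")
    peps <- records
  } else {
    stopifnot(is.data.frame(records), "peptide" %in% names(records))
    keep <- switch(mode_filter,
                   none = records$status == "ok",
                   nostop = records$nostop_ok,
                   full = records$full_ok,
                   one_amber = records$one_amber_ok)
    peps <- records$peptide[keep]
  }
  counts <- table(peps)
  counts <- setNames(as.integer(counts), names(counts))
  structure(list(sample_id = sample_id, counts = counts,
                 n_total = sum(counts)),
            class = "peptide_counts")
}

#' @export
print.peptide_counts <- function(x, ...) {
  cat(sprintf("peptide_counts%s: %d unique peptides, %d reads\n",
              if (!is.null(x$sample_id)) paste0(" [", x$sample_id, "]") else "",
              length(x$counts), x$n_total))
  invisible(x)
}

#' @export
as.data.frame.peptide_counts <- function(x, ...) {
  data.frame(peptide = names(x$counts), count = unname(x$counts),
             stringsAsFactors = FALSE)
}

#' Load a line-aligned variant/reference peptide pair list
#'
#' The two files list variant and reference peptides line by line, in
#' register; line `i` of each file forms pair `i`. Files of unequal length,
#' blank lines, or comment lines are configuration errors (silently skipping
#' them could desynchronize the pairing).
#'
#' @param variant_file path to the variant peptide list (one 11-mer per line)
#' @param reference_file path to the line-aligned reference peptide list
#' @param pair_names optional pair labels; default `pair_0001`, ...
#' @param peptide_length required peptide length (default 11)
#' @return data frame with columns `pair_name`, `variant`, `reference`
#' @export
read_variant_pairs <- function(variant_file, reference_file,
                               pair_names = NULL, peptide_length = 11L) {
  v <- readLines(variant_file)
  r <- readLines(reference_file)
  if (length(v) != length(r))
    stop("variant and reference files have different line counts (",
         length(v), " vs ", length(r), ")")
  check_pair_lines <- function(x, what) {
    if (any(!nzchar(trimws(x))))
      stop("blank line ", which(!nzchar(trimws(x)))[1L], " in ", what, " file")
    if (any(startsWith(trimws(x), "#")))
      stop("comment line ", which(startsWith(trimws(x), "#"))[1L], " in ",
           what, " file; pair files must contain peptides only")
    x <- toupper(trimws(x))
    bad <- which(nchar(x) != peptide_length |
                   !grepl(paste0("^[", paste(AA_ORDER, collapse = ""), "]+$"), x))
    if (length(bad) > 0L)
      stop("line ", bad[1L], " of ", what, " file is not a ", peptide_length,
           "-residue peptide: ", x[bad[1L]])
    x
  }
  v <- check_pair_lines(v, "variant")
  r <- check_pair_lines(r, "reference")
  if (is.null(pair_names))
    pair_names <- sprintf("pair_%04d", seq_along(v))
  data.frame(pair_name = pair_names, variant = v, reference = r,
             stringsAsFactors = FALSE)
}

#' Side-by-side counts for variant/reference pairs in one sample
#'
#' @param counts a `peptide_counts` object for the sample
#' @param pairs data frame from [read_variant_pairs()]
#' @return data frame `pair_name`, `variant`, `reference`, `variant_count`,
#'   `reference_count` (0 for peptides absent from the sample)
#' @export
count_paired <- function(counts, pairs) {
  stopifnot(inherits(counts, "peptide_counts"),
            all(c("pair_name", "variant", "reference") %in% names(pairs)))
  lookup <- function(p) {
    x <- counts$counts[p]
    x[is.na(x)] <- 0L
    unname(x)
  }
  data.frame(pair_name = pairs$pair_name, variant = pairs$variant,
             reference = pairs$reference,
             variant_count = lookup(pairs$variant),
             reference_count = lookup(pairs$reference),
             stringsAsFactors = FALSE)
}

#' Library composition summary
#'
#' Number of distinct peptides and the fraction of *unique* sequences (not
#' read-weighted) containing at least one stop codon — the headline
#' composition statistic for an NNS-encoded degenerate library, where each of
#' the ten variable codons is TAG with probability 1/32.
#'
#' @param counts a `peptide_counts` object (non-empty)
#' @return list with `n_unique` and `stop_fraction`
#' @export
summarize_library <- function(counts) {
  stopifnot(inherits(counts, "peptide_counts"))
  if (length(counts$counts) == 0L)
    stop("cannot summarize an empty count table")
  peps <- names(counts$counts)
  list(n_unique = length(peps),
       stop_fraction = mean(grepl("*", peps, fixed = TRUE)))
}

#' Write a peptide count table as TSV
#'
#' @param counts a `peptide_counts` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_counts_tsv <- function(counts, path) {
  write.table(as.data.frame(counts), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
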