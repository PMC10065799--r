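#' Flank specification for locating the peptide-coding region
#'
#' The peptide-coding insert sits between two fixed amplicon sequences. The
#' defaults are the constant portions of the library flanks (the six random
#' sample-index bases printed on either end of the amplicon are excluded so
#' that indexing never affects matching).
#'
#' @param five_prime fixed 5' flanking DNA sequence
#' @param three_prime fixed 3' flanking DNA sequence
#' @param max_mismatches maximum Hamming mismatches tolerated per flank
#'   (no indels); default 0 (exact matching)
#' @return an object of class `flank_spec`
#' @export
#' @examples
#' flank_spec()
flank_spec <- function(five_prime = "ACCGCAGGTACTTCCGTAGCTGGCCAGTCTGGCCAG",
                       three_prime = "GGAGGGCAGTCTGGGCAGTCTGGTGACTACAACAAAA",
                       max_mismatches = 0L) {
  five_prime <- toupper(five_prime)
  three_prime <- toupper(three_prime)
  if (!nzchar(five_prime) || !nzchar(three_prime))
    stop("both flanking sequences must be non-empty")
  if (!grepl("^[ACGT]+$", five_prime) || !grepl("^[ACGT]+$", three_prime))
    stop("flanking sequences must be DNA over {A,C,G,T}")
  max_mismatches <- as.integer(max_mismatches)
  if (is.na(max_mismatches) || max_mismatches < 0L)
    stop("max_mismatches must be a non-negative integer")
  structure(list(five_prime = five_prime, three_prime = three_prime,
                 max_mismatches = max_mismatches),
            class = "flank_spec")
}

#' @export
print.flank_spec <- function(x, ...) {
  cat("flank_spec\n",
      "  5': ", x$five_prime, "\n",
      "  3': ", x$three_prime, "\n",
      "  max mismatches per flank: ", x$max_mismatches, "\n", sep = "")
  invisible(x)
}

#' Read merged sequencing reads from FASTA or FASTQ
#'
#' Parses a file of merged (single-sequence) reads into a data frame with one
#' row per record, in file order. Sequences are upper-cased and must use the
#' alphabet {A,C,G,T,N}; any other symbol is a parse error naming the
#' offending record.
#'
#' @param path path to the sequence file
#' @param format `"fastq"`, `"fasta"`, or `"auto"` (detect from the first
#'   non-empty character: `@` for FASTQ, `>` for FASTA)
#' @return data frame with columns `read_id`, `sequence`, and `quality`
#'   (empty string for FASTA input); zero rows for an empty file
#' @export
read_merged_reads <- function(path, format = c("auto", "fastq", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    if (length(first) == 0L) return(empty_reads())
    format <- if (startsWith(first, "@")) "fastq"
              else if (startsWith(first, ">")) "fasta"
              else stop("cannot auto-detect format of ", path,
                        ": first character is neither '@' nor '>'")
  }
  if (file.size(path) == 0L) return(empty_reads())
  if (format == "fastq") {
    n_lines <- length(readLines(path))
    if (n_lines %% 4L != 0L)
      stop("malformed FASTQ: truncated record ", n_lines %/% 4L + 1L,
           " in ", path)
    seqs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                         with.qualities = TRUE)
    reads <- data.frame(
      read_id = sub("\\s.*$", "", names(seqs)),
      sequence = toupper(as.character(seqs)),
      quality = as.character(S4Vectors::mcols(seqs)$qualities),
      stringsAsFactors = FALSE
    )
  } else {
    seqs <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                     error = function(e)
                       stop("malformed FASTA in ", path, ": ",
                            conditionMessage(e), call. = FALSE))
    reads <- data.frame(
      read_id = sub("\\s.*$", "", names(seqs)),
      sequence = toupper(as.character(seqs)),
      quality = "",
      stringsAsFactors = FALSE
    )
  }
  bad <- which(!grepl("^[ACGTN]+$", reads$sequence))
  if (length(bad) > 0L)
    stop("record ", bad[1L], " (", reads$read_id[bad[1L]],
         ") contains characters outside {A,C,G,T,N}")
  if (any(!nzchar(reads$sequence)))
    stop("record ", which(!nzchar(reads$sequence))[1L], " has an empty sequence")
  rownames(reads) <- NULL
  reads
}

empty_reads <- function() {
  data.frame(read_id = character(), sequence = character(),
             quality = character(), stringsAsFactors = FALSE)
}

#' Extract peptide-coding regions by trimming fixed flanks
#'
#' Locates the leftmost occurrence of the 5' flank in each read, then the
#' first occurrence of the 3' flank after it, each tolerating at most
#' `flanks$max_mismatches` Hamming mismatches (no indels), and returns the
#' region strictly between them. Reads lacking either flank (or with an empty
#' insert) are discarded with a reason code, mirroring the screen pipeline in
#' which reads without both flanking regions are dropped.
#'
#' @param reads data frame as returned by [read_merged_reads()], or a
#'   character vector of sequences
#' @param flanks a [flank_spec()]
#' @return an object of class `trim_result`: a list with
#'   \describe{
#'     \item{regions}{data frame `read_id`, `dna` for kept reads}
#'     \item{discards}{data frame `read_id`, `reason` with reason one of
#'       `missing-5prime`, `missing-3prime`, `empty-insert`}
#'     \item{stats}{list `total`, `kept`, `discarded`, `discard_fraction`,
#'       and per-reason counts}
#'   }
#' @export
#' @examples
#' fs <- flank_spec()
#' insert <- "GAAGAAGAAATCTATGGTATTTTTGGTGCTAAA"
#' tr <- trim_reads(paste0(fs$five_prime, insert, fs$three_prime), fs)
#' tr$regions$dna  # recovers the 33-nt insert
trim_reads <- function(reads, flanks = flank_spec()) {
  if (is.character(reads)) {
    reads <- data.frame(read_id = paste0("read", seq_along(reads)),
                        sequence = toupper(reads), quality = "",
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  n <- nrow(reads)
  if (n == 0L) {
    return(new_trim_result(empty_regions(), empty_discards(), 0L))
  }
  k <- flanks$max_mismatches
  n5 <- nchar(flanks$five_prime)
  n3 <- nchar(flanks$three_prime)

  if (k == 0L) {
    # exact matching: fast fixed-string search
    p5 <- regexpr(flanks$five_prime, reads$sequence, fixed = TRUE)
    start5 <- ifelse(p5 > 0L, as.integer(p5), NA_integer_)
    after5 <- start5 + n5
    tail_seq <- ifelse(is.na(start5), NA_character_,
                       substr(reads$sequence, after5, nchar(reads$sequence)))
    p3 <- rep(NA_integer_, n)
    has5 <- !is.na(start5)
    if (any(has5)) {
      m3 <- regexpr(flanks$three_prime, tail_seq[has5], fixed = TRUE)
      p3[has5] <- ifelse(m3 > 0L, as.integer(m3) + after5[has5] - 1L, NA_integer_)
    }
    start3 <- p3
  } else {
    subj <- Biostrings::DNAStringSet(reads$sequence)
    hits5 <- Biostrings::vmatchPattern(flanks$five_prime, subj,
                                       max.mismatch = k, with.indels = FALSE)
    hits3 <- Biostrings::vmatchPattern(flanks$three_prime, subj,
                                       max.mismatch = k, with.indels = FALSE)
    s5 <- Biostrings::startIndex(hits5)
    s3 <- Biostrings::startIndex(hits3)
    start5 <- vapply(s5, function(s) if (length(s)) min(s) else NA_integer_,
                     integer(1))
    start3 <- mapply(function(s3i, a5) {
      if (is.na(a5)) return(NA_integer_)
      ok <- s3i[s3i >= a5]
      if (length(ok)) min(ok) else NA_integer_
    }, s3, start5 + n5)
  }

  reason <- rep(NA_character_, n)
  reason[is.na(start5)] <- "missing-5prime"
  reason[!is.na(start5) & is.na(start3)] <- "missing-3prime"
  insert_start <- start5 + n5
  insert_end <- start3 - 1L
  empty_ins <- !is.na(start5) & !is.na(start3) & insert_end < insert_start
  reason[empty_ins] <- "empty-insert"

  keep <- is.na(reason)
  regions <- data.frame(
    read_id = reads$read_id[keep],
    dna = substr(reads$sequence[keep], insert_start[keep], insert_end[keep]),
    stringsAsFactors = FALSE
  )
  discards <- data.frame(read_id = reads$read_id[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  new_trim_result(regions, discards, n)
}

empty_regions <- function() {
  data.frame(read_id = character(), dna = character(), stringsAsFactors = FALSE)
}
empty_discards <- function() {
  data.frame(read_id = character(), reason = character(), stringsAsFactors = FALSE)
}

new_trim_result <- function(regions, discards, total) {
  by_reason <- table(factor(discards$reason,
                            levels = c("missing-5prime", "missing-3prime",
                                       "empty-insert")))
  stats <- list(total = total, kept = nrow(regions),
                discarded = nrow(discards),
                discard_fraction = if (total > 0L) nrow(discards) / total else 0,
                by_reason = as.list(by_reason))
  structure(list(regions = regions, discards = discards, stats = stats),
            class = "trim_result")
}

#' @export
print.trim_result <- function(x, ...) {
  s <- x$stats
  cat(sprintf("trim_result: %d reads, %d kept, %d discarded (%.2f%%)\n",
              s$total, s$kept, s$discarded, 100 * s$discard_fraction))
  if (s$discarded > 0L) {
    for (r in names(s$by_reason))
      if (s$by_reason[[r]] > 0L) cat(sprintf("  %s: %d\n", r, s$by_reason[[r]]))
  }
  invisible(x)
}

#' Write sequences as FASTA
#'
#' @param ids record identifiers
#' @param sequences character vector of sequences (same length as `ids`);
#'   `*` symbols are permitted (translated peptide output)
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_fasta <- function(ids, sequences, path) {
  stopifnot(length(ids) == length(sequences))
  out <- character(2L * length(ids))
  out[c(TRUE, FALSE)] <- paste0(">", ids)
  out[c(FALSE, TRUE)] <- sequences
  writeLines(out, path)
  invisible(path)
}
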