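#' Translate peptide-coding regions into 11-residue peptides
#'
#' Codon-wise translation under the standard genetic code
#' (`Biostrings::GENETIC_CODE`), with all three stop codons rendered as `*`.
#' Records are additionally annotated with the number of stop residues, the
#' number of Amber (TAG) codons — the only stop reachable through an NNS
#' codon, and the one that Amber suppression can reassign — and whether the
#' central position carries the fixed tyrosine.
#'
#' Regions whose length differs from `3 * expected_length` get status
#' `wrong-length`; regions containing bases outside {A,C,G,T} (e.g. N) get
#' status `ambiguous-base`. Only `ok` records carry a peptide.
#'
#' @param regions data frame with columns `read_id` and `dna` (as produced by
#'   [trim_reads()]`$regions`), or a character vector of DNA sequences
#' @param expected_length expected peptide length in residues (odd; the
#'   central residue is the phosphoacceptor). Default 11 (X5-Y-X5 geometry).
#' @return data frame with columns `read_id`, `dna`, `status`
#'   (`ok` / `wrong-length` / `ambiguous-base`), `peptide` (NA unless ok),
#'   `n_stop`, `n_amber`, `central_is_tyr`
#' @export
#' @examples
#' translate_regions("TATTATTATTATTATTATTATTATTATTATTAT")$peptide
translate_regions <- function(regions, expected_length = 11L) {
  if (is.character(regions)) {
    regions <- data.frame(read_id = paste0("read", seq_along(regions)),
                          dna = regions, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(regions), all(c("read_id", "dna") %in% names(regions)))
  expected_length <- as.integer(expected_length)
  stopifnot(expected_length >= 1L, expected_length %% 2L == 1L)
  dna <- toupper(regions$dna)
  n <- length(dna)
  status <- rep("ok", n)
  status[nchar(dna) != 3L * expected_length] <- "wrong-length"
  status[status == "ok" & !grepl("^[ACGT]*$", dna)] <- "ambiguous-base"

  peptide <- rep(NA_character_, n)
  n_stop <- rep(NA_integer_, n)
  n_amber <- rep(NA_integer_, n)
  central_is_tyr <- rep(NA, n)

  ok <- status == "ok"
  if (any(ok)) {
    starts <- 3L * (seq_len(expected_length) - 1L) + 1L
    codons <- vapply(starts, function(s) substr(dna[ok], s, s + 2L),
                     character(sum(ok)))
    if (sum(ok) == 1L) codons <- matrix(codons, nrow = 1L)
    aa <- matrix(Biostrings::GENETIC_CODE[codons], nrow = sum(ok))
    peptide[ok] <- apply(aa, 1L, paste0, collapse = "")
    n_stop[ok] <- rowSums(aa == "*")
    n_amber[ok] <- rowSums(codons == "TAG")
    central_is_tyr[ok] <- aa[, central_index(expected_length)] == "Y"
  }

  out <- data.frame(read_id = regions$read_id, dna = dna, status = status,
                    peptide = peptide, n_stop = n_stop, n_amber = n_amber,
                    central_is_tyr = central_is_tyr, stringsAsFactors = FALSE)
  classify_peptides(out)
}

#' Classify translated peptides for the three matrix-building modes
#'
#' Adds the logical columns used to select records for position-specific
#' matrices:
#' \describe{
#'   \item{nostop_ok}{central tyrosine and no stop codons — the standard
#'     analysis mode for unsuppressed libraries}
#'   \item{full_ok}{any valid peptide of the expected length — used to
#'     quantify per-position stop-codon depletion}
#'   \item{one_amber_ok}{central tyrosine and exactly one stop which is an
#'     Amber (TAG) codon — the Amber-suppression sub-sampling mode, where the
#'     single TAG position encodes a non-canonical amino acid}
#' }
#'
#' @param translated data frame from [translate_regions()]
#' @return the same data frame with classification columns appended/updated
#' @export
classify_peptides <- function(translated) {
  ok <- translated$status == "ok"
  translated$nostop_ok <- ok & translated$central_is_tyr & translated$n_stop == 0L
  translated$full_ok <- ok
  translated$one_amber_ok <- ok & translated$central_is_tyr &
    translated$n_stop == 1L & translated$n_amber == 1L
  translated$nostop_ok[is.na(translated$nostop_ok)] <- FALSE
  translated$one_amber_ok[is.na(translated$one_amber_ok)] <- FALSE
  translated
}
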