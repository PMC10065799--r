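#' Log2 fold change in enrichment, variant versus reference
#'
#' `log2(mean(variant_E) / mean(reference_E))`, computed on raw mean
#' enrichments (not log-scale means).
#'
#' @param variant_E per-replicate enrichment scores of the variant
#' @param reference_E per-replicate enrichment scores of the reference
#' @return a single number
#' @export
variant_log2fc <- function(variant_E, reference_E) {
  stopifnot(length(variant_E) >= 1L, length(reference_E) >= 1L)
  mv <- mean(variant_E)
  mr <- mean(reference_E)
  if (mv <= 0 || mr <= 0)
    stop("mean enrichment must be positive (use a pseudocount upstream)")
  log2(mv / mr)
}

#' Two-sided test for a variant/reference enrichment difference
#'
#' Welch's unequal-variance t-test on the per-replicate enrichment scores.
#' When both samples are constant (zero spread), the test statistic is
#' undefined; equal constants return p = 1 (no evidence of any difference)
#' and unequal constants return the smallest representable positive p rather
#' than erroring mid-pipeline.
#'
#' @param variant_E per-replicate enrichment scores of the variant (>= 2)
#' @param reference_E per-replicate enrichment scores of the reference (>= 2)
#' @return two-sided p-value in (0, 1]
#' @export
variant_test <- function(variant_E, reference_E) {
  if (length(variant_E) < 2L || length(reference_E) < 2L)
    stop("at least 2 replicates per side are required for the test")
  if (sd(variant_E) == 0 && sd(reference_E) == 0) {
    return(if (mean(variant_E) == mean(reference_E)) 1
           else .Machine$double.xmin)
  }
  t.test(variant_E, reference_E, var.equal = FALSE)$p.value
}

#' Does a variant add or remove a tyrosine?
#'
#' Mutations that change the number of non-central tyrosines are ambiguous
#' in a phosphotyrosine-readout screen (the new/removed Tyr is itself a
#' potential phosphoacceptor) and are therefore flagged for exclusion.
#'
#' @param variant variant peptide (central residue Y)
#' @param reference reference peptide (central residue Y), same length
#' @return logical flag
#' @export
tyrosine_change <- function(variant, reference) {
  variant <- toupper(variant)
  reference <- toupper(reference)
  stopifnot(nchar(variant) == nchar(reference))
  centre <- central_index(nchar(variant))
  for (p in c(variant, reference))
    if (substr(p, centre, centre) != "Y")
      stop("central residue must be Y: ", p)
  count_y <- function(p) {
    res <- strsplit(p, "")[[1L]][-centre]
    sum(res == "Y")
  }
  count_y(variant) != count_y(reference)
}

#' Filter thresholds for variant-effect calling
#'
#' Defaults follow the five-step screen analysis: p-value cutoff 0.05,
#' minimum two-fold change in enrichment, both-low-activity cutoff at
#' enrichment 1.5, and a minimum average read count of 50.
#'
#' @param alpha significance cutoff on the replicate test p-value
#' @param min_fold minimum fold change (either direction) in mean enrichment
#' @param min_activity enrichment below which a sequence counts as
#'   low-activity; pairs where both members fall below are removed
#' @param min_reads minimum mean read count for each pair member
#' @return list of class `filter_thresholds`
#' @export
filter_thresholds <- function(alpha = 0.05, min_fold = 2,
                              min_activity = 1.5, min_reads = 50) {
  stopifnot(alpha > 0, min_fold > 0, min_activity > 0, min_reads > 0)
  structure(list(alpha = alpha, min_fold = min_fold,
                 min_activity = min_activity, min_reads = min_reads),
            class = "filter_thresholds")
}

#' Variant effects from replicate enrichment tables
#'
#' For each variant/reference pair, collects per-replicate enrichment
#' scores, computes the log2 fold change and the replicate test p-value, and
#' records the mean read counts needed by the read-depth filter. Enrichment
#' values are taken from the pseudocounted `log2_enrichment` column
#' (back-transformed), so zero-count peptides never produce undefined fold
#' changes.
#'
#' @param pairs data frame from [read_variant_pairs()]
#' @param enrichment_reps list of `enrichment_table` objects, one per
#'   replicate, whose universes contain the pair peptides
#' @return data frame of class `variant_effects`: `pair_name`, `variant`,
#'   `reference`, `mean_E_variant`, `sd_E_variant`, `mean_E_reference`,
#'   `sd_E_reference`, `log2fc`, `p_value`, `mean_reads_variant`,
#'   `mean_reads_reference`, `tyr_change`
#' @export
variant_effects <- function(pairs, enrichment_reps) {
  stopifnot(is.data.frame(pairs),
            all(c("pair_name", "variant", "reference") %in% names(pairs)),
            length(enrichment_reps) >= 1L)
  get_col <- function(tab, peptides, col) {
    unname(setNames(tab[[col]], tab$peptide)[peptides])
  }
  Ev <- vapply(enrichment_reps, get_col, numeric(nrow(pairs)),
               peptides = pairs$variant, col = "log2_enrichment")
  Er <- vapply(enrichment_reps, get_col, numeric(nrow(pairs)),
               peptides = pairs$reference, col = "log2_enrichment")
  Nv <- vapply(enrichment_reps, get_col, numeric(nrow(pairs)),
               peptides = pairs$variant, col = "n_input")
  Nr <- vapply(enrichment_reps, get_col, numeric(nrow(pairs)),
               peptides = pairs$reference, col = "n_input")
  if (nrow(pairs) == 1L) {
    Ev <- matrix(Ev, nrow = 1L); Er <- matrix(Er, nrow = 1L)
    Nv <- matrix(Nv, nrow = 1L); Nr <- matrix(Nr, nrow = 1L)
  }
  if (anyNA(Ev) || anyNA(Er))
    stop("pair peptide absent from a replicate's enrichment universe; ",
         "build the tables with universe = the pair peptide list")
  Ev <- 2^Ev
  Er <- 2^Er
  out <- pairs[, c("pair_name", "variant", "reference")]
  out$mean_E_variant <- rowMeans(Ev)
  out$sd_E_variant <- apply(Ev, 1L, sd)
  out$mean_E_reference <- rowMeans(Er)
  out$sd_E_reference <- apply(Er, 1L, sd)
  out$log2fc <- log2(out$mean_E_variant / out$mean_E_reference)
  out$p_value <- vapply(seq_len(nrow(pairs)), function(i)
    variant_test(Ev[i, ], Er[i, ]), numeric(1))
  out$mean_reads_variant <- rowMeans(Nv)
  out$mean_reads_reference <- rowMeans(Nr)
  out$tyr_change <- mapply(tyrosine_change, pairs$variant, pairs$reference,
                           USE.NAMES = FALSE)
  class(out) <- c("variant_effects", class(out))
  out
}

#' Apply the five-step variant-effect filter
#'
#' Annotates every pair with the reason codes of the filters it fails, in
#' order: (1) `not_significant` — p-value at or above `alpha`;
#' (2) `small_fold_change` — fold change in mean enrichment (either
#' direction) below `min_fold`; (3) `both_low_activity` — both sequences
#' below `min_activity`; (4) `tyr_change` — the mutation adds or removes a
#' tyrosine; (5) `low_reads` — mean read count of either member below
#' `min_reads`. A pair is a hit iff it fails no filter.
#'
#' @param effects a `variant_effects` data frame
#' @param thresholds a [filter_thresholds()] list
#' @return `effects` with columns `reason_codes` (comma-separated, empty for
#'   hits) and `verdict` (`"hit"` / `"rejected"`) appended
#' @export
apply_filters <- function(effects, thresholds = filter_thresholds()) {
  stopifnot(inherits(effects, "variant_effects"),
            inherits(thresholds, "filter_thresholds"))
  fc <- pmax(effects$mean_E_variant / effects$mean_E_reference,
             effects$mean_E_reference / effects$mean_E_variant)
  fails <- cbind(
    not_significant = effects$p_value >= thresholds$alpha,
    small_fold_change = fc < thresholds$min_fold,
    both_low_activity = effects$mean_E_variant < thresholds$min_activity &
      effects$mean_E_reference < thresholds$min_activity,
    tyr_change = effects$tyr_change,
    low_reads = effects$mean_reads_variant < thresholds$min_reads |
      effects$mean_reads_reference < thresholds$min_reads
  )
  effects$reason_codes <- apply(fails, 1L, function(f)
    paste(colnames(fails)[f], collapse = ","))
  effects$verdict <- ifelse(effects$reason_codes == "", "hit", "rejected")
  effects
}

#' Hits surviving the five-step filter
#'
#' @param effects output of [apply_filters()]
#' @return the subset of rows with verdict `"hit"`
#' @export
variant_hits <- function(effects) {
  stopifnot("verdict" %in% names(effects))
  effects[effects$verdict == "hit", , drop = FALSE]
}
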