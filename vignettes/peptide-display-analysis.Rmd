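---
title: "Deconvolving bacterial peptide-display specificity screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving bacterial peptide-display specificity screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepdisplay)
```

## The experiment and its statistical model

A peptide-display specificity screen compares two sequenced populations of
the same peptide library: an unselected **input** sample and a **selected**
sample in which cells were enriched in proportion to how well their displayed
peptide is recognized by a tyrosine kinase (phosphorylation read out with a
pan-phosphotyrosine antibody) or an SH2 domain (direct binding). Each library
member is an 11-residue peptide with a fixed central tyrosine — the
phosphoacceptor — and five variable residues on either side (positions
−5…+5).

The analysis rests on two ratios. For a peptide observed $n_{\text{peptide}}$
times among $n_{\text{total}}$ peptide-coding reads of a sample, its
frequency is

$$f_{\text{peptide}} = \frac{n_{\text{peptide}}}{n_{\text{total}}},$$

and its enrichment score is the frequency ratio between the selected and
input samples,

$$E_{\text{peptide}} = \frac{f_{\text{peptide,selected}}}{f_{\text{peptide,input}}}.$$

$E > 1$ means the peptide was preferentially phosphorylated/bound; $E < 1$
means it was depleted. This single-round enrichment model assumes selection
acts independently on each cell, that display level is roughly uniform
across library members, and that sequencing depth is large enough for
multinomial counting noise to be the dominant stochastic term.

For degenerate (X₅-Y-X₅) libraries whose diversity is on par with the
sequencing depth, per-peptide enrichments are uninformative (most peptides
are observed once). Instead the same two-sample comparison is applied
**per position**: each qualifying peptide contributes one count to the cell
(residue, position) of a 21 × 11 matrix, counts are converted to per-column
frequencies, and the selected-over-input frequency ratio is
log₂-transformed. The resulting matrix is a position-specific scoring
matrix (PSSM): entry $(a, j)$ estimates the log₂ preference for residue $a$
at position $j$, averaged over all sequence contexts. The implied
independence-across-positions assumption is the standard PSSM limitation —
context-dependent preferences are invisible to it.

### Matrix modes

Three record filters correspond to three biological questions:

* **nostop** — central Tyr and no stop codons. Stop-containing transcripts
  truncate before the display scaffold and are never displayed, so they are
  excluded from specificity estimates. The `*` row is undefined (all-NA).
* **full** — every valid 11-mer, including stops. Used to quantify the
  *depletion* of stop codons at each position, a built-in negative control:
  in the full-mode log₂ matrix the `*` row should be negative everywhere.
* **one_amber** — central Tyr plus exactly one stop that is specifically
  TAG. Under Amber suppression the TAG position encodes a non-canonical
  amino acid; restricting to single-TAG sequences holds the premature-
  termination penalty approximately constant across the subsample, so the
  `*` row becomes interpretable as the preference for the non-canonical
  residue. Non-Amber stops (TAA/TGA) never qualify, because no suppressor
  reassigns them; the check is done at the DNA level, not on the translated
  peptide.

Replicate screens are averaged cell-wise on the log₂ layer, following the
practice of averaging replicate heatmaps; averaging ratios before the log
transform is the main alternative and differs only at second order for the
small per-cell changes typical of these screens. Missing cells are ignored
rather than propagated, so a cell observed in two of three replicates is the
mean of those two.

## Scoring peptides against a matrix

The raw score of a central-Tyr peptide is the mean of the matrix entries of
its residues over the 10 variable positions (the fixed tyrosine is ignored).
Raw scores are then min–max normalized:

$$\text{score} = \frac{\text{raw} - \text{worst}}{\text{best} - \text{worst}},$$

where *best* (*worst*) is the mean of the column maxima (minima), excluding
the `*` row. The best achievable sequence therefore scores exactly 1 and the
worst exactly 0; the implementation sums both quantities in the same order
so the endpoints hold to the last bit, not merely to rounding. Adding a
constant to the whole matrix leaves normalized scores unchanged. Peptides
containing `*` are rejected (scoring a truncated peptide is meaningless),
while non-central tyrosines are allowed and scored from the Y row, since
natural phosphosite sequences frequently contain them. A degenerate
(constant) matrix has no score span and is an error rather than a silent
0/0.

## Variant-effect calling

For defined variant/reference pair libraries, each replicate yields a pair
of enrichment scores. The effect size is
$\log_2(\bar E_\text{variant} / \bar E_\text{reference})$ on raw means, and
significance is assessed with a two-sided Welch unequal-variance *t*-test
across replicates. The test is a declared choice: the original analysis
states only the 0.05 cutoff, and Welch is the conservative default when
per-pair variances cannot be assumed equal with 3–5 replicates. No
multiple-testing correction is applied, matching the use of raw p < 0.05;
the filter's remaining steps act as the false-positive control.

The five-step filter annotates each pair, in order, with every reason it
fails:

1. `not_significant` — p ≥ 0.05;
2. `small_fold_change` — fold change (in either direction) < 2;
3. `both_low_activity` — both mean enrichments < 1.5, i.e. neither sequence
   is a real substrate, so a ratio between them is noise;
4. `tyr_change` — the mutation adds or removes a non-central tyrosine,
   making the phosphotyrosine readout ambiguous;
5. `low_reads` — mean read count of either member < 50.

A pair is a hit iff it fails nothing. Step 5's "average read count" is
interpreted as the mean across replicates of the **input-sample** counts:
input counts measure library representation, which is what limits the
precision of an enrichment estimate, whereas selected counts are confounded
with the effect itself. Enrichment values entering the test are computed
from pseudocounted frequencies (below), so zero counts cannot produce
infinite fold changes. Degenerate zero-variance comparisons return p = 1
when the constants are equal — no evidence of a difference — rather than
erroring mid-pipeline.

All thresholds are configurable through `filter_thresholds()`; the defaults
(α = 0.05, fold ≥ 2, activity ≥ 1.5, reads ≥ 50) are the screen analysis'
published operating point.

## Numerical choices

* **Flank matching.** The 5′/3′ flank matcher uses Hamming distance only
  (no indels), leftmost 5′ match then first 3′ match after it — the
  deterministic adapter-trimming convention. The default tolerance is 0
  mismatches: exact matching is conservative and reproducible, and the
  original trimming tool's error settings are not part of the published
  analysis. The six randomized index bases flanking the printed amplicon
  sequences are excluded from the match patterns so indexing never affects
  trimming. Reads are searched on the given strand only, as the amplicon
  protocol fixes orientation.
* **Ambiguous bases.** Inserts containing N are discarded (status
  `ambiguous-base`) rather than translated to X: the counting alphabet is
  exactly 20 residues + `*`, and at typical quality thresholds such reads
  are rare.
* **Pseudocounts.** Raw per-peptide enrichment is reported without
  pseudocount, exactly as the frequency ratio. The log₂ column adds 0.5 to
  both raw counts (then renormalizes) so it stays finite; at the ~10⁵–10⁶
  read depths of defined-library screens this perturbs non-zero counts
  negligibly. Position matrices use a frequency-scale pseudocount of 10⁻⁴
  in the log₂ layer, the same order as one count at typical column totals.
* **Normalization order.** $n_\text{total}$ is computed after the active
  mode filter (and within the supplied peptide universe, when one is
  given), so frequencies sum to 1 over exactly the peptides being compared.
  Computing totals before filtering is exposed by filtering upstream
  instead; the default matches "total peptide-coding reads".
* **Ties.** `consensus_sequence()` resolves tied column maxima by the fixed
  alphabetical row order, making consensus construction deterministic.

## What the simulator emulates — and what it does not

`simulate_screen()` generates a complete synthetic screen with known ground
truth. Its generative model:

1. a library pool — either `sample_nns_library()` draws X₅-Y-X₅ coding
   regions codon-wise from the NNS distribution (N uniform on A/C/G/T, S on
   G/C, central codon TAT), reproducing the real library's composition
   statistics (all 20 residues per position; TAG, the only reachable stop,
   at 1/32 per degenerate codon, so ≈27.2 % of inserts carry at least one);
   or a defined peptide list reverse-translated by `design_library_oligos()`;
2. input reads drawn multinomially from the pool;
3. selected reads drawn with Boltzmann weights
   $\exp(s \cdot \text{score})$, where *score* is the peptide's mean
   ground-truth matrix value over variable positions and *s* is the
   selection strength — the simplest model consistent with one round of
   independent-cell capture;
4. stop-containing peptides additionally down-weighted by the premature-
   termination probability (1 = unsuppressed library, fully removed;
   intermediate values emulate partial Amber suppression);
5. each read emitted as 5′ flank + insert + 3′ flank, fully reproducible
   from one seed.

Default conditions are chosen to mirror a realistic single screen: input and
selected depths of 10⁵ reads, selection strength 1, termination probability
0.8 (strong but incomplete removal of stop-containing sequences, leaving
enough residual `*` counts to measure depletion), truth-matrix entries
uniform on [−2, 2] — the dynamic range of published log₂ heatmaps. Under
these conditions the deconvolved nostop-mode matrix recovers the truth at
Pearson r > 0.9 over variable-position cells, and a neutral screen
(strength 0) is centred at log₂E = 0.

The simulator deliberately omits PCR amplification bias, sequencing error,
display-level variation between clones, bead-capture saturation and
selection round-to-round carryover. Passing the recovery tests therefore
demonstrates that the *deconvolution* is correct and well-calibrated under
multinomial sampling noise — not that real screens are free of those
additional noise sources.

## Oligo design

`design_library_oligos()` reverse-translates peptides with the most
frequently used *E. coli* codon per residue, then greedily swaps synonymous
codons (positions left to right, alternatives in decreasing usage order)
until the GC fraction lies within 30–70 % and no SfiI recognition site
(`GGCCNNNNNGGCC`, the cloning enzyme's site) remains. Translation is
preserved by construction, swaps are deterministic, and peptides for which
the constraints cannot be met are reported as infeasible with their final
GC/motif diagnostics instead of being dropped.

## Problem sizes used in the test suite

Unit tests run at 10³–2×10⁴ records; oracle-equivalence checks compare
vectorized implementations against brute-force loops on 10⁴ random inputs;
the end-to-end recovery, stop-depletion and filter-calibration checks
simulate screens at 10⁵ reads per sample (200 variant pairs × 4 replicates
for the calibration), the depth at which a real degenerate-library screen
is sequenced per sample. The whole suite completes in about a minute on one
CPU.

## Known limitations

* PSSM scores assume positional independence; context-dependent
  preferences require pairwise or sequence-level models and are out of
  scope here.
* Enrichment scores from a single selection round compress at the high end
  (capture saturates), so score–rate relationships are monotone but not
  linear.
* The Welch test with 3–5 replicates has limited power; the filter's
  fold-change and activity steps do most of the practical work, and the
  absence of multiple-testing correction means the hit list is an
  operating point, not an FDR-controlled set.
* Near-identical peptides are counted as distinct species; no
  sequencing-error collapse is attempted.
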