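# pepdisplay

Deconvolution of deep-sequencing data from bacterial peptide-display
specificity screens of tyrosine kinases and SH2 domains.

In these screens, *E. coli* cells display 11-residue peptides with a central
tyrosine (an X₅-Y-X₅ degenerate library or a defined phosphosite/variant
library) on their surface. Cells are phosphorylated by a purified kinase (or
bound by an SH2 domain), the most-modified cells are captured, and the
peptide-coding DNA of the input and selected populations is deep-sequenced.
`pepdisplay` turns those two read sets into quantitative sequence-recognition
profiles:

- **Trim** — locate the fixed 5′/3′ flanking sequences around the
  peptide-coding region in each merged read and extract the 33-nt insert;
  reads lacking either flank are discarded with a reason code.
- **Translate** — codon-wise translation into 11-mers, stops rendered `*`,
  with Amber (TAG) codons tracked separately for suppression analyses.
- **Count & enrich** — for each peptide, frequency
  *f* = *n*<sub>peptide</sub>/*n*<sub>total</sub> per sample and enrichment
  score *E* = *f*<sub>selected</sub>/*f*<sub>input</sub>, aggregated across
  replicates.
- **Specificity matrices** — 21 × 11 position-specific count, frequency and
  log₂-enrichment matrices (rows: 20 amino acids alphabetically, then `*`;
  columns: positions −5…+5). Three modes: `nostop` (central Tyr, no stops),
  `full` (all sequences; quantifies per-position stop depletion) and
  `one_amber` (exactly one TAG plus central Tyr, for Amber-suppression
  screens with non-canonical amino acids).
- **Score** — any central-Tyr 11-mer against a log₂ matrix: the mean matrix
  value over the 10 variable positions, min–max normalized so the best
  achievable sequence scores 1 and the worst 0.
- **Variant effects** — per-pair log₂ fold change and Welch test across
  replicates, then the five-step filter (significance, fold change ≥ 2,
  activity ≥ 1.5, Tyr-change exclusion, read depth ≥ 50) with per-pair
  reason codes.
- **Simulate** — a ground-truth screen generator (NNS or defined libraries,
  Boltzmann selection on a known preference matrix, premature termination at
  stop codons, reads with flanks) so the whole pipeline is testable without
  sequencing data, plus a library-oligo designer (most-frequent *E. coli*
  codons, GC 30–70 %, SfiI-site removal).

## Worked example

Simulate a screen with known position preferences, recover the specificity
matrix, and score peptides against it:

```r
library(pepdisplay)

tm    <- random_truth_matrix(seed = 42)          # ground-truth log2 preferences
truth <- screen_truth(tm, selection_strength = 1,
                      depth_input = 2e4, depth_selected = 2e4,
                      amber_termination_prob = 0.8, seed = 42)
sim   <- simulate_screen(truth)                  # reads with flanks attached

sm <- screen_matrix(sim$input, sim$selected, mode = "nostop")
sm$input$trim
#> trim_result: 20000 reads, 20000 kept, 0 discarded (0.00%)

cons <- consensus_sequence(sm$log2_matrix)       # argmax residue per position
cons
#> [1] "PEGFRYFHMAA"

score_table(c(cons, "EEEIIYGEFEA", "AAAAAYAAAAA"), sm$log2_matrix)
#>       peptide raw_score normalized_score
#> 1 PEGFRYFHMAA     0.317            1.000
#> 2 EEEIIYGEFEA     0.115            0.695
#> 3 AAAAAYAAAAA     0.108            0.684
```

The consensus sequence scores exactly 1 by construction; the other scores
place arbitrary peptides on the 0 (worst possible) to 1 (best possible)
scale of that matrix. At this depth the recovered matrix correlates with the
simulated ground truth at r ≈ 0.88 over the variable-position cells (r > 0.9
at depth 10⁵, the default).

A command-line front end wrapping the same functions is installed at
`system.file("cli", "pepdisplay.R", package = "pepdisplay")`, with
subcommands `trim`, `translate`, `count`, `enrich`, `matrix`, `score`,
`variants`, `simulate`, `design-oligos` and `pipeline`; every run writes a
JSON manifest of parameters and input checksums.

## See also

The methods vignette (`vignettes/peptide-display-analysis.Rmd`) documents
the statistical model, the simulator's generative assumptions, parameter
defaults and known limitations.
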