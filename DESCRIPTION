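Package: pepdisplay
Title: Deep-Sequencing Analysis of Bacterial Peptide-Display Specificity Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deconvolution of selected-versus-input deep-sequencing data from
    bacterial peptide-display screens of tyrosine kinases and SH2 domains.
    Extracts peptide-coding regions between fixed flanking sequences, translates
    them into 11-residue peptides, tabulates peptide abundances, computes
    frequencies and enrichment scores, builds 21 x 11 position-specific
    count/frequency/log2-enrichment matrices (including Amber-suppression
    one-stop mode), scores arbitrary peptides against those matrices on a
    normalized 0-1 scale, and calls phosphosite-proximal variant effects from
    replicate screens with a five-step significance filter. A synthetic-screen
    simulator with known ground truth (degenerate NNS or defined libraries,
    preference-weighted selection, premature-termination at Amber codons) and a
    library oligo designer make every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
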