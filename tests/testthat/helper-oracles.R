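# Independent brute-force oracles and fixture builders used across tests.
# Oracles deliberately avoid the package's vectorized code paths.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Hand-written standard genetic code, independent of Biostrings::GENETIC_CODE.
oracle_codon_table <- local({
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",   # TTT..TGG
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- unlist(lapply(bases, function(b1)
    unlist(lapply(bases, function(b2) paste0(b1, b2, bases)))))
  setNames(aa, codons)
})

oracle_translate <- function(dna) {
  vapply(dna, function(d) {
    n <- nchar(d)
    out <- character(n / 3)
    for (i in seq_along(out)) {
      codon <- substr(d, 3 * i - 2, 3 * i)
      out[i] <- oracle_codon_table[[codon]]
    }
    paste0(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# one-pass dictionary accumulation
oracle_count <- function(peptides) {
  env <- new.env()
  for (p in peptides) {
    cur <- if (is.null(env[[p]])) 0L else env[[p]]
    env[[p]] <- cur + 1L
  }
  keys <- sort(ls(env))
  setNames(vapply(keys, function(k) env[[k]], integer(1)), keys)
}

# naive double loop over peptides x positions
oracle_position_counts <- function(peptides, rows = c(AA20, "*")) {
  width <- nchar(peptides[1])
  m <- matrix(0L, nrow = length(rows), ncol = width,
              dimnames = list(rows, NULL))
  for (p in peptides) {
    for (j in seq_len(width)) {
      r <- substr(p, j, j)
      m[r, j] <- m[r, j] + 1L
    }
  }
  m
}

# naive per-position summation against a log2 matrix
oracle_score <- function(peptide, m, centre = 6L) {
  total <- 0
  n <- 0
  for (j in seq_len(nchar(peptide))) {
    if (j == centre) next
    total <- total + m[substr(peptide, j, j), j]
    n <- n + 1
  }
  total / n
}

# textbook Welch unequal-variance t-test
oracle_welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * pt(-abs(tstat), df)
}

random_peptides <- function(n, width = 11L, central_y = TRUE,
                            alphabet = AA20) {
  m <- matrix(sample(alphabet, n * width, replace = TRUE), nrow = n)
  if (central_y) m[, (width + 1L) %/% 2L] <- "Y"
  apply(m, 1L, paste0, collapse = "")
}

random_dna33 <- function(n) {
  vapply(seq_len(n), function(i)
    paste0(sample(c("A", "C", "G", "T"), 33, replace = TRUE), collapse = ""),
    character(1))
}

# arbitrary log2 matrix fixture with all cells defined
random_log2_matrix <- function(scale = 2) {
  m <- matrix(runif(21 * 11, -scale, scale), nrow = 21,
              dimnames = list(c(AA20, "*"), position_labels(11)))
  pepdisplay:::new_position_matrix(m, layer = "log2_enrichment", mode = "full")
}

# toy matrix: A = +1, C = -1 at every variable position, all else 0
toy_ac_matrix <- function() {
  m <- matrix(0, nrow = 21, ncol = 11,
              dimnames = list(c(AA20, "*"), position_labels(11)))
  m["A", ] <- 1
  m["C", ] <- -1
  pepdisplay:::new_position_matrix(m, layer = "log2_enrichment", mode = "nostop")
}

write_fastq_fixture <- function(ids, seqs, path) {
  qual <- strrep("I", nchar(seqs))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
  path
}

write_fasta_fixture <- function(ids, seqs, path) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

# translated-record data frame straight from peptide strings (for counting
# and matrix tests that start downstream of translation)
records_from_peptides <- function(peptides) {
  pepdisplay::classify_peptides(data.frame(
    read_id = paste0("r", seq_along(peptides)),
    dna = NA_character_,
    status = "ok",
    peptide = peptides,
    n_stop = vapply(peptides, function(p)
      sum(strsplit(p, "")[[1]] == "*"), integer(1), USE.NAMES = FALSE),
    # treat every stop as Amber unless stated otherwise
    n_amber = vapply(peptides, function(p)
      sum(strsplit(p, "")[[1]] == "*"), integer(1), USE.NAMES = FALSE),
    central_is_tyr = substr(peptides, 6, 6) == "Y",
    stringsAsFactors = FALSE))
}
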