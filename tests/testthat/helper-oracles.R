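# Independent oracles used across tests: these deliberately re-derive results
# with naive loops, separate from the package implementation.

# Naive O(n * |rules|) site scan + split: the digestion oracle.
oracle_digest <- function(sequence, rule_list) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  cut_after <- rep(FALSE, max(n - 1L, 0L))
  for (r in rule_list) {
    for (i in seq_len(n - 1L)) {
      if (chars[i] %in% r$p1_residues && !(chars[i + 1L] %in% r$p1prime_blockers))
        cut_after[i] <- TRUE
    }
  }
  peptides <- character(0)
  start <- 1L
  for (i in seq_len(n - 1L)) {
    if (cut_after[i]) {
      peptides <- c(peptides, paste(chars[start:i], collapse = ""))
      start <- i + 1L
    }
  }
  peptides <- c(peptides, paste(chars[start:n], collapse = ""))
  list(peptides = peptides, cleaved = sum(cut_after), total = n - 1L)
}

# Random sequence over a residue set.
random_sequence <- function(len, alphabet = residue_table()$one_letter) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Build a synthetic Raman spectrum holding a tyrosine doublet with a chosen
# peak intensity ratio, plus optional linear baseline.
make_doublet_spectrum <- function(ratio, baseline = c(0, 0), sigma = 4) {
  x <- seq(780, 900, by = 0.5)
  y <- ratio * exp(-0.5 * ((x - 850) / sigma)^2) +
    1.0 * exp(-0.5 * ((x - 830) / sigma)^2) +
    baseline[1] + baseline[2] * x
  spectrum(x, y, kind = "raman")
}

table2_path <- function() {
  system.file("extdata", "table2_peptides.csv", package = "coixpep")
}

table3_path <- function() {
  system.file("extdata", "table3_profiles.csv", package = "coixpep")
}
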