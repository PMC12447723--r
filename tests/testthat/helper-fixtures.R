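# Shared fixtures, built once per test run and cached.
.fx <- new.env(parent = emptyenv())

# Default synthetic genome (the study conditions of the whole suite).
fx_sim <- function(seed = 1L) {
  key <- paste0("sim", seed)
  if (is.null(.fx[[key]])) .fx[[key]] <- simulate_genome(synthetic_config(seed = seed))
  .fx[[key]]
}

# A small, fast genome for structural tests that do not need learning power.
fx_small_sim <- function(seed = 5L) {
  key <- paste0("small", seed)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- simulate_genome(synthetic_config(
      n_chromosomes = 2L, chrom_length = 30000L, genes_per_chrom = 4L,
      exons_per_gene = 3L, seed = seed))
  }
  .fx[[key]]
}

# Full pipeline on the default fixture; trained once and reused by the
# learning, calibration-population and end-to-end tests.
fx_pipeline <- function(seed = 1L) {
  key <- paste0("pipe", seed)
  if (is.null(.fx[[key]])) .fx[[key]] <- run_pipeline(seed = seed)
  .fx[[key]]
}

# Independent reverse complement used as an oracle against the package's
# Biostrings-backed implementation.
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Hand-rolled per-position nucleotide log-odds scorer (PWM), used as an
# independent sanity oracle for the synthetic fixture's planted signal.
pwm_scores <- function(x_pos, x_neg, x_eval, pseudo = 0.01) {
  lod <- log((apply(x_pos, c(1, 2), mean) + pseudo) /
               (apply(x_neg, c(1, 2), mean) + pseudo))
  apply(x_eval, 3, function(w) sum(w * lod))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
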