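# Small in-code fixtures shared across test files.

tiny_config <- function(seed = 1, ...) {
  args <- list(
    n_subjects_discovery = 40, n_subjects_replication = 80,
    n_snps = 120, n_chromosomes = 2, n_genes = 12,
    missing_rate = 0.01, dropout_rate = 0.05, seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(synth_config, args)
}

# dosage matrix drawn under HWE at given frequencies, no LD
hwe_matrix <- function(n, freqs, seed = 1) {
  withr::with_seed(seed, {
    m <- length(freqs)
    matrix(rbinom(n * m, 2, rep(freqs, each = n)), n, m,
           dimnames = list(sprintf("s%03d", 1:n), sprintf("snp%03d", 1:m)))
  })
}
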