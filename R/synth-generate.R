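#' Generate a synthetic two-cohort pharmacogenomic study
#'
#' Draws genotypes, covariates and longitudinal symptom scores for the
#' discovery (HRSD17, endpoint week 6) and replication (QIDS-SR, endpoint
#' week 12) cohorts described by a [synth_config()].
#'
#' Genotypes are built from two independent haplotypes per subject, so every
#' SNP is in Hardy-Weinberg equilibrium within its subpopulation. Within an
#' LD block each haplotype allele copies its left neighbour with probability
#' `ld_rho` and is otherwise drawn fresh at that SNP's allele frequency,
#' giving a monotone decay of adjacent-SNP r2. The replication cohort is an
#' even mixture of two Balding-Nichols subpopulations whose allele-frequency
#' divergence is controlled by `ancestry_fst_like`.
#'
#' Symptom trajectories follow a latent-improvement model: each subject's
#' improvement fraction is `plogis(eta + e)` with logistic noise `e`, where
#' `eta` contains the intercept implied by `base_response_rate`, the causal
#' dosage effects (log allelic odds ratios), and the configured baseline
#' severity effect. The week-`W` score is the baseline reduced by the
#' improvement fraction reached at that week, so a subject responds
#' (>= 50 percent reduction at endpoint) with probability `plogis(eta)`
#' exactly, and the configured odds ratios are recoverable by logistic
#' regression of the derived phenotype on dosage.
#'
#' @param config A [synth_config()].
#' @return A `synth_study`: list with `discovery` and `replication` cohorts
#'   (each holding `genotypes` — subjects x SNPs minor-dosage matrix with
#'   `NA` for missing calls — plus `variants`, `subjects` and long-format
#'   `scores` tibbles), shared `genes` intervals, `pathways` list, the
#'   `truth` record (causal SNPs and spiked pathway id) and the `config`.
#' @export
#' @examples
#' study <- generate_cohorts(synth_config(n_snps = 300, seed = 42))
#' dim(study$discovery$genotypes)
generate_cohorts <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed_if(config$seed, {
    variants <- layout_variants(config)
    genes <- layout_genes(config)
    m <- nrow(variants)

    # base alt-allele frequencies; causal SNPs pinned to their configured MAF
    freqs <- runif(m, config$maf_range[1], config$maf_range[2])
    causal <- config$causal_spec
    if (!is.null(causal) && nrow(causal)) {
      freqs[match(causal$snp_id, variants$snp_id)] <- causal$maf
    }
    blocks <- ld_block_index(variants, config$ld_block_size)

    disc <- simulate_cohort(
      cohort = "discovery", n = config$n_subjects_discovery,
      variants = variants, freqs = list(freqs), blocks = blocks,
      config = config, instrument = "HRSD17",
      visit_weeks = config$visit_weeks_discovery
    )

    # replication: partial panel overlap + two Balding-Nichols subpopulations
    keep <- rep(TRUE, m)
    if (config$replication_snp_fraction < 1) {
      n_keep <- max(1L, round(config$replication_snp_fraction * m))
      keep_ids <- sample(variants$snp_id, n_keep)
      if (!is.null(causal)) keep_ids <- union(keep_ids, causal$snp_id)
      keep <- variants$snp_id %in% keep_ids
    }
    rep_freqs <- lapply(1:2, function(i) {
      bn_frequencies(freqs[keep], config$ancestry_fst_like)
    })
    repl <- simulate_cohort(
      cohort = "replication", n = config$n_subjects_replication,
      variants = variants[keep, ], freqs = rep_freqs, blocks = blocks[keep],
      config = config, instrument = "QIDS",
      visit_weeks = config$visit_weeks_replication,
      flip_effects = config$effect_flip_replication
    )

    truth <- list(
      causal = if (is.null(causal)) {
        tibble(snp_id = character(), or_response = numeric(),
               or_remission = numeric(), maf = numeric())
      } else causal,
      spiked_pathway = config$spiked_pathway
    )
    structure(
      list(discovery = disc, replication = repl, genes = genes,
           pathways = config$pathway_spec, truth = truth, config = config),
      class = "synth_study"
    )
  })
}

#' @export
print.synth_study <- function(x, ...) {
  cat("<synth_study>\n")
  for (ch in c("discovery", "replication")) {
    co <- x[[ch]]
    cat(sprintf("  %s: %d subjects x %d SNPs (%s, endpoint week %d)\n",
                ch, nrow(co$genotypes), ncol(co$genotypes), co$instrument,
                co$endpoint_week))
  }
  cat(sprintf("  genes: %d; pathways: %d; causal SNPs: %d\n",
              nrow(x$genes), length(x$pathways), nrow(x$truth$causal)))
  invisible(x)
}

# block index per SNP; blocks are runs of ld_block_size SNPs within a
# chromosome, the last block of each chromosome truncated
ld_block_index <- function(variants, block_size) {
  chr <- match(variants$chrom, unique(variants$chrom))
  within <- stats::ave(seq_len(nrow(variants)), chr, FUN = seq_along)
  chr * 1e6 + (within - 1L) %/% block_size
}

# Balding-Nichols subpopulation frequencies around base frequencies p
bn_frequencies <- function(p, fst) {
  if (fst <= 0) return(p)
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  q <- stats::rbeta(length(p), a, b)
  pmin(pmax(q, 1e-4), 1 - 1e-4)
}

# one haplotype matrix (n x m of 0/1 alt-allele indicators) with first-order
# Markov copying within LD blocks
simulate_haplotypes <- function(n, freqs, blocks, rho) {
  m <- length(freqs)
  H <- matrix(rbinom(n * m, 1L, rep(freqs, each = n)), n, m)
  if (rho <= 0 || m == 1) return(H)
  same <- c(FALSE, blocks[-1] == blocks[-m])
  cp <- matrix(runif(n * m) < rho, n, m)
  for (j in which(same)) {     # ascending order keeps the chain consistent
    idx <- cp[, j]
    H[idx, j] <- H[idx, j - 1]
  }
  H
}

simulate_genotypes <- function(n, freqs, blocks, rho) {
  simulate_haplotypes(n, freqs, blocks, rho) +
    simulate_haplotypes(n, freqs, blocks, rho)
}

instrument_range <- function(instrument) {
  switch(instrument, HRSD17 = c(0, 52), QIDS = c(0, 27),
         stopf("unknown instrument '%s'", instrument))
}

simulate_cohort <- function(cohort, n, variants, freqs, blocks, config,
                            instrument, visit_weeks, flip_effects = FALSE) {
  m <- nrow(variants)
  n_pops <- length(freqs)
  pop <- rep(seq_len(n_pops), length.out = n)
  pop <- pop[order(pop)]
  G <- matrix(0L, n, m)
  for (k in seq_len(n_pops)) {
    rows <- which(pop == k)
    G[rows, ] <- simulate_genotypes(length(rows), freqs[[k]], blocks,
                                    config$ld_rho)
  }
  dimnames(G) <- list(sprintf("%s_%04d", substr(cohort, 1, 4), seq_len(n)),
                      variants$snp_id)

  subjects <- tibble(
    subject_id = rownames(G),
    cohort = cohort,
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = sample(18:75, n, replace = TRUE),
    subpop = paste0("pop", pop)
  )

  rng <- instrument_range(instrument)
  baseline_mean <- if (instrument == "HRSD17") 22 else 15
  baseline_sd <- if (instrument == "HRSD17") 5 else 3.5
  baseline <- pmin(pmax(round(rnorm(n, baseline_mean, baseline_sd)),
                        rng[1] + 1), rng[2])

  # latent improvement: eta gives P(response) = plogis(eta) exactly
  eta <- rep(qlogis(config$base_response_rate), n)
  causal <- config$causal_spec
  if (!is.null(causal) && nrow(causal)) {
    sgn <- if (flip_effects) -1 else 1
    for (i in seq_len(nrow(causal))) {
      j <- match(causal$snp_id[i], variants$snp_id)
      if (is.na(j)) next
      dose <- G[, j]
      eta <- eta + sgn * (log(causal$or_response[i]) +
                            log(causal$or_remission[i])) *
        (dose - 2 * causal$maf[i])
    }
  }
  eta <- eta + config$baseline_severity_effect * (baseline - baseline_mean)
  improve <- plogis(eta + stats::rlogis(n))

  w_end <- max(visit_weeks)
  # saturating time course: most improvement happens early, so an LOCF
  # endpoint taken from a late-but-not-final visit barely attenuates the
  # genotype effect on the derived response phenotype
  time_frac <- function(w) (1 - exp(-3 * w / w_end)) / (1 - exp(-3))
  scores <- purrr::map_dfr(visit_weeks, function(w) {
    if (w == 0) {
      s <- baseline
    } else if (w == w_end) {
      s <- round(baseline * (1 - improve))
    } else {
      s <- round(baseline * (1 - improve * time_frac(w)) + rnorm(n, 0, 1))
    }
    tibble(subject_id = subjects$subject_id, week = w,
           score = pmin(pmax(s, rng[1]), rng[2]))
  })
  if (config$dropout_rate > 0) {
    post <- scores$week > 0
    drop <- post & (runif(nrow(scores)) < config$dropout_rate)
    scores <- scores[!drop, ]
  }
  scores <- arrange(scores, .data$subject_id, .data$week)

  if (config$missing_rate > 0) {
    G[runif(length(G)) < config$missing_rate] <- NA_integer_
  }

  structure(
    list(cohort = cohort, genotypes = G, variants = variants,
         subjects = subjects, scores = scores, instrument = instrument,
         visit_weeks = visit_weeks, endpoint_week = w_end),
    class = "synth_cohort"
  )
}
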