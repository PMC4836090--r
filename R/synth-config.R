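#' Configuration for the synthetic two-cohort study generator
#'
#' Builds the parameter object consumed by [generate_cohorts()]. The defaults
#' emulate the study the package analyses: a small discovery cohort of 109
#' inpatients rated on the 17-item Hamilton scale (HRSD17, weeks 0-6) and a
#' large replication cohort of 1677 outpatients rated on the QIDS-SR
#' (weeks 0-12), with LD-blocked genotypes, optional causal variants
#' concentrated in one "spiked" pathway, ancestry substructure in the
#' replication cohort only, and longitudinal visit dropout.
#'
#' The genome layout (variant positions, gene intervals, pathway membership)
#' is a deterministic function of the configuration, so causal variants can
#' be chosen by id before any genotype is drawn (see [spike_pathway()]).
#' Only allele frequencies, genotypes, covariates and symptom trajectories
#' are random.
#'
#' @param n_subjects_discovery,n_subjects_replication Cohort sizes.
#' @param n_snps Total number of biallelic SNPs on the panel.
#' @param n_chromosomes Number of chromosomes the panel is spread over.
#' @param ld_block_size SNPs per LD block; blocks never span chromosomes.
#' @param ld_rho Within-block haplotype copying probability in `[0, 1)`;
#'   adjacent-SNP r2 increases monotonically with this value.
#' @param maf_range Interval in (0, 0.5] from which per-SNP base minor allele
#'   frequencies are drawn uniformly.
#' @param missing_rate Per-call genotype missingness probability.
#' @param n_genes Number of gene intervals laid out evenly over the genome.
#' @param gene_length_bp Length of every gene interval in base pairs.
#' @param snp_spacing_bp Distance between adjacent SNPs in base pairs.
#' @param pathway_spec Named list mapping pathway ids to character vectors of
#'   member gene symbols. Default: ten equal-sized pathways partitioning the
#'   genes, `"PWY01"` ... `"PWY10"`.
#' @param causal_spec Tibble with columns `snp_id`, `or_response`,
#'   `or_remission` (allelic odds ratios; 1 = null) and `maf` (base minor
#'   allele frequency forced at that SNP). `NULL` means no causal variants.
#' @param spiked_pathway Id of the pathway the causal variants were placed
#'   in, recorded in the truth table (bookkeeping only).
#' @param base_response_rate Marginal probability of response for a subject
#'   with genotype at the allele-frequency expectation.
#' @param baseline_severity_effect Extra log-odds of improvement per
#'   (centred) baseline scale point; lower remission for severe baselines
#'   already arises mechanically because remission is an absolute cut-off.
#' @param ancestry_fst_like Balding-Nichols divergence parameter for the two
#'   replication-cohort subpopulations; 0 = homogeneous.
#' @param effect_flip_replication Should causal effect directions be
#'   reversed in the replication cohort? The downstream replication filter
#'   ignores direction, so either setting is a valid study.
#' @param replication_snp_fraction Fraction of panel SNPs genotyped in the
#'   replication cohort (causal SNPs are always retained), emulating partial
#'   overlap between genotyping platforms.
#' @param visit_weeks_discovery,visit_weeks_replication Ordered assessment
#'   weeks, starting at week 0 (baseline).
#' @param dropout_rate Probability that any post-baseline visit is missed.
#' @param seed RNG seed; `NULL` uses the session RNG.
#'
#' @return An object of class `synth_config` (a validated list).
#' @seealso [generate_cohorts()], [spike_pathway()], [write_study()]
#' @export
#' @examples
#' cfg <- synth_config(n_snps = 200, n_genes = 20, seed = 1)
#' study <- generate_cohorts(cfg)
synth_config <- function(n_subjects_discovery = 109,
                         n_subjects_replication = 1677,
                         n_snps = 2000,
                         n_chromosomes = 5,
                         ld_block_size = 10,
                         ld_rho = 0.5,
                         maf_range = c(0.05, 0.5),
                         missing_rate = 0.01,
                         n_genes = 100,
                         gene_length_bp = 10000,
                         snp_spacing_bp = 1000,
                         pathway_spec = NULL,
                         causal_spec = NULL,
                         spiked_pathway = NULL,
                         base_response_rate = 0.45,
                         baseline_severity_effect = 0,
                         ancestry_fst_like = 0.01,
                         effect_flip_replication = FALSE,
                         replication_snp_fraction = 1,
                         visit_weeks_discovery = c(0, 2, 4, 6),
                         visit_weeks_replication = c(0, 2, 4, 6, 9, 12),
                         dropout_rate = 0.1,
                         seed = NULL) {
  assert_count(n_subjects_discovery, "n_subjects_discovery", min = 2)
  assert_count(n_subjects_replication, "n_subjects_replication", min = 2)
  assert_count(n_snps, "n_snps")
  assert_count(n_chromosomes, "n_chromosomes")
  assert_count(ld_block_size, "ld_block_size")
  assert_count(n_genes, "n_genes")
  assert_count(gene_length_bp, "gene_length_bp")
  assert_count(snp_spacing_bp, "snp_spacing_bp")
  assert_prob(ld_rho, "ld_rho")
  if (ld_rho >= 1) stopf("`ld_rho` must be < 1")
  assert_prob(missing_rate, "missing_rate")
  assert_prob(dropout_rate, "dropout_rate")
  assert_prob(base_response_rate, "base_response_rate")
  assert_prob(replication_snp_fraction, "replication_snp_fraction")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stopf("`maf_range` must be an interval within (0, 0.5]")
  }
  if (ancestry_fst_like < 0 || ancestry_fst_like >= 1) {
    stopf("`ancestry_fst_like` must be in [0, 1)")
  }
  for (vw in list(visit_weeks_discovery, visit_weeks_replication)) {
    if (vw[1] != 0 || any(diff(vw) <= 0) || any(vw < 0)) {
      stopf("visit weeks must start at 0 (baseline) and strictly increase")
    }
  }

  cfg <- structure(
    list(
      n_subjects_discovery = as.integer(n_subjects_discovery),
      n_subjects_replication = as.integer(n_subjects_replication),
      n_snps = as.integer(n_snps),
      n_chromosomes = as.integer(n_chromosomes),
      ld_block_size = as.integer(ld_block_size),
      ld_rho = ld_rho,
      maf_range = maf_range,
      missing_rate = missing_rate,
      n_genes = as.integer(n_genes),
      gene_length_bp = as.integer(gene_length_bp),
      snp_spacing_bp = as.integer(snp_spacing_bp),
      pathway_spec = pathway_spec,
      causal_spec = causal_spec,
      spiked_pathway = spiked_pathway,
      base_response_rate = base_response_rate,
      baseline_severity_effect = baseline_severity_effect,
      ancestry_fst_like = ancestry_fst_like,
      effect_flip_replication = isTRUE(effect_flip_replication),
      replication_snp_fraction = replication_snp_fraction,
      visit_weeks_discovery = as.integer(visit_weeks_discovery),
      visit_weeks_replication = as.integer(visit_weeks_replication),
      dropout_rate = dropout_rate,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "synth_config"
  )

  if (is.null(cfg$pathway_spec)) cfg$pathway_spec <- default_pathways(cfg)
  validate_pathways(cfg)
  if (!is.null(cfg$causal_spec)) cfg$causal_spec <- validate_causal(cfg)
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  cohorts: discovery n=%d (HRSD17), replication n=%d (QIDS-SR)\n",
              x$n_subjects_discovery, x$n_subjects_replication))
  cat(sprintf("  panel: %d SNPs on %d chromosomes, LD blocks of %d (rho=%.2f)\n",
              x$n_snps, x$n_chromosomes, x$ld_block_size, x$ld_rho))
  cat(sprintf("  genes: %d x %d bp; pathways: %d\n",
              x$n_genes, x$gene_length_bp, length(x$pathway_spec)))
  n_causal <- if (is.null(x$causal_spec)) 0L else nrow(x$causal_spec)
  cat(sprintf("  causal SNPs: %d%s\n", n_causal,
              if (!is.null(x$spiked_pathway))
                sprintf(" (spiked pathway %s)", x$spiked_pathway) else ""))
  invisible(x)
}

# deterministic variant layout: ids, chromosomes, evenly spaced positions,
# cycled allele pairs
layout_variants <- function(config) {
  n <- config$n_snps
  per_chr <- diff(round(seq(0, n, length.out = config$n_chromosomes + 1)))
  chrom <- rep(paste0("chr", seq_len(config$n_chromosomes)), per_chr)
  pos <- unlist(lapply(per_chr, function(k) seq_len(k) * config$snp_spacing_bp))
  pairs <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"), nrow = 2)
  idx <- (seq_len(n) - 1L) %% ncol(pairs) + 1L
  tibble(
    snp_id = sprintf("snp%05d", seq_len(n)),
    chrom = chrom,
    pos = as.integer(pos),
    ref = pairs[1, idx],
    alt = pairs[2, idx]
  )
}

# deterministic gene layout: genes centred in equal-width slots per chromosome
layout_genes <- function(config) {
  n <- config$n_snps
  per_chr <- diff(round(seq(0, n, length.out = config$n_chromosomes + 1)))
  genes_per_chr <- diff(round(seq(0, config$n_genes,
                                  length.out = config$n_chromosomes + 1)))
  out <- vector("list", config$n_chromosomes)
  g0 <- 0L
  for (c in seq_len(config$n_chromosomes)) {
    ng <- genes_per_chr[c]
    if (ng == 0) next
    chr_len <- per_chr[c] * config$snp_spacing_bp
    slot <- chr_len / ng
    centre <- (seq_len(ng) - 0.5) * slot
    start <- pmax(1L, as.integer(round(centre - config$gene_length_bp / 2)))
    out[[c]] <- tibble(
      gene = sprintf("gene%03d", g0 + seq_len(ng)),
      chrom = paste0("chr", c),
      start = start,
      end = start + config$gene_length_bp - 1L
    )
    g0 <- g0 + ng
  }
  bind_rows(out)
}

default_pathways <- function(config) {
  genes <- layout_genes(config)$gene
  k <- max(1L, min(10L, length(genes)))
  grp <- cut(seq_along(genes), breaks = k, labels = FALSE)
  split(genes, sprintf("PWY%02d", grp))
}

validate_pathways <- function(config) {
  genes <- layout_genes(config)$gene
  unknown <- setdiff(unlist(config$pathway_spec), genes)
  if (length(unknown)) {
    stopf("pathway_spec names genes absent from the layout: %s",
          paste(head(unknown, 3), collapse = ", "))
  }
  invisible(config)
}

validate_causal <- function(config) {
  cs <- as_tibble(config$causal_spec)
  needed <- c("snp_id", "or_response", "or_remission", "maf")
  if (!"or_remission" %in% names(cs)) cs$or_remission <- 1
  if (!"or_response" %in% names(cs)) cs$or_response <- 1
  missing_cols <- setdiff(needed, names(cs))
  if (length(missing_cols)) {
    stopf("causal_spec lacks columns: %s", paste(missing_cols, collapse = ", "))
  }
  ids <- layout_variants(config)$snp_id
  bad <- setdiff(cs$snp_id, ids)
  if (length(bad)) {
    stopf("causal_spec names SNPs absent from the panel: %s",
          paste(head(bad, 3), collapse = ", "))
  }
  if (any(cs$maf <= 0 | cs$maf > 0.5)) stopf("causal maf must be in (0, 0.5]")
  if (any(cs$or_response <= 0 | cs$or_remission <= 0)) {
    stopf("causal odds ratios must be positive")
  }
  cs
}

#' Place causal variants inside one pathway's genes
#'
#' Convenience constructor for spiked studies: selects `n_causal_per_gene`
#' SNPs strictly inside each member gene of `pathway` (evenly spaced over the
#' gene body, deterministic given the configuration) and assigns them the
#' given allelic odds ratio and a base minor allele frequency evenly spread
#' over `maf`.
#'
#' @param config A [synth_config()].
#' @param pathway Pathway id to spike; default the first pathway.
#' @param n_causal_per_gene Causal SNPs per member gene (genes with fewer
#'   interior SNPs contribute what they have).
#' @param or_response,or_remission Allelic odds ratios shared by all causal
#'   SNPs (1 = no effect on that phenotype).
#' @param maf Length-2 interval over which causal base MAFs are evenly
#'   spaced.
#' @return The configuration with `causal_spec` and `spiked_pathway` filled.
#' @export
#' @examples
#' cfg <- spike_pathway(synth_config(n_snps = 500, seed = 7), or_response = 2)
spike_pathway <- function(config, pathway = NULL, n_causal_per_gene = 5,
                          or_response = 2, or_remission = 1,
                          maf = c(0.2, 0.3)) {
  stopifnot(inherits(config, "synth_config"))
  pathway <- pathway %||% names(config$pathway_spec)[1]
  members <- config$pathway_spec[[pathway]]
  if (is.null(members)) stopf("no pathway named '%s'", pathway)
  variants <- layout_variants(config)
  genes <- layout_genes(config)
  picks <- character(0)
  for (g in members) {
    gi <- genes[genes$gene == g, ]
    inside <- variants$snp_id[variants$chrom == gi$chrom &
                                variants$pos >= gi$start &
                                variants$pos <= gi$end]
    if (!length(inside)) next
    k <- min(n_causal_per_gene, length(inside))
    picks <- c(picks, inside[unique(round(seq(1, length(inside),
                                              length.out = k)))])
  }
  picks <- unique(picks)
  if (!length(picks)) stopf("pathway '%s' contains no interior SNPs", pathway)
  config$causal_spec <- tibble(
    snp_id = picks,
    or_response = or_response,
    or_remission = or_remission,
    maf = seq(maf[1], maf[2], length.out = length(picks))
  )
  config$spiked_pathway <- pathway
  config$causal_spec <- validate_causal(config)
  config
}
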