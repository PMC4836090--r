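# End-to-end orchestration: simulate (or load) -> QC -> phenotypes ->
# association -> replication filter -> annotation -> gene/pathway set
# analysis, with per-stage seeds and a reconciling run report.

#' Read a study directory written by [write_study()]
#'
#' @param dir Directory containing `discovery.ped/.map`,
#'   `replication.ped/.map`, per-cohort `*_scores.tsv`, `genes.bed` and
#'   `pathways.gmt`.
#' @return A list shaped like a `synth_study` (without a truth record
#'   unless `truth.tsv` is present).
#' @export
read_study <- function(dir) {
  need <- c("discovery.ped", "discovery.map", "replication.ped",
            "replication.map", "discovery_scores.tsv",
            "replication_scores.tsv", "genes.bed", "pathways.gmt")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stopf("study directory '%s' lacks: %s", dir,
          paste(missing, collapse = ", "))
  }
  read_cohort <- function(ch, instrument, visit_weeks) {
    pm <- read_ped_map(file.path(dir, paste0(ch, ".ped")),
                       file.path(dir, paste0(ch, ".map")))
    sc <- readr::read_tsv(file.path(dir, paste0(ch, "_scores.tsv")),
                          show_col_types = FALSE)
    subjects <- distinct(sc, .data$subject_id, .data$cohort, .data$sex,
                         .data$age, .data$subpop)
    list(cohort = ch, genotypes = pm$genotypes,
         variants = rename(pm$variants, ref = "other", alt = "counted"),
         subjects = subjects,
         scores = sc[, c("subject_id", "week", "score")],
         instrument = instrument,
         endpoint_week = max(sc$week))
  }
  study <- list(
    discovery = read_cohort("discovery", "HRSD17"),
    replication = read_cohort("replication", "QIDS"),
    genes = read_gene_bed(file.path(dir, "genes.bed")),
    pathways = read_gmt(file.path(dir, "pathways.gmt")),
    truth = NULL
  )
  tr_path <- file.path(dir, "truth.tsv")
  if (file.exists(tr_path)) {
    tr <- readr::read_tsv(tr_path, show_col_types = FALSE)
    study$truth <- list(causal = tr,
                        spiked_pathway = tr$spiked_pathway[1] %||% NA)
  }
  class(study) <- "synth_study"
  study
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e),
          class = "pathgwas_stage_error")
  })
}

#' Run the full multi-level replication analysis
#'
#' Executes the staged analysis on a synthetic or loaded two-cohort study:
#' quality control per cohort, phenotype derivation, per-SNP logistic
#' association with phenotype-specific covariates (ancestry components in
#' the replication cohort), the cross-cohort replication filter, SNP-to-
#' gene annotation, and matched-random-set enrichment at the gene and
#' pathway levels.
#'
#' @param study A [synth_config()] (simulated on the fly), a
#'   `synth_study`, or a directory path for [read_study()].
#' @param phenotypes Phenotypes to analyse (`"response"`, `"remission"`).
#' @param thresholds Member-significance thresholds for set analysis.
#' @param n_perm Permutations per set.
#' @param seed Base seed; stage seeds are derived from it (generation uses
#'   the config's own seed when set, else this one).
#' @param alpha Family-wise error rate for Bonferroni layers.
#' @param snp_alpha Nominal threshold of the SNP replication filter.
#' @param qc_args Named list of overrides for [run_qc()] (e.g.
#'   `list(relatedness = FALSE)`).
#' @param ancestry_k MDS components used as replication-cohort covariates.
#' @param min_baseline_replication Entry-severity threshold on the
#'   replication baseline score.
#' @param gate Permutation gate passed to [run_set_analysis()].
#' @param levels Which set-analysis levels to run (`"genes"`,
#'   `"pathways"`).
#' @param out_dir Optional directory: stage outputs are written as TSV.
#' @return A `pipeline_result` list: `qc`, `phenotypes`, `ancestry`,
#'   `gwas` (per phenotype x cohort), `replication` tables, `gene_lists`,
#'   `annotation`, `enrichment` (`genes` and `pathways` per phenotype),
#'   `config`, and `counts` reconciling variant totals across stages.
#' @export
run_pipeline <- function(study,
                         phenotypes = c("response", "remission"),
                         thresholds = c(0.05, 0.01),
                         n_perm = 100000,
                         seed = NULL,
                         alpha = 0.05,
                         snp_alpha = 0.05,
                         qc_args = list(),
                         ancestry_k = 2,
                         min_baseline_replication = 10,
                         gate = "nominal",
                         levels = c("genes", "pathways"),
                         out_dir = NULL) {
  levels <- match.arg(levels, several.ok = TRUE)
  phenotypes <- match.arg(phenotypes, several.ok = TRUE)
  if (inherits(study, "synth_config")) {
    if (is.null(study$seed) && !is.null(seed)) study$seed <- as.integer(seed)
    study <- pipeline_stage("simulate", generate_cohorts(study))
  } else if (is.character(study)) {
    study <- pipeline_stage("load", read_study(study))
  }
  stopifnot(inherits(study, "synth_study"))

  qc <- list(); pheno <- list(); ancestry <- list(); covars <- list()
  for (ch in c("discovery", "replication")) {
    co <- study[[ch]]
    qc[[ch]] <- pipeline_stage(paste0("qc_", ch), do.call(run_qc, c(
      list(genotypes = co$genotypes, variants = co$variants), qc_args)))
    pheno[[ch]] <- pipeline_stage(paste0("pheno_", ch), derive_phenotypes(
      co$scores, co$instrument, co$endpoint_week,
      min_baseline = if (ch == "replication") min_baseline_replication))
    if (ch == "replication" && ancestry_k > 0) {
      # cluster labels are not used downstream; only the components enter
      # the association models as covariates
      ancestry[[ch]] <- pipeline_stage("ancestry", ancestry_components(
        qc[[ch]]$genotypes, k_components = ancestry_k, k_clusters = NULL))
    }
  }

  gwas <- list(); repl <- list(); gene_lists <- list()
  panel <- distinct(bind_rows(qc$discovery$variants[, c("snp_id", "chrom", "pos")],
                              qc$replication$variants[, c("snp_id", "chrom", "pos")]))
  annotation <- pipeline_stage("annotate",
                               annotate_snps(panel, study$genes,
                                             window = 20000))
  enrichment <- list()
  pathway_sets <- pipeline_stage("expand_pathways",
                                 expand_pathways(study$pathways, annotation))

  for (ph in phenotypes) {
    gwas[[ph]] <- list()
    for (ch in c("discovery", "replication")) {
      co <- study[[ch]]
      pc <- pheno[[ch]]
      eligible <- pc[pc$eligible, ]
      outcome <- setNames(as.numeric(eligible[[ph]]), eligible$subject_id)
      cv <- build_covariates(co$subjects, phenotype = ph,
                             baseline = pc[, c("subject_id", "baseline")],
                             ancestry = ancestry[[ch]])
      gwas[[ph]][[ch]] <- pipeline_stage(
        paste("gwas", ph, ch, sep = "_"),
        run_gwas(qc[[ch]]$genotypes, outcome, covariates = cv,
                 variants = qc[[ch]]$variants, phenotype = ph, cohort = ch))
    }
    repl[[ph]] <- pipeline_stage(
      paste0("replication_filter_", ph),
      replication_filter(gwas[[ph]]$discovery, gwas[[ph]]$replication,
                         alpha = snp_alpha))
    rep_ids <- attr(repl[[ph]], "replicated")
    gene_lists[[ph]] <- pipeline_stage(
      paste0("gene_list_", ph),
      suppressWarnings(build_gene_sets(annotation, rep_ids)))

    set_seed <- if (is.null(seed)) NULL else as.integer(seed) + 1000L
    enrichment[[ph]] <- list()
    if ("genes" %in% levels && length(gene_lists[[ph]])) {
      gene_sets <- expand_pathways(
        setNames(as.list(gene_lists[[ph]]), gene_lists[[ph]]), annotation)
      enrichment[[ph]]$genes <- pipeline_stage(
        paste0("gsea_genes_", ph),
        run_set_analysis(gene_sets, annotation, cohorts = gwas[[ph]],
                         thresholds = thresholds, n_perm = n_perm,
                         seed = set_seed, alpha = alpha, gate = gate))
    }
    if ("pathways" %in% levels) {
      enrichment[[ph]]$pathways <- pipeline_stage(
        paste0("gsea_pathways_", ph),
        run_set_analysis(pathway_sets, annotation, cohorts = gwas[[ph]],
                         thresholds = thresholds, n_perm = n_perm,
                         seed = if (is.null(set_seed)) NULL
                                else set_seed + 1L,
                         alpha = alpha, gate = gate))
    }
  }

  counts <- tibble(
    cohort = c("discovery", "replication"),
    variants_in = c(qc$discovery$input_counts["variants"],
                    qc$replication$input_counts["variants"]),
    variants_qc = c(ncol(qc$discovery$genotypes),
                    ncol(qc$replication$genotypes)),
    subjects_in = c(qc$discovery$input_counts["subjects"],
                    qc$replication$input_counts["subjects"]),
    subjects_qc = c(nrow(qc$discovery$genotypes),
                    nrow(qc$replication$genotypes))
  )

  result <- structure(
    list(qc = qc, phenotypes = pheno, ancestry = ancestry, gwas = gwas,
         replication = repl, gene_lists = gene_lists,
         annotation = annotation, pathway_sets = pathway_sets,
         enrichment = enrichment, counts = counts,
         truth = study$truth,
         settings = list(phenotypes = phenotypes, thresholds = thresholds,
                         n_perm = n_perm, seed = seed, alpha = alpha,
                         snp_alpha = snp_alpha, qc_args = qc_args,
                         gate = gate)),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$counts)
  for (ph in names(x$replication)) {
    nrep <- length(attr(x$replication[[ph]], "replicated"))
    cat(sprintf("  %s: %d replicated SNPs, %d genes listed\n", ph, nrep,
                length(x$gene_lists[[ph]])))
    pw <- x$enrichment[[ph]]$pathways
    if (!is.null(pw)) {
      rs <- replicated_sets(pw)
      cat(sprintf("    replicated pathways (p<0.05 both cohorts): %s\n",
                  if (nrow(rs)) paste(rs$set_id, collapse = ", ")
                  else "none"))
    }
  }
  invisible(x)
}

# serialise the tabular stage outputs of a pipeline run
write_pipeline_result <- function(result, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stopf("cannot create output directory '%s'", dir)
  }
  wt <- function(x, name) readr::write_tsv(x, file.path(dir, name))
  for (ch in names(result$qc)) {
    wt(result$qc[[ch]]$report, sprintf("qc_report_%s.tsv", ch))
    wt(result$phenotypes[[ch]], sprintf("phenotypes_%s.tsv", ch))
  }
  for (ph in names(result$gwas)) {
    for (ch in names(result$gwas[[ph]])) {
      wt(result$gwas[[ph]][[ch]], sprintf("assoc_%s_%s.tsv", ph, ch))
    }
    wt(result$replication[[ph]], sprintf("replicated_snps_%s.tsv", ph))
    for (lvl in names(result$enrichment[[ph]])) {
      wt(result$enrichment[[ph]][[lvl]],
         sprintf("enrichment_%s_%s.tsv", lvl, ph))
    }
  }
  wt(result$counts, "counts.tsv")
  invisible(dir)
}
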