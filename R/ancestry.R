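#' Ancestry components by IBS distance, MDS and complete-linkage clustering
#'
#' Computes the pairwise identity-by-state distance `1 - mean IBS share`
#' (share = IBS count / 2 per SNP over jointly non-missing SNPs), projects
#' it to `k_components` dimensions by classical multidimensional scaling,
#' and cuts a complete-linkage agglomerative clustering of the same
#' distance at `k_clusters`. The components are intended as association
#' covariates for stratified cohorts.
#'
#' @param genotypes Subjects x SNPs minor-dosage matrix (post-QC).
#' @param k_components Number of MDS axes to return.
#' @param k_clusters Number of clusters to cut the dendrogram at; `NULL`
#'   skips the clustering step (no `cluster` column).
#' @param max_snps Upper bound on the number of (evenly thinned) SNPs used;
#'   IBS sharing stabilises quickly and thinning keeps the cost linear in
#'   panel size.
#' @return Tibble with `subject_id`, `MDS1` ... `MDSk` and `cluster`
#'   (integer labels).
#' @export
ancestry_components <- function(genotypes, k_components = 2, k_clusters = 2,
                                max_snps = 500) {
  check_dosage(genotypes)
  n <- nrow(genotypes)
  if (k_components >= n) stopf("`k_components` must be < number of subjects")
  if (!is.null(k_clusters) && (k_clusters < 1 || k_clusters > n)) {
    stopf("invalid `k_clusters`")
  }
  m <- ncol(genotypes)
  if (m > max_snps) {
    genotypes <- genotypes[, round(seq(1, m, length.out = max_snps)),
                           drop = FALSE]
  }
  cc <- ibs_counts(genotypes)
  share <- (2 * cc$ibs2 + cc$ibs1) / (2 * pmax(cc$nonmiss, 1))
  D <- 1 - share
  diag(D) <- 0
  mds <- cmdscale(as.dist(D), k = k_components)
  out <- tibble(subject_id = rownames(genotypes) %||%
                  sprintf("subj%04d", seq_len(n)))
  for (k in seq_len(k_components)) out[[paste0("MDS", k)]] <- mds[, k]
  if (!is.null(k_clusters)) {
    cl <- cutree(hclust(as.dist(D), method = "complete"), k = k_clusters)
    out$cluster <- as.integer(cl)
  }
  out
}
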