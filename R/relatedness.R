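# Identity-by-state sharing, method-of-moments identity-by-descent
# (PI_HAT), and the iterative exclusion of related subjects.

# indicator crossproducts shared by relatedness and ancestry computations:
# per-pair counts of IBS0 / IBS1 / IBS2 SNPs and jointly non-missing SNPs
ibs_counts <- function(geno) {
  I0 <- (geno == 0); I0[is.na(I0)] <- FALSE; storage.mode(I0) <- "double"
  I1 <- (geno == 1); I1[is.na(I1)] <- FALSE; storage.mode(I1) <- "double"
  I2 <- (geno == 2); I2[is.na(I2)] <- FALSE; storage.mode(I2) <- "double"
  ibs2 <- tcrossprod(I0) + tcrossprod(I1) + tcrossprod(I2)
  opp <- tcrossprod(I0, I2)
  ibs0 <- opp + t(opp)
  nonmiss <- tcrossprod(I0 + I1 + I2)
  list(ibs0 = ibs0, ibs1 = nonmiss - ibs0 - ibs2, ibs2 = ibs2,
       nonmiss = nonmiss)
}

#' Method-of-moments relatedness (PI_HAT) for all subject pairs
#'
#' Estimates the IBD coefficients P(IBD = 0, 1, 2) for every pair from the
#' observed identity-by-state sharing and its expectation under the supplied
#' allele frequencies (the PLINK method-of-moments approach, without the
#' small-sample bias correction), and reports `pi_hat = P(IBD=2) +
#' P(IBD=1)/2`, clipped to `[0, 1]`. Expected sharing for pairs with missing
#' calls is scaled by the pair's non-missing fraction, which assumes
#' missingness is unrelated to genotype.
#'
#' @param genotypes Subjects x SNPs minor-dosage matrix, ideally the QC'd,
#'   LD-pruned panel.
#' @param freqs Per-SNP minor allele frequencies; estimated from the matrix
#'   when omitted.
#' @return Tibble with one row per unordered pair: `subject_a`, `subject_b`,
#'   `ibs0`, `ibs1`, `ibs2` (proportions summing to 1) and `pi_hat`.
#' @export
estimate_relatedness <- function(genotypes, freqs = NULL) {
  check_dosage(genotypes)
  n <- nrow(genotypes)
  if (n < 2) stopf("at least 2 subjects required")
  if (is.null(freqs)) freqs <- col_freqs(genotypes)$maf
  p <- pmin(pmax(freqs, 1e-6), 0.5)
  q <- 1 - p
  # per-SNP IBS-class probabilities conditional on the IBD state
  e0_z0 <- sum(2 * p^2 * q^2)
  e1_z0 <- sum(4 * p^3 * q + 4 * p * q^3)
  e2_z0 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e1_z1 <- sum(2 * p^2 * q + 2 * p * q^2)
  e2_z1 <- sum(p^3 + q^3 + p^2 * q + p * q^2)
  m <- ncol(genotypes)

  cc <- ibs_counts(genotypes)
  ut <- upper.tri(cc$nonmiss)
  nn <- cc$nonmiss[ut]
  scale <- pmax(nn, 1) / m
  z0 <- cc$ibs0[ut] / (e0_z0 * scale)
  z1 <- (cc$ibs1[ut] - z0 * e1_z0 * scale) / (e1_z1 * scale)
  z2 <- (cc$ibs2[ut] - z0 * e2_z0 * scale - z1 * e2_z1 * scale) / pmax(nn, 1)
  pi_hat <- pmin(pmax(z2 + z1 / 2, 0), 1)

  ids <- rownames(genotypes) %||% sprintf("subj%04d", seq_len(n))
  idx <- which(ut, arr.ind = TRUE)
  tibble(
    subject_a = ids[idx[, 1]], subject_b = ids[idx[, 2]],
    ibs0 = cc$ibs0[ut] / pmax(nn, 1),
    ibs1 = cc$ibs1[ut] / pmax(nn, 1),
    ibs2 = cc$ibs2[ut] / pmax(nn, 1),
    pi_hat = pi_hat
  )
}

#' Choose subjects to exclude from related pairs
#'
#' Treats pairs with `pi_hat` above the threshold as edges of a graph and,
#' within each connected component, repeatedly removes the subject with the
#' most remaining above-threshold partners (ties: higher genotype
#' missingness, then the lexicographically later subject id) until no edge
#' remains.
#'
#' @param estimates Pair tibble from [estimate_relatedness()].
#' @param threshold Exclude pairs with `pi_hat` strictly above this (default
#'   0.1875, halfway between second- and third-degree relatives).
#' @param missingness Optional named per-subject missingness vector used as
#'   the first tie-break.
#' @return Character vector of excluded subject ids (possibly empty).
#' @export
exclude_related <- function(estimates, threshold = 0.1875,
                            missingness = NULL) {
  edges <- estimates[estimates$pi_hat > threshold,
                     c("subject_a", "subject_b")]
  excluded <- character(0)
  while (nrow(edges)) {
    deg <- sort(table(c(edges$subject_a, edges$subject_b)), decreasing = TRUE)
    top <- names(deg)[deg == max(deg)]
    if (length(top) > 1 && !is.null(missingness)) {
      mr <- missingness[top]
      mr[is.na(mr)] <- -Inf
      top <- top[mr == max(mr)]
    }
    victim <- max(top)          # later id on a full tie
    excluded <- c(excluded, victim)
    edges <- edges[edges$subject_a != victim & edges$subject_b != victim, ,
                   drop = FALSE]
  }
  excluded
}
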