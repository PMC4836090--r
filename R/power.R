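# Power calculations: case-control allelic SNP power (genetic power
# calculator style) and set-level proportion power (G*Power style), both
# one-sample exact and two-proportion variants.

#' Case-control power of the 1-df allelic association test
#'
#' The case minor-allele frequency implied by the allelic odds ratio is
#' `p1 = OR * p / (1 - p + OR * p)`; power is that of the two-sided 1-df
#' chi-square test comparing allele frequencies between `2 * n_cases` case
#' alleles and `2 * n_controls` control alleles, via its noncentrality
#' parameter.
#'
#' @param maf_controls Control minor-allele frequency.
#' @param allelic_or Allelic odds ratio (1 = null).
#' @param n_cases,n_controls Group sizes (subjects).
#' @param alpha Two-sided type-I error rate.
#' @return Power in `[0, 1]`; equals `alpha` when `allelic_or = 1`.
#' @export
#' @examples
#' snp_cc_power(0.2, 2.84, 55, 54, alpha = 0.05)
snp_cc_power <- function(maf_controls, allelic_or, n_cases, n_controls,
                         alpha = 0.05) {
  assert_prob(alpha, "alpha")
  if (maf_controls <= 0 || maf_controls >= 1) stopf("invalid `maf_controls`")
  if (allelic_or <= 0) stopf("`allelic_or` must be positive")
  p0 <- maf_controls
  p1 <- allelic_or * p0 / (1 - p0 + allelic_or * p0)
  a1 <- 2 * n_cases          # allele counts
  a0 <- 2 * n_controls
  pbar <- (a1 * p1 + a0 * p0) / (a1 + a0)
  v <- pbar * (1 - pbar) * (1 / a1 + 1 / a0)
  ncp <- (p1 - p0)^2 / v
  pchisq(qchisq(1 - alpha, df = 1), df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Exact one-sample binomial power for a proportion of significant SNPs
#'
#' The rejection region is the smallest count `k` with
#' `P(X >= k | n, p0) <= alpha`; power is `P(X >= k | n, p1)`. This is the
#' exact-test power for detecting that a set's proportion of sub-threshold
#' SNPs exceeds the chance proportion `p0`.
#'
#' @param n Number of SNPs in the set.
#' @param p0 Chance proportion (0.05 for the 0.05 member threshold).
#' @param p1 Alternative proportion.
#' @param alpha Test size.
#' @return Power; 0 with a warning when no rejection region is achievable.
#' @export
#' @examples
#' set_power_one_sample_exact(26, 0.05, 0.34, 0.0006)
set_power_one_sample_exact <- function(n, p0, p1, alpha) {
  assert_count(n, "n")
  if (n > 10000) stopf("`n` above the enumeration bound of 10000")
  assert_prob(p0, "p0"); assert_prob(p1, "p1"); assert_prob(alpha, "alpha")
  k <- 0:n
  tail0 <- 1 - pbinom(k - 1, n, p0)        # P(X >= k | p0)
  ok <- which(tail0 <= alpha)
  if (!length(ok)) {
    warnf("alpha %.2g unattainable at n = %d: power 0", alpha, n)
    return(0)
  }
  k_crit <- k[min(ok)]
  1 - pbinom(k_crit - 1, n, p1)
}

#' Two-group power for comparing proportions of significant SNPs
#'
#' `method = "normal"`: standard two-proportion z-test power with the
#' pooled-null and alternative variances and two-sided `alpha`.
#' `method = "exact"`: exact power of the two-sided Fisher test, summing
#' the joint binomial probability of every outcome pair whose Fisher p is
#' at or below `alpha` (limited to `n1, n2 <= 200`).
#'
#' @param n1,n2 SNPs per group (null-proportion group first).
#' @param p0 Null/chance proportion (group 1).
#' @param p1 Alternative proportion (group 2).
#' @param alpha Two-sided type-I error rate.
#' @param method `"normal"` or `"exact"`.
#' @return Power in `[0, 1]`.
#' @export
#' @examples
#' set_power_two_prop(7531, 7531, 0.05, 0.063, 0.007)
set_power_two_prop <- function(n1, n2, p0, p1, alpha,
                               method = c("normal", "exact")) {
  method <- match.arg(method)
  assert_count(n1, "n1"); assert_count(n2, "n2")
  assert_prob(p0, "p0"); assert_prob(p1, "p1"); assert_prob(alpha, "alpha")
  if (method == "normal") {
    pbar <- (n1 * p0 + n2 * p1) / (n1 + n2)
    se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
    se1 <- sqrt(p0 * (1 - p0) / n1 + p1 * (1 - p1) / n2)
    za <- qnorm(1 - alpha / 2)
    d <- abs(p1 - p0)
    pnorm((d - za * se0) / se1) + pnorm((-d - za * se0) / se1)
  } else {
    if (n1 > 200 || n2 > 200) stopf("exact method limited to n1, n2 <= 200")
    pr1 <- dbinom(0:n1, n1, p0)
    pr2 <- dbinom(0:n2, n2, p1)
    power <- 0
    for (x2 in 0:n2) {
      if (pr2[x2 + 1] < 1e-14) next
      rej <- vapply(0:n1, function(x1) {
        p <- tryCatch(
          fisher_enrichment(x2, n2 - x2, x1, n1 - x1)$fisher_p,
          pathgwas_degenerate = function(e) 1)
        p <= alpha
      }, logical(1))
      power <- power + pr2[x2 + 1] * sum(pr1[rej])
    }
    power
  }
}
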