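# Variant- and subject-level quality control: MAF, call rate, Hardy-Weinberg
# exact test, windowed LD pruning, and the ordered filter driver.

#' Minor allele frequency of one variant
#'
#' @param calls Dosage vector in `{0, 1, 2, NA}` counting copies of the alt
#'   allele.
#' @return List with `maf`, `minor` (`"alt"` or `"ref"`; alt on a tie) and
#'   `n_called`.
#' @export
#' @examples
#' compute_maf(c(0, 1, 2, 1))
compute_maf <- function(calls) {
  ok <- !is.na(calls)
  if (!any(ok)) stopf("all calls missing: MAF undefined")
  f_alt <- sum(calls[ok]) / (2 * sum(ok))
  list(maf = min(f_alt, 1 - f_alt),
       minor = if (f_alt <= 0.5) "alt" else "ref",
       n_called = sum(ok))
}

# columnwise alt-allele frequency and call rate for a dosage matrix
col_freqs <- function(geno) {
  called <- colSums(!is.na(geno))
  f_alt <- ifelse(called > 0, colSums(geno, na.rm = TRUE) / (2 * called), NA)
  list(f_alt = f_alt, maf = pmin(f_alt, 1 - f_alt),
       call_rate = called / nrow(geno))
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Conditional on the observed allele counts, sums the probabilities of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed genotype table (two-sided by probability ordering, no mid-p
#' correction).
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return Exact p-value in (0, 1].
#' @export
#' @examples
#' hwe_exact_test(5, 0, 5)   # extreme heterozygote deficit
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) stopf("at least one genotype required")
  n_rare <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  h <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  h1 <- (n_rare - h) / 2                       # rare-allele homozygotes
  h2 <- n - h - h1
  logp <- lgamma(n + 1) - lgamma(h1 + 1) - lgamma(h2 + 1) - lgamma(h + 1) +
    h * log(2) -
    (lgamma(2 * n + 1) - lgamma(n_rare + 1) - lgamma(2 * n - n_rare + 1))
  p_all <- exp(logp - max(logp))
  p_all <- p_all / sum(p_all)
  p_obs <- p_all[match(n_het, h)]
  min(1, sum(p_all[p_all <= p_obs * (1 + 1e-7)]))
}

# vectorised HWE p over the columns of a dosage matrix
col_hwe <- function(geno) {
  vapply(seq_len(ncol(geno)), function(j) {
    g <- geno[, j]
    hwe_exact_test(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                   sum(g == 2, na.rm = TRUE))
  }, numeric(1))
}

#' Composite LD r2 between two variants
#'
#' Squared Pearson correlation of additive dosages over pairwise-complete
#' subjects (composite, phase-free LD).
#'
#' @param calls_a,calls_b Dosage vectors.
#' @return r2 in `[0, 1]`.
#' @export
genotype_r2 <- function(calls_a, calls_b) {
  ok <- !is.na(calls_a) & !is.na(calls_b)
  if (sum(ok) < 2) {
    stopf("fewer than 2 pairwise-complete subjects",
          class = "pathgwas_ld_undefined")
  }
  a <- calls_a[ok]; b <- calls_b[ok]
  if (sd(a) == 0 || sd(b) == 0) {
    stopf("zero dosage variance on complete subset: LD undefined",
          class = "pathgwas_ld_undefined")
  }
  cor(a, b)^2
}

#' Greedy windowed LD pruning
#'
#' Slides a window of `window_snps` position-sorted variants (advancing by
#' `step_snps`) along each chromosome. Within a window, while any retained
#' pair has r2 above the threshold, the pair with the largest r2 is located
#' and its lower-MAF member dropped (tie: the later position goes). Pairs
#' with undefined LD (monomorphic on the complete subset) are unprunable.
#'
#' @param genotypes Subjects x SNPs dosage matrix.
#' @param variants Tibble with `snp_id`, `chrom`, `pos` matching the matrix
#'   columns, position-sorted within chromosome.
#' @param r2_threshold Prune when r2 is strictly above this value.
#' @param window_snps,step_snps Window size and step in SNPs.
#' @return Character vector of retained `snp_id`s.
#' @export
prune_ld <- function(genotypes, variants, r2_threshold = 0.8,
                     window_snps = 50, step_snps = window_snps %/% 2) {
  if (window_snps < 2) stopf("`window_snps` must be >= 2")
  if (step_snps < 1) stopf("`step_snps` must be >= 1")
  stopifnot(ncol(genotypes) == nrow(variants))
  keep <- rep(TRUE, nrow(variants))
  fr <- col_freqs(genotypes)
  for (idx in split(seq_len(nrow(variants)), variants$chrom)) {
    if (is.unsorted(variants$pos[idx])) {
      stopf("variants must be position-sorted within chromosome")
    }
    starts <- unique(c(seq(1, max(length(idx) - window_snps + 1, 1),
                           by = step_snps)))
    for (s in starts) {
      w <- idx[s:min(s + window_snps - 1, length(idx))]
      act <- w[keep[w]]
      if (length(act) < 2) next
      r2 <- pairwise_r2(genotypes[, act, drop = FALSE])
      r2[!is.finite(r2)] <- 0           # undefined LD: unprunable pair
      diag(r2) <- 0
      # dropping a SNP never changes the r2 of the remaining pairs, so the
      # window matrix is computed once and shrunk in place
      repeat {
        top <- max(r2)
        if (top <= r2_threshold) break
        hit <- which(r2 == top, arr.ind = TRUE)[1, ]
        pair <- act[sort(hit)]
        mafs <- fr$maf[pair]
        drop <- if (mafs[1] < mafs[2]) pair[1]
                else if (mafs[2] < mafs[1]) pair[2]
                else pair[2]                       # tie: later position
        keep[drop] <- FALSE
        di <- match(drop, act)
        r2[di, ] <- 0
        r2[, di] <- 0
      }
    }
  }
  variants$snp_id[keep]
}

# exact pairwise-complete squared dosage correlation for a window of SNPs,
# assembled from crossproducts of the zero-filled matrix and the
# missingness indicator (equivalent to cor(use = "pairwise.complete.obs"))
pairwise_r2 <- function(X) {
  M <- !is.na(X); storage.mode(M) <- "double"
  X0 <- X; X0[is.na(X0)] <- 0
  n <- crossprod(M)
  sx <- crossprod(X0, M)       # sum of x_j over rows complete for (j, k)
  sxy <- crossprod(X0)
  sxx <- crossprod(X0 * X0, M)
  cov <- sxy - sx * t(sx) / n
  vx <- sxx - sx^2 / n
  r2 <- cov^2 / (vx * t(vx))
  r2[n < 2] <- NA
  r2
}

#' Run the full variant/subject quality-control sequence
#'
#' Applies, in a fixed and reported order: subject missingness, variant
#' missingness, minor allele frequency, Hardy-Weinberg exact test, windowed
#' LD pruning, and (optionally) relatedness exclusion. Dosages in the
#' returned matrix are re-coded to count the minor allele as observed after
#' filtering.
#'
#' @param genotypes Subjects x SNPs dosage matrix (`NA` = missing).
#' @param variants Optional variant tibble (`snp_id`, `chrom`, `pos`, and
#'   `ref`/`alt` if available); defaults to a single-chromosome layout in
#'   column order.
#' @param maf,geno,mind,hwe,r2,pihat Thresholds: minimum MAF, maximum
#'   per-variant missingness, maximum per-subject missingness, minimum HWE
#'   exact p, LD-pruning r2 (pairs strictly above are pruned), and the
#'   PI_HAT above which one member of a pair is excluded.
#' @param window_snps,step_snps LD-pruning window geometry.
#' @param relatedness Estimate identity-by-descent and exclude related
#'   subjects? The method-of-moments estimate is computed on the LD-pruned
#'   panel.
#' @return A `qc_result`: list with filtered `genotypes`, updated `variants`
#'   (maf, call_rate, hwe_p), `report` (per-filter removal counts),
#'   `excluded_subjects`, and `relatedness` estimates (or `NULL`).
#' @export
run_qc <- function(genotypes, variants = NULL, maf = 0.01, geno = 0.05,
                   mind = 0.05, hwe = 0.001, r2 = 0.8, window_snps = 50,
                   step_snps = window_snps %/% 2, pihat = 0.1875,
                   relatedness = TRUE) {
  check_dosage(genotypes)
  if (is.null(variants)) {
    variants <- tibble(snp_id = colnames(genotypes) %||%
                         sprintf("snp%05d", seq_len(ncol(genotypes))),
                       chrom = "chr1", pos = seq_len(ncol(genotypes)))
  }
  stopifnot(nrow(variants) == ncol(genotypes))
  n_var0 <- ncol(genotypes); n_sub0 <- nrow(genotypes)
  report <- list()
  note <- function(filter, threshold, removed, remaining, unit) {
    report[[length(report) + 1]] <<- tibble(
      filter = filter, unit = unit, threshold = threshold,
      removed = removed, remaining = remaining)
  }
  excluded <- tibble(subject_id = character(), reason = character())

  # 1. subject missingness
  sub_miss <- rowMeans(is.na(genotypes))
  bad_sub <- sub_miss > mind
  if (any(bad_sub)) {
    excluded <- bind_rows(excluded, tibble(
      subject_id = rownames(genotypes)[bad_sub],
      reason = sprintf("missingness %.3f > %.3f", sub_miss[bad_sub], mind)))
  }
  genotypes <- genotypes[!bad_sub, , drop = FALSE]
  note("subject_missingness", mind, sum(bad_sub), nrow(genotypes), "subjects")

  # 2. variant missingness
  fr <- col_freqs(genotypes)
  drop_miss <- fr$call_rate < 1 - geno
  genotypes <- genotypes[, !drop_miss, drop = FALSE]
  variants <- variants[!drop_miss, ]
  note("variant_missingness", geno, sum(drop_miss), ncol(genotypes),
       "variants")

  # 3. MAF
  fr <- col_freqs(genotypes)
  drop_maf <- is.na(fr$maf) | fr$maf < maf
  genotypes <- genotypes[, !drop_maf, drop = FALSE]
  variants <- variants[!drop_maf, ]
  note("maf", maf, sum(drop_maf), ncol(genotypes), "variants")

  # 4. HWE exact test
  hwe_p <- col_hwe(genotypes)
  drop_hwe <- hwe_p < hwe
  genotypes <- genotypes[, !drop_hwe, drop = FALSE]
  variants <- variants[!drop_hwe, ]
  hwe_p <- hwe_p[!drop_hwe]
  note("hwe", hwe, sum(drop_hwe), ncol(genotypes), "variants")

  # re-code to minor allele before LD pruning / relatedness
  fr <- col_freqs(genotypes)
  flip <- !is.na(fr$f_alt) & fr$f_alt > 0.5
  if (any(flip)) {
    genotypes[, flip] <- 2L - genotypes[, flip, drop = FALSE]
    if (all(c("ref", "alt") %in% names(variants))) {
      tmp <- variants$ref[flip]
      variants$ref[flip] <- variants$alt[flip]
      variants$alt[flip] <- tmp
    }
    fr <- col_freqs(genotypes)
  }

  # 5. LD pruning
  kept_ids <- prune_ld(genotypes, variants, r2_threshold = r2,
                       window_snps = window_snps, step_snps = step_snps)
  drop_ld <- !(variants$snp_id %in% kept_ids)
  genotypes <- genotypes[, !drop_ld, drop = FALSE]
  variants <- variants[!drop_ld, ]
  hwe_p <- hwe_p[!drop_ld]
  fr <- col_freqs(genotypes)
  note("ld_prune", r2, sum(drop_ld), ncol(genotypes), "variants")

  # 6. relatedness
  rel <- NULL
  if (isTRUE(relatedness) && nrow(genotypes) >= 2) {
    if (ncol(genotypes) < 100) {
      warnf("relatedness estimated on only %d variants; PI_HAT is noisy",
            ncol(genotypes))
    }
    rel <- estimate_relatedness(genotypes, fr$maf)
    rel_excl <- exclude_related(rel, threshold = pihat,
                                missingness = rowMeans(is.na(genotypes)))
    if (length(rel_excl)) {
      excluded <- bind_rows(excluded, tibble(
        subject_id = rel_excl,
        reason = sprintf("PI_HAT > %.4f", pihat)))
      genotypes <- genotypes[!(rownames(genotypes) %in% rel_excl), ,
                             drop = FALSE]
    }
    note("relatedness", pihat, length(rel_excl), nrow(genotypes), "subjects")
  }

  variants$maf <- fr$maf
  variants$call_rate <- fr$call_rate
  variants$hwe_p <- hwe_p

  structure(
    list(genotypes = genotypes, variants = variants,
         report = bind_rows(report), excluded_subjects = excluded,
         relatedness = rel,
         thresholds = list(maf = maf, geno = geno, mind = mind, hwe = hwe,
                           r2 = r2, pihat = pihat),
         input_counts = c(subjects = n_sub0, variants = n_var0)),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result>\n")
  cat(sprintf("  %d/%d variants and %d/%d subjects retained\n",
              ncol(x$genotypes), x$input_counts["variants"],
              nrow(x$genotypes), x$input_counts["subjects"]))
  print(x$report)
  invisible(x)
}

#' @rdname run_qc
#' @param x A `qc_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.qc_result <- function(x, ...) x$variants

#' @rdname run_qc
#' @exportS3Method generics::glance
glance.qc_result <- function(x, ...) {
  tibble(
    n_subjects_in = unname(x$input_counts["subjects"]),
    n_subjects_out = nrow(x$genotypes),
    n_variants_in = unname(x$input_counts["variants"]),
    n_variants_out = ncol(x$genotypes),
    n_removed = sum(x$report$removed)
  )
}
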