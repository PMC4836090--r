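test_that("minor allele frequency follows the hand counts", {
  expect_equal(compute_maf(c(0, 0, 0))$maf, 0)
  m <- compute_maf(c(0, 1, 2, 1))
  expect_equal(m$maf, 0.5)
  m2 <- compute_maf(c(2, 2, 2, 1))
  expect_equal(m2$maf, 0.125)
  expect_identical(m2$minor, "ref")
  expect_error(compute_maf(c(NA, NA)), "missing")
})

test_that("HWE exact test matches the enumeration oracle", {
  expect_equal(hwe_exact_test(0, 1, 0), 1)

  # ten minor alleles in ten diploids, zero heterozygotes: an extreme
  # heterozygote deficit; the enumeration oracle puts its exact p at
  # ~1.4e-3 (the only admissible table at or below the observed mass)
  p_5_0_5 <- hwe_oracle(5, 0, 5)
  expect_equal(hwe_exact_test(5, 0, 5), p_5_0_5)
  expect_lt(p_5_0_5, 0.01)

  expect_equal(hwe_exact_test(20, 20, 10), hwe_oracle(20, 20, 10))

  # sweep all genotype triples with total <= 25 (full sweep to 50 lives in
  # the acceptance suite)
  for (n in c(1, 2, 5, 10, 25)) {
    for (a in 0:n) {
      for (h in 0:(n - a)) {
        b <- n - a - h
        expect_equal(hwe_exact_test(a, h, b), hwe_oracle(a, h, b),
                     tolerance = 1e-12,
                     info = sprintf("(%d,%d,%d)", a, h, b))
      }
    }
  }
})

test_that("dosage r2 matches the direct correlation formula", {
  expect_equal(genotype_r2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  expect_equal(genotype_r2(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  a <- c(0, 1, 2, 2, 1, 0); b <- c(0, 1, 1, 2, 1, 0)
  expect_equal(genotype_r2(a, b), cor(a, b)^2)
  expect_error(genotype_r2(c(0, NA), c(NA, 1)), class = "pathgwas_ld_undefined")
  expect_error(genotype_r2(c(1, 1, 1), c(0, 1, 2)),
               class = "pathgwas_ld_undefined")
})

test_that("pairwise_r2 reproduces cor(use = 'pairwise.complete.obs')", {
  g <- hwe_matrix(60, runif(12, 0.1, 0.5), seed = 4)
  g[sample(length(g), 40)] <- NA
  ref <- suppressWarnings(cor(g, use = "pairwise.complete.obs")^2)
  got <- pathgwas:::pairwise_r2(g)
  expect_equal(got, ref, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("LD pruning removes duplicates and leaves independent panels alone", {
  base <- hwe_matrix(50, rep(0.3, 1), seed = 2)[, 1]
  g <- cbind(a = base, b = base, c = base)
  v <- tibble::tibble(snp_id = c("a", "b", "c"), chrom = "chr1", pos = 1:3)
  expect_length(prune_ld(g, v, window_snps = 3), 1)

  g2 <- hwe_matrix(300, runif(20, 0.2, 0.5), seed = 6)
  v2 <- tibble::tibble(snp_id = colnames(g2), chrom = "chr1", pos = 1:20)
  expect_identical(prune_ld(g2, v2), colnames(g2))
})

test_that("pruned output never contains an over-threshold pair (post-condition)", {
  st <- generate_cohorts(synth_config(
    n_subjects_discovery = 400, n_subjects_replication = 2, n_snps = 60,
    n_chromosomes = 1, ld_block_size = 10, ld_rho = 0.99,
    missing_rate = 0, dropout_rate = 0, seed = 21))
  g <- st$discovery$genotypes
  v <- st$discovery$variants
  kept <- prune_ld(g, v, r2_threshold = 0.8, window_snps = 15,
                   step_snps = 7)
  expect_lt(length(kept), ncol(g))     # near-duplicate blocks must shrink
  idx <- match(kept, v$snp_id)
  for (s in seq(1, max(length(idx) - 14, 1), by = 7)) {
    w <- idx[idx >= s & idx < s + 15]
    if (length(w) < 2) next
    for (i in seq_along(w)[-1]) {
      for (j in seq_len(i - 1)) {
        r2 <- tryCatch(genotype_r2(g[, w[i]], g[, w[j]]),
                       pathgwas_ld_undefined = function(e) 0)
        expect_lte(r2, 0.8)
      }
    }
  }
})

test_that("PI_HAT recovers duplicate, parent-child and unrelated pairs", {
  freqs <- withr::with_seed(11, runif(4000, 0.1, 0.5))
  g <- hwe_matrix(12, freqs, seed = 12)
  # duplicate of subject 1
  g <- rbind(g, dup = g[1, ])
  rel <- estimate_relatedness(g, freqs)
  dup_row <- rel[rel$subject_a == "s001" & rel$subject_b == "dup", ]
  expect_lt(abs(dup_row$pi_hat - 1), 0.02)
  expect_equal(rel$ibs0 + rel$ibs1 + rel$ibs2, rep(1, nrow(rel)))

  # child: one allele transmitted from the parent, one from the population
  withr::with_seed(13, {
    transmitted <- ifelse(g[2, ] == 1, rbinom(length(freqs), 1, 0.5),
                          g[2, ] / 2)
    kid <- transmitted + rbinom(length(freqs), 1, freqs)
  })
  g2 <- rbind(g[1:12, ], kid = kid)
  rel2 <- estimate_relatedness(g2, freqs)
  pc <- rel2[rel2$subject_a == "s002" & rel2$subject_b == "kid", ]
  expect_lt(abs(pc$pi_hat - 0.5), 0.05)
  unrelated <- rel2[rel2$subject_a != "s002" & rel2$subject_b != "dup" &
                      rel2$subject_b != "kid", ]
  expect_lt(abs(mean(unrelated$pi_hat)), 0.05)
})

test_that("related-pair exclusion removes a minimal hitting set", {
  est <- tibble::tibble(subject_a = "A", subject_b = "B", pi_hat = 0.4)
  expect_length(exclude_related(est), 1)
  expect_length(exclude_related(est, threshold = 0.5), 0)

  tri <- tibble::tibble(subject_a = c("A", "A", "B"),
                        subject_b = c("B", "C", "C"),
                        pi_hat = 0.3)
  excl <- exclude_related(tri)
  expect_length(excl, 2)
  # brute force: no single subject covers all three edges
  for (v in c("A", "B", "C")) {
    left <- tri[tri$subject_a != v & tri$subject_b != v, ]
    expect_gt(nrow(left), 0)
  }
})

test_that("QC report conserves counts and the filters are idempotent", {
  st <- generate_cohorts(tiny_config(seed = 14, n_snps = 150,
                                     missing_rate = 0.02))
  g <- st$discovery$genotypes
  # plant pathological columns: monomorphic, missing-heavy, HWE-violating
  g[, 1] <- 0L                                          # MAF 0
  g[seq_len(nrow(g) * 0.5), 2] <- NA                    # call rate 50 %
  g[, 3] <- rep(c(0L, 2L), length.out = nrow(g))        # no heterozygotes
  qc <- run_qc(g, st$discovery$variants, relatedness = FALSE)

  rep_v <- qc$report[qc$report$unit == "variants", ]
  expect_equal(ncol(g), ncol(qc$genotypes) + sum(rep_v$removed))
  rep_s <- qc$report[qc$report$unit == "subjects", ]
  expect_equal(nrow(g), nrow(qc$genotypes) + sum(rep_s$removed))
  removed_ids <- setdiff(colnames(g), colnames(qc$genotypes))
  expect_true(all(colnames(g)[1:3] %in% removed_ids))

  qc2 <- run_qc(qc$genotypes, qc$variants[, c("snp_id", "chrom", "pos",
                                              "ref", "alt")],
                relatedness = FALSE)
  expect_identical(qc2$genotypes, qc$genotypes)
  expect_equal(sum(qc2$report$removed), 0)
})

test_that("MDS components separate simulated subpopulations", {
  st <- generate_cohorts(synth_config(
    n_subjects_discovery = 2, n_subjects_replication = 160, n_snps = 300,
    ancestry_fst_like = 0.3, missing_rate = 0, dropout_rate = 0, seed = 33))
  g <- st$replication$genotypes
  lab <- st$replication$subjects$subpop
  anc <- ancestry_components(g, k_components = 2, k_clusters = 2)
  expect_gt(abs(cor(anc$MDS1, as.numeric(lab == "pop1"))), 0.9)
  tb <- table(anc$cluster, lab)
  agreement <- max(tb["1", "pop1"] + tb["2", "pop2"],
                   tb["2", "pop1"] + tb["1", "pop2"]) / length(lab)
  expect_gt(agreement, 0.9)

  anc1 <- ancestry_components(g, k_components = 2, k_clusters = 1)
  expect_equal(unique(anc1$cluster), 1L)

  perm <- withr::with_seed(3, sample(nrow(g)))
  anc_p <- ancestry_components(g[perm, ], k_components = 2, k_clusters = 2)
  reord <- anc_p[match(anc$subject_id, anc_p$subject_id), ]
  for (k in c("MDS1", "MDS2")) {
    agree <- max(abs(reord[[k]] - anc[[k]])) < 1e-8 ||
      max(abs(reord[[k]] + anc[[k]])) < 1e-8
    expect_true(agree, info = k)
  }
  expect_error(ancestry_components(g, k_components = nrow(g)), "k_components")
})
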