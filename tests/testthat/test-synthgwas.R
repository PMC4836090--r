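test_that("generation is deterministic given a seed, including written files", {
  cfg <- tiny_config(seed = 42)
  s1 <- generate_cohorts(cfg)
  s2 <- generate_cohorts(cfg)
  expect_identical(s1$discovery$genotypes, s2$discovery$genotypes)
  expect_identical(s1$replication$scores, s2$replication$scores)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(s1, d1)
  write_study(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("cohort structure respects the configuration invariants", {
  cfg <- tiny_config(seed = 3)
  st <- generate_cohorts(cfg)
  for (ch in c("discovery", "replication")) {
    co <- st[[ch]]
    vals <- co$genotypes[!is.na(co$genotypes)]
    expect_true(all(vals %in% 0:2))
    by_chr <- split(co$variants$pos, co$variants$chrom)
    expect_true(all(vapply(by_chr, function(p) all(diff(p) > 0), logical(1))))
    expect_true(all(co$scores$week %in% co$visit_weeks))
    expect_true(all(co$scores$score >= 0))
    # baseline never dropped, only post-baseline visits
    expect_setequal(unique(co$scores$subject_id[co$scores$week == 0]),
                    co$subjects$subject_id)
  }
  expect_true(all(st$truth$causal$snp_id %in% st$discovery$variants$snp_id))
})

test_that("adjacent-SNP r2 is near zero without LD and rises with ld_rho", {
  st0 <- generate_cohorts(synth_config(
    n_subjects_discovery = 1000, n_subjects_replication = 2,
    n_snps = 120, n_chromosomes = 1, ld_rho = 0, missing_rate = 0,
    dropout_rate = 0, seed = 9))
  g <- st0$discovery$genotypes
  r2_adj <- vapply(seq_len(ncol(g) - 1), function(j) {
    suppressWarnings(cor(g[, j], g[, j + 1])^2)
  }, numeric(1))
  expect_lt(median(r2_adj, na.rm = TRUE), 0.05)

  st9 <- generate_cohorts(synth_config(
    n_subjects_discovery = 1000, n_subjects_replication = 2,
    n_snps = 120, n_chromosomes = 1, ld_block_size = 10, ld_rho = 0.9,
    missing_rate = 0, dropout_rate = 0, seed = 9))
  g9 <- st9$discovery$genotypes
  blk <- (seq_len(ncol(g9)) - 1) %/% 10
  same_block <- blk[-length(blk)] == blk[-1]
  r2_adj9 <- vapply(which(same_block), function(j) {
    suppressWarnings(cor(g9[, j], g9[, j + 1])^2)
  }, numeric(1))
  expect_gt(median(r2_adj9, na.rm = TRUE), 0.5)
})

test_that("null SNPs pass the HWE exact test and show ~5 % nominal hits", {
  st <- generate_cohorts(synth_config(
    n_subjects_discovery = 800, n_subjects_replication = 2, n_snps = 400,
    ld_rho = 0, missing_rate = 0, dropout_rate = 0, seed = 17))
  g <- st$discovery$genotypes
  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    hwe_exact_test(sum(g[, j] == 0), sum(g[, j] == 1), sum(g[, j] == 2))
  }, numeric(1))
  expect_gte(mean(hwe_p >= 0.001), 0.99)

  ph <- derive_phenotypes(st$discovery$scores, "HRSD17", 6)
  out <- setNames(as.numeric(ph$response[ph$eligible]),
                  ph$subject_id[ph$eligible])
  res <- run_gwas(g, out)
  rate <- mean(res$p < 0.05, na.rm = TRUE)
  halfwidth <- 2.58 * sqrt(0.05 * 0.95 / sum(!is.na(res$p)))
  expect_lt(abs(rate - 0.05), halfwidth + 1e-9)
})

test_that("a configured allelic odds ratio is recovered by logistic regression", {
  # one causal response SNP, OR 2.0 at MAF 0.3, n = 2000: the refit OR
  # should land inside its 95 % Wald interval in >= 90 % of replicates
  hits <- 0
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    cfg <- synth_config(
      n_subjects_discovery = 2000, n_subjects_replication = 2,
      n_snps = 40, n_chromosomes = 1, ld_rho = 0, missing_rate = 0,
      dropout_rate = 0, seed = 5000 + r,
      causal_spec = tibble::tibble(snp_id = "snp00020", or_response = 2,
                                   or_remission = 1, maf = 0.3))
    st <- generate_cohorts(cfg)
    ph <- derive_phenotypes(st$discovery$scores, "HRSD17", 6)
    y <- as.numeric(ph$response[match(rownames(st$discovery$genotypes),
                                      ph$subject_id)])
    fit <- fit_logistic(y, cbind(1, dose = st$discovery$genotypes[, "snp00020"]))
    est <- fit$coefficients[2]
    ci <- est + c(-1.96, 1.96) * fit$se[2]
    if (log(2) >= ci[1] && log(2) <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.90)
})

test_that("replication subpopulation divergence grows with the fst parameter", {
  div <- vapply(c(0.01, 0.1, 0.3), function(fst) {
    st <- generate_cohorts(synth_config(
      n_subjects_discovery = 2, n_subjects_replication = 400, n_snps = 300,
      ancestry_fst_like = fst, missing_rate = 0, dropout_rate = 0,
      seed = 31))
    g <- st$replication$genotypes
    pop <- st$replication$subjects$subpop
    f1 <- colMeans(g[pop == "pop1", ]) / 2
    f2 <- colMeans(g[pop == "pop2", ]) / 2
    mean(abs(f1 - f2))
  }, numeric(1))
  expect_true(all(diff(div) > 0))
})

test_that("written study files have the contracted shapes and round-trip", {
  cfg <- tiny_config(seed = 8, n_subjects_discovery = 10, n_snps = 20,
                     n_genes = 4, missing_rate = 0.05)
  st <- generate_cohorts(cfg)
  dir <- withr::local_tempdir()
  manifest <- write_study(st, dir)
  expect_length(readLines(file.path(dir, "discovery.ped")), 10)
  expect_length(readLines(file.path(dir, "discovery.map")), 20)
  gmt <- readLines(file.path(dir, "pathways.gmt"))
  expect_length(gmt, length(st$pathways))
  expect_true(all(lengths(strsplit(gmt, "\t")) >= 3))
  expect_true(all(file.exists(manifest$file)))

  rt <- read_ped_map(file.path(dir, "discovery.ped"),
                     file.path(dir, "discovery.map"),
                     alt = st$discovery$variants$alt)
  expect_identical(unname(rt$genotypes),
                   unname(st$discovery$genotypes))
})

test_that("configuration validation catches contract violations", {
  expect_error(synth_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(synth_config(ld_rho = 1), "ld_rho")
  expect_error(synth_config(visit_weeks_discovery = c(2, 4)), "baseline")
  expect_error(
    synth_config(causal_spec = tibble::tibble(
      snp_id = "nope", or_response = 2, or_remission = 1, maf = 0.3)),
    "absent")
  cfg <- spike_pathway(tiny_config(), or_response = 2)
  expect_true(all(cfg$causal_spec$snp_id %in%
                    pathgwas:::layout_variants(cfg)$snp_id))
  expect_identical(cfg$spiked_pathway, names(cfg$pathway_spec)[1])
})
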