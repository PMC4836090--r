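make_strata <- function(n_intra, n_inter) {
  tibble::tibble(
    snp_id = sprintf("p%04d", seq_len(n_intra + n_inter)),
    intragenic = rep(c(TRUE, FALSE), c(n_intra, n_inter))
  )
}

test_that("matched random sets honour the composition contract", {
  strata <- make_strata(200, 300)
  target <- list(snps = list(strata$snp_id[c(1:10, 201:205)]),
                 n_intragenic = 10, n_intergenic = 5)
  rs <- build_matched_random_set(target, strata, seed = 7)
  expect_length(rs$snp_id, 15)
  drawn <- strata[match(rs$snp_id, strata$snp_id), ]
  expect_equal(sum(drawn$intragenic), 10)
  expect_equal(sum(!drawn$intragenic), 5)
  expect_length(intersect(rs$snp_id, unlist(target$snps)), 0)
  rs2 <- build_matched_random_set(target, strata, seed = 7)
  expect_identical(rs$snp_id, rs2$snp_id)

  small <- make_strata(9, 300)
  expect_error(build_matched_random_set(target, small),
               class = "pathgwas_pool_error")
})

test_that("random-set inclusion is uniform over the eligible pool", {
  strata <- make_strata(60, 0)
  target <- list(snps = list(strata$snp_id[1:10]),
                 n_intragenic = 12, n_intergenic = 0)
  n_draws <- 800
  counts <- integer(nrow(strata))
  names(counts) <- strata$snp_id
  for (s in seq_len(n_draws)) {
    rs <- build_matched_random_set(target, strata, seed = s)
    counts[rs$snp_id] <- counts[rs$snp_id] + 1
  }
  expect_equal(unname(counts[1:10]), rep(0L, 10))   # target never drawn
  pool <- counts[11:60]
  p_incl <- 12 / 50
  bound <- 2.58 * sqrt(p_incl * (1 - p_incl) / n_draws)
  expect_true(all(abs(pool / n_draws - p_incl) < bound + 0.02))
})

test_that("Fisher enrichment equals enumeration and the R reference", {
  expect_equal(fisher_enrichment(5, 95, 5, 95)$fisher_p, 1)
  expect_equal(fisher_enrichment(3, 1, 1, 3)$fisher_p, fisher_oracle(3, 1, 1, 3))

  # pathway-scale table: 478/7053 significant vs a 5 %-rate matched set
  big <- fisher_enrichment(478, 7053, 377, 7154)
  expect_equal(big$fisher_p, fisher_oracle(478, 7053, 377, 7154),
               tolerance = 1e-10)
  expect_equal(big$fisher_p,
               fisher.test(matrix(c(478, 7053, 377, 7154), 2,
                                  byrow = TRUE))$p.value,
               tolerance = 1e-6)
  expect_lt(big$fisher_p, 0.001)
  expect_equal(big$fisher_or, (478 * 7154) / (7053 * 377))

  withr::with_seed(15, {
    for (i in 1:50) {
      tb <- matrix(rpois(4, 12), 2)
      if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
      mine <- fisher_enrichment(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])
      expect_equal(mine$fisher_p, fisher.test(tb)$p.value, tolerance = 1e-9)
    }
  })
  expect_error(fisher_enrichment(0, 5, 0, 5), class = "pathgwas_degenerate")
})

test_that("permutation p matches the exact hypergeometric null", {
  # tiny case: 3-of-4 significant in the target, 1-of-4 in the random set;
  # exact enumeration over C(8,4) assignments gives P(X >= 3) = 17/70
  exact <- (choose(4, 3) * choose(4, 1) + choose(4, 4) * choose(4, 0)) /
    choose(8, 4)
  expect_equal(exact, 17 / 70)
  n_perm <- 20000
  p_hat <- permutation_p(3, 4, 1, 4, n_perm = n_perm, seed = 2)
  expect_lt(abs(p_hat - exact), 3 * sqrt(exact * (1 - exact) / n_perm) + 2 / n_perm)

  # identical groups: the observed statistic is central
  expect_gt(permutation_p(10, 100, 10, 100, n_perm = 5000, seed = 3), 0.4)

  # analytic equivalence across a grid of tables
  grid <- expand.grid(n_true = c(5, 12, 30), total = 100,
                      r_true = c(2, 5, 10), r_total = 100)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    tail_p <- phyper(g$n_true - 1, g$n_true + g$r_true,
                     g$total + g$r_total - g$n_true - g$r_true,
                     g$total, lower.tail = FALSE)
    p_hat <- permutation_p(g$n_true, g$total, g$r_true, g$r_total,
                           n_perm = 20000, seed = i)
    expect_lt(abs(p_hat - tail_p),
              3 * sqrt(tail_p * (1 - tail_p) / 20000) + 1e-4)
  }
  expect_error(permutation_p(1, 2, 1, 2, n_perm = 0), "n_perm")
})

test_that("more significant members never raise the permutation p", {
  ps <- vapply(5:20, function(k) {
    permutation_p(k, 50, 5, 50, n_perm = 10000, seed = 99)
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("set analysis wires counts, gates and verdicts correctly", {
  st <- generate_cohorts(tiny_config(seed = 55, n_snps = 200, n_genes = 20,
                                     missing_rate = 0))
  ann <- annotate_snps(st$discovery$variants, st$genes)
  sets <- expand_pathways(st$pathways, ann)
  fake_result <- function(seed) {
    withr::with_seed(seed, tibble::tibble(
      snp_id = st$discovery$variants$snp_id,
      p = runif(200), converged = TRUE))
  }
  cohorts <- list(discovery = fake_result(1), replication = fake_result(2))
  res <- run_set_analysis(sets, ann, cohorts, thresholds = c(0.05, 0.01),
                          n_perm = 2000, seed = 11)
  expect_s3_class(res, "enrich_result")
  expect_equal(res$n_true + res$n_false, res$total)
  expect_equal(sort(unique(res$threshold)), c(0.01, 0.05))
  expect_equal(res$r_true + res$r_false, res$total)
  expect_true(all(is.na(res$permuted_p) | res$permuted_p > 0))
  expect_true(all(res$bonferroni_threshold == 0.05 / nrow(sets)))
  # nominal gate: permutation only where Fisher p < 0.05
  expect_true(all(is.na(res$permuted_p[res$fisher_p >= 0.05])))

  res2 <- run_set_analysis(sets, ann, cohorts, thresholds = c(0.05, 0.01),
                           n_perm = 2000, seed = 11)
  expect_identical(res$permuted_p, res2$permuted_p)

  v <- attr(res, "verdicts")
  expect_true(all(c("set_id", "threshold", "replicated") %in% names(v)))

  # sets below the member floor are skipped with a message
  small_sets <- sets[1, ]
  small_sets$snps <- list(sets$snps[[1]][1])
  small_sets$total <- 1L
  class(small_sets) <- class(sets)
  expect_message(
    out <- run_set_analysis(small_sets, ann, cohorts["discovery"],
                            thresholds = 0.05, n_perm = 100),
    "skipped")
  expect_equal(nrow(out), 0)
})

test_that("untested members are dropped from the cohort's totals", {
  strata_ann <- tibble::tibble(
    snp_id = sprintf("p%04d", 1:200),
    gene = rep(c("G", "H"), c(50, 150)),
    assigned = TRUE, intragenic = TRUE, distance = 0L)
  sets <- expand_pathways(list(G = "G"), strata_ann)
  expect_equal(sets$total, 50)
  # only 40 of the 50 members carry an association test in this cohort
  res_tbl <- tibble::tibble(snp_id = sprintf("p%04d", c(1:40, 51:200)),
                            p = rep(c(0.01, 0.5), 95), converged = TRUE)
  out <- run_set_analysis(sets, strata_ann, list(one = res_tbl),
                          thresholds = 0.05, n_perm = 100, seed = 1,
                          gate = "always")
  expect_equal(out$total, 40)
  expect_equal(out$n_dropped, 10)
  expect_equal(out$n_true, 20)
})
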