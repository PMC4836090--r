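---
title: "Multi-level GWAS replication with matched-random-set enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level GWAS replication with matched-random-set enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis this package implements

pathgwas re-implements, as tested code, a three-level genome-wide
association replication analysis of antidepressant treatment response: a
small discovery cohort (109 inpatients rated on the 17-item Hamilton
depression scale over 6 weeks) and a large replication cohort (1677
outpatients from a citalopram level-1 trial rated on the QIDS-SR over 12
weeks) are analysed per SNP, per gene, and per pathway, with replication
across cohorts as the principal guard against false positives.

The stages, and the package functions behind them, are:

1. **Quality control** (`run_qc()`): minor allele frequency < 0.01, call
   rate filters at 5 % for both variants and subjects, Hardy-Weinberg
   exact test at p < 0.001, greedy windowed LD pruning at r² > 0.8,
   and exclusion of one member of every subject pair with
   method-of-moments PI_HAT > 0.1875.
2. **Phenotypes** (`derive_phenotypes()`): last observation carried
   forward when a baseline and at least one post-baseline score exist;
   response = ≥ 50 % symptom reduction from baseline; remission =
   HRSD17 ≤ 7 or QIDS-SR ≤ 5; replication subjects additionally need a
   baseline QIDS-SR ≥ 10.
3. **Association** (`run_gwas()`): per-SNP additive logistic regression
   with sex and age as covariates, baseline severity added for remission
   only, and two MDS components of the identity-by-state distance matrix
   added in the (ancestrally mixed) replication cohort.
4. **Replication filter** (`replication_filter()`): SNPs with p < 0.05 in
   the discovery cohort are looked up in the replication cohort; those
   with p < 0.05 in both go forward. Effect direction is deliberately not
   a criterion.
5. **Annotation** (`annotate_snps()`): a SNP belongs to every gene whose
   interval extended by 20 kb on each side contains it; SNPs inside the
   gene body are *intragenic*, window-only assignments are intergenic for
   set-matching purposes.
6. **Set enrichment** (`run_set_analysis()`): for each gene or pathway
   set, the count of members with association p below a threshold (0.05
   primary, 0.01 as sensitivity) is compared against a random SNP set
   matched on size and intragenic/intergenic composition, by two-sided
   Fisher exact test; nominally significant results receive a one-sided
   permutation p from re-assigning SNPs between the two groups (100,000
   permutations in the source design). Bonferroni correction divides
   alpha by the number of sets at each level; a set is *replicated* when
   its permutation p is below 0.05 in both cohorts.
7. **Power** (`snp_cc_power()`, `set_power_one_sample_exact()`,
   `set_power_two_prop()`): the allelic 1-df case-control power by
   noncentrality, and two set-level formulations of "the proportion of
   significant SNPs exceeds the 5 % chance level".

`run_pipeline()` chains all stages on a configuration, a generated study,
or a study directory, and is fully reproducible given a seed.

## The permutation null

Re-assigning the pooled SNPs of the target and random sets to two groups
of the original sizes makes the count of significant SNPs landing in the
target group exactly hypergeometric in the pooled significance
indicators. `permutation_p()` therefore draws each permutation statistic
from that distribution (`rhyper`) rather than shuffling index vectors;
the two procedures are distributionally identical, and the tests assert
agreement with the analytic hypergeometric tail to Monte-Carlo accuracy.
The estimator is add-one, `(b + 1)/(B + 1)`, so a saturated result at
B = 100,000 prints as `< 1e-5`, never 0.

One consequence worth knowing: the permutation test is one-sided and
discrete. For sets of a few hundred members its null rejection rate at
0.05 is noticeably conservative (about 0.03–0.04 in our calibration
runs), approaching 0.05 only for sets of thousands of SNPs like those in
the source analysis. The calibration tests therefore use sets of ~500
members, where the conservatism is mild.

## What the synthetic-data generator emulates

Neither cohort's raw data is publicly available (the discovery consents
exclude sharing; the replication genotypes are access-controlled), so the
package ships a generator (`synth_config()`, `generate_cohorts()`) that
reproduces the statistical structure the analysis relies on:

* **Genotypes.** Two independent haplotypes per subject, so every SNP is
  in Hardy-Weinberg equilibrium within its subpopulation. Within LD
  blocks (default 10 SNPs, never spanning chromosomes) each haplotype
  allele copies its left neighbour with probability `ld_rho`, giving
  tunable, monotonically decaying r². Base minor allele frequencies are
  uniform on `maf_range` (default 0.05–0.5); calls go missing
  independently at `missing_rate` (default 1 %).
* **Ancestry.** The replication cohort is an even mix of two
  Balding-Nichols subpopulations with divergence `ancestry_fst_like`
  (default 0.01); the discovery cohort is homogeneous, mirroring the
  single-origin discovery sample.
* **Phenotypes.** Each subject has a latent improvement fraction
  `plogis(eta + e)` with standard-logistic noise `e`, where `eta`
  contains the intercept implied by `base_response_rate` (default 0.45),
  the causal dosage terms (log allelic odds ratios, centred), and an
  optional baseline-severity term. The endpoint score is the baseline
  reduced by that fraction, so response (≥ 50 % reduction) occurs with
  probability exactly `plogis(eta)` and configured odds ratios are
  recoverable by logistic regression — a property the tests verify by
  Wald-interval coverage. Intermediate visits follow a saturating
  improvement curve (most improvement early, as in antidepressant
  trials); this matters because the LOCF endpoint of a subject who
  misses late visits would otherwise dilute the genetic effect. Visits
  after baseline drop out independently at `dropout_rate` (default
  10 %), so LOCF ineligibility occurs realistically.
* **Genome.** Variant positions, gene intervals and pathway membership
  are deterministic functions of the configuration, so causal SNPs can
  be placed by id before generation. Genes are centred in equal slots;
  pathways default to ten equal blocks of genes.

What it does **not** emulate: real human haplotype structure, imputation
(the synthetic panel is dense by construction), chip-specific marker
content (platform overlap is reduced to a configurable SNP subset), or
genotype-calling artefacts. Passing tests therefore demonstrate the
statistical machinery, not robustness to real-data pathologies.

## The spiked study

`spike_pathway()` plants causal variants in one pathway: by default 5
SNPs per member gene at conditional allelic OR 2.0 and MAF spread over
0.2–0.3. Two design points deserve explanation:

* With ~50 causal variants, the *marginal* per-SNP odds ratio is
  substantially smaller than the conditional one (the other causal
  dosages act as omitted variables in a logistic model). Placing the
  causal variants inside LD blocks (`ld_rho = 0.85`, adjacent r² ≈ 0.7,
  below the 0.8 pruning threshold) lets neighbouring effects add
  coherently, so single-SNP marginal odds ratios return to roughly the
  configured magnitude — the same mechanism that produces association
  peaks in real GWAS.
* At these settings the spiked pathway is recovered as the top-ranked
  replicated set in well over 90 % of replicate studies at the default
  scale (2,000 SNPs; 109/1,677 subjects; 10,000 permutations), which the
  acceptance tests measure over 100 replicates.

## Numerical and procedural choices

* **Logistic fits.** `fit_logistic()` wraps `stats::glm.fit`
  (IRLS); the genome-wide scan uses an internal plain IRLS with a
  covariate-only warm start for speed. Both are held to a
  Newton-Raphson oracle at 1e-6 in the tests. Quasi-complete separation
  (|beta| > 15 or vanishing IRLS weights) flags the fit unusable rather
  than erroring; unusable SNPs are excluded downstream.
* **HWE exact test.** Conditional enumeration of heterozygote counts,
  two-sided by probability ordering, no mid-p correction.
* **LD.** Composite (genotype-correlation) r² on pairwise-complete
  subjects; pruning is greedy within sliding windows (50 SNPs, step 25
  by default), always dropping the lower-MAF member of the worst pair,
  with the later position going on ties. Undefined LD (monomorphic
  overlap) makes a pair unprunable.
* **Relatedness.** PLINK-style method-of-moments PI_HAT without the
  small-sample bias correction; expected sharing for pairs with missing
  calls is scaled by the pair's call overlap, which assumes
  missingness is independent of genotype.
* **Matching strata.** A SNP is intragenic if it lies inside *any* gene
  body. Random sets are drawn uniformly without replacement per stratum,
  excluding target members; one draw per target by default
  (`n_random` allows averaging). When a stratum pool is exhausted (tiny
  panels), the set is skipped with a message rather than mismatched.
* **Gating.** Permutation p-values are computed for Fisher-nominal
  results by default (`gate = "nominal"`), following the source
  design's "first selection, then permutation" ordering; `"always"` and
  `"bonferroni"` are available (calibration runs use `"always"`).
* **Ties and determinism.** All stochastic steps accept a seed and are
  reproducible bit-for-bit; pipeline stage seeds are derived from the
  base seed by fixed offsets.

## Problem sizes used by the test suite

The suite runs the full pipeline at reduced but honest scales: oracle
sweeps are exhaustive (all HWE tables to total 50; all Fisher margins to
40); null calibration uses 20 independent two-cohort studies of 5,000
independent markers contributing 400 set-cohort results with 10,000
permutations each; spike-in recovery uses 100 replicate studies at 2,000
SNPs. Null calibration is run on independent markers (`ld_rho = 0`)
because with LD-blocked markers the per-SNP rejection-rate comparison
against binomial bounds would be overdispersed by design, not by defect.

## Known limitations

* The pairwise-population-concordance clustering of the source software
  is not reproduced; ancestry adjustment uses MDS components directly.
* Set-level power formulas are reported in both one-sample-exact and
  two-proportion forms because the source's printed values are not
  mutually consistent under any single standard procedure; the package
  reproduces the pathway-scale value with the two-proportion normal
  method and the gene-scale value with the exact binomial method.
* The SNP-level power routine implements the allelic 1-df test; the
  published 0.72 depends on an unpublished case/control split and is
  checked only for consistency against simulation.
* Permutation p-values for small sets are conservative (see above);
  replication verdicts inherit that conservatism.
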