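Package: pathgwas
Title: Multi-Level GWAS Replication Analysis with Matched Random Set
    Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a three-level (SNP, gene,
    pathway) genome-wide association replication analysis for
    antidepressant treatment response. Provides genotype and subject
    quality control (minor allele frequency, missingness, Hardy-Weinberg
    exact test, LD pruning, identity-by-descent relatedness exclusion,
    IBS/MDS ancestry components), derivation of binary response and
    remission phenotypes from longitudinal depression-scale scores with
    last-observation-carried-forward, per-SNP logistic association with
    phenotype-specific covariates, cross-cohort replication filtering,
    SNP-to-gene annotation with 20 kb flanking windows, gene-set
    enrichment against composition-matched random SNP sets (Fisher exact
    test plus permutation), layered Bonferroni correction, and
    case-control and set-level power calculations. A synthetic two-cohort
    study generator with LD-blocked genotypes, causal variants spiked
    into a designated pathway, ancestry substructure and longitudinal
    dropout makes the whole pipeline testable end to end without access
    to restricted patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
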