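# SNP-to-gene annotation with flanking windows, replicated-gene list
# assembly, and expansion of gene sets into SNP sets for enrichment.

variants_granges <- function(variants) {
  GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos, width = 1),
    snp_id = variants$snp_id
  )
}

genes_granges <- function(genes, window = 0) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = pmax(1L, genes$start - window),
                              end = genes$end + window),
    gene = genes$gene
  )
}

#' Annotate SNPs with genes using flanking windows
#'
#' A SNP is assigned to every gene whose `[start - window, end + window]`
#' interval contains it (boundaries inclusive); it is `intragenic` for a
#' gene when it lies within `[start, end]` itself. SNPs falling in no
#' window are reported once with `assigned = FALSE` and their nearest gene
#' and distance.
#'
#' @param variants Tibble with `snp_id`, `chrom`, `pos` (1-based).
#' @param genes Tibble with `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive; see [read_gene_bed()]).
#' @param window Flank size in base pairs on each side (default 20000).
#' @return Tibble with `snp_id`, `gene`, `assigned`, `intragenic`,
#'   `distance` (0 inside the gene body; base pairs to the nearer gene
#'   bound otherwise; `NA` gene when the chromosome has none).
#' @export
annotate_snps <- function(variants, genes, window = 20000) {
  snp_gr <- variants_granges(variants)
  win_gr <- genes_granges(genes, window = window)
  gene_gr <- genes_granges(genes, window = 0)

  hits <- GenomicRanges::findOverlaps(snp_gr, win_gr)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  pos <- variants$pos[qi]
  gstart <- genes$start[si]
  gend <- genes$end[si]
  inside <- pos >= gstart & pos <= gend
  assigned <- tibble(
    snp_id = variants$snp_id[qi],
    gene = genes$gene[si],
    assigned = TRUE,
    intragenic = inside,
    distance = ifelse(inside, 0L,
                      pmin(abs(pos - gstart), abs(pos - gend)))
  )

  orphan <- setdiff(variants$snp_id, assigned$snp_id)
  if (length(orphan)) {
    oi <- match(orphan, variants$snp_id)
    near <- GenomicRanges::distanceToNearest(snp_gr[oi], gene_gr)
    nq <- S4Vectors::queryHits(near)
    ns <- S4Vectors::subjectHits(near)
    unass <- tibble(
      snp_id = orphan,
      gene = NA_character_,
      assigned = FALSE,
      intragenic = FALSE,
      distance = NA_integer_
    )
    unass$gene[nq] <- genes$gene[ns]
    # base pairs from the SNP to the nearer gene bound (not the gap size)
    opos <- variants$pos[oi][nq]
    unass$distance[nq] <- as.integer(pmax(genes$start[ns] - opos,
                                          opos - genes$end[ns], 0L))
    assigned <- bind_rows(assigned, unass)
  }
  arrange(assigned, match(.data$snp_id, variants$snp_id))
}

# one row per SNP with its genome-wide intragenic status (inside any gene
# body); the stratum used for matched-random-set composition
snp_strata <- function(annotation) {
  annotation |>
    group_by(.data$snp_id) |>
    summarise(intragenic = any(.data$intragenic & .data$assigned),
              .groups = "drop")
}

#' Genes harbouring replicated SNPs
#'
#' @param annotation Output of [annotate_snps()].
#' @param replicated_snps Character vector of replicated SNP ids (see
#'   [replication_filter()]).
#' @return Character vector of unique gene symbols with at least one
#'   assigned replicated SNP (window-assigned counts), the input for
#'   external functional enrichment and for gene-level set analysis.
#' @export
build_gene_sets <- function(annotation, replicated_snps) {
  if (!length(replicated_snps)) {
    warnf("no replicated SNPs: empty gene list")
    return(character(0))
  }
  sort(unique(annotation$gene[annotation$assigned &
                                annotation$snp_id %in% replicated_snps]))
}

#' Expand gene sets into SNP sets
#'
#' For each named set of gene symbols, collects every panel SNP assigned to
#' any member gene (window semantics of [annotate_snps()]) and counts the
#' genome-wide intragenic/intergenic composition used for matched-random
#' sampling. Member genes absent from the interval annotation are skipped
#' and recorded.
#'
#' @param sets Named list mapping set ids to character vectors of gene
#'   symbols. For gene-level analysis pass one singleton set per gene.
#' @param annotation Output of [annotate_snps()] on the full post-QC panel.
#' @return A `snp_sets` tibble: `set_id`, `snps` (list column), `total`,
#'   `n_intragenic`, `n_intergenic`, `genes_missing`.
#' @export
expand_pathways <- function(sets, annotation) {
  strata <- snp_strata(annotation)
  known_genes <- unique(annotation$gene[annotation$assigned])
  rows <- purrr::imap(sets, function(members, id) {
    missing <- setdiff(members, known_genes)
    ann <- annotation[annotation$assigned & annotation$gene %in% members, ]
    snps <- unique(ann$snp_id)
    intr <- strata$intragenic[match(snps, strata$snp_id)]
    n_snps <- length(snps)
    tibble(
      set_id = id,
      snps = list(snps),
      total = n_snps,
      n_intragenic = sum(intr),
      n_intergenic = n_snps - sum(intr),
      genes_missing = list(missing)
    )
  })
  out <- bind_rows(rows)
  n_missing <- sum(lengths(out$genes_missing))
  if (n_missing) {
    inform(sprintf("%d set gene(s) absent from the annotation were skipped",
                   n_missing))
  }
  class(out) <- c("snp_sets", class(out))
  out
}
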