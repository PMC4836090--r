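# Readers and writers for the study's plain-text interchange formats.
# PED/MAP is parsed here because no installed package handles PLINK text;
# BED and GMT go through rtracklayer and fgsea.

#' Read PLINK-style PED/MAP text files into a dosage matrix
#'
#' @param ped,map Paths to whitespace-separated PED and MAP files. The PED
#'   carries family id, individual id, paternal and maternal ids, sex code
#'   (1 male / 2 female) and phenotype, followed by two allele columns per
#'   SNP with `0` for a missing call.
#' @param alt Optional character vector (one allele per MAP SNP) fixing
#'   which allele is counted by the dosage; by default the empirically
#'   rarer allele is counted (alphabetically first on a tie).
#' @return List with `genotypes` (subjects x SNPs dosage matrix, `NA` for
#'   missing), `variants` (snp_id, chrom, pos, counted allele, other
#'   allele) and `subjects` (ids and sex).
#' @export
read_ped_map <- function(ped, map, alt = NULL) {
  map_df <- readr::read_table(
    map, col_names = c("chrom", "snp_id", "cm", "pos"),
    col_types = readr::cols(
      chrom = readr::col_character(), snp_id = readr::col_character(),
      cm = readr::col_double(), pos = readr::col_integer())
  )
  m <- nrow(map_df)
  lines <- readr::read_lines(ped)
  toks <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(toks) != 6 + 2 * m)
  if (length(bad)) {
    stopf("PED line %d has %d fields, expected %d", bad[1],
          lengths(toks)[bad[1]], 6 + 2 * m)
  }
  tok <- matrix(unlist(toks), nrow = length(toks), byrow = TRUE)
  subjects <- tibble(
    subject_id = tok[, 2],
    sex = c("male", "female", NA)[match(tok[, 5], c("1", "2"), nomatch = 3)]
  )
  a1 <- tok[, 6 + 2 * seq_len(m) - 1, drop = FALSE]
  a2 <- tok[, 6 + 2 * seq_len(m), drop = FALSE]
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA

  counted <- character(m); other <- character(m)
  G <- matrix(NA_integer_, nrow(tok), m,
              dimnames = list(subjects$subject_id, map_df$snp_id))
  for (j in seq_len(m)) {
    als <- sort(unique(stats::na.omit(c(a1[, j], a2[, j]))))
    if (length(als) > 2) stopf("SNP %s has >2 alleles", map_df$snp_id[j])
    if (length(als) == 0) { counted[j] <- NA; other[j] <- NA; next }
    if (!is.null(alt)) {
      counted[j] <- alt[j]
      other[j] <- setdiff(als, alt[j])[1] %||% als[1]
    } else if (length(als) == 1) {
      counted[j] <- als; other[j] <- NA
    } else {
      cnt1 <- sum(a1[, j] == als[1], na.rm = TRUE) +
        sum(a2[, j] == als[1], na.rm = TRUE)
      cnt2 <- sum(a1[, j] == als[2], na.rm = TRUE) +
        sum(a2[, j] == als[2], na.rm = TRUE)
      if (cnt1 <= cnt2) {  # tie -> alphabetically first allele counted
        counted[j] <- als[1]; other[j] <- als[2]
      } else {
        counted[j] <- als[2]; other[j] <- als[1]
      }
    }
    G[, j] <- (a1[, j] == counted[j]) + (a2[, j] == counted[j])
  }
  list(
    genotypes = G,
    variants = tibble(snp_id = map_df$snp_id, chrom = map_df$chrom,
                      pos = map_df$pos, counted = counted, other = other),
    subjects = subjects
  )
}

#' Write a genotype matrix as PED/MAP
#'
#' @param genotypes Subjects x SNPs dosage matrix (`NA` = missing call).
#' @param variants Tibble with `snp_id`, `chrom`, `pos`, `ref`, `alt`;
#'   dosages count the `alt` allele.
#' @param subjects Tibble with `subject_id` and `sex` ("male"/"female").
#' @param ped,map Output paths.
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(genotypes, variants, subjects, ped, map) {
  check_dosage(genotypes)
  stopifnot(ncol(genotypes) == nrow(variants),
            nrow(genotypes) == nrow(subjects))
  readr::write_lines(
    sprintf("%s\t%s\t0\t%d", variants$chrom, variants$snp_id, variants$pos),
    map
  )
  m <- nrow(variants)
  n <- nrow(genotypes)
  allele_strings <- vapply(seq_len(m), function(j) {
    g <- genotypes[, j]
    codes <- c("0 0",
               paste(variants$ref[j], variants$ref[j]),
               paste(variants$ref[j], variants$alt[j]),
               paste(variants$alt[j], variants$alt[j]))
    codes[ifelse(is.na(g), 1L, g + 2L)]
  }, character(n))
  if (n == 1) allele_strings <- matrix(allele_strings, nrow = 1)
  sexcode <- ifelse(subjects$sex == "male", 1L, 2L)
  lead <- sprintf("%s %s 0 0 %d -9", subjects$subject_id,
                  subjects$subject_id, sexcode)
  body <- apply(allele_strings, 1, paste, collapse = " ")
  readr::write_lines(paste(lead, body), ped)
  invisible(c(ped = ped, map = map))
}

#' Read gene intervals from a BED file
#'
#' BED input is 0-based half-open; intervals are converted to the 1-based
#' inclusive coordinates used throughout the package.
#'
#' @param path BED file with the gene symbol in column 4.
#' @return Tibble with `gene`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_gene_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stopf("reading BED requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "bed")
  tibble(
    gene = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),  # rtracklayer already shifts to 1-based
    end = GenomicRanges::end(gr)
  )
}

#' Write gene intervals to a BED file
#' @param genes Tibble with `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive); written as 0-based half-open BED4.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_bed <- function(genes, path) {
  readr::write_lines(
    sprintf("%s\t%d\t%d\t%s", genes$chrom, genes$start - 1L, genes$end,
            genes$gene),
    path
  )
  invisible(path)
}

#' Read gene sets from a GMT file
#' @param path GMT file (set id, description, then member gene symbols,
#'   tab-separated).
#' @return Named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    stopf("reading GMT requires the fgsea package")
  }
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#' @param pathways Named list of character vectors of gene symbols.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(pathways))
  readr::write_lines(
    vapply(seq_along(pathways), function(i) {
      paste(c(names(pathways)[i], descriptions[i], pathways[[i]]),
            collapse = "\t")
    }, character(1)),
    path
  )
  invisible(path)
}

#' Write a generated study to disk
#'
#' Serialises both cohorts of a `synth_study` as PED/MAP, the longitudinal
#' scores and covariates as TSV, gene intervals as BED, pathways as GMT and
#' the causal-variant truth record as TSV.
#'
#' @param study A `synth_study` from [generate_cohorts()].
#' @param dir Output directory (created if needed).
#' @return A manifest tibble (`file`, `rows`) listing every file written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synth_study"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stopf("cannot create output directory '%s'", dir)
  }
  manifest <- list()
  add <- function(file, rows) {
    manifest[[length(manifest) + 1]] <<- tibble(file = file, rows = rows)
  }
  for (ch in c("discovery", "replication")) {
    co <- study[[ch]]
    ped <- file.path(dir, paste0(ch, ".ped"))
    map <- file.path(dir, paste0(ch, ".map"))
    write_ped_map(co$genotypes, co$variants, co$subjects, ped, map)
    add(ped, nrow(co$genotypes)); add(map, nrow(co$variants))
    scores <- left_join(co$scores, co$subjects, by = "subject_id") |>
      select("subject_id", "cohort", "sex", "age", "subpop", "week", "score")
    sc_path <- file.path(dir, paste0(ch, "_scores.tsv"))
    readr::write_tsv(scores, sc_path)
    add(sc_path, nrow(scores))
  }
  bed <- file.path(dir, "genes.bed")
  write_gene_bed(study$genes, bed); add(bed, nrow(study$genes))
  gmt <- file.path(dir, "pathways.gmt")
  write_gmt(study$pathways, gmt); add(gmt, length(study$pathways))
  truth <- file.path(dir, "truth.tsv")
  tr <- study$truth$causal
  tr$spiked_pathway <- study$truth$spiked_pathway %||% NA_character_
  readr::write_tsv(tr, truth); add(truth, nrow(tr))
  bind_rows(manifest)
}
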