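# ggplot2 displays for association and enrichment results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Manhattan plot of a GWAS scan
#'
#' @param object A `gwas_result` from [run_gwas()].
#' @param alpha_line Nominal threshold drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gwas_result <- function(object, alpha_line = 0.05, ...) {
  df <- object[!is.na(object$p), ]
  df <- arrange(df, .data$chrom, .data$pos)
  df$index <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = -log10(.data$p),
                                   colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(alpha_line), linetype = 2) +
    ggplot2::labs(x = "SNP (genome order)", y = "-log10 p",
                  title = paste("Association scan:",
                                df$phenotype[1], "/", df$cohort[1])) +
    ggplot2::theme_minimal()
}

#' Quantile-quantile plot of association p-values
#'
#' @param result A `gwas_result` (or any tibble with a `p` column).
#' @return A ggplot object comparing observed to uniform quantiles.
#' @export
plot_qq <- function(result) {
  p <- sort(result$p[!is.na(result$p)])
  df <- tibble(expected = -log10(stats::ppoints(length(p))),
               observed = -log10(p))
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "expected -log10 p", y = "observed -log10 p") +
    ggplot2::theme_minimal()
}

#' Enrichment overview: observed vs chance-expected significant members
#'
#' Bars show each set's observed proportion of sub-threshold SNPs per
#' cohort with the matched random set's proportion as a point, at the
#' primary member threshold.
#'
#' @param object An `enrich_result` from [run_set_analysis()].
#' @param threshold Which member threshold to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.enrich_result <- function(object, threshold = 0.05, ...) {
  df <- object[object$threshold == threshold, ]
  df$random_pct <- df$r_true / (df$r_true + df$r_false)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set_id)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$pct_true),
                      fill = "steelblue", alpha = 0.8) +
    ggplot2::geom_point(ggplot2::aes(y = .data$random_pct)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::facet_wrap(~cohort) +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "proportion of significant member SNPs", x = NULL,
                  caption = "bar: target set; point: matched random set") +
    ggplot2::theme_minimal()
}
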