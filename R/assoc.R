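# Per-SNP logistic association with phenotype-specific covariates, the
# SNP-level Bonferroni threshold, and the two-cohort replication filter.

#' Logistic regression fit for one SNP model
#'
#' Maximum-likelihood logistic regression by iteratively reweighted least
#' squares (via [stats::glm.fit()]), with Wald z statistics and two-sided
#' p-values. Quasi-complete separation and non-convergence are flagged
#' (`usable = FALSE`) rather than thrown; a rank-deficient design is an
#' error naming the offending column.
#'
#' @param y Binary outcome vector (0/1 or logical), both classes present.
#' @param x Design matrix including an intercept column.
#' @return Object of class `snp_logit` with `coefficients`, `se`,
#'   `statistic`, `p.value`, `n`, `deviance`, `converged` and `usable`.
#'   [generics::tidy()] returns the per-term table, [generics::glance()] the
#'   fit summary.
#' @export
#' @examples
#' set.seed(1)
#' x <- cbind(1, rbinom(50, 2, 0.3))
#' y <- rbinom(50, 1, plogis(-0.2 + 0.5 * x[, 2]))
#' tidy(fit_logistic(y, x))
fit_logistic <- function(y, x) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stopf("outcome must be binary 0/1")
  if (length(unique(y)) < 2) stopf("outcome has a single class")
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    colnames(x) <- c("(Intercept)", paste0("x", seq_len(ncol(x) - 1)))
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stopf("collinear design: column '%s' is linearly dependent", bad[1])
  }
  fit <- suppressWarnings(glm.fit(x, y, family = binomial()))
  beta <- fit$coefficients
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  xtwx <- crossprod(x * sqrt(w))
  cov <- tryCatch(chol2inv(chol(xtwx)), error = function(e) NULL)
  # scale-free separation flag: fitted log-odds pinned at +/- infinity
  eta <- drop(x %*% ifelse(is.na(beta), 0, beta))
  separated <- is.null(cov) || max(abs(eta)) > 25 || min(w) < 1e-10
  if (is.null(cov)) {
    se <- rep(NA_real_, length(beta))
  } else {
    se <- sqrt(diag(cov))
  }
  z <- beta / se
  structure(
    list(coefficients = beta, se = setNames(se, names(beta)),
         statistic = z, p.value = 2 * pnorm(-abs(z)),
         n = length(y), deviance = fit$deviance,
         df.residual = fit$df.residual,
         converged = isTRUE(fit$converged),
         usable = isTRUE(fit$converged) && !separated),
    class = "snp_logit"
  )
}

#' @rdname fit_logistic
#' @param x A `snp_logit` object (for the methods).
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.snp_logit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients),
         std.error = unname(x$se), statistic = unname(x$statistic),
         p.value = unname(x$p.value))
}

#' @rdname fit_logistic
#' @exportS3Method generics::glance
glance.snp_logit <- function(x, ...) {
  tibble(n = x$n, deviance = x$deviance, df.residual = x$df.residual,
         converged = x$converged, usable = x$usable)
}

#' @export
print.snp_logit <- function(x, ...) {
  cat(sprintf("<snp_logit> n=%d, converged=%s, usable=%s\n",
              x$n, x$converged, x$usable))
  print(tidy(x))
  invisible(x)
}

# lean per-SNP fit used by the genome-wide scan: plain IRLS on the normal
# equations (the same maximum-likelihood iteration as fit_logistic, with
# far less per-call overhead); returns NULL for rank-deficient designs
fast_logit <- function(X, y, maxit = 30, tol = 1e-10, start = NULL) {
  p <- ncol(X)
  beta <- numeric(p)
  if (!is.null(start) && length(start) == p) {
    beta <- start
  } else {
    beta[1] <- qlogis(min(max(mean(y), 1e-3), 1 - 1e-3))
  }
  dev_old <- Inf
  conv <- FALSE
  ch <- NULL
  w <- NULL
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    # deviance via eta avoids clamped logs: log(mu) = eta - softplus(eta)
    softplus <- pmax(eta, 0) + log1p(exp(-abs(eta)))
    dev <- -2 * (sum(y * eta) - sum(softplus))
    w <- mu * (1 - mu)
    if (min(w) < 1e-12) w <- pmax(w, 1e-12)
    if (abs(dev - dev_old) < tol * (abs(dev) + 0.1)) { conv <- TRUE; break }
    dev_old <- dev
    z <- eta + (y - mu) / w
    ch <- tryCatch(chol(crossprod(X, X * w)), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    beta <- drop(chol2inv(ch) %*% crossprod(X, w * z))
  }
  # SE from the weights of the last evaluated iterate; at convergence the
  # remaining step is below tol so the difference is negligible
  ch <- tryCatch(chol(crossprod(X, X * w)), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  se <- sqrt(diag(chol2inv(ch)))
  # separation flagged on the fitted log-odds, not coefficient size, so
  # small-scale covariates (MDS axes) cannot trip it
  usable <- conv && max(abs(drop(X %*% beta))) <= 25 && min(w) >= 1e-10
  list(beta = beta, se = se, usable = usable)
}

#' Assemble the covariate table for one phenotype/cohort analysis
#'
#' Sex and age always enter; baseline symptom severity enters for the
#' remission phenotype only; MDS ancestry components enter when an ancestry
#' table is supplied (the stratified replication cohort).
#'
#' @param subjects Tibble with `subject_id`, `sex`, `age`.
#' @param phenotype `"response"` or `"remission"`.
#' @param baseline Tibble with `subject_id`, `baseline` (required for
#'   remission).
#' @param ancestry Optional tibble from [ancestry_components()]; its `MDS*`
#'   columns are used.
#' @return Tibble of numeric covariates keyed by `subject_id`.
#' @export
build_covariates <- function(subjects, phenotype = c("response", "remission"),
                             baseline = NULL, ancestry = NULL) {
  phenotype <- match.arg(phenotype)
  out <- tibble(
    subject_id = subjects$subject_id,
    sex = as.numeric(subjects$sex == "male"),
    age = as.numeric(subjects$age)
  )
  if (phenotype == "remission") {
    if (is.null(baseline)) stopf("remission requires a baseline column")
    out <- left_join(out, baseline[, c("subject_id", "baseline")],
                     by = "subject_id")
  }
  if (!is.null(ancestry)) {
    mds <- ancestry[, c("subject_id", grep("^MDS", names(ancestry),
                                           value = TRUE))]
    out <- left_join(out, mds, by = "subject_id")
  }
  out
}

#' Genome-wide per-SNP logistic association scan
#'
#' Fits one additive-dosage logistic model per polymorphic SNP. Subjects
#' with a missing genotype are dropped for that SNP only; monomorphic SNPs
#' (on the analysed subjects) are skipped and listed in the `skipped`
#' attribute.
#'
#' @param genotypes Subjects x SNPs minor-dosage matrix.
#' @param outcome Named logical/0-1 vector of phenotype calls (names =
#'   subject ids); subjects absent or `NA` are excluded.
#' @param covariates Optional tibble from [build_covariates()]; rows with
#'   missing covariates are excluded.
#' @param variants Optional variant tibble (`snp_id`, `chrom`, `pos`)
#'   carried into the output.
#' @param phenotype,cohort Labels carried into the output.
#' @return A `gwas_result` tibble: `snp_id`, `chrom`, `pos`, `maf`,
#'   `n_used`, `beta`, `odds_ratio`, `statistic`, `p`, `converged`, plus
#'   `phenotype` and `cohort` columns. SNPs whose fit was unusable
#'   (separation, non-convergence) carry `converged = FALSE` and `NA` p.
#' @export
run_gwas <- function(genotypes, outcome, covariates = NULL, variants = NULL,
                     phenotype = NA_character_, cohort = NA_character_) {
  check_dosage(genotypes)
  ids <- rownames(genotypes)
  y_all <- outcome[match(ids, names(outcome))]
  keep <- !is.na(y_all)
  Z <- NULL
  if (!is.null(covariates)) {
    cv <- covariates[match(ids, covariates$subject_id), ]
    Z <- as.matrix(cv[, setdiff(names(cv), "subject_id"), drop = FALSE])
    keep <- keep & complete.cases(Z)
  }
  G <- genotypes[keep, , drop = FALSE]
  y <- as.numeric(y_all[keep])
  if (length(unique(y)) < 2) stopf("outcome has a single class after filtering")
  Z <- if (is.null(Z)) matrix(1, nrow(G), 1,
                              dimnames = list(NULL, "(Intercept)"))
       else cbind("(Intercept)" = 1, Z[keep, , drop = FALSE])

  if (is.null(variants)) {
    variants <- tibble(snp_id = colnames(G), chrom = NA_character_,
                       pos = NA_integer_)
  }
  m <- ncol(G)
  beta <- se <- rep(NA_real_, m)
  n_used <- integer(m)
  conv <- rep(FALSE, m)
  maf <- col_freqs(G)$maf
  skipped <- character(0)
  any_na_dose <- anyNA(G)
  # warm start for every per-SNP fit: the covariate-only model
  null_fit <- fast_logit(Z, y)
  start <- if (is.null(null_fit)) NULL else c(null_fit$beta, 0)
  for (j in seq_len(m)) {
    dose <- G[, j]
    ok <- if (any_na_dose) !is.na(dose) else rep(TRUE, length(dose))
    yj <- y[ok]
    dj <- dose[ok]
    n_used[j] <- length(dj)
    rng <- range(dj)
    if (rng[1] == rng[2] || length(unique(yj)) < 2) {
      skipped <- c(skipped, colnames(G)[j])
      next
    }
    X <- cbind(Z[ok, , drop = FALSE], dose = dj)
    fit <- fast_logit(X, yj, start = start)
    if (is.null(fit)) { skipped <- c(skipped, colnames(G)[j]); next }
    k <- length(fit$beta)
    beta[j] <- fit$beta[k]
    se[j] <- fit$se[k]
    conv[j] <- fit$usable
  }
  out <- tibble(
    snp_id = colnames(G),
    chrom = variants$chrom[match(colnames(G), variants$snp_id)],
    pos = variants$pos[match(colnames(G), variants$snp_id)],
    maf = maf,
    n_used = n_used,
    beta = beta,
    odds_ratio = exp(beta),
    statistic = beta / se,
    p = 2 * pnorm(-abs(beta / se)),
    converged = conv,
    phenotype = phenotype,
    cohort = cohort
  )
  out <- out[!(out$snp_id %in% skipped), ]
  attr(out, "skipped") <- skipped
  class(out) <- c("gwas_result", class(out))
  out
}

#' Bonferroni-corrected significance threshold
#' @param alpha Family-wise error rate.
#' @param n_tests Number of tests at this analysis level.
#' @return `alpha / n_tests`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 585693)
bonferroni_threshold <- function(alpha, n_tests) {
  if (n_tests < 1) stopf("`n_tests` must be >= 1")
  alpha / n_tests
}

#' Cross-cohort replication filter
#'
#' SNPs nominally significant (`p < alpha`) in the discovery cohort are
#' looked up in the replication cohort; those with `p < alpha` in both are
#' replicated. Effect direction is deliberately not a criterion. Discovery
#' hits absent from the replication panel are annotated `"untested"`.
#'
#' @param discovery,replication `gwas_result` tibbles (or any tibble with
#'   `snp_id` and `p`; an optional `converged` column gates usable fits).
#' @param alpha Nominal threshold applied in both cohorts.
#' @return Tibble with `snp_id`, `p_discovery`, `p_replication` and
#'   `status` (`"replicated"`, `"not_replicated"`, `"untested"`). The
#'   replicated ids are also attached as attribute `"replicated"`.
#' @export
replication_filter <- function(discovery, replication, alpha = 0.05) {
  usable <- function(x) {
    ok <- !is.na(x$p)
    if ("converged" %in% names(x)) ok <- ok & x$converged
    x[ok, c("snp_id", "p")]
  }
  d <- usable(discovery)
  r <- usable(replication)
  if (!length(intersect(d$snp_id, r$snp_id))) {
    warnf("no SNPs tested in both cohorts")
  }
  hits <- d[d$p < alpha, ]
  out <- tibble(
    snp_id = hits$snp_id,
    p_discovery = hits$p,
    p_replication = r$p[match(hits$snp_id, r$snp_id)]
  )
  out$status <- dplyr::case_when(
    is.na(out$p_replication) ~ "untested",
    out$p_replication < alpha ~ "replicated",
    TRUE ~ "not_replicated"
  )
  attr(out, "replicated") <- out$snp_id[out$status == "replicated"]
  out
}
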