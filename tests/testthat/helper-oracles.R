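# Independent oracles used to freeze expected values. Each is written
# against the bare mathematical definition, separately from the package's
# implementation path.

# Hardy-Weinberg exact test by direct enumeration of heterozygote counts:
# P(h hets | n1 rare alleles among 2n) computed from binomial coefficients.
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n1 <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  hs <- seq(n1 %% 2, min(n1, 2 * n - n1), by = 2)
  pr <- vapply(hs, function(h) {
    h1 <- (n1 - h) / 2
    exp(lchoose(n, h) + lchoose(n - h, h1) + h * log(2) - lchoose(2 * n, n1))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hs)]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# two-sided Fisher exact p by complete enumeration of tables with the
# observed margins, probabilities from log-binomial coefficients
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; N <- m1 + m2
  as <- max(0, k - m2):min(k, m1)
  pr <- exp(lchoose(m1, as) + lchoose(m2, k - as) - lchoose(N, k))
  obs <- pr[match(a, as)]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# Newton-Raphson logistic MLE from the analytic score and Hessian
newton_logit_oracle <- function(X, y, maxit = 100, tol = 1e-12) {
  beta <- numeric(ncol(X))
  for (it in seq_len(maxit)) {
    mu <- plogis(drop(X %*% beta))
    score <- crossprod(X, y - mu)
    hess <- crossprod(X, X * (mu * (1 - mu)))
    step <- solve(hess, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  mu <- plogis(drop(X %*% beta))
  se <- sqrt(diag(solve(crossprod(X, X * (mu * (1 - mu))))))
  list(beta = drop(beta), se = se)
}
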