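# internal helpers shared across modules

`%||%` <- rlang::`%||%`

stopf <- function(fmt, ..., class = "pathgwas_error") {
  rlang::abort(sprintf(fmt, ...), class = class)
}

warnf <- function(fmt, ...) {
  rlang::warn(sprintf(fmt, ...))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stopf("`%s` must be a probability in [0, 1]", name)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    stopf("`%s` must be a whole number >= %d", name, min)
  }
  invisible(as.integer(x))
}

# run `expr` under a private RNG stream when `seed` is given, otherwise use
# the session RNG; all stochastic operations in the package route through this
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# dosage matrix sanity check: integer-ish values in {0,1,2,NA}
check_dosage <- function(geno) {
  if (!is.matrix(geno)) stopf("genotypes must be a matrix")
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    stopf("genotype dosages must be 0, 1, 2 or NA")
  }
  invisible(geno)
}
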