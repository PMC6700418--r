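# Independent oracle implementations used to cross-check the package.
# These deliberately avoid stats::cor and the package's own code paths.

# product-moment correlation by the raw sum formula
pearson_sum_formula <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  if (den == 0) return(NA_real_)
  num / den
}

# phi coefficient from the 2x2 contingency-table closed form
phi_contingency <- function(pa, pb) {
  n11 <- sum(pa == 1 & pb == 1)
  n10 <- sum(pa == 1 & pb == 0)
  n01 <- sum(pa == 0 & pb == 1)
  n00 <- sum(pa == 0 & pb == 0)
  den <- sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
  if (den == 0) return(NA_real_)
  (n11 * n00 - n10 * n01) / den
}

# one-sided KS ("x stochastically greater") via permutation
ks_stat_greater <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)(pts)
  fy <- stats::ecdf(y)(pts)
  max(fy - fx) # "x stochastically greater" <=> CDF of x lies below y's
}

ks_perm_p <- function(x, y, n_perm = 10000) {
  obs <- ks_stat_greater(x, y)
  pool <- c(x, y)
  n1 <- length(x)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pool), n1)
    if (ks_stat_greater(pool[idx], pool[-idx]) >= obs) hits <- hits + 1L
  }
  hits / n_perm
}

# Mann-Whitney U with tie handling, plus exact p by full enumeration
mw_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

mw_exact_p_greater <- function(x, y) {
  obs <- mw_u(x, y)
  pool <- c(x, y)
  picks <- utils::combn(length(pool), length(x))
  stats <- apply(picks, 2, function(i) mw_u(pool[i], pool[-i]))
  mean(stats >= obs)
}
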