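# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: naive enumeration, closed forms and exact
# integer arithmetic.

# Exact Pascal triangle: pascal[n+1, k+1] = choose(n, k), built by integer
# addition. All entries for n <= 40 are < 2^53, hence exact in doubles.
pascal_triangle <- function(nmax) {
  p <- matrix(0, nmax + 1L, nmax + 1L)
  p[, 1L] <- 1
  for (n in 1:nmax) {
    for (k in 1:n) p[n + 1L, k + 1L] <- p[n, k] + p[n, k + 1L]
  }
  p
}

# Exact two-sided Fisher p for a 2x2 table (a b / c d) by enumeration over
# the hypergeometric support with exact integer numerators. The tie rule
# (probability at most observed, with relative slack) matches the
# definition of the statistic; arithmetic is exact.
fisher_oracle_p <- function(a, b, c, d, pascal, slack = 1e-7) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || b + d == 0) return(1)
  ks <- max(0L, c1 - r2):min(r1, c1)
  num <- pascal[r1 + 1L, ks + 1L] * pascal[r2 + 1L, c1 - ks + 1L]
  n_obs <- num[match(a, ks)]
  sum(num[num <= n_obs * (1 + slack)]) / pascal[r1 + r2 + 1L, c1 + 1L]
}

# Log-rank chi-square by direct accumulation over distinct death times
# (independent re-derivation used for permutation enumeration).
logrank_stat_oracle <- function(ta, tb) {
  tt <- c(ta, tb)
  in_a <- c(rep(TRUE, length(ta)), rep(FALSE, length(tb)))
  O <- E <- V <- 0
  for (t in sort(unique(tt))) {
    n <- sum(tt >= t); na <- sum(tt >= t & in_a)
    d <- sum(tt == t); da <- sum(tt == t & in_a)
    O <- O + da; E <- E + d * na / n
    if (n > 1) V <- V + d * (na / n) * (1 - na / n) * (n - d) / (n - 1)
  }
  if (V == 0) 0 else (O - E)^2 / V
}

# Exact permutation p-value of the log-rank statistic over all group
# relabelings (uncensored two-sample case, small n).
logrank_permutation_p <- function(ta, tb) {
  pool <- c(ta, tb)
  na <- length(ta)
  obs <- logrank_stat_oracle(ta, tb)
  combs <- utils::combn(length(pool), na)
  stats <- apply(combs, 2L, function(idx)
    logrank_stat_oracle(pool[idx], pool[-idx]))
  mean(stats >= obs - 1e-12)
}

# Naive Cox partial log-likelihood (Breslow ties) by double loop over
# deaths and risk sets; independent of the cumulative-sum implementation.
cox_loglik_naive <- function(beta, x, time, event = rep(TRUE, length(time))) {
  eta <- x * beta
  ll <- 0
  for (i in which(event)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# Random valid cohort frame for round-trip properties.
random_cohort <- function(n, seed) {
  set.seed(seed)
  cohort(animal_id = sprintf("id%04d", sample.int(10 * n, n)),
         age_days  = stats::runif(n, 1, 1400),
         genotype  = sample(c("dwarf", "control"), n, replace = TRUE),
         treatment = sample(c("GH", "saline"), n, replace = TRUE),
         sex       = sample(c("male", "female"), n, replace = TRUE),
         event     = TRUE,
         protocol_label = "sim")
}
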