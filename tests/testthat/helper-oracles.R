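# Independent oracles used to cross-check the package's fitted quantities.
# These are deliberately naive re-derivations (loops, closed forms), kept
# free of any package internals.

# Cox partial log-likelihood for a single covariate, no ties assumed
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
  }
  ll
}

# maximise the oracle likelihood by golden-section search on a wide bracket
oracle_cox_mle <- function(time, event, x, lower = -8, upper = 8) {
  stats::optimize(oracle_cox_loglik, c(lower, upper), maximum = TRUE,
                  time = time, event = event, x = x,
                  tol = 1e-10)$maximum
}

# two-sample logrank chi-square, tie-free data, computed from first principles
oracle_logrank <- function(time, event, group) {
  stopifnot(all(group %in% c(0, 1)))
  u <- 0; v <- 0
  for (t in sort(time[event == 1])) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == 1)
    d1 <- sum(event == 1 & time == t & group == 1)
    u <- u + d1 - n1 / n
    v <- v + (n1 / n) * (1 - n1 / n)
  }
  u^2 / v
}

# all permutations of 1..n as a list of index vectors
all_permutations <- function(n) {
  perm_of <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perm_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  perm_of(seq_len(n))
}

# a tiny survival data set with distinct event times
make_tiny_survival <- function(n = 6, seed = 1) {
  set.seed(seed)
  list(time = sort(rexp(n)) * c(1, 1.3, 0.7, 1.9, 1.1, 0.8)[seq_len(n)],
       event = rep(1L, n),
       x = round(rnorm(n), 2))
}

# small cohort configuration used across pipeline tests
small_config <- function(seed = 11, n = 1200, n_sub = 400, ...) {
  generator_config(n_cohort = n, n_subcohort = n_sub, seed = seed, ...)
}

# counted-allele genotype matrix of a simulated cohort
cohort_genotypes <- function(cohort, snps = default_snp_panel(),
                             dosages = FALSE) {
  rsids <- vapply(snps, `[[`, character(1), "rsid")
  cols <- if (dosages) paste0(rsids, "_ds") else rsids
  m <- as.matrix(cohort[, cols])
  colnames(m) <- rsids
  m
}
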