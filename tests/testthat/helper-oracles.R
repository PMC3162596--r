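# Independent oracles, deliberately written as naive step-by-step code so
# they share no logic with the package implementation.

# Exhaustive running-sum evaluation: walk the (already ranked) list one
# position at a time.
oracle_running_sum <- function(ids, scores, gene_set, weight_exponent = 1) {
  L <- length(ids)
  hits <- ids %in% gene_set
  nr <- 0
  for (i in seq_len(L)) if (hits[i]) nr <- nr + abs(scores[i])^weight_exponent
  rs <- numeric(L)
  cur <- 0
  for (i in seq_len(L)) {
    if (hits[i]) {
      cur <- cur + if (nr > 0) abs(scores[i])^weight_exponent / nr else
        1 / sum(hits)
    } else {
      cur <- cur - 1 / (L - sum(hits))
    }
    rs[i] <- cur
  }
  mx <- 0; mn <- 0
  for (i in seq_len(L)) {
    if (rs[i] > mx) mx <- rs[i]
    if (rs[i] < mn) mn <- rs[i]
  }
  # magnitude ties (to within 1e-12) resolve to the negative extremum,
  # matching the documented convention
  best <- if (abs(mx) > abs(mn) + 1e-12) mx else mn
  if (best > 0) {
    pos <- which(rs == best)[1]
    le <- ids[hits & seq_len(L) <= pos]
  } else if (best < 0) {
    pos <- which(rs == best)[1]
    le <- ids[hits & seq_len(L) >= pos]
  } else le <- character(0)
  list(es = best, running_sum = rs, leading_edge = le)
}

# Upper-tail Student-t probability by numerical integration of the density,
# independent of pt().
oracle_t_upper_p <- function(t_stat, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  if (t_stat >= 0) {
    stats::integrate(dens, t_stat, Inf, rel.tol = 1e-12)$value
  } else {
    1 - stats::integrate(dens, -Inf, t_stat, rel.tol = 1e-12)$value
  }
}

# Exact hypergeometric upper tail by direct summation of binomial
# coefficients.
oracle_hyper_tail <- function(k, n, K, N) {
  hi <- min(n, K)
  if (k > hi) return(0)
  i <- max(k, max(0, n - (N - K))):hi
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Small, fast generator configuration for unit tests.
small_config <- function(seed = 7, ...) {
  args <- list(seed = seed, n_genes = 400, n_enriched_per_tissue = 20,
               total_reads_per_tissue = 1e6, n_terms = 12, term_overlap = 10)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_config, args)
}
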