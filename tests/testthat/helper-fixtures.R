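# Shared fixtures and independent oracles, built in code at test time.

# Small, fast cohort configuration for unit tests.
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_subjects = 200, n_genes = 40, variants_per_gene = 8,
                   n_sets = 4, genes_per_set = 10, n_causal_genes = 4,
                   seed = 42)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Independent two-sided Fisher oracle: exhaustive hypergeometric enumeration
# over all tables with the observed margins, summing those with probability
# not exceeding the observed one (with the customary 1e-7 relative guard
# against floating-point ties). a,b = case carriers/non-carriers,
# c,d = control carriers/non-carriers.
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  x <- max(0, r1 + c1 - n):min(r1, c1)
  logp <- lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)
  p <- exp(logp)
  p_obs <- p[x == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Textbook Pearson chi-square oracle: sum (O-E)^2/E over the 2x2 table,
# then the 1-df survival function.
chisq_enum_oracle <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  e <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  stats::pchisq(sum((obs - e)^2 / e), df = 1, lower.tail = FALSE)
}

# Binomial deviance of fitted probabilities.
binomial_deviance <- function(y, p) -2 * sum(y * log(p) + (1 - y) * log(1 - p))

# Agreement between cluster labels and true labels, maximized over label
# permutations (3 clusters or fewer).
best_label_agreement <- function(cluster, truth) {
  k <- sort(unique(truth))
  perms <- if (length(k) == 3)
    list(k, k[c(1, 3, 2)], k[c(2, 1, 3)], k[c(2, 3, 1)], k[c(3, 1, 2)], k[c(3, 2, 1)])
  else list(k)
  best <- 0
  for (p in perms) {
    mapped <- p[match(cluster, sort(unique(cluster)))]
    best <- max(best, mean(mapped == truth))
  }
  best
}
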