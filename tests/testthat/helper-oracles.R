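# Independent oracles used by the test suite. Each re-derives a result by
# the most transparent route available (explicit loops, enumeration,
# textbook formulas) without calling the implementation under test.

# Brute-force differential-proportion permutation test: per permutation,
# relabel a copy of the annotation table cell by cell and rebuild the
# count tables with table(). Shares the RNG stream contract of the fast
# implementation (two sample.int calls per permutation) so a common seed
# makes the two comparable permutation by permutation.
oracle_dpa <- function(ann, cond1, cond2, w, t, seed) {
  n <- nrow(ann)
  k <- as.integer(round(w * n))
  clusters <- sort(unique(ann$cluster))
  prop_tab <- function(a) {
    tab <- table(factor(a$cluster, clusters), a$condition)
    sweep(tab, 2, colSums(tab), `/`)
  }
  p0 <- prop_tab(ann)
  obs <- p0[, cond1] - p0[, cond2]
  set.seed(seed)
  null <- matrix(0, nrow = t, ncol = length(clusters))
  for (i in seq_len(t)) {
    sel <- sample.int(n, k)
    pool <- sample.int(n, k)
    a <- ann
    a$cluster[sel] <- ann$cluster[pool]
    p <- prop_tab(a)
    null[i, ] <- p[, cond1] - p[, cond2]
  }
  p_inc <- p_dec <- numeric(length(clusters))
  for (j in seq_along(clusters)) {
    p_inc[j] <- sum(null[, j] >= obs[j]) / t
    p_dec[j] <- sum(null[, j] <= obs[j]) / t
  }
  data.frame(cluster = clusters, delta_p = as.numeric(obs),
             p_increase = p_inc, p_decrease = p_dec,
             p_final = pmin(p_inc, p_dec), stringsAsFactors = FALSE)
}

# Two-sided Fisher's exact p for a 2x2 table by full hypergeometric
# enumeration: sum of probabilities of all outcomes no more probable than
# the observed one, margins fixed.
oracle_fisher_2x2 <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Textbook Benjamini-Hochberg step-up: p_(i) * n / i with a cumulative
# minimum taken from the largest rank downward, capped at 1.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# Loop re-implementation of the randomized-network null. Shares the
# sampling contract of lrnet_null (all m*T ligand draws in one call,
# then all m*T receptor draws, row-major permutation layout) so a shared
# seed gives identical draws; filtering and summation are recomputed
# path by path.
oracle_lrnet_null <- function(w_st, lr_weights, lig_pool, rec_pool, m,
                              min_path_weight, seed) {
  T_paths <- length(lr_weights)
  set.seed(seed)
  lig <- matrix(sample(lig_pool, m * T_paths, replace = TRUE), nrow = m)
  rec <- matrix(sample(rec_pool, m * T_paths, replace = TRUE), nrow = m)
  hits <- 0
  for (i in seq_len(m)) {
    w_i <- 0
    for (j in seq_len(T_paths)) {
      pw <- lig[i, j] + lr_weights[j] + rec[i, j]
      if (pw >= min_path_weight) w_i <- w_i + pw
    }
    if (w_i >= w_st) hits <- hits + 1
  }
  hits / m
}
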