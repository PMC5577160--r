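# Independent oracles, deliberately written differently from the package
# implementations they cross-check.

# hypergeometric upper tail by exhaustive enumeration of all draws
# (only for small N: walks every combination)
oracle_hyper_enum <- function(x, draws, K, N) {
  if (draws == 0) return(as.numeric(x <= 0))
  pop <- c(rep(1, K), rep(0, N - K))
  combos <- utils::combn(N, draws)
  hits <- colSums(matrix(pop[combos], nrow = draws))
  mean(hits >= x)
}

# hypergeometric upper tail by plain (non log-sum-exp) factorial summation
oracle_hyper_sum <- function(x, draws, K, N) {
  i <- max(x, draws - (N - K)):min(draws, K)
  if (length(i) == 0 || min(draws, K) < x) return(0)
  sum(exp(lgamma(K + 1) - lgamma(i + 1) - lgamma(K - i + 1) +
          lgamma(N - K + 1) - lgamma(draws - i + 1) - lgamma(N - K - draws + i + 1) -
          (lgamma(N + 1) - lgamma(draws + 1) - lgamma(N - draws + 1))))
}

# exhaustive quasi-biclique feasibility for tiny bipartite graphs:
# is there any block with >= n genes, >= m tumors and both per-node
# densities >= r? Enumerates gene subsets; for each, tumors eligible by
# their (G-dependent) degree, then tumor subsets among the eligible.
oracle_block_exists <- function(adj, n, m, r) {
  ng <- nrow(adj)
  for (size_g in n:ng) {
    gene_sets <- utils::combn(ng, size_g, simplify = FALSE)
    for (G in gene_sets) {
      tumor_deg <- colSums(adj[G, , drop = FALSE])
      eligible <- which(tumor_deg >= r * size_g)
      if (length(eligible) < m) next
      for (size_t in m:length(eligible)) {
        tum_sets <- utils::combn(length(eligible), size_t, simplify = FALSE)
        for (Ti in tum_sets) {
          T_set <- eligible[Ti]
          if (all(rowSums(adj[G, T_set, drop = FALSE]) >= r * size_t)) {
            return(TRUE)
          }
        }
      }
    }
  }
  FALSE
}

# brute-force optimum GA weight over all k-subsets of the candidate pool
oracle_best_weight <- function(candidates, sga, t_abn, t_nor, k, r_me) {
  subsets <- utils::combn(candidates$gene, k, simplify = FALSE)
  min(vapply(subsets, solution_weight, numeric(1),
             sga = sga, t_abn = t_abn, t_nor = t_nor, k = k, r_me = r_me))
}

# verify a returned block against all four quasi-biclique constraints
block_satisfies <- function(adj, block, n, m, r) {
  sub <- adj[block$genes, block$tumors, drop = FALSE]
  length(block$genes) >= n && length(block$tumors) >= m &&
    all(rowSums(sub) >= r * ncol(sub)) &&
    all(colSums(sub) >= r * nrow(sub))
}
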