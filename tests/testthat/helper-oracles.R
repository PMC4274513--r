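# Independent oracles: deliberately naive implementations used to verify
# the package's metric code, never sharing code paths with it.

# Floyd-Warshall all-pairs shortest paths. mode "binary": unit edge
# lengths on positive-weight pairs; "weighted_inverse": lengths 1/w.
fw_distances <- function(W, mode = "binary") {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && W[i, j] > 0) {
        D[i, j] <- if (mode == "binary") 1 else 1 / W[i, j]
      }
    }
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

fw_e2 <- function(W, mode = "binary") {
  D <- fw_distances(W, mode)
  d <- D[upper.tri(D)]
  mean(ifelse(is.finite(d), 1 / d, 0))
}

fw_diameter <- function(W, mode = "binary") {
  D <- fw_distances(W, mode)
  d <- D[upper.tri(D)]
  max(d[is.finite(d)])
}

# Newman modularity of a membership vector, straight from the definition
# (weighted adjacency, strength-sequence null), no igraph.
q_formula <- function(W, memb) {
  m2 <- sum(W)
  k <- rowSums(W)
  sum((W - outer(k, k) / m2) * outer(memb, memb, "==")) / m2
}

# Exhaustive maximum of Q over all 2-way partitions (node 1 fixed in
# cluster 1). Feasible for n <= ~14.
best_bipartition_q <- function(W) {
  n <- nrow(W)
  best <- q_formula(W, rep(1L, n))
  for (code in seq_len(2^(n - 1)) - 1L) {
    memb <- c(1L, as.integer(intToBits(code)[seq_len(n - 1)]) + 1L)
    q <- q_formula(W, memb)
    if (q > best) best <- q
  }
  best
}

# Power-iteration principal eigenvector (unit Euclidean norm, non-negative).
power_centrality <- function(W, iters = 10000, tol = 1e-14) {
  v <- rep(1, nrow(W)) / sqrt(nrow(W))
  for (i in seq_len(iters)) {
    v2 <- W %*% v
    v2 <- as.numeric(v2) / sqrt(sum(v2^2))
    if (max(abs(v2 - v)) < tol) break
    v <- v2
  }
  abs(v)
}

# Holm step-down rejection set by literal enumeration of the definition:
# for each k in order of increasing p, reject only if every p_(j), j <= k,
# satisfies p_(j) <= alpha / (m - j + 1).
holm_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  thresholds <- alpha / (m - seq_len(m) + 1)
  ok <- p[ord] <= thresholds
  reject_sorted <- logical(m)
  for (k in seq_len(m)) reject_sorted[k] <- all(ok[seq_len(k)])
  reject <- logical(m)
  reject[ord] <- reject_sorted
  reject
}
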