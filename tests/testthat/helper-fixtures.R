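# Canonical small networks used across the test files.

make_star <- function(n, weight = 1) {
  W <- matrix(0, n, n)
  W[1, 2:n] <- weight
  W[2:n, 1] <- weight
  weighted_network(W, group_id = sprintf("star%d", n))
}

make_complete <- function(n, weight = 1) {
  W <- matrix(weight, n, n)
  diag(W) <- 0
  weighted_network(W, group_id = sprintf("complete%d", n))
}

make_path <- function(n) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) W[i, i + 1] <- W[i + 1, i] <- 1
  weighted_network(W, group_id = sprintf("path%d", n))
}

make_cycle <- function(n) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) W[i, i + 1] <- W[i + 1, i] <- 1
  W[1, n] <- W[n, 1] <- 1
  weighted_network(W, group_id = sprintf("cycle%d", n))
}

# two k-cliques joined by a single bridge edge
make_two_cliques <- function(k) {
  n <- 2L * k
  W <- matrix(0, n, n)
  W[1:k, 1:k] <- 1
  W[(k + 1):n, (k + 1):n] <- 1
  diag(W) <- 0
  W[k, k + 1] <- W[k + 1, k] <- 1
  weighted_network(W, group_id = sprintf("twoclique%d", k))
}

# random connected binary network (edges resampled until connected)
random_connected_net <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    W <- matrix(0, n, n)
    up <- upper.tri(W)
    W[up] <- as.numeric(runif(sum(up)) < p)
    W <- W + t(W)
    g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
    if (igraph::is_connected(g) && sum(W) > 0) {
      return(weighted_network(W, group_id = sprintf("rand%d_%d", n, seed)))
    }
  }
}
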