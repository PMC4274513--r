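# Per-group network statistics: density, shortest paths, diameter, the two
# efficiency indices E1 and E2, eigenvector centralities, the centralisation
# index CI and maximum modularity Q.

#' Convert a weighted network to an igraph object
#'
#' Positive-weight pairs become undirected edges carrying the symmetrized
#' weight as an edge attribute.
#'
#' @param net A [weighted_network()].
#' @return An undirected `igraph` graph with a `weight` edge attribute.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$W, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Edge density of a group network
#'
#' Number of observed relationships divided by the number of possible
#' relationships, I / (N(N-1)/2). Equals 1 when every pair of individuals
#' was observed interacting.
#'
#' @param net A [weighted_network()].
#' @return Density in (0, 1] (validation forbids empty networks).
#' @export
edge_density <- function(net) {
  N <- n_nodes(net)
  n_edges(net) / (N * (N - 1) / 2)
}

#' All-pairs shortest path lengths
#'
#' In `binary` mode (the default throughout the package) the distance
#' between two individuals is the fewest number of links on the graph of
#' positive-weight edges. In `weighted_inverse` mode each edge has length
#' 1/weight, so strong associations are short, and distances are minimum
#' total lengths; offered for sensitivity analysis. Unreachable pairs are a
#' flagged state (`connected[i, j] = FALSE`, `D[i, j] = Inf`), not an error.
#'
#' @param net A [weighted_network()].
#' @param mode `"binary"` or `"weighted_inverse"`.
#' @return An object of class `distance_matrix`: list with `D` (numeric
#'   matrix, `Inf` for unreachable pairs), `connected` (logical matrix,
#'   diagonal `FALSE`) and `mode`.
#' @export
shortest_paths_matrix <- function(net, mode = c("binary", "weighted_inverse")) {
  mode <- match.arg(mode)
  g <- as_igraph(net)
  D <- if (mode == "binary") {
    igraph::distances(g, weights = NA)
  } else {
    igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  }
  dimnames(D) <- list(net$node_ids, net$node_ids)
  connected <- is.finite(D)
  diag(connected) <- FALSE
  structure(list(D = D, connected = connected, mode = mode),
            class = "distance_matrix")
}

#' Network diameter
#'
#' The longest of the shortest paths. When the network is fragmented the
#' diameter is taken over connected pairs only (i.e. within the components),
#' with a warning; a network with no connected pair at all is an error.
#'
#' @param dm A `distance_matrix` from [shortest_paths_matrix()].
#' @return The maximum finite shortest-path length.
#' @export
net_diameter <- function(dm) {
  finite <- dm$D[upper.tri(dm$D)][dm$connected[upper.tri(dm$connected)]]
  if (length(finite) == 0) {
    pn_stop("diameter undefined: no connected pair of individuals",
            "primatenet_validation_error")
  }
  if (!all(dm$connected[upper.tri(dm$connected)])) {
    pn_warn("network is fragmented; diameter taken over connected pairs only",
            "primatenet_fragmented_warning")
  }
  max(finite)
}

#' Global Efficiency (E1)
#'
#' The ratio between the number of individuals N and the number of
#' connections I multiplied by the network diameter D: E1 = N / (I * D).
#' High values indicate that many individuals are reachable through few,
#' short connections. The raw formula value is returned without clipping;
#' on very small or sparse graphs it can exceed 1.
#'
#' @param net A [weighted_network()].
#' @param dm Optional precomputed `distance_matrix`; defaults to binary
#'   shortest paths on `net`.
#' @return E1, a dimensionless ratio.
#' @export
global_efficiency <- function(net, dm = shortest_paths_matrix(net)) {
  n_nodes(net) / (n_edges(net) * net_diameter(dm))
}

#' Average Dyadic Efficiency (E2)
#'
#' The mean over all unordered pairs of individuals of the inverse shortest
#' path length 1/d. Disconnected pairs contribute 0 (the Latora-Marchiori
#' convention), so E2 is always defined and lies in [0, 1]; it equals 1
#' exactly when every pair is directly connected.
#'
#' @param dm A `distance_matrix` from [shortest_paths_matrix()].
#' @return E2 in [0, 1].
#' @export
dyadic_efficiency <- function(dm) {
  d <- dm$D[upper.tri(dm$D)]
  mean(ifelse(is.finite(d), 1 / d, 0))
}

#' Eigenvector centralities of a group network
#'
#' The principal eigenvector of the weight matrix, with non-negative entries
#' normalized to unit Euclidean length. On fragmented networks centralities
#' are computed on the largest component (ties broken by the component
#' containing the earliest node) and individuals outside it score 0.
#' Invariant under global rescaling of the weights.
#'
#' @param net A [weighted_network()].
#' @return An object of class `centrality_vector`: list with `C` (named
#'   per-node scores) and `C_max`.
#' @export
eigencentrality <- function(net) {
  W <- net$W
  g <- as_igraph(net)
  comp <- igraph::components(g)
  big <- which(comp$csize == max(comp$csize))
  # tie-break: the component containing the lowest-index node
  keep <- if (length(big) > 1) comp$membership[min(which(comp$membership %in% big))] else big
  idx <- which(comp$membership == keep)
  C <- stats::setNames(numeric(n_nodes(net)), net$node_ids)
  if (length(idx) == 1) {
    pn_stop(sprintf("[%s] largest component has a single node; no edge to anchor centrality",
                    net$group_id), "primatenet_validation_error")
  }
  eig <- eigen(W[idx, idx, drop = FALSE], symmetric = TRUE)
  v <- eig$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v[v < 0] <- 0                      # Perron vector; clip numerical dust
  C[idx] <- v / sqrt(sum(v^2))
  structure(list(C = C, C_max = max(C)), class = "centrality_vector")
}

# Sum of (C_max - C_i) for an unweighted N-node star, under the package's
# own eigenvector normalization; the reference denominator of the
# centralisation index.
star_reference_sum <- function(N) {
  W <- matrix(0, N, N)
  W[1, 2:N] <- 1
  W[2:N, 1] <- 1
  cv <- eigencentrality(weighted_network(W, group_id = sprintf("star%d", N)))
  sum(cv$C_max - cv$C)
}

#' Centralisation index (CI)
#'
#' Group-level summary of how dominated the network is by its most central
#' individual: 100 times the sum of differences between the highest
#' eigenvector centrality and each individual's centrality, divided by the
#' same sum evaluated on an unweighted star of equal size (the most
#' centralised topology). A star scores 100, any vertex-transitive network
#' (complete graph, cycle) scores 0, and values above 100 flag networks
#' fragmented into isolated clusters.
#'
#' @param cv A `centrality_vector` from [eigencentrality()], or a
#'   [weighted_network()] (centralities are then computed internally).
#' @param N Number of individuals; defaults to the length of the centrality
#'   vector. Must be >= 3 (the star reference is degenerate at N = 2).
#' @return CI on the 0-100 scale (>= 0; may exceed 100).
#' @export
centralisation_index <- function(cv, N = NULL) {
  if (inherits(cv, "weighted_network")) {
    N <- N %||% n_nodes(cv)
    cv <- eigencentrality(cv)
  }
  N <- N %||% length(cv$C)
  if (N < 3) {
    pn_stop("centralisation index needs N >= 3 (star reference undefined)",
            "primatenet_validation_error")
  }
  100 * sum(cv$C_max - cv$C) / star_reference_sum(N)
}

# Modularity of a membership vector on the weighted graph, via the standard
# degree-sequence (configuration model) null.
partition_quality <- function(g, membership) {
  igraph::modularity(g, membership, weights = igraph::E(g)$weight)
}

# Deterministic single-node-move refinement: repeatedly move each node to
# the community (existing or fresh singleton) that maximizes Q, scanning
# nodes in index order, until a full pass yields no improvement.
refine_partition <- function(g, membership, max_pass = 20L) {
  n <- length(membership)
  q <- partition_quality(g, membership)
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (v in seq_len(n)) {
      cand <- unique(c(membership, max(membership) + 1L))
      best_q <- q
      best_c <- membership[v]
      for (cc in cand) {
        if (cc == membership[v]) next
        trial <- membership
        trial[v] <- cc
        tq <- partition_quality(g, trial)
        if (tq > best_q + 1e-12) {
          best_q <- tq
          best_c <- cc
        }
      }
      if (best_c != membership[v]) {
        membership[v] <- best_c
        q <- best_q
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(membership = membership, Q = q)
}

# Relabel communities 1, 2, ... in order of first appearance so equal-Q
# partitions have a canonical representative.
canonical_membership <- function(membership) {
  as.integer(factor(membership, levels = unique(membership)))
}

#' Maximum modularity (Q) and its partition
#'
#' Finds a high-modularity division of the group into clusters: the fraction
#' of within-cluster connection weight minus the fraction expected if
#' connections were distributed at random with the same degree sequence.
#' The optimizer is Newman's leading-eigenvector method followed by a
#' deterministic single-node-move refinement pass; if no split beats the
#' trivial one-cluster partition (Q = 0) the trivial partition is returned,
#' so the reported Q is always in [0, 1].
#'
#' @param net A [weighted_network()] with at least one edge.
#' @param seed Integer seed isolating any randomness in the eigensolver;
#'   results are reproducible for a fixed seed (default 1).
#' @return An object of class `modularity_result`: list with `Q`, the named
#'   integer `membership` vector (clusters numbered in order of first
#'   appearance), and `method`.
#' @export
maximum_modularity <- function(net, seed = 1L) {
  g <- as_igraph(net)
  if (igraph::ecount(g) == 0) {
    pn_stop(sprintf("[%s] modularity needs at least one edge", net$group_id),
            "primatenet_validation_error")
  }
  cl <- local_seed(seed, igraph::cluster_leading_eigen(
    g, weights = igraph::E(g)$weight))
  memb <- as.integer(igraph::membership(cl))
  ref <- refine_partition(g, memb)
  trivial <- rep(1L, n_nodes(net))
  if (ref$Q <= partition_quality(g, trivial) + 1e-12) {
    memb <- trivial
    q <- partition_quality(g, trivial)
  } else {
    memb <- ref$membership
    q <- ref$Q
  }
  memb <- canonical_membership(memb)
  names(memb) <- net$node_ids
  structure(list(Q = q, membership = memb, method = "leading_eigen+refine"),
            class = "modularity_result")
}

#' Compute every per-group network statistic
#'
#' One call per group: N, I, edge density, diameter, Global Efficiency (E1),
#' Average Dyadic Efficiency (E2), centralisation index (CI) and maximum
#' modularity (Q). Deterministic given `seed`. CI is `NA` (with a warning)
#' for groups of fewer than 3 individuals, where its star reference is
#' undefined.
#'
#' @param net A [weighted_network()].
#' @param path_mode Shortest-path mode, see [shortest_paths_matrix()].
#' @param seed Seed passed to the modularity optimizer.
#' @return A one-row `data.frame` with columns `group_id`, `N`, `I`,
#'   `density`, `diameter`, `E1`, `E2`, `CI`, `Q`, `path_mode`.
#' @examples
#' W <- matrix(0, 5, 5); W[1, 2:5] <- 1; W[2:5, 1] <- 1   # 5-node star
#' compute_metrics(weighted_network(W, group_id = "star"))
#' @export
compute_metrics <- function(net, path_mode = c("binary", "weighted_inverse"),
                            seed = 1L) {
  path_mode <- match.arg(path_mode)
  wrap <- function(expr) {
    tryCatch(expr, error = function(e) {
      pn_stop(sprintf("[%s] %s", net$group_id, conditionMessage(e)),
              class(e)[1])
    })
  }
  dm <- wrap(shortest_paths_matrix(net, path_mode))
  D <- wrap(net_diameter(dm))
  ci <- if (n_nodes(net) >= 3) {
    wrap(centralisation_index(eigencentrality(net), n_nodes(net)))
  } else {
    pn_warn(sprintf("[%s] N < 3: centralisation index undefined, set to NA",
                    net$group_id), "primatenet_ci_warning")
    NA_real_
  }
  data.frame(
    group_id = net$group_id,
    N = n_nodes(net),
    I = n_edges(net),
    density = edge_density(net),
    diameter = D,
    E1 = global_efficiency(net, dm),
    E2 = dyadic_efficiency(dm),
    CI = ci,
    Q = maximum_modularity(net, seed = seed)$Q,
    path_mode = path_mode,
    stringsAsFactors = FALSE
  )
}

#' Compute metrics for a list of networks
#'
#' @param nets List of [weighted_network()] objects.
#' @inheritParams compute_metrics
#' @return A `data.frame`, one row per network, in input order.
#' @export
cohort_metrics <- function(nets, path_mode = "binary", seed = 1L) {
  do.call(rbind, lapply(nets, compute_metrics, path_mode = path_mode,
                        seed = seed))
}

#' Write a metrics table to CSV
#'
#' Deterministic column order (`group_id`, `N`, `I`, `density`, `diameter`,
#' `E1`, `E2`, `CI`, `Q`, `path_mode`).
#'
#' @param metrics Metrics `data.frame` from [cohort_metrics()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  cols <- c("group_id", "N", "I", "density", "diameter", "E1", "E2", "CI",
            "Q", "path_mode")
  utils::write.csv(metrics[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a community partition to CSV
#'
#' @param mod A `modularity_result` from [maximum_modularity()].
#' @param path Output CSV path (columns `node_id`, `cluster_id`).
#' @return `path`, invisibly.
#' @export
write_partition <- function(mod, path) {
  utils::write.csv(
    data.frame(node_id = names(mod$membership),
               cluster_id = unname(mod$membership)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
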