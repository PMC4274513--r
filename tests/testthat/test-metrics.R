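test_that("edge density counts observed over possible relationships", {
  expect_equal(edge_density(make_complete(5)), 1)
  expect_equal(edge_density(make_path(4)), 0.5)
  expect_equal(edge_density(make_star(4)), 0.5)
})

test_that("shortest paths honour mode and flag disconnected pairs", {
  dm <- shortest_paths_matrix(make_path(4))
  expect_equal(dm$D[1, 4], 3)

  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[3, 4] <- W[4, 3] <- 1
  dm2 <- shortest_paths_matrix(weighted_network(W, "dyads"))
  expect_false(dm2$connected[1, 3])
  expect_true(dm2$connected[1, 2])
  expect_equal(dm2$D[1, 3], Inf)

  # weighted triangle: strong indirect route beats the weak direct edge
  Wt <- matrix(c(0, 1, 0.25, 1, 0, 1, 0.25, 1, 0), 3, 3)
  dmt <- shortest_paths_matrix(weighted_network(Wt, "tri"), "weighted_inverse")
  expect_equal(dmt$D[1, 3], 2)
})

test_that("diameter is the longest shortest path, over components when fragmented", {
  expect_equal(net_diameter(shortest_paths_matrix(make_complete(6))), 1)
  expect_equal(net_diameter(shortest_paths_matrix(make_path(4))), 3)
  expect_equal(net_diameter(shortest_paths_matrix(make_star(6))), 2)

  W <- matrix(0, 5, 5)
  W[1, 2] <- W[2, 1] <- 1
  W[3, 4] <- W[4, 3] <- 1
  W[4, 5] <- W[5, 4] <- 1
  dm <- shortest_paths_matrix(weighted_network(W, "frag"))
  expect_warning(D <- net_diameter(dm), class = "primatenet_fragmented_warning")
  expect_equal(D, 2)
})

test_that("Global Efficiency follows N / (I * D)", {
  expect_equal(global_efficiency(make_complete(5)), 0.5)
  expect_equal(global_efficiency(make_star(5)), 0.625)
  expect_equal(global_efficiency(make_path(4)), 4 / 9)
})

test_that("E1 * I * D recovers N on random connected binary graphs", {
  for (s in 1:50) {
    net <- random_connected_net(sample(4:12, 1), p = runif(1, 0.3, 0.8),
                                seed = 1000 + s)
    dm <- shortest_paths_matrix(net)
    e1 <- global_efficiency(net, dm)
    expect_equal(e1 * n_edges(net) * net_diameter(dm), n_nodes(net),
                 tolerance = 1e-12)
  }
})

test_that("Average Dyadic Efficiency matches hand and oracle values", {
  expect_equal(dyadic_efficiency(shortest_paths_matrix(make_complete(8))), 1)
  expect_equal(dyadic_efficiency(shortest_paths_matrix(make_path(3))),
               (1 + 1 + 0.5) / 3)
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[3, 4] <- W[4, 3] <- 1
  expect_equal(dyadic_efficiency(shortest_paths_matrix(weighted_network(W, "d"))),
               1 / 3)
})

test_that("E2 and diameter agree with Floyd-Warshall on random graphs (N <= 12)", {
  set.seed(99)
  for (s in 1:20) {
    n <- sample(4:12, 1)
    W <- matrix(0, n, n)
    up <- upper.tri(W)
    W[up] <- ifelse(runif(sum(up)) < 0.35, rlnorm(sum(up)), 0)
    W <- W + t(W)
    if (all(W == 0)) W[1, 2] <- W[2, 1] <- 1
    net <- weighted_network(W, paste0("fw", s))
    for (mode in c("binary", "weighted_inverse")) {
      dm <- shortest_paths_matrix(net, mode)
      expect_equal(dyadic_efficiency(dm), fw_e2(W, mode), tolerance = 1e-12)
      expect_equal(suppressWarnings(net_diameter(dm)), fw_diameter(W, mode),
                   tolerance = 1e-12)
    }
  }
})

test_that("adding an edge never decreases E2 and never increases a distance", {
  for (s in 1:10) {
    net <- random_connected_net(8, 0.35, seed = 2000 + s)
    W <- net$W
    absent <- which(W == 0 & upper.tri(W), arr.ind = TRUE)
    if (nrow(absent) == 0) next
    pick <- absent[1, ]
    W2 <- W
    W2[pick[1], pick[2]] <- W2[pick[2], pick[1]] <- 1
    dm1 <- shortest_paths_matrix(net)
    dm2 <- shortest_paths_matrix(weighted_network(W2, "aug"))
    expect_true(all(dm2$D <= dm1$D))
    expect_gte(dyadic_efficiency(dm2), dyadic_efficiency(dm1))
  }
})

test_that("eigenvector centralities match a power-iteration oracle", {
  cv <- eigencentrality(make_complete(6))
  expect_equal(unname(cv$C), rep(1 / sqrt(6), 6), tolerance = 1e-10)

  cv <- eigencentrality(make_star(7))
  expect_gt(cv$C[1], max(cv$C[-1]))
  expect_equal(var(unname(cv$C[-1])), 0, tolerance = 1e-16)

  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 5
  W[3, 4] <- W[4, 3] <- 1
  cv <- eigencentrality(weighted_network(W, "chain"))
  expect_equal(unname(cv$C), as.numeric(power_centrality(W)), tolerance = 1e-8)
})

test_that("centrality is scale invariant and confined to the largest component", {
  net <- random_connected_net(9, 0.4, seed = 31)
  scaled <- weighted_network(net$W * 37.5, "scaled")
  expect_equal(eigencentrality(net)$C, eigencentrality(scaled)$C,
               tolerance = 1e-10, ignore_attr = TRUE)

  W <- matrix(0, 6, 6)
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1
  W[4, 5] <- W[5, 4] <- 1
  W[5, 6] <- W[6, 5] <- 1
  W[1, 3] <- W[3, 1] <- 1   # first component bigger by one edge? equal sizes: tie
  cv <- eigencentrality(weighted_network(W, "twocomp"))
  expect_true(all(cv$C[4:6] == 0))
  expect_true(all(cv$C[1:3] > 0))
})

test_that("centralisation index calibrates to the star and vanishes on vertex-transitive graphs", {
  for (n in c(5, 10, 20)) {
    expect_equal(centralisation_index(make_star(n)), 100, tolerance = 1e-6)
  }
  for (n in c(3, 6, 11)) {
    expect_equal(centralisation_index(make_complete(n)), 0, tolerance = 1e-6)
    expect_equal(centralisation_index(make_cycle(n)), 0, tolerance = 1e-6)
  }
  net <- random_connected_net(10, 0.4, seed = 5)
  expect_equal(centralisation_index(weighted_network(net$W * 10, "x")),
               centralisation_index(net), tolerance = 1e-9)
  expect_error(centralisation_index(make_complete(2) |> eigencentrality(), N = 2),
               class = "primatenet_validation_error")
})

test_that("fragmented networks can exceed CI = 100", {
  W <- matrix(0, 5, 5)
  W[1, 2] <- W[2, 1] <- 1
  W[3, 4] <- W[4, 3] <- 1
  W[4, 5] <- W[5, 4] <- 1
  expect_gt(centralisation_index(weighted_network(W, "frag")), 100)
})

test_that("modularity optimizer recovers planted cliques exactly and bounds hold", {
  net <- make_two_cliques(5)
  mm <- maximum_modularity(net)
  expect_equal(mm$Q, best_bipartition_q(net$W), tolerance = 1e-12)
  expect_equal(unname(mm$membership), rep(1:2, each = 5))

  expect_equal(maximum_modularity(make_complete(7))$Q, 0)
  expect_equal(unname(maximum_modularity(make_complete(7))$membership),
               rep(1L, 7))

  # planted structure must beat degree-preserving rewirings
  q_planted <- maximum_modularity(net)$Q
  g <- as_igraph(net)
  set.seed(11)
  rewired_q <- replicate(100, {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 50))
    W <- as.matrix(igraph::as_adjacency_matrix(gr))
    maximum_modularity(weighted_network(W, "rw"))$Q
  })
  expect_gt(q_planted, max(rewired_q) - 1e-9)
  expect_gt(q_planted, mean(rewired_q))
})

test_that("returned Q is consistent with the direct modularity formula", {
  for (s in 1:10) {
    net <- random_connected_net(sample(6:12, 1), 0.4, seed = 3000 + s)
    mm <- maximum_modularity(net)
    expect_equal(mm$Q, q_formula(net$W, unname(mm$membership)),
                 tolerance = 1e-12)
    expect_lte(mm$Q, 1)
    expect_gte(mm$Q, 0)
  }
})

test_that("all scalar metrics are invariant under node relabelling", {
  net <- random_connected_net(10, 0.45, seed = 77)
  set.seed(123)
  perm <- sample(10)
  Wp <- net$W[perm, perm]
  netp <- weighted_network(Wp, "perm")
  a <- compute_metrics(net)
  b <- compute_metrics(netp)
  for (col in c("N", "I", "density", "diameter", "E1", "E2", "CI", "Q")) {
    expect_equal(a[[col]], b[[col]], tolerance = 1e-9, label = col)
  }
})

test_that("compute_metrics composes the components deterministically", {
  rec <- compute_metrics(make_star(5))
  expect_equal(rec$density, 0.4)
  expect_equal(rec$diameter, 2)
  expect_equal(rec$E1, 0.625)
  expect_equal(rec$CI, 100, tolerance = 1e-6)

  rec2 <- compute_metrics(make_complete(4))
  expect_equal(rec2$density, 1)
  expect_equal(rec2$E2, 1)
  expect_equal(rec2$CI, 0, tolerance = 1e-6)

  net <- generate_network(15, 0.5, 0.5, seed = 1)
  expect_identical(compute_metrics(net), compute_metrics(net))
})
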