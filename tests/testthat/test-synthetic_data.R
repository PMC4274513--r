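test_that("taxonomy generation respects nesting counts and matches its tree", {
  cfg <- cohort_config(seed = 4)
  tax <- generate_taxonomy(cfg)
  sp <- tax$species_table
  expect_equal(nrow(sp), 24)
  expect_equal(length(unique(sp$genus)), 15)
  expect_equal(length(unique(sp$family)), 6)
  # strict nesting: one genus per species, one family per genus
  expect_true(all(tapply(sp$family, sp$genus, function(x) length(unique(x))) == 1))
  expect_setequal(tax$tree$tip.label, sp$species)
  expect_true(ape::is.ultrametric(tax$tree, tol = 1e-6))
  expect_true(all(tax$tree$edge.length > 0))

  tiny <- generate_taxonomy(cohort_config(n_families = 1, n_genera = 1,
                                          n_species = 2, n_groups = 2))
  expect_equal(length(tiny$tree$tip.label), 2)

  expect_identical(ape::write.tree(generate_taxonomy(cfg)$tree),
                   ape::write.tree(generate_taxonomy(cfg)$tree))
  expect_error(cohort_config(n_families = 5, n_genera = 3),
               class = "primatenet_config_error")
})

test_that("generate_network hits its structural endpoints", {
  # ci_target = 1, q_target = 0: exact star with CI ~ 100
  net <- generate_network(12, 1, 0, seed = 8)
  deg <- rowSums(net$W > 0)
  expect_equal(unname(deg[1]), 11)
  expect_true(all(deg[-1] == 1))
  expect_gt(centralisation_index(net), 90)

  # ci_target = 0, q_target = 0: dense, decentralised
  net2 <- generate_network(10, 0, 0, seed = 9, p_dense = 0.9)
  expect_gt(edge_density(net2), 0.6)
  expect_lt(centralisation_index(net2), 35)
})

test_that("generated networks are always connected and valid", {
  set.seed(20)
  for (s in 1:50) {
    n <- sample(5:25, 1)
    net <- generate_network(n, runif(1), runif(1), seed = 5000 + s)
    expect_silent(validate_network(net))
    g <- as_igraph(net)
    expect_true(igraph::is_connected(g))
    expect_equal(n_nodes(net), n)
  }
  expect_error(generate_network(2, 0.5, 0.5, seed = 1),
               class = "primatenet_config_error")
})

test_that("q_target raises realized modularity", {
  qs <- sapply(1:50, function(s) {
    c(lo = maximum_modularity(generate_network(16, 0.2, 0.1, seed = 7000 + s))$Q,
      hi = maximum_modularity(generate_network(16, 0.2, 0.9, seed = 7000 + s))$Q)
  })
  expect_gt(mean(qs["hi", ]), mean(qs["lo", ]))
})

test_that("default cohort reproduces the target composition deterministically", {
  cfg <- cohort_config(seed = 6)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$metadata), 78)
  expect_equal(length(unique(coh$metadata$species)), 24)
  expect_equal(length(coh$networks), 78)
  expect_true(all(coh$metadata$group_size >= 3))
  expect_true(all(coh$metadata$neocortex_ratio >= 1.5 &
                    coh$metadata$neocortex_ratio <= 4.2))
  # flagged groups exist and carry the not_applicable context
  expect_equal(sum(coh$metadata$flagged), 4)
  expect_true(all(coh$metadata$context[coh$metadata$flagged] == "not_applicable"))
  # metadata group size equals network node count
  expect_equal(coh$metadata$group_size,
               vapply(coh$networks, n_nodes, integer(1),
                      USE.NAMES = FALSE))
  # determinism under the same seed, independence of metric values
  coh2 <- generate_cohort(cohort_config(seed = 6))
  expect_identical(coh$metadata, coh2$metadata)
  expect_identical(coh$networks[[10]]$W, coh2$networks[[10]]$W)
})

test_that("default cohorts span the qualitative metric regimes", {
  coh <- generate_cohort(cohort_config(seed = 1))
  m <- cohort_metrics(coh$networks)
  expect_gt(sum(m$CI > 60), 0)
  expect_gt(sum(m$CI < 30), 0)
  expect_gt(sum(m$Q > 0.4), 0)
  expect_gt(sum(m$Q < 0.1), 0)
})

test_that("Brownian traits on the generated tree carry K near 1", {
  tree <- generate_taxonomy(cohort_config(seed = 2))$tree
  set.seed(5)
  ks <- replicate(200, {
    x <- ape::rTraitCont(tree, model = "BM", sigma = 1)
    blomberg_K(x, tree, n_perm = 0, seed = 1)$K
  })
  expect_gt(mean(ks), 0.85)
  expect_lt(mean(ks), 1.15)
})

test_that("cohort files round-trip through the ingestion layer", {
  cfg <- cohort_config(n_families = 2, n_genera = 3, n_species = 5,
                       n_groups = 8, seed = 10)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_cohort(dir)
  expect_equal(nrow(back$metadata), 8)
  expect_identical(back$networks[["grp_003"]]$W, coh$networks[["grp_003"]]$W)
  expect_setequal(back$tree$tip.label, coh$tree$tip.label)
})
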