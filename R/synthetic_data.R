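# Synthetic cohort generator: nested taxonomy with an ultrametric species
# tree, per-species neocortex ratios with phylogenetic autocorrelation, and
# per-group association networks whose centralisation and modularity are
# controlled by two topology knobs. Planted covariate effects act through
# those knobs, never by overwriting computed metrics, so downstream recovery
# tests exercise the real metric code.

#' Configuration of a synthetic cohort
#'
#' Defaults emulate the composition of the comparative dataset the package
#' targets: 78 groups from 24 species in 15 genera and 6 families, group
#' sizes 5-40. The planted-effect coefficients act on network topology:
#' `beta_logsize_E1` (negative) is the logit-density slope per unit log group
#' size, which makes larger groups sparser and so less globally efficient;
#' `beta_neo_E1` (positive) moves the star-vs-dense interpolation knob with
#' the species' neocortex ratio, raising Global Efficiency for large-brained
#' species; `beta_CI_E2` (negative) scales the group-level spread of the
#' centralisation knob, which induces the negative relationship between the
#' centralisation index and Average Dyadic Efficiency. `noise_sd` adds
#' Gaussian residual noise to both knob equations; at 0 the knobs are a
#' deterministic function of the covariates.
#'
#' @param n_families,n_genera,n_species,n_groups Taxonomic composition;
#'   must satisfy `n_species >= n_genera >= n_families >= 1` and
#'   `n_groups >= n_species`.
#' @param group_size_range Integer interval of group sizes (min >= 3, the
#'   smallest size at which the centralisation index is defined).
#' @param beta_logsize_E1,beta_neo_E1,beta_CI_E2 Planted slopes, see above.
#' @param noise_sd Residual scale of the knob equations.
#' @param neocortex_range Per-species neocortex ratios are mapped into this
#'   interval (default 1.5-4.2, bracketing published strepsirrhine-to-human
#'   values).
#' @param p_flagged_groups Number of groups given to the flagged
#'   (largest-neocortex) species, emulating an outlier subset such as the
#'   human groups of comparative datasets; their context is
#'   `not_applicable`.
#' @param seed Integer seed; fans out to per-group seeds via [group_seed()].
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_families = 6L, n_genera = 15L, n_species = 24L,
                          n_groups = 78L, group_size_range = c(5L, 40L),
                          beta_logsize_E1 = -0.8, beta_neo_E1 = 0.25,
                          beta_CI_E2 = -1, noise_sd = 0.15,
                          neocortex_range = c(1.5, 4.2),
                          p_flagged_groups = 4L, seed = 1L) {
  cfg <- list(n_families = as.integer(n_families),
              n_genera = as.integer(n_genera),
              n_species = as.integer(n_species),
              n_groups = as.integer(n_groups),
              group_size_range = as.integer(group_size_range),
              beta_logsize_E1 = beta_logsize_E1,
              beta_neo_E1 = beta_neo_E1,
              beta_CI_E2 = beta_CI_E2,
              noise_sd = noise_sd,
              neocortex_range = neocortex_range,
              p_flagged_groups = as.integer(p_flagged_groups),
              seed = as.integer(seed))
  with(cfg, {
    if (!(n_species >= n_genera && n_genera >= n_families && n_families >= 1)) {
      pn_stop("need n_species >= n_genera >= n_families >= 1",
              "primatenet_config_error")
    }
    if (n_groups < n_species) {
      pn_stop("need n_groups >= n_species (every species gets a group)",
              "primatenet_config_error")
    }
    if (length(group_size_range) != 2 || group_size_range[1] < 3 ||
        diff(group_size_range) < 0) {
      pn_stop("group_size_range must be an increasing interval with min >= 3",
              "primatenet_config_error")
    }
    if (noise_sd < 0) pn_stop("noise_sd must be >= 0", "primatenet_config_error")
  })
  structure(cfg, class = "cohort_config")
}

# Distribute n_child items over n_parent parents, each parent >= 1, extras
# assigned uniformly at random (deterministic under the caller's seed).
allocate_nested <- function(n_child, n_parent) {
  counts <- rep(1L, n_parent)
  extra <- n_child - n_parent
  if (extra > 0) {
    add <- table(sample.int(n_parent, extra, replace = TRUE))
    counts[as.integer(names(add))] <- counts[as.integer(names(add))] +
      as.integer(add)
  }
  counts
}

# Random sequential coalescence of subtrees between heights h_lo and h_hi.
# items: list of list(str = newick fragment, h = height of its root).
coalesce_clade <- function(items, h_lo, h_hi) {
  k <- length(items)
  if (k == 1) return(items[[1]])
  hs <- sort(stats::runif(k - 1, h_lo, h_hi))
  for (j in seq_len(k - 1)) {
    idx <- sample.int(length(items), 2)
    a <- items[[idx[1]]]
    b <- items[[idx[2]]]
    h <- hs[j]
    node <- list(str = sprintf("(%s:%.10f,%s:%.10f)", a$str, h - a$h,
                               b$str, h - b$h),
                 h = h)
    items <- c(items[-idx], list(node))
  }
  items[[1]]
}

#' Generate a nested taxonomy and matching ultrametric species tree
#'
#' Every species belongs to exactly one genus and every genus to exactly one
#' family. The tree is built by nested coalescence so that it agrees with
#' the taxonomy by construction: species coalesce within their genus at
#' shallow depths, genera within their family at intermediate depths, and
#' families near the root; all tips are at height 0 (ultrametric, unit root
#' depth scale). Deterministic given the config seed.
#'
#' @param cfg A [cohort_config()].
#' @return List with `species_table` (`data.frame`: species, genus, family)
#'   and `tree` (an `ape` `phylo` with `n_species` tips).
#' @export
generate_taxonomy <- function(cfg) {
  local_seed(cfg$seed + 1L, {
    families <- sprintf("family_%02d", seq_len(cfg$n_families))
    genera <- sprintf("genus_%02d", seq_len(cfg$n_genera))
    species <- sprintf("species_%02d", seq_len(cfg$n_species))
    gen_per_fam <- allocate_nested(cfg$n_genera, cfg$n_families)
    sp_per_gen <- allocate_nested(cfg$n_species, cfg$n_genera)
    genus_family <- rep(families, gen_per_fam)
    species_genus <- rep(genera, sp_per_gen)
    species_table <- data.frame(
      species = species,
      genus = species_genus,
      family = genus_family[match(species_genus, genera)],
      stringsAsFactors = FALSE
    )
    # species coalesce in (0.05, 0.35), genera in (0.40, 0.65),
    # families in (0.70, 1.00): nested heights keep branch lengths positive
    genus_clades <- lapply(genera, function(g) {
      tips <- lapply(species[species_genus == g],
                     function(s) list(str = s, h = 0))
      coalesce_clade(tips, 0.05, 0.35)
    })
    family_clades <- lapply(families, function(f) {
      idx <- which(genus_family == f)
      coalesce_clade(genus_clades[idx], 0.40, 0.65)
    })
    root <- coalesce_clade(family_clades, 0.70, 1.00)
    tree <- ape::read.tree(text = paste0(root$str, ";"))
    list(species_table = species_table, tree = tree)
  })
}

#' Generate one group association network with controlled structure
#'
#' Edge probabilities interpolate between a star anchored at the first node
#' (`ci_target` close to 1) and a dense Erdos-Renyi topology with edge
#' probability `p_dense` (`ci_target` close to 0). A planted partition into
#' 2-4 contiguous blocks then downweights between-block edge probabilities
#' by `(1 - q_target)`, so high `q_target` yields strongly modular networks.
#' Edge weights are lognormal. Connectivity is guaranteed: any component
#' separated from the first node is reattached to it through a hub-anchored
#' spanning backbone, so at `ci_target = 1`, `q_target = 0` the result is an
#' exact star.
#'
#' @param n Group size (>= 3).
#' @param ci_target Star-vs-dense interpolation knob in [0, 1].
#' @param q_target Block-strength knob in [0, 1].
#' @param seed Integer seed; the draw is fully deterministic given it.
#' @param p_dense Edge probability of the dense endpoint.
#' @param group_id,interaction_type Labels stored on the network.
#' @return A validated [weighted_network()].
#' @export
generate_network <- function(n, ci_target, q_target, seed,
                             p_dense = 0.5, group_id = "synthetic",
                             interaction_type = "contact") {
  if (n < 3) pn_stop("generate_network needs n >= 3", "primatenet_config_error")
  stopifnot(ci_target >= 0, ci_target <= 1, q_target >= 0, q_target <= 1)
  local_seed(seed, {
    k <- if (n < 8) 2L else sample(2:4, 1)
    block <- sort(rep_len(seq_len(k), n))
    W <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        p_star <- as.numeric(i == 1L)        # hub is node 1
        p <- ci_target * p_star + (1 - ci_target) * p_dense
        if (block[i] != block[j]) p <- p * (1 - q_target)
        if (stats::runif(1) < p) {
          W[i, j] <- W[j, i] <- stats::rlnorm(1, meanlog = 0, sdlog = 0.5)
        }
      }
    }
    # hub-anchored spanning backbone: reattach any orphan component
    g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
    comp <- igraph::components(g)
    hub_comp <- comp$membership[1]
    for (cc in setdiff(unique(comp$membership), hub_comp)) {
      j <- min(which(comp$membership == cc))
      W[1, j] <- W[j, 1] <- stats::rlnorm(1, meanlog = 0, sdlog = 0.5)
    }
    weighted_network(W, group_id = group_id,
                     node_ids = sprintf("%s_i%02d", group_id, seq_len(n)),
                     interaction_type = interaction_type)
  })
}

#' Generate a full synthetic cohort
#'
#' Produces group metadata, one association network per group, and the
#' species tree. Neocortex ratios are simulated by Brownian motion on the
#' tree and mapped affinely into `neocortex_range`, giving them
#' phylogenetic autocorrelation; sex ratios are uniform on [0.2, 0.8];
#' context is captive or wild (roughly the 33:41 split of comparative
#' datasets), except for the flagged largest-neocortex species whose
#' context is `not_applicable`. Each group's network knobs follow the
#' planted-effect equations of [cohort_config()], and its network is drawn
#' with a per-group seed derived from the global seed by stable hashing of
#' the group id.
#'
#' @param cfg A [cohort_config()].
#' @return An object of class `synthetic_cohort`: list with `metadata`
#'   (`data.frame`, one row per group, including the realized knobs
#'   `ci_target`/`q_target`/`p_dense` and the `flagged` column), `networks`
#'   (named list of [weighted_network()]), `tree` and `config`.
#' @examples
#' cfg <- cohort_config(n_families = 2, n_genera = 3, n_species = 4,
#'                      n_groups = 6, seed = 7)
#' coh <- generate_cohort(cfg)
#' nrow(coh$metadata)
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  tax <- generate_taxonomy(cfg)
  tree <- tax$tree
  sp <- tax$species_table
  local_seed(cfg$seed + 2L, {
    bm <- ape::rTraitCont(tree, model = "BM", sigma = 1)
    bm <- bm[sp$species]
    rng <- range(bm)
    neo <- if (diff(rng) > 0) {
      cfg$neocortex_range[1] +
        (bm - rng[1]) / diff(rng) * diff(cfg$neocortex_range)
    } else {
      rep(mean(cfg$neocortex_range), length(bm))
    }
    neo_mid <- mean(cfg$neocortex_range)

    # group counts per species: flagged species gets p_flagged_groups,
    # every other species at least one, extras uniform
    flag_sp <- which.max(neo)
    counts <- rep(1L, cfg$n_species)
    counts[flag_sp] <- min(cfg$p_flagged_groups,
                           cfg$n_groups - (cfg$n_species - 1L))
    extra <- cfg$n_groups - sum(counts)
    if (extra > 0) {
      others <- setdiff(seq_len(cfg$n_species), flag_sp)
      add <- table(sample(others, extra, replace = TRUE))
      counts[as.integer(names(add))] <- counts[as.integer(names(add))] +
        as.integer(add)
    }
    sp_of_group <- rep(seq_len(cfg$n_species), counts)

    n_g <- sample(seq(cfg$group_size_range[1], cfg$group_size_range[2]),
                  cfg$n_groups, replace = TRUE)
    sex_ratio <- stats::runif(cfg$n_groups, 0.2, 0.8)
    flagged <- sp_of_group == flag_sp
    context <- ifelse(flagged, "not_applicable",
                      sample(c("captive", "wild"), cfg$n_groups,
                             replace = TRUE, prob = c(33, 41)))
    interaction_type <- sample(INTERACTION_TYPES, cfg$n_groups,
                               replace = TRUE, prob = c(0.4, 0.2, 0.4))

    # planted-effect knob equations (see cohort_config)
    p_dense <- stats::plogis(2.6 + cfg$beta_logsize_E1 * log(n_g) +
                               cfg$noise_sd * stats::rnorm(cfg$n_groups))
    ci_target <- stats::plogis(stats::qlogis(0.35) +
                                 cfg$beta_neo_E1 * (neo[sp_of_group] - neo_mid) +
                                 abs(cfg$beta_CI_E2) *
                                   stats::runif(cfg$n_groups, -1.5, 1.5) +
                                 cfg$noise_sd * stats::rnorm(cfg$n_groups))
    q_target <- stats::runif(cfg$n_groups, 0.05, 0.95)

    metadata <- data.frame(
      group_id = sprintf("grp_%03d", seq_len(cfg$n_groups)),
      species = sp$species[sp_of_group],
      genus = sp$genus[sp_of_group],
      family = sp$family[sp_of_group],
      group_size = n_g,
      sex_ratio = sex_ratio,
      neocortex_ratio = unname(neo[sp_of_group]),
      context = context,
      interaction_type = interaction_type,
      flagged = flagged,
      ci_target = ci_target,
      q_target = q_target,
      p_dense = p_dense,
      stringsAsFactors = FALSE
    )
    networks <- lapply(seq_len(cfg$n_groups), function(i) {
      generate_network(n_g[i], ci_target[i], q_target[i],
                       seed = group_seed(cfg$seed, metadata$group_id[i]),
                       p_dense = p_dense[i],
                       group_id = metadata$group_id[i],
                       interaction_type = interaction_type[i])
    })
    names(networks) <- metadata$group_id
    validate_cohort_metadata(metadata)
    structure(list(metadata = metadata, networks = networks, tree = tree,
                   config = cfg),
              class = "synthetic_cohort")
  })
}

#' Write a synthetic cohort to disk
#'
#' Emits exactly the formats the ingestion functions read: one adjacency CSV
#' per group under `networks/`, `metadata.csv`, a newick `tree.nwk`, and a
#' `manifest.json` listing every file with its per-group seed and MD5
#' checksum.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  net_dir <- file.path(dir, "networks")
  dir.create(net_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(net_dir)) {
    pn_stop(sprintf("cannot create output directory '%s'", dir),
            "primatenet_io_error")
  }
  files <- vapply(cohort$networks, function(net) {
    f <- file.path(net_dir, paste0(net$group_id, ".csv"))
    write_adjacency(net, f)
    f
  }, character(1))
  meta_path <- file.path(dir, "metadata.csv")
  utils::write.csv(cohort$metadata, meta_path, row.names = FALSE, quote = FALSE)
  tree_path <- file.path(dir, "tree.nwk")
  ape::write.tree(cohort$tree, tree_path)
  manifest <- list(
    seed = cohort$config$seed,
    n_groups = nrow(cohort$metadata),
    metadata = basename(meta_path),
    tree = basename(tree_path),
    networks = data.frame(
      group_id = cohort$metadata$group_id,
      file = file.path("networks", basename(files)),
      seed = vapply(cohort$metadata$group_id,
                    function(g) group_seed(cohort$config$seed, g), integer(1)),
      md5 = unname(tools::md5sum(files)),
      stringsAsFactors = FALSE
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.json`.
#' @return List with `metadata`, `networks`, `tree`, `manifest`.
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) {
    pn_stop(sprintf("no manifest.json in '%s'", dir), "primatenet_format_error")
  }
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  metadata <- read_cohort_metadata(file.path(dir, manifest$metadata))
  it <- stats::setNames(metadata$interaction_type, metadata$group_id)
  networks <- lapply(seq_len(nrow(manifest$networks)), function(i) {
    gid <- manifest$networks$group_id[i]
    read_adjacency(file.path(dir, manifest$networks$file[i]), group_id = gid,
                   interaction_type = if (gid %in% names(it)) it[[gid]] else "contact")
  })
  names(networks) <- manifest$networks$group_id
  tree <- ape::read.tree(file.path(dir, manifest$tree))
  list(metadata = metadata, networks = networks, tree = tree,
       manifest = manifest)
}
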