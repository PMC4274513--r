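# The full comparative-statistics battery for one cohort: hierarchical
# models for both efficiency responses on the full and no-flagged subsets,
# the correlation ledger under step-down sequential Bonferroni, variance
# homogeneity tests, and Blomberg's K for both efficiencies.

# (x, y, optional control) specs of the correlation ledger; every variable
# is a cohort_table column.
ledger_pairs <- function() {
  list(
    list(label = "E1~E2",                         x = "E1", y = "E2"),
    list(label = "Q~CI",                          x = "Q", y = "CI"),
    list(label = "Q~CI|density",                  x = "Q", y = "CI", control = "density"),
    list(label = "CI~log_group_size",             x = "CI", y = "log_group_size"),
    list(label = "Q~log_group_size",              x = "Q", y = "log_group_size"),
    list(label = "E2~Q",                          x = "E2", y = "Q"),
    list(label = "E1~neocortex_ratio|log_group_size", x = "E1", y = "neocortex_ratio", control = "log_group_size"),
    list(label = "CI~neocortex_ratio",            x = "CI", y = "neocortex_ratio"),
    list(label = "E1~log_group_size|CI",          x = "E1", y = "log_group_size", control = "CI"),
    list(label = "E1~neocortex_ratio|CI",         x = "E1", y = "neocortex_ratio", control = "CI"),
    list(label = "density~log_group_size",        x = "density", y = "log_group_size"),
    list(label = "E1~log_group_size|density",     x = "E1", y = "log_group_size", control = "density"),
    list(label = "E2~log_group_size|density",     x = "E2", y = "log_group_size", control = "density"),
    list(label = "neocortex_ratio~log_group_size", x = "neocortex_ratio", y = "log_group_size")
  )
}

#' Build the correlation ledger for a cohort
#'
#' Computes every Pearson and first-order partial correlation of the
#' battery on the cohort table, then applies the step-down sequential
#' Bonferroni correction at `family_alpha`.
#'
#' @param cohort A [cohort_table()].
#' @param family_alpha Family-wise error level.
#' @param pairs Optional list of pair specs (label, x, y, optional control)
#'   overriding the built-in battery.
#' @return A `data.frame`: label, control, r, n, p, alpha_adjusted,
#'   significant; sorted by raw p.
#' @export
correlation_ledger <- function(cohort, family_alpha = 0.05, pairs = NULL) {
  pairs <- pairs %||% ledger_pairs()
  rows <- lapply(pairs, function(sp) {
    res <- if (is.null(sp$control)) {
      pearson_r(cohort[[sp$x]], cohort[[sp$y]])
    } else {
      partial_r(cohort[[sp$x]], cohort[[sp$y]], cohort[[sp$control]])
    }
    data.frame(label = sp$label, control = sp$control %||% "",
               r = res$r, n = res$n, p = res$p, stringsAsFactors = FALSE)
  })
  sequential_bonferroni(do.call(rbind, rows), family_alpha = family_alpha)
}

# Variance-homogeneity rows: efficiencies across context (captive vs wild)
# and across interaction type (contact vs proximity), plus CI across
# context. Rows whose two-level subset is infeasible are dropped.
variance_test_table <- function(cohort) {
  specs <- list(
    list(label = "E1~context", var = "E1", by = "context",
         keep = c("captive", "wild")),
    list(label = "E2~context", var = "E2", by = "context",
         keep = c("captive", "wild")),
    list(label = "E1~interaction_type", var = "E1", by = "interaction_type",
         keep = c("contact", "proximity")),
    list(label = "E2~interaction_type", var = "E2", by = "interaction_type",
         keep = c("contact", "proximity")),
    list(label = "CI~context", var = "CI", by = "context",
         keep = c("captive", "wild"))
  )
  rows <- lapply(specs, function(sp) {
    sub <- cohort[cohort[[sp$by]] %in% sp$keep, ]
    out <- tryCatch(
      variance_homogeneity_test(sub[[sp$var]], sub[[sp$by]]),
      primatenet_validation_error = function(e) NULL)
    if (is.null(out)) return(NULL)
    data.frame(label = sp$label, F = out$F, df1 = out$df1, df2 = out$df2,
               p = out$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full comparative-statistics battery
#'
#' Fits the hierarchical model for both efficiency responses (E1 and E2) on
#' the complete cohort and, when any group is flagged, on the cohort with
#' flagged groups removed (the outlier-sensitivity rerun); builds the
#' correlation ledger under step-down sequential Bonferroni; runs the
#' variance-homogeneity tests across context and interaction type; and
#' computes Blomberg's K with a permutation test for the species means of
#' both efficiencies. Deterministic given `seed`.
#'
#' @param cohort A [cohort_table()].
#' @param tree An `ape` `phylo` whose tips are the cohort's species.
#' @param inference `"reml"` or `"bayesian_mcmc"` for the mixed models.
#' @param n_perm Permutations for the K test.
#' @param family_alpha Family-wise error level of the ledger.
#' @param seed Integer seed.
#' @return An object of class `battery_report`: list with `models` (named
#'   list of `model_result`, names like `E1.all`, `E2.no_flagged`),
#'   `variance_proportions`, `correlations`, `variance_tests`,
#'   `phylo_signal` (list with entries `E1`, `E2`) and `meta`.
#' @export
run_paper_battery <- function(cohort, tree, inference = "reml",
                              n_perm = 999L, family_alpha = 0.05, seed = 1L) {
  subsets <- list(all = cohort)
  if (any(cohort$flagged)) {
    subsets$no_flagged <- cohort[!cohort$flagged, ]
  }
  models <- list()
  varprops <- list()
  for (resp in c("E1", "E2")) {
    for (nm in names(subsets)) {
      spec <- model_spec(response = resp, inference = inference, seed = seed)
      key <- paste(resp, nm, sep = ".")
      models[[key]] <- fit_mixed_model(subsets[[nm]], spec)
      varprops[[key]] <- variance_proportions(models[[key]])
    }
  }
  correlations <- correlation_ledger(cohort, family_alpha = family_alpha)
  vtests <- variance_test_table(cohort)
  sp_tree <- ape::keep.tip(tree, intersect(tree$tip.label,
                                           unique(cohort$species)))
  signal <- lapply(c(E1 = "E1", E2 = "E2"), function(v) {
    trait <- tapply(cohort[[v]], cohort$species, mean)
    trait <- trait[sp_tree$tip.label]
    blomberg_K(trait, sp_tree, n_perm = n_perm, seed = seed)
  })
  structure(list(
    models = models,
    variance_proportions = varprops,
    correlations = correlations,
    variance_tests = vtests,
    phylo_signal = signal,
    meta = list(inference = inference, n_perm = as.integer(n_perm),
                family_alpha = family_alpha, seed = as.integer(seed),
                n_groups = nrow(cohort),
                subsets = names(subsets))
  ), class = "battery_report")
}

#' Write a battery report bundle to disk
#'
#' Emits `report.json` (the whole report) plus flat CSVs:
#' `model_coefficients.csv`, `variance_components.csv`, `correlations.csv`,
#' `variance_tests.csv`, `phylo_signal.csv`. Output is byte-identical for
#' identical inputs and seed.
#'
#' @param report A `battery_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_battery_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  coefs <- do.call(rbind, lapply(names(report$models), function(k) {
    cbind(model = k, report$models[[k]]$coefficients)
  }))
  vc <- do.call(rbind, lapply(names(report$models), function(k) {
    data.frame(model = k,
               level = names(report$models[[k]]$varcomp),
               variance = unname(report$models[[k]]$varcomp),
               proportion = unname(report$variance_proportions[[k]]),
               stringsAsFactors = FALSE)
  }))
  ks <- do.call(rbind, lapply(names(report$phylo_signal), function(v) {
    s <- report$phylo_signal[[v]]
    data.frame(response = v, K = s$K, p = s$p, n_perm = s$n_perm,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(coefs, file.path(dir, "model_coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(vc, file.path(dir, "variance_components.csv"),
                   row.names = FALSE)
  utils::write.csv(report$correlations, file.path(dir, "correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(report$variance_tests, file.path(dir, "variance_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(ks, file.path(dir, "phylo_signal.csv"), row.names = FALSE)
  json <- list(
    meta = report$meta,
    models = lapply(report$models, function(m) {
      list(coefficients = m$coefficients,
           varcomp = as.list(m$varcomp),
           convergence = m$convergence[setdiff(names(m$convergence), "fit")])
    }),
    variance_proportions = lapply(report$variance_proportions, as.list),
    correlations = report$correlations,
    variance_tests = report$variance_tests,
    phylo_signal = lapply(report$phylo_signal, unclass)
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.battery_report <- function(x, ...) {
  cat(sprintf("<battery_report> %d groups, %d models (%s), %d ledger rows, %d variance tests\n",
              x$meta$n_groups, length(x$models), x$meta$inference,
              nrow(x$correlations), nrow(x$variance_tests)))
  for (v in names(x$phylo_signal)) {
    cat(sprintf("  %s: K = %.3f, P = %.3f\n", v, x$phylo_signal[[v]]$K,
                x$phylo_signal[[v]]$p))
  }
  invisible(x)
}
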