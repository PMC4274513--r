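# Pipeline stages: generate -> metrics -> stats. Each stage is an exported
# function returning a status code (0 success, 1 partial computation
# failure, 2 input/config error) so the command-line wrapper stays a thin
# shell around them. Log lines carry a stage tag and, where applicable, a
# group id.

pn_log <- function(stage, msg, ..., level = "INFO") {
  message(sprintf("[%s] %s %s", stage, level, sprintf(msg, ...)))
}

#' Pipeline stage: generate a synthetic cohort on disk
#'
#' @param out Output directory.
#' @param config A [cohort_config()].
#' @return Invisibly, a list with `status` (0 ok, 2 input/config error) and
#'   `dir`.
#' @export
pipeline_generate <- function(out, config = cohort_config()) {
  res <- tryCatch({
    cohort <- generate_cohort(config)
    write_cohort(cohort, out)
    pn_log("generate", "wrote %d groups to %s", nrow(cohort$metadata), out)
    list(status = 0L, dir = out)
  }, error = function(e) {
    pn_log("generate", "%s", conditionMessage(e), level = "ERROR")
    list(status = 2L, dir = out)
  })
  invisible(res)
}

#' Pipeline stage: compute metrics for a cohort directory
#'
#' Reads the manifest, computes the full metrics record per group, and
#' writes the metrics CSV. Per-group failures are logged with the group id
#' and skipped; the run continues and the status is 1 if any group failed.
#'
#' @param input_dir Cohort directory written by [pipeline_generate()].
#' @param out_file Output metrics CSV path.
#' @param path_mode Shortest-path mode (see [shortest_paths_matrix()]).
#' @param seed Seed for the modularity optimizer.
#' @return Invisibly, a list with `status` (0/1/2), `metrics` and `failed`
#'   (character vector of failed group ids).
#' @export
pipeline_metrics <- function(input_dir, out_file,
                             path_mode = c("binary", "weighted_inverse"),
                             seed = 1L) {
  path_mode <- match.arg(path_mode)
  man_path <- file.path(input_dir, "manifest.json")
  if (!file.exists(man_path)) {
    pn_log("metrics", "missing manifest.json in %s", input_dir, level = "ERROR")
    return(invisible(list(status = 2L, metrics = NULL, failed = character(0))))
  }
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  failed <- character(0)
  rows <- list()
  for (i in seq_len(nrow(manifest$networks))) {
    gid <- manifest$networks$group_id[i]
    rows[[gid]] <- tryCatch({
      net <- read_adjacency(file.path(input_dir, manifest$networks$file[i]),
                            group_id = gid)
      withCallingHandlers(
        compute_metrics(net, path_mode = path_mode, seed = seed),
        warning = function(w) {
          pn_log("metrics", "group=%s %s", gid, conditionMessage(w),
                 level = "WARN")
          invokeRestart("muffleWarning")
        })
    }, error = function(e) {
      pn_log("metrics", "group=%s failed: %s", gid, conditionMessage(e),
             level = "ERROR")
      failed <<- c(failed, gid)
      NULL
    })
  }
  metrics <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(metrics) || nrow(metrics) == 0) {
    pn_log("metrics", "no group could be processed", level = "ERROR")
    return(invisible(list(status = 2L, metrics = NULL, failed = failed)))
  }
  write_metrics(metrics, out_file)
  pn_log("metrics", "wrote %d rows to %s (%d failures)", nrow(metrics),
         out_file, length(failed))
  invisible(list(status = if (length(failed)) 1L else 0L,
                 metrics = metrics, failed = failed))
}

#' Pipeline stage: run the statistics battery
#'
#' Joins the metrics CSV with the cohort metadata, reads the species tree,
#' runs [run_paper_battery()] and writes the report bundle.
#'
#' @param metrics_csv Metrics CSV from [pipeline_metrics()].
#' @param metadata_csv Cohort metadata CSV.
#' @param tree_file Newick species tree.
#' @param out_dir Report bundle output directory.
#' @param inference,n_perm,seed Passed to [run_paper_battery()].
#' @return Invisibly, a list with `status` (0 ok, 2 input error) and
#'   `report`.
#' @export
pipeline_stats <- function(metrics_csv, metadata_csv, tree_file, out_dir,
                           inference = "reml", n_perm = 999L, seed = 1L) {
  res <- tryCatch({
    metrics <- utils::read.csv(metrics_csv, stringsAsFactors = FALSE)
    metadata <- read_cohort_metadata(metadata_csv)
    tree <- ape::read.tree(tree_file)
    tab <- cohort_table(metadata, metrics)
    report <- run_paper_battery(tab, tree, inference = inference,
                                n_perm = n_perm, seed = seed)
    write_battery_report(report, out_dir)
    pn_log("stats", "report bundle written to %s", out_dir)
    list(status = 0L, report = report)
  }, error = function(e) {
    pn_log("stats", "%s", conditionMessage(e), level = "ERROR")
    list(status = 2L, report = NULL)
  })
  invisible(res)
}

#' Run the full pipeline in one call
#'
#' generate -> metrics -> stats under one seed, writing everything below
#' `out`. Stops at the first stage whose status is 2.
#'
#' @param out Output directory.
#' @param config A [cohort_config()].
#' @param path_mode,inference,n_perm Stage options.
#' @return Invisibly, a list with per-stage results and overall `status`.
#' @export
pipeline_all <- function(out, config = cohort_config(),
                         path_mode = "binary", inference = "reml",
                         n_perm = 999L) {
  gen <- pipeline_generate(file.path(out, "cohort"), config)
  if (gen$status == 2L) return(invisible(list(status = 2L, generate = gen)))
  met <- pipeline_metrics(file.path(out, "cohort"),
                          file.path(out, "metrics.csv"),
                          path_mode = path_mode, seed = config$seed)
  if (met$status == 2L) {
    return(invisible(list(status = 2L, generate = gen, metrics = met)))
  }
  st <- pipeline_stats(file.path(out, "metrics.csv"),
                       file.path(out, "cohort", "metadata.csv"),
                       file.path(out, "cohort", "tree.nwk"),
                       file.path(out, "report"),
                       inference = inference, n_perm = n_perm,
                       seed = config$seed)
  invisible(list(status = max(gen$status, met$status, st$status),
                 generate = gen, metrics = met, stats = st))
}
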