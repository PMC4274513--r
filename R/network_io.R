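# Ingestion, validation and serialization of per-group association networks
# and cohort metadata.

INTERACTION_TYPES <- c("contact", "grooming", "proximity")
CONTEXT_LEVELS <- c("captive", "wild", "not_applicable")

#' Construct a weighted group association network
#'
#' A `weighted_network` holds one group's socio-positive association matrix
#' (body contact, grooming or proximity). The matrix is symmetrized on
#' construction (arithmetic mean of the two directed weights), its diagonal
#' forced to zero, and the result validated: square, dimension >= 2, all
#' weights non-negative, at least one positive weight.
#'
#' @param W Square numeric matrix of non-negative association weights.
#'   Row/column names, when present, become the node labels.
#' @param group_id Opaque group label.
#' @param node_ids Optional character vector of node labels; defaults to the
#'   matrix dimnames or `"n1" ... "nN"`.
#' @param interaction_type One of `"contact"`, `"grooming"`, `"proximity"`.
#' @return An object of class `weighted_network` with fields `group_id`,
#'   `node_ids`, `W` and `interaction_type`.
#' @seealso [read_adjacency()], [symmetrize()]
#' @examples
#' W <- matrix(c(0, 2, 0, 2, 0, 1, 0, 1, 0), 3, 3)
#' net <- weighted_network(W, group_id = "demo")
#' n_nodes(net)
#' n_edges(net)
#' @export
weighted_network <- function(W, group_id = "group", node_ids = NULL,
                             interaction_type = "contact") {
  if (!is.matrix(W) || !is.numeric(W)) {
    pn_stop("W must be a numeric matrix", "primatenet_format_error")
  }
  interaction_type <- match.arg(interaction_type, INTERACTION_TYPES)
  if (is.null(node_ids)) {
    node_ids <- rownames(W) %||% colnames(W) %||% paste0("n", seq_len(nrow(W)))
  }
  W <- symmetrize(W)
  dimnames(W) <- list(node_ids, node_ids)
  net <- structure(
    list(group_id = group_id, node_ids = node_ids, W = W,
         interaction_type = interaction_type),
    class = "weighted_network"
  )
  validate_network(net)
}

#' Validate a weighted network
#'
#' Checks the structural invariants of a [weighted_network()]: square matrix
#' matching the node labels, dimension >= 2, symmetry, zero diagonal,
#' non-negative weights, and at least one positive weight (an all-zero
#' matrix signals an empty network and is rejected).
#'
#' @param net A `weighted_network`.
#' @return `net`, invisibly unchanged, if valid; otherwise an error of class
#'   `primatenet_validation_error`.
#' @export
validate_network <- function(net) {
  W <- net$W
  n <- length(net$node_ids)
  if (nrow(W) != ncol(W) || nrow(W) != n) {
    pn_stop(sprintf("[%s] weight matrix is not square on %d node labels",
                    net$group_id, n), "primatenet_validation_error")
  }
  if (n < 2) {
    pn_stop(sprintf("[%s] a network needs at least 2 individuals, got %d",
                    net$group_id, n), "primatenet_validation_error")
  }
  if (anyNA(W)) {
    pn_stop(sprintf("[%s] weight matrix contains missing values", net$group_id),
            "primatenet_validation_error")
  }
  if (any(W < 0)) {
    pn_stop(sprintf("[%s] negative association weights are not allowed",
                    net$group_id), "primatenet_validation_error")
  }
  if (!isTRUE(all.equal(W, t(W), tolerance = 1e-12, check.attributes = FALSE))) {
    pn_stop(sprintf("[%s] weight matrix is not symmetric", net$group_id),
            "primatenet_validation_error")
  }
  if (any(diag(W) != 0)) {
    pn_stop(sprintf("[%s] diagonal entries must be zero", net$group_id),
            "primatenet_validation_error")
  }
  if (all(W == 0)) {
    pn_stop(sprintf("[%s] all weights are zero (empty network)", net$group_id),
            "primatenet_validation_error")
  }
  invisible(net)
}

#' Symmetrize a non-negative weight matrix
#'
#' Replaces the pair of directed weights between every two individuals by
#' their arithmetic mean, which preserves total interaction mass, and forces
#' the diagonal to zero. Idempotent on already-symmetric input.
#'
#' @param W Square numeric matrix with non-negative entries.
#' @return A symmetric matrix of the same dimension with zero diagonal.
#' @examples
#' W <- matrix(0, 2, 2); W[1, 2] <- 5
#' symmetrize(W)          # 2.5 in both off-diagonal cells
#' @export
symmetrize <- function(W) {
  if (!is.matrix(W) || !is.numeric(W) || nrow(W) != ncol(W)) {
    pn_stop("symmetrize() needs a square numeric matrix",
            "primatenet_format_error")
  }
  if (anyNA(W)) {
    pn_stop("symmetrize() input contains missing values",
            "primatenet_validation_error")
  }
  if (any(W < 0)) {
    pn_stop("symmetrize() input has negative weights",
            "primatenet_validation_error")
  }
  out <- (W + t(W)) / 2
  diag(out) <- 0
  out
}

#' Number of individuals in a network
#' @param net A `weighted_network`.
#' @return Integer N, the matrix dimension.
#' @export
n_nodes <- function(net) length(net$node_ids)

#' Number of connections in a network
#'
#' A connection is an unordered pair of individuals whose symmetrized
#' association weight is strictly positive.
#'
#' @param net A `weighted_network`.
#' @return Integer I, the number of observed relationships.
#' @export
n_edges <- function(net) {
  W <- net$W
  sum(W[upper.tri(W)] > 0)
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("<weighted_network> %s: N = %d, I = %d, interaction = %s\n",
              x$group_id, n_nodes(x), n_edges(x), x$interaction_type))
  invisible(x)
}

# Guess the field separator of a delimited text file from its first line.
detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  counts <- vapply(c("\t", ",", ";"), function(d) {
    lengths(regmatches(first, gregexpr(d, first, fixed = TRUE)))
  }, integer(1))
  if (all(counts == 0)) {
    pn_stop(sprintf("cannot detect delimiter in '%s'", path),
            "primatenet_format_error")
  }
  names(counts)[which.max(counts)]
}

#' Read a group association matrix from a delimited file
#'
#' The file must contain a square numeric block whose first row and first
#' column carry the node labels (CSV, TSV or semicolon-delimited; the
#' delimiter is auto-detected). Blank cells are read as 0 (absence of an
#' observation is absence of an edge). Asymmetric input is symmetrized by
#' [symmetrize()] before validation.
#'
#' @param path Path to the file.
#' @param group_id Group label; defaults to the file name without extension.
#' @param interaction_type Interaction class of this network.
#' @return A validated [weighted_network()].
#' @export
read_adjacency <- function(path, group_id = NULL, interaction_type = "contact") {
  if (!file.exists(path)) {
    pn_stop(sprintf("no such file: '%s'", path), "primatenet_format_error")
  }
  delim <- detect_delim(path)
  df <- tryCatch(
    utils::read.table(path, sep = delim, header = TRUE, row.names = 1,
                      check.names = FALSE, stringsAsFactors = FALSE,
                      comment.char = ""),
    error = function(e) {
      pn_stop(sprintf("cannot parse '%s' as a delimited matrix: %s",
                      path, conditionMessage(e)), "primatenet_format_error")
    }
  )
  if (nrow(df) != ncol(df)) {
    pn_stop(sprintf("'%s': matrix block is %d x %d, not square",
                    path, nrow(df), ncol(df)), "primatenet_format_error")
  }
  if (!all(vapply(df, is.numeric, logical(1)))) {
    pn_stop(sprintf("'%s': non-numeric entries in matrix body", path),
            "primatenet_format_error")
  }
  if (!identical(rownames(df), colnames(df))) {
    pn_stop(sprintf("'%s': row and column node labels disagree", path),
            "primatenet_format_error")
  }
  W <- as.matrix(df)
  W[is.na(W)] <- 0
  weighted_network(W, group_id = group_id %||% sub("\\.[^.]*$", "", basename(path)),
                   node_ids = rownames(df), interaction_type = interaction_type)
}

#' Write a group association matrix to a delimited file
#'
#' Writes the labelled weight matrix with full (17 significant digit)
#' precision so that a write/read round trip reproduces the weights exactly.
#'
#' @param net A `weighted_network`.
#' @param path Output file path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(net, path, sep = ",") {
  W <- net$W
  body <- matrix(formatC(W, format = "g", digits = 17), nrow(W), ncol(W))
  lines <- c(
    paste(c("", net$node_ids), collapse = sep),
    vapply(seq_len(nrow(W)), function(i) {
      paste(c(net$node_ids[i], body[i, ]), collapse = sep)
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a group association network from a three-column edge list
#'
#' Columns `node_a`, `node_b`, `weight` (header required), undirected
#' interpretation. Duplicate pairs, in either orientation, are summed before
#' symmetrization. Node order is order of first appearance in the file.
#'
#' @inheritParams read_adjacency
#' @return A validated [weighted_network()].
#' @export
read_edge_list <- function(path, group_id = NULL, interaction_type = "contact") {
  if (!file.exists(path)) {
    pn_stop(sprintf("no such file: '%s'", path), "primatenet_format_error")
  }
  delim <- detect_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("node_a", "node_b", "weight")
  if (!all(need %in% names(df))) {
    pn_stop(sprintf("'%s': edge list needs columns %s", path,
                    paste(need, collapse = ", ")), "primatenet_format_error")
  }
  if (!is.numeric(df$weight)) {
    pn_stop(sprintf("'%s': weight column is not numeric", path),
            "primatenet_format_error")
  }
  nodes <- unique(c(rbind(as.character(df$node_a), as.character(df$node_b))))
  W <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(df))) {
    a <- as.character(df$node_a[r]); b <- as.character(df$node_b[r])
    W[a, b] <- W[a, b] + df$weight[r]
    W[b, a] <- W[b, a] + df$weight[r]
  }
  weighted_network(W, group_id = group_id %||% sub("\\.[^.]*$", "", basename(path)),
                   node_ids = nodes, interaction_type = interaction_type)
}

#' Read and validate a cohort metadata table
#'
#' One row per group, CSV with columns `group_id`, `species`, `genus`,
#' `family`, `group_size`, `sex_ratio` (proportion of males), `neocortex_ratio`,
#' `context` (`captive`/`wild`/`not_applicable`) and `interaction_type`.
#' Taxonomy labels are preserved verbatim so they can serve as random-effect
#' grouping factors downstream. An optional logical `flagged` column marks
#' the outlier subset (e.g. human groups) excluded in sensitivity reruns.
#'
#' @param path Path to the CSV file.
#' @return A validated `data.frame`, one row per group.
#' @export
read_cohort_metadata <- function(path) {
  if (!file.exists(path)) {
    pn_stop(sprintf("no such file: '%s'", path), "primatenet_format_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group_id", "species", "genus", "family", "group_size",
            "sex_ratio", "neocortex_ratio", "context", "interaction_type")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    pn_stop(sprintf("'%s': missing metadata columns: %s", path,
                    paste(missing, collapse = ", ")), "primatenet_format_error")
  }
  validate_cohort_metadata(df)
}

#' Validate cohort metadata invariants
#'
#' @param df Metadata `data.frame` (see [read_cohort_metadata()] for columns).
#' @return `df` with `flagged` defaulted to `FALSE` when absent.
#' @export
validate_cohort_metadata <- function(df) {
  bad <- function(msg, ids) {
    pn_stop(sprintf("%s (groups: %s)", msg, paste(ids, collapse = ", ")),
            "primatenet_validation_error")
  }
  if (anyDuplicated(df$group_id)) {
    bad("duplicated group ids", df$group_id[duplicated(df$group_id)])
  }
  out <- which(df$sex_ratio < 0 | df$sex_ratio > 1 | is.na(df$sex_ratio))
  if (length(out)) bad("sex_ratio outside [0, 1]", df$group_id[out])
  out <- which(!(df$neocortex_ratio > 0))
  if (length(out)) bad("neocortex_ratio must be > 0", df$group_id[out])
  out <- which(df$group_size < 2 | df$group_size != round(df$group_size))
  if (length(out)) bad("group_size must be an integer >= 2", df$group_id[out])
  out <- which(!df$context %in% CONTEXT_LEVELS)
  if (length(out)) bad(sprintf("context must be one of %s",
                               paste(CONTEXT_LEVELS, collapse = "/")),
                       df$group_id[out])
  out <- which(!df$interaction_type %in% INTERACTION_TYPES)
  if (length(out)) bad(sprintf("interaction_type must be one of %s",
                               paste(INTERACTION_TYPES, collapse = "/")),
                       df$group_id[out])
  if (is.null(df$flagged)) df$flagged <- FALSE
  df
}
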