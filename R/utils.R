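# Internal helpers: classed conditions and seed management.

pn_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "primatenet_error")))
}

pn_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "primatenet_warning")))
}

#' Evaluate an expression under a local RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so library internals that consume random numbers
#' never perturb user-level reproducibility.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-group seed from a global seed and a group label
#'
#' Stable string hash (polynomial rolling hash over UTF-8 code points)
#' combined with the global seed, reduced below 2^31 so the result is a
#' valid R integer seed. Insertion order of groups therefore never affects
#' the networks they receive.
#'
#' @param global_seed Integer cohort-level seed.
#' @param group_id Character label of the group.
#' @return A single integer seed.
#' @export
group_seed <- function(global_seed, group_id) {
  stopifnot(length(group_id) == 1L, is.character(group_id))
  h <- 0
  for (b in utf8ToInt(group_id)) {
    h <- (h * 131 + b) %% 1987654321
  }
  as.integer((abs(as.numeric(global_seed)) * 7919 + h) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
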