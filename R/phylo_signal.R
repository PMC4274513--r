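# Blomberg's K with a tip-permutation test.

#' Blomberg's K phylogenetic signal statistic
#'
#' K compares the observed partitioning of trait variance on a phylogeny to
#' the partitioning expected under Brownian motion (BM). With phylogenetic
#' variance-covariance matrix C implied by the tree, phylogenetic mean
#' a = (1'C^-1 x)/(1'C^-1 1), MSE0 = (x-a)'(x-a)/(n-1) and
#' MSE = (x-a)'C^-1(x-a)/(n-1), the statistic is
#' K = (MSE0/MSE) / E_BM(MSE0/MSE), where the BM expectation is
#' (tr(C) - n/(1'C^-1 1))/(n-1). K is near 1 for BM-evolved traits, near 0
#' when trait values are independent of the phylogeny, and is invariant
#' under affine transformation of the trait.
#'
#' The permutation test shuffles trait values across tips; low MSE (hence
#' high K) indicates signal, so p is the proportion of permutations whose
#' MSE is at most the observed MSE, with the observed arrangement counted:
#' p = (1 + b)/(n_perm + 1).
#'
#' @param trait Named numeric vector; names must be exactly the tree's tip
#'   labels.
#' @param tree An `ape` `phylo` with positive branch lengths.
#' @param n_perm Number of tip-label permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return An object of class `phylo_signal`: list with `K`, `p`, `n_perm`.
#' @export
blomberg_K <- function(trait, tree, n_perm = 999L, seed = 1L) {
  if (is.null(names(trait))) {
    pn_stop("trait vector must be named by species", "primatenet_validation_error")
  }
  extra <- setdiff(names(trait), tree$tip.label)
  miss <- setdiff(tree$tip.label, names(trait))
  if (length(extra) || length(miss)) {
    pn_stop(sprintf(
      "trait/tree tip mismatch; not in tree: %s; missing trait: %s",
      paste(c(extra, "-")[1:max(1, length(extra))], collapse = ","),
      paste(c(miss, "-")[1:max(1, length(miss))], collapse = ",")),
      "primatenet_validation_error")
  }
  if (any(tree$edge.length <= 0)) {
    pn_stop("tree must have strictly positive branch lengths",
            "primatenet_validation_error")
  }
  C <- ape::vcv(tree)
  x <- trait[rownames(C)]
  n <- length(x)
  invC <- chol2inv(chol(C))
  ones <- rep(1, n)
  denom_1C1 <- as.numeric(ones %*% invC %*% ones)
  expected_ratio <- (sum(diag(C)) - n / denom_1C1) / (n - 1)

  mse_pair <- function(xx) {
    a <- as.numeric(ones %*% invC %*% xx) / denom_1C1
    dev <- xx - a
    c(mse0 = sum(dev^2) / (n - 1),
      mse = as.numeric(dev %*% invC %*% dev) / (n - 1))
  }
  obs <- mse_pair(x)
  K <- (obs["mse0"] / obs["mse"]) / expected_ratio
  p <- local_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      perm <- mse_pair(sample(as.numeric(x)))
      if (perm["mse"] <= obs["mse"]) hits <- hits + 1L
    }
    (1 + hits) / (n_perm + 1)
  })
  structure(list(K = unname(K), p = p, n_perm = as.integer(n_perm)),
            class = "phylo_signal")
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.3f, permutation P = %.3f (%d permutations)\n",
              x$K, x$p, x$n_perm))
  invisible(x)
}
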