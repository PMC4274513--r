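# Pearson and first-order partial correlations, and the step-down
# sequential Bonferroni (Holm) multiple-comparison procedure.

check_cor_input <- function(x, y, what = "correlation") {
  if (length(x) != length(y)) {
    pn_stop("vectors must have equal length", "primatenet_validation_error")
  }
  if (length(x) < 3) {
    pn_stop(sprintf("%s needs at least 3 observations", what),
            "primatenet_validation_error")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    pn_stop("non-finite values in correlation input",
            "primatenet_validation_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    pn_stop("undefined correlation: zero variance",
            "primatenet_validation_error")
  }
}

#' Pearson product-moment correlation
#'
#' Standard r with its two-sided t-test p-value (df = n - 2).
#'
#' @param x,y Equal-length finite numeric vectors with nonzero variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  check_cor_input(x, y)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' First-order partial correlation
#'
#' Correlation between `x` and `y` after removing the linear effect of a
#' single control variable, via the closed form
#' r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)),
#' equivalently the correlation of the residuals of `x` and `y` each
#' regressed on `control`. Two-sided p-value from t = r sqrt((n-3)/(1-r^2))
#' on n - 3 degrees of freedom.
#'
#' @param x,y,control Equal-length finite numeric vectors.
#' @return List with `r`, `p`, `n`, `control` (always `TRUE`).
#' @export
partial_r <- function(x, y, control) {
  check_cor_input(x, y)
  check_cor_input(x, control, "partial correlation")
  rxy <- stats::cor(x, y)
  rxz <- stats::cor(x, control)
  ryz <- stats::cor(y, control)
  den <- (1 - rxz^2) * (1 - ryz^2)
  if (den <= .Machine$double.eps) {
    pn_stop("undefined partial correlation: a variable is collinear with the control",
            "primatenet_validation_error")
  }
  r <- (rxy - rxz * ryz) / sqrt(den)
  n <- length(x)
  df <- n - 3
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  list(r = r, p = p, n = n, control = TRUE)
}

#' Step-down sequential Bonferroni (Holm) correction
#'
#' Sorts the raw p-values ascending and compares the k-th smallest to
#' `family_alpha / (m - k + 1)`, rejecting until the first failure; no test
#' is rejected after the first acceptance, so the rejection flags are
#' monotone in the sorted order.
#'
#' @param ledger `data.frame` with columns `label` and `p` (raw p-values in
#'   [0, 1]); other columns (e.g. `r`) are carried through.
#' @param family_alpha Family-wise error level (default 0.05).
#' @return The ledger sorted by raw p ascending, with columns
#'   `alpha_adjusted` (the step-down threshold for that rank) and
#'   `significant` appended.
#' @examples
#' sequential_bonferroni(data.frame(label = c("a", "b", "c"),
#'                                  p = c(0.001, 0.02, 0.9)))
#' @export
sequential_bonferroni <- function(ledger, family_alpha = 0.05) {
  stopifnot(is.data.frame(ledger), all(c("label", "p") %in% names(ledger)))
  if (any(ledger$p < 0 | ledger$p > 1 | is.na(ledger$p))) {
    pn_stop("raw p-values must lie in [0, 1]", "primatenet_validation_error")
  }
  m <- nrow(ledger)
  out <- ledger[order(ledger$p), , drop = FALSE]
  out$alpha_adjusted <- family_alpha / (m - seq_len(m) + 1)
  pass <- out$p <= out$alpha_adjusted
  out$significant <- cumprod(pass) > 0   # stop at the first acceptance
  rownames(out) <- NULL
  out
}
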