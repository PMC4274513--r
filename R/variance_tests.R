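# Variance-homogeneity test across a two-level grouping.

#' Brown-Forsythe variance-homogeneity test
#'
#' Levene-type test robust to non-normality: one-way ANOVA on the absolute
#' deviations of each observation from its group median, across exactly two
#' groups, giving F on (1, n - 2) degrees of freedom. Used to compare the
#' spread of an efficiency measure across contexts (captive vs wild) or
#' interaction types.
#'
#' @param values Numeric vector.
#' @param grouping Factor (or coercible) with exactly two observed levels,
#'   each with at least 2 observations.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
variance_homogeneity_test <- function(values, grouping) {
  g <- factor(grouping)
  g <- droplevels(g)
  if (nlevels(g) != 2) {
    pn_stop(sprintf("variance test needs exactly 2 groups, got %d", nlevels(g)),
            "primatenet_validation_error")
  }
  if (any(table(g) < 2)) {
    pn_stop("each group needs at least 2 observations",
            "primatenet_validation_error")
  }
  if (length(values) != length(g) || !all(is.finite(values))) {
    pn_stop("values must be finite and match the grouping length",
            "primatenet_validation_error")
  }
  med <- tapply(values, g, stats::median)
  z <- abs(values - med[as.integer(g)])
  n <- length(z)
  if (all(z == z[1])) {
    # identical deviations in both groups: no spread difference at all
    return(list(F = 0, df1 = 1L, df2 = n - 2L, p = 1))
  }
  fit <- stats::anova(stats::lm(z ~ g))
  list(F = fit$`F value`[1], df1 = 1L, df2 = as.integer(fit$Df[2]),
       p = fit$`Pr(>F)`[1])
}
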