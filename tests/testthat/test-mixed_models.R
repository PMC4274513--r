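# A small planted cohort shared by the model tests: noiseless knobs so the
# planted topology effects are as clean as the generator allows.
planted_cohort_table <- function(seed, noise_sd = 0) {
  cfg <- cohort_config(noise_sd = noise_sd, seed = seed)
  coh <- generate_cohort(cfg)
  cohort_table(coh$metadata, cohort_metrics(coh$networks))
}

test_that("cohort_table joins, validates sizes, and flags unmatched groups", {
  cfg <- cohort_config(n_families = 2, n_genera = 3, n_species = 5,
                       n_groups = 10, seed = 13)
  coh <- generate_cohort(cfg)
  m <- cohort_metrics(coh$networks)
  tab <- cohort_table(coh$metadata, m)
  expect_s3_class(tab, "cohort_table")
  expect_equal(nrow(tab), 10)
  expect_equal(tab$log_group_size, log(tab$group_size))

  expect_error(cohort_table(coh$metadata, m[-3, ]),
               class = "primatenet_join_error")
  bad <- coh$metadata
  bad$group_size[1] <- bad$group_size[1] + 1
  expect_error(cohort_table(bad, m), class = "primatenet_validation_error")
})

test_that("REML fit recovers the planted slope signs on a noiseless cohort", {
  tab <- planted_cohort_table(seed = 31)
  f1 <- fit_mixed_model(tab, model_spec("E1"))
  c1 <- f1$coefficients
  est <- c1$estimate[c1$term == "log_group_size"]
  expect_lt(est, 0)
  expect_lt(c1$ci_hi[c1$term == "log_group_size"], 0)   # interval excludes 0

  f2 <- fit_mixed_model(tab, model_spec("E2"))
  c2 <- f2$coefficients
  expect_lt(c2$estimate[c2$term == "CI"], 0)
  expect_lt(c2$ci_hi[c2$term == "CI"], 0)

  expect_true(all(f1$varcomp >= 0))
  expect_named(f1$varcomp, c("family", "genus", "residual"))
})

test_that("REML and Bayesian MCMC agree on fixed-effect signs", {
  tab <- planted_cohort_table(seed = 57)
  reml <- fit_mixed_model(tab, model_spec("E2", inference = "reml"))
  bayes <- fit_mixed_model(tab, model_spec("E2", inference = "bayesian_mcmc",
                                           n_iter = 3000, n_burnin = 500,
                                           seed = 5))
  key <- c("log_group_size", "CI")
  sr <- sign(reml$coefficients$estimate[match(key, reml$coefficients$term)])
  sb <- sign(bayes$coefficients$estimate[match(key, bayes$coefficients$term)])
  expect_identical(sr, sb)
  expect_lt(bayes$convergence$max_psrf, 1.2)
  # Bayesian rerun with the same seed is identical
  bayes2 <- fit_mixed_model(tab, model_spec("E2", inference = "bayesian_mcmc",
                                            n_iter = 3000, n_burnin = 500,
                                            seed = 5))
  expect_identical(bayes$coefficients, bayes2$coefficients)
})

test_that("a pure-noise response yields intervals covering zero at nominal rate", {
  tab <- planted_cohort_table(seed = 99, noise_sd = 0.15)
  cover <- c()
  for (s in 1:20) {
    set.seed(s)
    tab$E1 <- rnorm(nrow(tab))
    fit <- fit_mixed_model(tab, model_spec("E1"))
    cf <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
    cover <- c(cover, cf$ci_lo <= 0 & cf$ci_hi >= 0)
  }
  expect_gte(mean(cover), 0.9)
})

test_that("an injected family intercept shift is absorbed by the family component", {
  tab <- planted_cohort_table(seed = 11, noise_sd = 0.15)
  recovered <- sapply(1:20, function(s) {
    set.seed(s)
    shift <- setNames(rnorm(length(unique(tab$family)), sd = sqrt(0.3)),
                      unique(tab$family))
    tab$E1 <- rnorm(nrow(tab), sd = 0.2) + shift[tab$family]
    fit <- fit_mixed_model(tab, model_spec("E1"))
    fit$varcomp["family"]
  })
  expect_gt(mean(recovered), 0)
  expect_lt(mean(recovered), 2 * 0.3)
  expect_gt(mean(recovered), 0.3 / 2)
})

test_that("degenerate nesting drops the single-level term with a warning", {
  cfg <- cohort_config(n_families = 1, n_genera = 3, n_species = 6,
                       n_groups = 24, group_size_range = c(5, 15), seed = 2)
  coh <- generate_cohort(cfg)
  tab <- cohort_table(coh$metadata, cohort_metrics(coh$networks))
  expect_warning(fit <- fit_mixed_model(tab, model_spec("E1")),
                 class = "primatenet_nesting_warning")
  expect_equal(unname(fit$varcomp["family"]), 0)
})

test_that("variance proportions normalize the components", {
  expect_equal(unname(variance_proportions(c(family = 1, genus = 1, residual = 2))),
               c(0.25, 0.25, 0.50))
  expect_equal(unname(variance_proportions(c(family = 0, genus = 0, residual = 3))),
               c(0, 0, 1))
  expect_error(variance_proportions(c(family = -1, genus = 0, residual = 1)),
               class = "primatenet_validation_error")
})
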