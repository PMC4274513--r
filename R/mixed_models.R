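# Hierarchical models for the cohort table: efficiency responses on fixed
# covariates with genus-nested-in-family random intercepts, fit either by
# REML (lme4/lmerTest) or by Bayesian MCMC (JAGS), plus variance-component
# summaries.

#' Join metadata and metrics into the cohort analysis table
#'
#' Inner-joins the group metadata and the per-group metrics on `group_id`,
#' checks that every group is present on both sides and that the metadata
#' group size equals the network node count, and adds the
#' `log_group_size` covariate.
#'
#' @param metadata Metadata `data.frame` (see [read_cohort_metadata()]).
#' @param metrics Metrics `data.frame` (see [cohort_metrics()]).
#' @return A `data.frame` of class `cohort_table`.
#' @export
cohort_table <- function(metadata, metrics) {
  metadata <- validate_cohort_metadata(metadata)
  unmatched <- c(setdiff(metadata$group_id, metrics$group_id),
                 setdiff(metrics$group_id, metadata$group_id))
  if (length(unmatched)) {
    pn_stop(sprintf("groups present on only one side of the join: %s",
                    paste(sort(unique(unmatched)), collapse = ", ")),
            "primatenet_join_error")
  }
  keep <- setdiff(names(metrics), setdiff(names(metadata), "group_id"))
  tab <- merge(metadata, metrics[, keep], by = "group_id", sort = TRUE)
  bad <- tab$group_id[tab$group_size != tab$N]
  if (length(bad)) {
    pn_stop(sprintf("metadata group_size disagrees with network size for: %s",
                    paste(bad, collapse = ", ")), "primatenet_validation_error")
  }
  tab$log_group_size <- log(tab$group_size)
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Specify a hierarchical efficiency model
#'
#' @param response `"E1"` (Global Efficiency) or `"E2"` (Average Dyadic
#'   Efficiency).
#' @param fixed_effects Ordered subset of `log_group_size`, `sex_ratio`,
#'   `neocortex_ratio`, `CI`.
#' @param inference `"reml"` (lme4 + Satterthwaite tests) or
#'   `"bayesian_mcmc"` (JAGS, weakly-informative priors: diffuse normals on
#'   slopes, half-Cauchy scale 2.5 on standard deviations).
#' @param n_iter,n_burnin,n_thin,n_chains MCMC settings (Bayesian mode).
#' @param seed Integer seed (Bayesian mode chains derive their RNG seeds
#'   from it).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(response = c("E1", "E2"),
                       fixed_effects = c("log_group_size", "sex_ratio",
                                         "neocortex_ratio", "CI"),
                       inference = c("reml", "bayesian_mcmc"),
                       n_iter = 4000L, n_burnin = 1000L, n_thin = 2L,
                       n_chains = 2L, seed = 1L) {
  response <- match.arg(response)
  inference <- match.arg(inference)
  allowed <- c("log_group_size", "sex_ratio", "neocortex_ratio", "CI")
  if (!length(fixed_effects) || !all(fixed_effects %in% allowed)) {
    pn_stop(sprintf("fixed_effects must be a non-empty subset of %s",
                    paste(allowed, collapse = ", ")),
            "primatenet_config_error")
  }
  structure(list(response = response, fixed_effects = fixed_effects,
                 inference = inference, n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), n_thin = as.integer(n_thin),
                 n_chains = as.integer(n_chains), seed = as.integer(seed)),
            class = "model_spec")
}

check_model_data <- function(cohort, spec) {
  need <- c(spec$response, spec$fixed_effects, "family", "genus")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    pn_stop(sprintf("cohort table lacks columns: %s",
                    paste(miss, collapse = ", ")), "primatenet_validation_error")
  }
  sub <- cohort[, need]
  if (anyNA(sub)) {
    pn_stop("missing values in model variables", "primatenet_validation_error")
  }
  cohort
}

fit_reml <- function(cohort, spec) {
  use_family <- length(unique(cohort$family)) >= 2
  use_genus <- length(unique(cohort$genus)) >= 2
  if (!use_family || !use_genus) {
    pn_warn("degenerate taxonomic nesting: refitting without single-level terms",
            "primatenet_nesting_warning")
  }
  re <- c(if (use_family) "(1 | family)",
          if (use_genus) "(1 | family:genus)")
  if (is.null(re)) {
    pn_stop("no taxonomic level has >= 2 groups; not a hierarchical model",
            "primatenet_validation_error")
  }
  fml <- stats::as.formula(paste(
    spec$response, "~", paste(c(spec$fixed_effects, re), collapse = " + ")))
  fit <- suppressMessages(lmerTest::lmer(fml, data = cohort, REML = TRUE))
  sm <- summary(fit)$coefficients
  terms <- c("(Intercept)", spec$fixed_effects)
  coefs <- data.frame(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    ci_lo = sm[, "Estimate"] - stats::qnorm(0.975) * sm[, "Std. Error"],
    ci_hi = sm[, "Estimate"] + stats::qnorm(0.975) * sm[, "Std. Error"],
    p = sm[, "Pr(>|t|)"],
    stringsAsFactors = FALSE, row.names = NULL
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  getvar <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else 0
  }
  varcomp <- c(family = getvar("family"),
               genus = getvar("family:genus"),
               residual = getvar("Residual"))
  list(coefficients = coefs, varcomp = varcomp,
       convergence = list(singular = lme4::isSingular(fit),
                          messages = fit@optinfo$conv$lme4$messages %||% character(0)),
       fit = fit)
}

jags_model_string <- "
model {
  for (i in 1:n) {
    y[i] ~ dnorm(mu[i], tau)
    mu[i] <- inprod(X[i, ], beta) + u_fam[fam[i]] + u_gen[gen[i]]
  }
  for (j in 1:J) { u_fam[j] ~ dnorm(0, tau_fam) }
  for (k in 1:K) { u_gen[k] ~ dnorm(0, tau_gen) }
  for (p in 1:P) { beta[p] ~ dnorm(0, 1.0E-4) }
  sigma ~ dt(0, pow(2.5, -2), 1) T(0,)
  sigma_fam ~ dt(0, pow(2.5, -2), 1) T(0,)
  sigma_gen ~ dt(0, pow(2.5, -2), 1) T(0,)
  tau <- pow(sigma, -2)
  tau_fam <- pow(sigma_fam, -2)
  tau_gen <- pow(sigma_gen, -2)
}
"

fit_bayesian <- function(cohort, spec) {
  y <- cohort[[spec$response]]
  # standardize predictors for mixing; slopes back-transformed afterwards
  Xraw <- as.matrix(cohort[, spec$fixed_effects, drop = FALSE])
  mu_x <- colMeans(Xraw)
  sd_x <- apply(Xraw, 2, stats::sd)
  sd_x[sd_x == 0] <- 1
  X <- cbind(1, sweep(sweep(Xraw, 2, mu_x), 2, sd_x, "/"))
  fam <- as.integer(factor(cohort$family))
  gen <- as.integer(factor(paste(cohort$family, cohort$genus, sep = ":")))
  data <- list(y = y, X = X, n = length(y), P = ncol(X),
               J = max(fam), K = max(gen), fam = fam, gen = gen)
  inits <- lapply(seq_len(spec$n_chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = spec$seed * 1000L + ch)
  })
  mf <- tempfile(fileext = ".jags")
  writeLines(jags_model_string, mf)
  on.exit(unlink(mf))
  jm <- rjags::jags.model(mf, data = data, inits = inits,
                          n.chains = spec$n_chains, quiet = TRUE)
  update(jm, spec$n_burnin, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("beta", "sigma", "sigma_fam", "sigma_gen"),
                              n.iter = spec$n_iter, thin = spec$n_thin,
                              progress.bar = "none")
  M <- as.matrix(samp)
  beta_cols <- grep("^beta\\[", colnames(M))
  B <- M[, beta_cols, drop = FALSE]
  # back-transform from standardized to raw predictor scale
  slopes <- sweep(B[, -1, drop = FALSE], 2, sd_x, "/")
  intercept <- B[, 1] - slopes %*% mu_x
  Braw <- cbind(intercept, slopes)
  terms <- c("(Intercept)", spec$fixed_effects)
  tail_p <- function(v) {
    lo <- mean(v < 0)
    max(2 * min(lo, 1 - lo), 2 / length(v))
  }
  coefs <- data.frame(
    term = terms,
    estimate = colMeans(Braw),
    se = apply(Braw, 2, stats::sd),
    ci_lo = apply(Braw, 2, stats::quantile, 0.025),
    ci_hi = apply(Braw, 2, stats::quantile, 0.975),
    p = apply(Braw, 2, tail_p),
    stringsAsFactors = FALSE, row.names = NULL
  )
  varcomp <- c(family = mean(M[, "sigma_fam"]^2),
               genus = mean(M[, "sigma_gen"]^2),
               residual = mean(M[, "sigma"]^2))
  gd <- tryCatch(
    max(coda::gelman.diag(samp, multivariate = FALSE)$psrf[, 1], na.rm = TRUE),
    error = function(e) NA_real_)
  list(coefficients = coefs, varcomp = varcomp,
       convergence = list(max_psrf = gd,
                          n_eff_min = min(coda::effectiveSize(samp))),
       fit = NULL)
}

#' Fit a hierarchical efficiency model
#'
#' Fits the chosen efficiency response on the fixed covariates with nested
#' taxonomic random intercepts (family, and genus within family). REML mode
#' uses lme4 with Satterthwaite p-values; Bayesian mode uses MCMC in JAGS
#' with weakly-informative priors, reporting posterior means, 95% credible
#' intervals, a two-tailed posterior probability as `p`, and convergence
#' diagnostics (max split-Rhat, min effective size). If a taxonomic level
#' has fewer than two distinct values it is dropped with a warning.
#' Deterministic given `spec$seed`.
#'
#' @param cohort A [cohort_table()].
#' @param spec A [model_spec()].
#' @return An object of class `model_result`: list with `coefficients`
#'   (`data.frame`: term, estimate, se, ci_lo, ci_hi, p), `varcomp` (named
#'   variances: family, genus, residual), `convergence`, `spec`.
#' @export
fit_mixed_model <- function(cohort, spec) {
  stopifnot(inherits(spec, "model_spec"))
  check_model_data(cohort, spec)
  res <- if (spec$inference == "reml") {
    fit_reml(cohort, spec)
  } else {
    fit_bayesian(cohort, spec)
  }
  res$spec <- spec
  class(res) <- "model_result"
  res
}

#' Proportions of variance per random level
#'
#' Each variance component (family, genus within family, residual) divided
#' by their sum, so the proportions add to 1; the genus and family shares
#' quantify how much of an efficiency measure is explained by taxonomy.
#'
#' @param res A `model_result` from [fit_mixed_model()], or a named numeric
#'   vector of variance components.
#' @return Named numeric vector of proportions in [0, 1].
#' @examples
#' variance_proportions(c(family = 1, genus = 1, residual = 2))
#' @export
variance_proportions <- function(res) {
  vc <- if (inherits(res, "model_result")) res$varcomp else res
  if (any(vc < 0)) {
    pn_stop("variance components must be non-negative",
            "primatenet_validation_error")
  }
  vc / sum(vc)
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> %s ~ %s [%s]\n", x$spec$response,
              paste(x$spec$fixed_effects, collapse = " + "),
              x$spec$inference))
  print(x$coefficients, digits = 4)
  cat("variance components:\n")
  print(round(x$varcomp, 6))
  invisible(x)
}
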