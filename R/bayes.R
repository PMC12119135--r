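#' Prior specification for Bayesian inference
#'
#' Defaults follow the package's standard prior set: Normal priors for
#' interaction coefficients and intercepts, an optional horseshoe prior on
#' the coefficients to promote sparsity, a half-Normal prior on noise scales,
#' and an optional Wishart prior on the residual precision for correlated
#' noise (used by default in the species-metabolite model).
#'
#' The horseshoe is the regularized variant: half-Cauchy local and global
#' scales with a finite slab so that large signals are softly bounded.
#'
#' @param coeff prior family for coefficient matrices: `"normal"` or
#'   `"horseshoe"`.
#' @param coeff_scale sd of the Normal coefficient prior. Default 1.
#' @param global_scale scale of the horseshoe's global half-Cauchy. Default 1.
#' @param slab_scale slab sd of the regularized horseshoe. Default 2.
#' @param intercept_scale sd of the Normal intercept prior. Default 5.
#' @param noise_scale scale of the half-Normal prior on noise sds. Default 1.
#' @param covariance `"none"` for independent per-variable noise or
#'   `"wishart"` for a full residual covariance with a Wishart prior on the
#'   precision (identity scale, df = dim + 1).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(coeff = c("normal", "horseshoe"), coeff_scale = 1,
                       global_scale = 1, slab_scale = 2,
                       intercept_scale = 5, noise_scale = 1,
                       covariance = c("none", "wishart")) {
  coeff <- match.arg(coeff)
  covariance <- match.arg(covariance)
  for (s in c(coeff_scale, global_scale, slab_scale, intercept_scale, noise_scale))
    if (!is.finite(s) || s <= 0)
      abort("all prior scales must be strictly positive", type = "validation")
  structure(list(coeff = coeff, coeff_scale = coeff_scale,
                 global_scale = global_scale, slab_scale = slab_scale,
                 intercept_scale = intercept_scale, noise_scale = noise_scale,
                 covariance = covariance),
            class = "prior_spec")
}

#' MCMC sampler settings
#'
#' @param chains number of chains (>= 2). Default 4.
#' @param tune adaptation/burn-in iterations per chain. Default 1000.
#' @param draws retained iterations per chain. Default 1000.
#' @param thin thinning interval. Default 1.
#' @return An object of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 4, tune = 1000, draws = 1000, thin = 1) {
  if (chains < 2) abort("at least 2 chains are required", type = "validation")
  structure(list(chains = as.integer(chains), tune = as.integer(tune),
                 draws = as.integer(draws), thin = as.integer(thin)),
            class = "mcmc_control")
}

# ---- JAGS model assembly ----------------------------------------------------

# Prior block for a coefficient matrix `name` (NRxNC constants must be in the
# data list as <name>_nr / <name>_nc).
jags_coeff_prior <- function(name, priors) {
  nr <- paste0(name, "_nr"); nc <- paste0(name, "_nc")
  if (priors$coeff == "normal") {
    sprintf("
  for (i in 1:%s) { for (j in 1:%s) {
    %s[i,j] ~ dnorm(0, %.10g)
  } }", nr, nc, name, 1 / priors$coeff_scale^2)
  } else {
    # regularized horseshoe: half-Cauchy local/global scales, finite slab
    sprintf("
  hs_global_%s ~ dt(0, %.10g, 1) T(0,)
  for (i in 1:%s) { for (j in 1:%s) {
    hs_local_%s[i,j] ~ dt(0, 1, 1) T(0,)
    hs_lt2_%s[i,j] <- %.10g * pow(hs_local_%s[i,j], 2) /
      (%.10g + pow(hs_global_%s, 2) * pow(hs_local_%s[i,j], 2))
    %s[i,j] ~ dnorm(0, 1 / (pow(hs_global_%s, 2) * hs_lt2_%s[i,j]))
  } }",
      name, 1 / priors$global_scale^2, nr, nc,
      name, name, priors$slab_scale^2, name, priors$slab_scale^2, name, name,
      name, name, name)
  }
}

# Likelihood + noise block for responses y (TT x NR) against design x
# (TT x NC) with coefficient matrix `coef_name` and intercept `int_name`.
# `suffix` distinguishes the abundance and metabolite blocks of the MVAR.
jags_regression_block <- function(coef_name, int_name, y_name, x_name,
                                  suffix, priors) {
  nr <- paste0(coef_name, "_nr"); nc <- paste0(coef_name, "_nc")
  iprec <- 1 / priors$intercept_scale^2
  nprec <- 1 / priors$noise_scale^2
  mean_block <- sprintf("
  for (t in 1:TT) { for (i in 1:%s) {
    eta%s[t,i] <- %s[i] + inprod(%s[i,], %s[t,])
  } }", nr, suffix, int_name, coef_name, x_name)
  intercepts <- sprintf("
  for (i in 1:%s) { %s[i] ~ dnorm(0, %.10g) }", nr, int_name, iprec)
  if (priors$covariance == "none") {
    noise <- sprintf("
  for (i in 1:%s) {
    sigma%s[i] ~ dnorm(0, %.10g) T(0,)
    prec%s[i] <- 1 / pow(sigma%s[i], 2)
  }
  for (t in 1:TT) { for (i in 1:%s) {
    %s[t,i] ~ dnorm(eta%s[t,i], prec%s[i])
  } }", nr, suffix, nprec, suffix, suffix, nr, y_name, suffix, suffix)
  } else {
    noise <- sprintf("
  Omega%s ~ dwish(Rscale%s, %s + 1)
  Cov%s <- inverse(Omega%s)
  for (i in 1:%s) { sigma%s[i] <- sqrt(Cov%s[i,i]) }
  for (t in 1:TT) {
    %s[t,1:%s] ~ dmnorm(eta%s[t,], Omega%s)
  }", suffix, suffix, nr, suffix, suffix, nr, suffix, suffix,
       y_name, nr, suffix, suffix)
  }
  paste0(mean_block, intercepts, jags_coeff_prior(coef_name, priors), noise)
}

run_jags <- function(model_string, data, monitor, mcmc, seed) {
  seed <- check_seed(seed)
  inits <- lapply(seq_len(mcmc$chains), function(k)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed + k - 1L) %% .Machine$integer.max))
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = mcmc$chains, quiet = TRUE)
  if (mcmc$tune > 0) stats::update(jm, mcmc$tune, progress.bar = "none")
  rjags::coda.samples(jm, variable.names = monitor,
                      n.iter = mcmc$draws * mcmc$thin, thin = mcmc$thin,
                      progress.bar = "none")
}

# ---- posterior container ----------------------------------------------------

new_posterior_samples <- function(draws, model, matrices, vectors, data,
                                  loglik_fn, meta = list()) {
  pooled <- as.matrix(draws)
  ess <- tryCatch(coda::effectiveSize(draws), error = function(e) NULL)
  rhat <- tryCatch(
    coda::gelman.diag(draws, multivariate = FALSE, autoburnin = FALSE)$psrf[, 1],
    error = function(e) rep(NA_real_, ncol(pooled)))
  diagnostics <- data.frame(
    parameter = colnames(pooled),
    ess = if (is.null(ess)) NA_real_ else as.numeric(ess[colnames(pooled)]),
    rhat = as.numeric(rhat[colnames(pooled)]),
    row.names = NULL)
  warnings <- character()
  bad <- diagnostics$parameter[!is.na(diagnostics$rhat) & diagnostics$rhat > 1.05]
  if (length(bad))
    warnings <- sprintf("R-hat > 1.05 for %d parameter(s): %s",
                        length(bad), paste(utils::head(bad, 5), collapse = ", "))
  structure(list(draws = draws, model = model, matrices = matrices,
                 vectors = vectors, data = data, loglik_fn = loglik_fn,
                 meta = meta, diagnostics = diagnostics, warnings = warnings),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("<posterior_samples> %s model; %d chains x %d draws; %d parameters\n",
              x$model, coda::nchain(x$draws), coda::niter(x$draws),
              coda::nvar(x$draws)))
  cat(sprintf("  max R-hat %.3f; min ESS %.0f\n",
              suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
              suppressWarnings(min(x$diagnostics$ess, na.rm = TRUE))))
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' Pooled posterior draws of one parameter block
#'
#' Extracts all draws (chains pooled, in chain order) of a named matrix or
#' vector parameter from a `posterior_samples` object.
#'
#' @param post a `posterior_samples` object.
#' @param name parameter block name, e.g. `"A"`, `"B"`, `"intercept"`,
#'   `"sigma"`.
#' @return For a matrix block, an array `(n_draws, nrow, ncol)`; for a vector
#'   block, a matrix `(n_draws, length)`.
#' @export
posterior_draws <- function(post, name) {
  stopifnot(inherits(post, "posterior_samples"))
  pooled <- as.matrix(post$draws)
  if (name %in% names(post$matrices)) {
    dm <- post$matrices[[name]]
    idx <- outer(seq_len(dm[1]), seq_len(dm[2]),
                 function(i, j) sprintf("%s[%d,%d]", name, i, j))
    if (!all(idx %in% colnames(pooled)))
      abort(sprintf("no draws found for matrix '%s'", name), type = "lookup")
    arr <- array(pooled[, c(idx)], dim = c(nrow(pooled), dm[1], dm[2]))
    return(arr)
  }
  if (name %in% names(post$vectors)) {
    len <- post$vectors[[name]]
    cols <- if (len == 1L && name %in% colnames(pooled)) name
            else sprintf("%s[%d]", name, seq_len(len))
    if (!all(cols %in% colnames(pooled)))
      abort(sprintf("no draws found for vector '%s'", name), type = "lookup")
    return(pooled[, cols, drop = FALSE])
  }
  abort(sprintf("unknown parameter block '%s'", name), type = "lookup")
}

#' Summarize a posterior into point estimates and credible intervals
#'
#' Per-parameter posterior medians and equal-tailed credible intervals at
#' `level`, assembled into the same `fit_summary` structure the linear
#' estimators return, with the model log-likelihood evaluated at the
#' posterior-median parameters (so [information_criteria()] applies).
#'
#' @param post a `posterior_samples` object.
#' @param level credible level in (0, 1). Default 0.95.
#' @return A `fit_summary`; `estimates` holds posterior-median matrices and
#'   vectors under their block names.
#' @export
posterior_summary <- function(post, level = 0.95) {
  stopifnot(inherits(post, "posterior_samples"))
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1)
    abort("level must be a single number in (0, 1)", type = "validation")
  pooled <- as.matrix(post$draws)
  if (nrow(pooled) == 0) abort("posterior has no draws", type = "validation")
  probs <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  qs <- t(apply(pooled, 2, stats::quantile, probs = probs, names = FALSE))
  tab <- data.frame(parameter = colnames(pooled), estimate = qs[, 2],
                    lower = qs[, 1], upper = qs[, 3], row.names = NULL)
  med_of <- function(cols) stats::setNames(tab$estimate, tab$parameter)[cols]
  estimates <- list()
  for (nm in names(post$matrices)) {
    dm <- post$matrices[[nm]]
    idx <- outer(seq_len(dm[1]), seq_len(dm[2]),
                 function(i, j) sprintf("%s[%d,%d]", nm, i, j))
    estimates[[nm]] <- matrix(med_of(c(idx)), dm[1], dm[2])
  }
  for (nm in names(post$vectors)) {
    len <- post$vectors[[nm]]
    cols <- if (len == 1L && nm %in% tab$parameter) nm
            else sprintf("%s[%d]", nm, seq_len(len))
    estimates[[nm]] <- unname(med_of(cols))
  }
  ll <- if (is.function(post$loglik_fn)) post$loglik_fn(estimates) else NA_real_
  new_fit_summary(model = post$model, estimates = estimates, table = tab,
                  level = level, loglik = ll,
                  n_params = ncol(pooled),
                  n_obs = post$meta$n_obs %||% NA_integer_,
                  notes = post$meta$notes %||% character())
}
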