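mvn_loglik <- function(resid, Cov) {
  n <- ncol(resid)
  ch <- chol(Cov)
  z <- backsolve(ch, t(resid), transpose = TRUE)
  -0.5 * nrow(resid) * (n * log(2 * pi) + 2 * sum(log(diag(ch)))) -
    0.5 * sum(z^2)
}

reg_loglik_fn <- function(Y, X, coef_name, int_name, suffix, covariance) {
  force(Y); force(X)
  function(est) {
    resid <- Y - (X %*% t(est[[coef_name]]) +
                    matrix(est[[int_name]], nrow(Y), ncol(Y), byrow = TRUE))
    cov_name <- paste0("Cov", suffix)
    if (covariance == "wishart" && !is.null(est[[cov_name]]))
      mvn_loglik(resid, est[[cov_name]])
    else gaussian_loglik(resid, est[[paste0("sigma", suffix)]])
  }
}

#' Bayesian inference of a lag-1 VAR by MCMC
#'
#' Samples the joint posterior of the interaction matrix `A`, intercepts and
#' noise scales of the model `X_t = A X_{t-1} + c + eps_t`, under the priors
#' of [prior_spec()] (Normal coefficients and intercepts, half-Normal noise
#' by default; horseshoe and full-covariance options available). Sampling is
#' delegated to JAGS; chains are seeded from `seed` so runs are reproducible.
#'
#' @param data a complete [timeseries()].
#' @param priors a [prior_spec()]. Default `prior_spec()`.
#' @param mcmc an [mcmc_control()]. Default 4 chains, 1000 tune + 1000 draws.
#' @param seed integer seed (required).
#' @param relative convert each row to relative abundances before inference.
#'   Compositional data lose absolute scale, so inferred interactions are not
#'   globally identifiable; the output notes record this caveat. Default
#'   `FALSE`.
#' @return A `posterior_samples` object with blocks `A`, `intercept`,
#'   `sigma` (and `Cov` for the full-covariance model), per-parameter ESS and
#'   R-hat diagnostics, and any sampler warnings.
#' @seealso [posterior_summary()], [posterior_stability()]
#' @export
infer_var_bayes <- function(data, priors = prior_spec(),
                            mcmc = mcmc_control(), seed, relative = FALSE) {
  stopifnot(inherits(priors, "prior_spec"), inherits(mcmc, "mcmc_control"))
  check_timeseries(data, need_complete = TRUE, min_times = 3L)
  notes <- character()
  if (relative) {
    data <- to_relative_abundance(data)
    notes <- c(notes, relative_abundance_caveat)
  }
  n <- n_vars(data); T <- n_times(data)
  if (T < n + 2)
    abort(sprintf("need at least n_vars + 2 = %d timepoints", n + 2),
          type = "validation")
  Y <- data$values[-1, , drop = FALSE]
  X <- data$values[-T, , drop = FALSE]
  jd <- list(y = Y, x = X, TT = nrow(Y), A_nr = n, A_nc = n)
  if (priors$covariance == "wishart") jd$Rscale <- diag(n)
  model <- paste0("model {",
                  jags_regression_block("A", "intercept", "y", "x", "", priors),
                  "\n}\n")
  monitor <- c("A", "intercept", "sigma",
               if (priors$covariance == "wishart") "Cov")
  draws <- run_jags(model, jd, monitor, mcmc, seed)
  matrices <- c(list(A = c(n, n)),
                if (priors$covariance == "wishart") list(Cov = c(n, n)))
  new_posterior_samples(
    draws, model = "var", matrices = matrices,
    vectors = list(intercept = n, sigma = n), data = data,
    loglik_fn = reg_loglik_fn(Y, X, "A", "intercept", "", priors$covariance),
    meta = list(n_obs = nrow(Y) * n, priors = priors, notes = notes))
}

relative_abundance_caveat <- paste(
  "inference on relative abundances: the compositional transform removes",
  "absolute scale, so interaction parameters are not globally identifiable")

#' Bayesian inference of the species-metabolite MVAR by MCMC
#'
#' Fits the coupled model `X_t = A dX_{t-1} + c_x + eps_x`,
#' `S_t = B dX_{t-1} + c_s + eps_s` (with `dX_{t-1} = X_{t-1} - X_{t-2}`)
#' to a time series containing both taxon and metabolite columns. Default
#' priors are Normal on coefficients and intercepts with a Wishart prior on
#' each block's residual precision (correlated noise); see [prior_spec()].
#'
#' @inheritParams infer_var_bayes
#' @param response `"level"` (as the model is written) or `"delta"` to model
#'   the abundance change instead of its level.
#' @return A `posterior_samples` with blocks `A` (taxa x taxa), `B`
#'   (metabolites x taxa), `intercept_x`, `intercept_s`, `sigma_x`,
#'   `sigma_s` (and the covariance blocks when active).
#' @export
infer_mvar_bayes <- function(data, priors = prior_spec(covariance = "wishart"),
                             mcmc = mcmc_control(), seed, relative = FALSE,
                             response = c("level", "delta")) {
  stopifnot(inherits(priors, "prior_spec"), inherits(mcmc, "mcmc_control"))
  response <- match.arg(response)
  check_timeseries(data, need_complete = TRUE, min_times = 3L)
  tc <- taxon_cols(data); mc <- metabolite_cols(data)
  if (!length(tc) || !length(mc))
    abort("MVAR inference needs at least one taxon and one metabolite column (see `kinds`)",
          type = "validation")
  notes <- character()
  if (relative) {
    data <- to_relative_abundance(data)
    notes <- c(notes, relative_abundance_caveat)
  }
  T <- n_times(data)
  Xm <- data$values[, tc, drop = FALSE]
  Sm <- data$values[, mc, drop = FALSE]
  n <- length(tc); m <- length(mc)
  D <- Xm[2:(T - 1), , drop = FALSE] - Xm[1:(T - 2), , drop = FALSE]
  Yx <- Xm[3:T, , drop = FALSE]
  if (response == "delta") Yx <- Yx - Xm[2:(T - 1), , drop = FALSE]
  Ys <- Sm[3:T, , drop = FALSE]
  jd <- list(yx = Yx, ys = Ys, dx = D, TT = nrow(Yx),
             A_nr = n, A_nc = n, B_nr = m, B_nc = n)
  if (priors$covariance == "wishart") {
    jd$Rscale_x <- diag(n); jd$Rscale_s <- diag(m)
  }
  model <- paste0(
    "model {",
    jags_regression_block("A", "intercept_x", "yx", "dx", "_x", priors),
    jags_regression_block("B", "intercept_s", "ys", "dx", "_s", priors),
    "\n}\n")
  monitor <- c("A", "B", "intercept_x", "intercept_s", "sigma_x", "sigma_s",
               if (priors$covariance == "wishart") c("Cov_x", "Cov_s"))
  draws <- run_jags(model, jd, monitor, mcmc, seed)
  matrices <- c(list(A = c(n, n), B = c(m, n)),
                if (priors$covariance == "wishart")
                  list(Cov_x = c(n, n), Cov_s = c(m, m)))
  llx <- reg_loglik_fn(Yx, D, "A", "intercept_x", "_x", priors$covariance)
  lls <- reg_loglik_fn(Ys, D, "B", "intercept_s", "_s", priors$covariance)
  new_posterior_samples(
    draws, model = "mvar", matrices = matrices,
    vectors = list(intercept_x = n, intercept_s = m, sigma_x = n, sigma_s = m),
    data = data,
    loglik_fn = function(est) llx(est) + lls(est),
    meta = list(n_obs = nrow(Yx) * (n + m), priors = priors, notes = notes,
                response = response))
}
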