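#' Inference of generalized Lotka-Volterra parameters by gradient matching
#'
#' Estimates growth rates `mu` and the interaction matrix `M` of
#' `dx_i/dt = x_i (mu_i + sum_j M[i,j] x_j)` without repeated ODE solves:
#' the per-capita growth rate `d ln(x_i)/dt` is approximated by central
#' differences at interior timepoints and regressed on `(1, x)`, per species.
#' `method = "bayes"` places the [prior_spec()] priors on the same linearized
#' regression and samples it by MCMC. Gradient matching trades some bias
#' (from numerical differentiation) for speed; it needs densely sampled,
#' strictly positive abundances.
#'
#' @param data a complete [timeseries()] with strictly positive abundances
#'   sampled on a real-valued time grid (>= 3 timepoints).
#' @param method `"gradient_matching_linear"` (least squares, default) or
#'   `"bayes"`.
#' @param priors a [prior_spec()], used by `method = "bayes"`; the coefficient
#'   prior applies to `M` and the intercept prior to `mu`.
#' @param mcmc an [mcmc_control()], used by `method = "bayes"`.
#' @param seed integer seed, required for `method = "bayes"`.
#' @param level confidence level for the linear fit's intervals.
#' @return A `fit_summary` (linear) with `estimates$mu`, `estimates$M`, or a
#'   `posterior_samples` (bayes) with blocks `M`, `mu`, `sigma`.
#' @export
infer_glv <- function(data, method = c("gradient_matching_linear", "bayes"),
                      priors = prior_spec(), mcmc = mcmc_control(),
                      seed = NULL, level = 0.95) {
  method <- match.arg(method)
  check_timeseries(data, need_complete = TRUE, min_times = 3L)
  V <- data$values
  if (any(V <= 0)) {
    bad <- which(V <= 0, arr.ind = TRUE)[1, ]
    abort(sprintf("abundances must be strictly positive for the log-derivative step; offending cell: variable '%s' at time %g",
                  data$names[bad[2]], data$times[bad[1]]),
          type = "validation")
  }
  T <- n_times(data); n <- n_vars(data)
  interior <- 2:(T - 1)
  # central difference of log-abundance on a possibly non-uniform grid
  dt2 <- data$times[interior + 1L] - data$times[interior - 1L]
  G <- (log(V[interior + 1L, , drop = FALSE]) -
          log(V[interior - 1L, , drop = FALSE])) / dt2
  Xi <- V[interior, , drop = FALSE]

  if (method == "bayes") {
    jd <- list(y = G, x = Xi, TT = nrow(G), M_nr = n, M_nc = n)
    if (priors$covariance == "wishart") jd$Rscale <- diag(n)
    model <- paste0("model {",
                    jags_regression_block("M", "mu", "y", "x", "", priors),
                    "\n}\n")
    monitor <- c("M", "mu", "sigma",
                 if (priors$covariance == "wishart") "Cov")
    draws <- run_jags(model, jd, monitor, mcmc, seed)
    matrices <- c(list(M = c(n, n)),
                  if (priors$covariance == "wishart") list(Cov = c(n, n)))
    return(new_posterior_samples(
      draws, model = "glv", matrices = matrices,
      vectors = list(mu = n, sigma = n), data = data,
      loglik_fn = reg_loglik_fn(G, Xi, "M", "mu", "", priors$covariance),
      meta = list(n_obs = nrow(G) * n, priors = priors)))
  }

  D <- cbind(1, Xi)
  qrD <- qr(D)
  if (qrD$rank < ncol(D))
    abort("gradient-matching design is rank-deficient; add timepoints",
          type = "estimation")
  coefs <- qr.coef(qrD, G)
  resid <- G - D %*% coefs
  N <- nrow(G)
  sigma <- sqrt(colSums(resid^2) / N)
  M <- t(coefs[-1, , drop = FALSE])
  mu <- coefs[1, ]
  dimnames(M) <- list(data$names, data$names)

  dfree <- N - ncol(D)
  lower <- upper <- rep(NA_real_, n * n + n)
  if (dfree > 0) {
    DtDinv <- chol2inv(chol(crossprod(D)))
    tq <- stats::qt(1 - (1 - level) / 2, dfree)
    s2 <- colSums(resid^2) / dfree
    se_M <- t(sqrt(outer(diag(DtDinv)[-1], s2)))
    se_mu <- sqrt(diag(DtDinv)[1] * s2)
    se <- c(se_M, se_mu)
    lower <- c(M, mu) - tq * se
    upper <- c(M, mu) + tq * se
  }
  tab <- data.frame(
    parameter = c(sprintf("M[%d,%d]", rep(seq_len(n), n), rep(seq_len(n), each = n)),
                  sprintf("mu[%d]", seq_len(n))),
    estimate = c(M, mu), lower = lower, upper = upper)
  new_fit_summary(model = "glv",
                  estimates = list(mu = mu, M = M, sigma = sigma),
                  table = tab, level = level,
                  loglik = gaussian_loglik(resid, sigma),
                  n_params = n * n + n + n, n_obs = N * n)
}
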