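new_fit_summary <- function(model, estimates, table, level, loglik,
                            n_params, n_obs, notes = character()) {
  structure(list(model = model, estimates = estimates, table = table,
                 level = level, loglik = loglik, n_params = n_params,
                 n_obs = n_obs, notes = notes),
            class = "fit_summary")
}

#' @export
print.fit_summary <- function(x, ...) {
  cat(sprintf("<fit_summary> %s model; logLik = %.4g; k = %d; n = %d\n",
              x$model, x$loglik, x$n_params, x$n_obs))
  print(utils::head(x$table, 12), row.names = FALSE)
  if (nrow(x$table) > 12) cat("  ...", nrow(x$table) - 12, "more rows\n")
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}

# Gaussian log-likelihood of a multi-response linear model with per-response
# noise sd (MLE convention used for AIC/BIC).
gaussian_loglik <- function(resid, sigma) {
  sum(vapply(seq_len(ncol(resid)), function(i)
    sum(stats::dnorm(resid[, i], 0, sigma[i], log = TRUE)), numeric(1)))
}

#' Least-squares inference of a lag-1 VAR
#'
#' Regresses each variable at time t on all variables at time t-1 plus an
#' intercept, one equation per variable, by QR least squares. With
#' `penalty = "ridge"` the coefficient block (not the intercept) is shrunk by
#' an L2 penalty, solved through the augmented-rows form of the normal
#' equations; ridge fits report no confidence intervals.
#'
#' @param data a complete [timeseries()] (impute missing entries first).
#' @param penalty `"none"` (ordinary least squares) or `"ridge"`.
#' @param lambda ridge penalty (>= 0), used only with `penalty = "ridge"`.
#' @param level confidence level for OLS intervals. Default 0.95.
#' @return A `fit_summary` whose `estimates` hold `A` (coefficient matrix),
#'   `intercept` and `sigma` (residual sd per variable, MLE), with a
#'   per-parameter `table` of estimates and intervals, the Gaussian
#'   log-likelihood at the estimate, `n_params` and `n_obs`.
#' @examples
#' ts <- simulate_var(var_params(matrix(0.5), noise_sd = 0), 10, x0 = 1)
#' infer_var_linear(ts)$estimates$A
#' @export
infer_var_linear <- function(data, penalty = c("none", "ridge"), lambda = 0,
                             level = 0.95) {
  penalty <- match.arg(penalty)
  check_timeseries(data, need_complete = TRUE, min_times = 3L)
  n <- n_vars(data); T <- n_times(data)
  if (T < n + 2)
    abort(sprintf("need at least n_vars + 2 = %d timepoints, got %d", n + 2, T),
          type = "validation")
  Y <- data$values[-1, , drop = FALSE]
  X <- cbind(1, data$values[-T, , drop = FALSE])
  if (penalty == "ridge") {
    if (lambda < 0) abort("lambda must be >= 0", type = "validation")
    # augmented rows: penalize A entries only, never the intercept
    Xa <- rbind(X, cbind(0, sqrt(lambda) * diag(n)))
    Ya <- rbind(Y, matrix(0, n, n))
  } else {
    Xa <- X; Ya <- Y
  }
  qrX <- qr(Xa)
  if (qrX$rank < ncol(Xa))
    abort(paste("design matrix is rank-deficient; the system is underdetermined.",
                "Add timepoints or use penalty = 'ridge'."),
          type = "estimation")
  coefs <- qr.coef(qrX, Ya)                       # (n+1) x n, column = equation
  resid <- Y - X %*% coefs
  N <- nrow(Y)
  sigma <- sqrt(colSums(resid^2) / N)             # MLE scale
  A <- t(coefs[-1, , drop = FALSE])               # rows = response variable
  intercept <- coefs[1, ]
  dimnames(A) <- list(data$names, data$names)

  param <- c(sprintf("A[%d,%d]", rep(seq_len(n), n), rep(seq_len(n), each = n)),
             sprintf("intercept[%d]", seq_len(n)))
  est <- c(A, intercept)
  lower <- upper <- rep(NA_real_, length(est))
  if (penalty == "none") {
    XtXinv <- chol2inv(chol(crossprod(X)))
    dfree <- N - ncol(X)
    tq <- stats::qt(1 - (1 - level) / 2, dfree)
    s2 <- colSums(resid^2) / dfree
    # se of coefs[j, i] = sqrt(s2_i * XtXinv[j, j]); order matches `param`
    se_A <- t(sqrt(outer(diag(XtXinv)[-1], s2)))  # n x n, rows = response
    se_c <- sqrt(diag(XtXinv)[1] * s2)
    se <- c(se_A, se_c)
    lower <- est - tq * se
    upper <- est + tq * se
  }
  tab <- data.frame(parameter = param, estimate = est,
                    lower = lower, upper = upper)
  new_fit_summary(
    model = "var",
    estimates = list(A = A, intercept = intercept, sigma = sigma),
    table = tab, level = level,
    loglik = gaussian_loglik(resid, sigma),
    n_params = n * n + n + n,                     # A + intercept + sigma
    n_obs = N * n,
    notes = if (penalty == "ridge")
      sprintf("ridge penalty lambda = %g; intervals not reported", lambda)
    else character()
  )
}

#' Akaike and Bayesian information criteria
#'
#' `AIC = 2k - 2 lnL` and `BIC = k ln(n) - 2 lnL`, where `lnL` is the
#' log-likelihood at the point estimate, `k` the parameter count and `n` the
#' number of modeled scalar observations carried by the fit.
#'
#' @param fit a `fit_summary` (from [infer_var_linear()], [infer_glv()] or
#'   [posterior_summary()]).
#' @return A list with elements `aic` and `bic`.
#' @examples
#' f <- microdyn:::new_fit_summary("demo", list(), data.frame(), 0.95,
#'                                 loglik = -10, n_params = 3, n_obs = 100)
#' information_criteria(f)
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "fit_summary"))
  if (!is.finite(fit$loglik)) abort("fit carries no log-likelihood", type = "validation")
  if (fit$n_obs < 2) abort("n_obs must be >= 2", type = "validation")
  k <- fit$n_params
  list(aic = 2 * k - 2 * fit$loglik,
       bic = k * log(fit$n_obs) - 2 * fit$loglik)
}
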