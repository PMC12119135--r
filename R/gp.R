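gp_kernel_fun <- function(kernel) {
  switch(kernel,
    rbf = function(t1, t2, ell, s2) {
      d <- outer(t1, t2, "-")
      s2 * exp(-0.5 * (d / ell)^2)
    },
    matern32 = function(t1, t2, ell, s2) {
      d <- abs(outer(t1, t2, "-")) * sqrt(3) / ell
      s2 * (1 + d) * exp(-d)
    },
    abort(sprintf("unknown kernel '%s'", kernel), type = "validation"))
}

gp_chol <- function(K) {
  # small jitter keeps the Cholesky stable for near-singular kernels
  chol(K + diag(1e-10 + 1e-12 * mean(diag(K)), nrow(K)))
}

gp_lml <- function(t_obs, y, ell, s2, noise2, kfun) {
  K <- kfun(t_obs, t_obs, ell, s2) + diag(noise2, length(t_obs))
  L <- tryCatch(gp_chol(K), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  a <- backsolve(L, backsolve(L, y, transpose = TRUE))
  -0.5 * sum(y * a) - sum(log(diag(L))) - 0.5 * length(y) * log(2 * pi)
}

fit_one_gp <- function(t_obs, y, kernel, n_restarts, fixed) {
  kfun <- gp_kernel_fun(kernel)
  m <- mean(y)
  yc <- y - m
  span <- max(diff(range(t_obs)), .Machine$double.eps)
  vy <- max(stats::var(y), 1e-12)
  init <- c(lengthscale = fixed$lengthscale %||% (span / 5),
            signal_var = fixed$signal_var %||% vy,
            noise_var = fixed$noise_var %||% (0.05 * vy + 1e-8))
  free <- c(is.null(fixed$lengthscale), is.null(fixed$signal_var),
            is.null(fixed$noise_var))
  lml_init <- gp_lml(t_obs, yc, init[1], init[2], init[3], kfun)

  theta <- init
  lml_best <- lml_init
  if (any(free)) {
    nll <- function(lp) {
      p <- init
      p[free] <- exp(lp)
      -gp_lml(t_obs, yc, p[1], p[2], p[3], kfun)
    }
    lo <- log(c(span * 1e-3, vy * 1e-8, 1e-12))[free]
    hi <- log(c(span * 1e2, vy * 1e6, vy * 1e4 + 1))[free]
    starts <- list(log(pmin(pmax(init[free], exp(lo)), exp(hi))))
    for (r in seq_len(n_restarts)) {
      u <- stats::runif(sum(free))
      starts[[r + 1L]] <- lo + u * (hi - lo)
    }
    for (st in starts) {
      opt <- try(stats::optim(st, nll, method = "L-BFGS-B",
                              lower = lo, upper = hi), silent = TRUE)
      if (inherits(opt, "try-error")) next
      if (-opt$value > lml_best) {
        lml_best <- -opt$value
        theta <- init
        theta[free] <- exp(opt$par)
      }
    }
  }
  K <- kfun(t_obs, t_obs, theta[1], theta[2]) + diag(theta[3], length(t_obs))
  L <- gp_chol(K)
  list(times = t_obs, y = y, mean_shift = m,
       lengthscale = unname(theta[1]), signal_var = unname(theta[2]),
       noise_var = unname(theta[3]),
       lml = lml_best, lml_init = lml_init,
       chol = L, alpha = backsolve(L, backsolve(L, yc, transpose = TRUE)))
}

#' Fit Gaussian-process regressions over time
#'
#' Fits one GP per variable (independently, by default) to the observed
#' entries of a time series, maximizing the log marginal likelihood over
#' lengthscale, signal variance and noise variance with multiple seeded
#' restarts. The prior mean of each GP is the variable's observed mean.
#' Hyperparameters can be pinned via `fixed` (e.g. to evaluate a GP with
#' known kernel parameters), in which case only the free ones are optimized.
#'
#' @param data a [timeseries()]; masked entries are simply excluded from the
#'   training set. Every variable needs at least 2 observed points.
#' @param kernel `"rbf"` (squared-exponential, default) or `"matern32"`.
#' @param per_variable fit separate hyperparameters per variable (default);
#'   `FALSE` shares one hyperparameter set across variables, chosen to
#'   maximize the summed marginal likelihood.
#' @param n_restarts random optimizer restarts in addition to the default
#'   start. Default 5.
#' @param seed integer seed for the restart draws. Default 1.
#' @param fixed optional named list pinning any of `lengthscale`,
#'   `signal_var`, `noise_var`.
#' @param log1p model `log1p(values)` instead of raw values (for strictly
#'   non-negative abundances); predictions are transformed back. Default
#'   `FALSE`.
#' @return An object of class `gp_fit`.
#' @export
gp_fit <- function(data, kernel = c("rbf", "matern32"), per_variable = TRUE,
                   n_restarts = 5, seed = 1, fixed = list(), log1p = FALSE) {
  kernel <- match.arg(kernel)
  check_timeseries(data, min_times = 2L)
  set.seed(check_seed(seed))
  n_obs <- colSums(data$mask)
  if (any(n_obs < 2))
    abort(sprintf("variable '%s' has %d observed point(s); at least 2 are required",
                  data$names[which(n_obs < 2)[1]], min(n_obs)),
          type = "imputation")
  vals <- data$values
  if (log1p) vals <- log1p(vals)
  fits <- lapply(seq_len(n_vars(data)), function(v) {
    obs <- data$mask[, v]
    fit_one_gp(data$times[obs], vals[obs, v], kernel, n_restarts, fixed)
  })
  if (!per_variable && n_vars(data) > 1) {
    # refit all variables with the hyperparameters of the variable whose
    # candidate set maximizes the summed marginal likelihood
    cand <- lapply(fits, function(f)
      list(lengthscale = f$lengthscale, signal_var = f$signal_var,
           noise_var = f$noise_var))
    score <- vapply(cand, function(h) sum(vapply(seq_len(n_vars(data)),
      function(v) {
        obs <- data$mask[, v]
        gp_lml(data$times[obs], vals[obs, v] - mean(vals[obs, v]),
               h$lengthscale, h$signal_var, h$noise_var, gp_kernel_fun(kernel))
      }, numeric(1))), numeric(1))
    best <- cand[[which.max(score)]]
    fits <- lapply(seq_len(n_vars(data)), function(v) {
      obs <- data$mask[, v]
      fit_one_gp(data$times[obs], vals[obs, v], kernel, 0, best)
    })
  }
  names(fits) <- data$names
  structure(list(kernel = kernel, fits = fits, names = data$names,
                 log1p = log1p, per_variable = per_variable),
            class = "gp_fit")
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("<gp_fit> %s kernel; %d variable(s)\n", x$kernel, length(x$fits)))
  h <- t(vapply(x$fits, function(f)
    c(lengthscale = f$lengthscale, signal_var = f$signal_var,
      noise_var = f$noise_var, lml = f$lml), numeric(4)))
  print(round(h, 4))
  invisible(x)
}

#' Predict from fitted Gaussian processes
#'
#' Standard GP posterior mean and variance at arbitrary query times, with an
#' equal-tailed Gaussian band at `level`. Far from the data the mean reverts
#' to the prior mean (the training average) and the variance to the prior
#' signal variance.
#'
#' @param fit a [gp_fit()] object.
#' @param query_times numeric vector of times to predict at.
#' @param level band level in (0, 1). Default 0.95.
#' @param include_noise add the observation-noise variance to the band
#'   (predictive band for new noisy observations rather than for the latent
#'   function). Default `FALSE`.
#' @return A list of matrices `mean`, `lower`, `upper`, `sd` (query times in
#'   rows, variables in columns).
#' @export
gp_predict <- function(fit, query_times, level = 0.95, include_noise = FALSE) {
  stopifnot(inherits(fit, "gp_fit"))
  if (!length(query_times)) abort("empty query times", type = "validation")
  if (level <= 0 || level >= 1) abort("level must be in (0, 1)", type = "validation")
  kfun <- gp_kernel_fun(fit$kernel)
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- lapply(fit$fits, function(f) {
    Ks <- kfun(f$times, query_times, f$lengthscale, f$signal_var)
    mu <- drop(crossprod(Ks, f$alpha)) + f$mean_shift
    v <- backsolve(f$chol, Ks, transpose = TRUE)
    var_f <- pmax(f$signal_var - colSums(v^2), 0)
    if (include_noise) var_f <- var_f + f$noise_var
    cbind(mean = mu, sd = sqrt(var_f))
  })
  mean <- vapply(out, function(o) o[, "mean"], numeric(length(query_times)))
  sd <- vapply(out, function(o) o[, "sd"], numeric(length(query_times)))
  mean <- matrix(mean, ncol = length(fit$fits),
                 dimnames = list(NULL, fit$names))
  sd <- matrix(sd, ncol = length(fit$fits), dimnames = list(NULL, fit$names))
  lower <- mean - z * sd
  upper <- mean + z * sd
  if (fit$log1p) {
    mean <- expm1(mean); lower <- expm1(lower); upper <- expm1(upper)
  }
  list(mean = mean, lower = lower, upper = upper, sd = sd)
}

#' Fill in missing time-series entries with GP predictions
#'
#' Replaces every masked entry of `data` with the GP posterior mean at that
#' timepoint; observed entries are untouched. The returned series is
#' complete (its mask is all `TRUE`) and carries a `provenance` attribute, a
#' character matrix marking each entry `"observed"` or `"imputed"`.
#'
#' @param data a [timeseries()] with missing entries (a series with none is
#'   returned unchanged).
#' @param fit an existing [gp_fit()]; if `NULL` one is fitted with the
#'   remaining arguments.
#' @param ... passed to [gp_fit()] when `fit` is `NULL` (e.g. `kernel`,
#'   `seed`).
#' @return The completed [timeseries()].
#' @export
impute <- function(data, fit = NULL, ...) {
  check_timeseries(data, min_times = 2L)
  if (all(data$mask)) return(data)
  if (is.null(fit)) fit <- gp_fit(data, ...)
  pred <- gp_predict(fit, data$times)
  values <- data$values
  values[!data$mask] <- pred$mean[!data$mask]
  out <- timeseries(values, times = data$times, names = data$names,
                    kinds = data$kinds)
  prov <- matrix("observed", n_times(data), n_vars(data),
                 dimnames = dimnames(data$mask))
  prov[!data$mask] <- "imputed"
  attr(out, "provenance") <- prov
  out
}
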