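#' Simulate a lag-1 VAR process
#'
#' Iterates `X_t = A X_{t-1} + c + eps_t` from `x0`, with
#' `eps_t ~ N(0, noise_sd^2)` drawn from the seeded generator. With
#' `noise_sd = 0` the recursion is exact. A VAR is a statistical model, so
#' simulated "abundances" may go negative; set `clip_negative = TRUE` to
#' truncate at zero.
#'
#' @param params a [var_params()] object.
#' @param n_steps number of transitions (the result has `n_steps + 1` rows).
#' @param x0 initial state vector.
#' @param seed integer seed; required whenever `noise_sd > 0`.
#' @param clip_negative truncate states at zero after each step. Default
#'   `FALSE`.
#' @return A [timeseries()] on the index time grid `0, 1, ..., n_steps`.
#' @examples
#' p <- var_params(matrix(0.5), noise_sd = 0)
#' simulate_var(p, n_steps = 3, x0 = 1)$values
#' @export
simulate_var <- function(params, n_steps, x0, seed = NULL,
                         clip_negative = FALSE) {
  stopifnot(inherits(params, "var_params"))
  n <- nrow(params$A)
  x0 <- as.numeric(x0)
  if (length(x0) != n)
    abort("x0 length must equal the dimension of A", type = "shape")
  if (n_steps < 1) abort("n_steps must be >= 1", type = "validation")
  noisy <- any(params$noise_sd > 0)
  if (noisy) set.seed(check_seed(seed))
  X <- matrix(NA_real_, n_steps + 1L, n)
  X[1L, ] <- x0
  for (t in seq_len(n_steps)) {
    eps <- if (noisy) stats::rnorm(n, 0, params$noise_sd) else 0
    x <- drop(params$A %*% X[t, ]) + params$intercept + eps
    if (clip_negative) x <- pmax(x, 0)
    X[t + 1L, ] <- x
  }
  timeseries(X, times = 0:n_steps,
             names = colnames(params$A) %||% paste0("taxon", seq_len(n)))
}

#' Simulate the species-metabolite MVAR process
#'
#' Iterates the coupled pair of regressions on the lagged abundance change
#' `dX_{t-1} = X_{t-1} - X_{t-2}`: abundances
#' `X_t = A dX_{t-1} + c_x + eps_x` and metabolites
#' `S_t = B dX_{t-1} + c_s + eps_s`. Two initial abundance rows are needed to
#' form the first difference; metabolite rows at t = 0, 1 are set to
#' `s_init`. `response = "delta"` switches the abundance equation to model the
#' change (`X_t = X_{t-1} + A dX_{t-1} + ...`) instead of the level.
#'
#' @param params an [mvar_params()] object.
#' @param n_steps total number of transitions from row 1 (the result has
#'   `n_steps + 1` rows); must be >= 2.
#' @param x0,x1 abundance vectors at t = 0 and t = 1.
#' @param s_init metabolite vector used for t = 0 and t = 1.
#' @param seed integer seed; required when any noise sd is positive.
#' @param response `"level"` (default) models the abundance level at time t;
#'   `"delta"` models its change.
#' @return A [timeseries()] whose columns are the taxa followed by the
#'   metabolites, tagged via `kinds`.
#' @export
simulate_mvar <- function(params, n_steps, x0, x1, s_init, seed = NULL,
                          response = c("level", "delta")) {
  stopifnot(inherits(params, "mvar_params"))
  response <- match.arg(response)
  n <- nrow(params$A); m <- nrow(params$B)
  x0 <- as.numeric(x0); x1 <- as.numeric(x1); s_init <- as.numeric(s_init)
  if (length(x0) != n || length(x1) != n)
    abort("x0 and x1 must match the dimension of A", type = "shape")
  if (length(s_init) != m)
    abort("s_init must match the row count of B", type = "shape")
  if (n_steps < 2) abort("n_steps must be >= 2 (the lagged difference needs two rows)",
                         type = "validation")
  noisy <- any(params$noise_sd_x > 0) || any(params$noise_sd_s > 0)
  if (noisy) set.seed(check_seed(seed))
  X <- matrix(NA_real_, n_steps + 1L, n)
  S <- matrix(NA_real_, n_steps + 1L, m)
  X[1L, ] <- x0; X[2L, ] <- x1
  S[1L, ] <- s_init; S[2L, ] <- s_init
  for (t in 3:(n_steps + 1L)) {
    dx <- X[t - 1L, ] - X[t - 2L, ]
    ex <- if (noisy) stats::rnorm(n, 0, params$noise_sd_x) else 0
    es <- if (noisy) stats::rnorm(m, 0, params$noise_sd_s) else 0
    xt <- drop(params$A %*% dx) + params$intercept_x + ex
    if (response == "delta") xt <- X[t - 1L, ] + xt
    X[t, ] <- xt
    S[t, ] <- drop(params$B %*% dx) + params$intercept_s + es
  }
  timeseries(cbind(X, S), times = 0:n_steps,
             names = c(paste0("taxon", seq_len(n)), paste0("metabolite", seq_len(m))),
             kinds = rep(c("taxon", "metabolite"), c(n, m)))
}

ode_integrate <- function(rhs, y0, times, what) {
  sol <- try(suppressWarnings(
    deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                 method = "ode45", rtol = 1e-8, atol = 1e-10)), silent = TRUE)
  if (inherits(sol, "try-error"))
    abort(sprintf("%s integration failed near t = %g (stiff blow-up?)",
                  what, times[1]), type = "integration", time = times[1])
  bad <- !stats::complete.cases(sol)
  if (any(bad) || nrow(sol) < length(times)) {
    t_fail <- if (any(bad)) sol[which(bad)[1], 1] else sol[nrow(sol), 1]
    abort(sprintf("%s integration failed near t = %g (stiff blow-up?)",
                  what, t_fail), type = "integration", time = t_fail)
  }
  unname(sol[, -1, drop = FALSE])
}

#' Simulate generalized Lotka-Volterra dynamics
#'
#' Integrates `dx_i/dt = x_i (mu_i + sum_j M[i,j] x_j)` with an adaptive
#' Runge-Kutta scheme (rtol 1e-8, atol 1e-10) and evaluates the trajectory at
#' `times`. Optional multiplicative log-normal measurement noise is applied
#' per observation; the underlying trajectory from a non-negative start stays
#' non-negative.
#'
#' @param params a [glv_params()] object.
#' @param times strictly increasing sampling times.
#' @param x0 non-negative initial abundances.
#' @param noise_sd standard deviation (log scale) of multiplicative
#'   measurement noise; 0 disables it.
#' @param seed integer seed; required when `noise_sd > 0`.
#' @return A [timeseries()] of abundances at `times`.
#' @export
simulate_glv <- function(params, times, x0, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(params, "glv_params"))
  x0 <- as.numeric(x0)
  if (length(x0) != length(params$mu))
    abort("x0 length must match length(mu)", type = "shape")
  if (any(x0 < 0)) abort("x0 must be non-negative", type = "validation")
  if (any(diff(times) <= 0)) abort("times must be strictly increasing", type = "format")
  rhs <- function(t, x, p) {
    x <- pmax(x, 0)
    list(x * (params$mu + drop(params$M %*% x)))
  }
  X <- pmax(ode_integrate(rhs, x0, times, "gLV"), 0)
  if (noise_sd > 0) {
    set.seed(check_seed(seed))
    X <- X * exp(matrix(stats::rnorm(length(X), 0, noise_sd), nrow(X), ncol(X)))
  }
  timeseries(X, times = times, names = paste0("taxon", seq_along(x0)))
}

#' Simulate MacArthur consumer-resource dynamics
#'
#' Integrates the CR system of [cr_params()]: species grow by converting
#' linear resource uptake into biomass, resources are supplied, diluted and
#' consumed. Resource columns are tagged `kind = "metabolite"`.
#'
#' @param params a [cr_params()] object.
#' @param times strictly increasing sampling times.
#' @param x0 non-negative initial species abundances.
#' @param r0 non-negative initial resource concentrations.
#' @param noise_sd log-normal measurement noise sd; 0 disables it.
#' @param seed integer seed; required when `noise_sd > 0`.
#' @return A [timeseries()] with species then resource columns.
#' @export
simulate_cr <- function(params, times, x0, r0, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(params, "cr_params"))
  ns <- nrow(params$uptake_rate); nr <- ncol(params$uptake_rate)
  x0 <- as.numeric(x0); r0 <- as.numeric(r0)
  if (length(x0) != ns || length(r0) != nr)
    abort("x0/r0 lengths must match the uptake matrix dimensions", type = "shape")
  if (any(x0 < 0) || any(r0 < 0))
    abort("initial species and resource levels must be non-negative",
          type = "validation")
  if (any(diff(times) <= 0)) abort("times must be strictly increasing", type = "format")
  rhs <- function(t, y, p) {
    x <- pmax(y[seq_len(ns)], 0)
    R <- pmax(y[ns + seq_len(nr)], 0)
    flux <- params$uptake_rate * rep(R, each = ns)          # per-capita uptake flux
    dx <- x * (rowSums(params$growth_yield * flux) - params$death_rate)
    dR <- params$resource_supply - params$resource_dilution * R -
      colSums(flux * x)
    list(c(dx, dR))
  }
  Y <- pmax(ode_integrate(rhs, c(x0, r0), times, "CR"), 0)
  if (noise_sd > 0) {
    set.seed(check_seed(seed))
    Y <- Y * exp(matrix(stats::rnorm(length(Y), 0, noise_sd), nrow(Y), ncol(Y)))
  }
  timeseries(Y, times = times,
             names = c(paste0("taxon", seq_len(ns)), paste0("resource", seq_len(nr))),
             kinds = rep(c("taxon", "metabolite"), c(ns, nr)))
}
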