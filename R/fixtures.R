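#' Generate a random parameter set and simulated series
#'
#' Draws random parameters for one of the four model families and simulates a
#' trajectory from them, fully reproducibly from `seed`. This is both the
#' package's synthetic-data feature and the fixture generator used by the
#' test suite and acceptance workflow.
#'
#' Sampling laws (fixed, documented in the methods vignette):
#' * `var`/`mvar`: entries of `A` drawn `N(0, 0.3)`, then rescaled to spectral
#'   radius 0.8 when `stability = "stable"` (1.25 when `"unstable"`);
#'   intercepts 0; `B` entries `N(0, 0.5)`; initial states standard normal.
#'   Gaussian observation noise with sd `noise_sd` (default 1.5, the noise
#'   level of the package's reference synthetic study).
#' * `glv`: `mu ~ U(0.3, 1)`, `M` diagonal -1 with off-diagonals `N(0, 0.2)`,
#'   `x0 ~ U(0.1, 1)`, time grid step 0.1.
#' * `cr`: yields `U(0.2, 0.6)`, uptake `U(0.2, 1)`, death `U(0.05, 0.2)`,
#'   supply `U(0.5, 1.5)`, dilution 0.1; as many resources as species.
#'
#' For the ODE families `noise_sd` is multiplicative log-normal measurement
#' noise (default 0.05).
#'
#' @param model one of `"var"`, `"mvar"`, `"glv"`, `"cr"`.
#' @param n_vars number of taxa (>= 1). MVAR fixtures also get `n_vars`
#'   metabolites.
#' @param n_steps number of transitions (VAR/MVAR) or time-grid steps
#'   (gLV/CR).
#' @param seed integer seed controlling both parameter draws and simulation
#'   noise.
#' @param noise_sd observation-noise level; `NULL` selects the per-model
#'   default described above.
#' @param stability for `var`/`mvar`: `"any"` (no rescaling), `"stable"`
#'   (spectral radius of `A` forced below 1) or `"unstable"` (above 1).
#'   Ignored for the ODE families.
#' @return A list with elements `params` (the drawn parameter object) and
#'   `series` (the simulated [timeseries()]).
#' @examples
#' fx <- generate_fixture("var", n_vars = 3, n_steps = 50, seed = 1,
#'                        stability = "stable")
#' max(Mod(eigen(fx$params$A)$values)) # < 1 by construction
#' @export
generate_fixture <- function(model = c("var", "mvar", "glv", "cr"),
                             n_vars, n_steps, seed,
                             noise_sd = NULL,
                             stability = c("any", "stable", "unstable")) {
  model <- match.arg(model)
  stability <- match.arg(stability)
  if (n_vars < 1) abort("n_vars must be >= 1", type = "validation")
  seed <- check_seed(seed)
  set.seed(seed)
  noise_sd <- noise_sd %||% switch(model, var = 1.5, mvar = 1.5, 0.05)

  draw_A <- function() {
    for (try in 1:1000) {
      A <- matrix(stats::rnorm(n_vars^2, 0, 0.3), n_vars, n_vars)
      rho <- spectral_radius(A)
      if (stability == "any") return(A)
      if (rho > 0)
        return(A * switch(stability, stable = 0.8, unstable = 1.25) / rho)
    }
    abort("could not draw an interaction matrix with the requested stability in 1000 attempts",
          type = "generator")
  }

  switch(model,
    var = {
      params <- var_params(draw_A(), intercept = 0, noise_sd = noise_sd)
      series <- simulate_var(params, n_steps = n_steps,
                             x0 = stats::rnorm(n_vars),
                             seed = seed + 1L)
      list(params = params, series = series)
    },
    mvar = {
      params <- mvar_params(
        A = draw_A(),
        B = matrix(stats::rnorm(n_vars^2, 0, 0.5), n_vars, n_vars),
        noise_sd_x = noise_sd, noise_sd_s = noise_sd
      )
      x0 <- stats::rnorm(n_vars)
      series <- simulate_mvar(params, n_steps = n_steps, x0 = x0,
                              x1 = x0 + stats::rnorm(n_vars),
                              s_init = stats::rnorm(n_vars),
                              seed = seed + 1L)
      list(params = params, series = series)
    },
    glv = {
      M <- matrix(stats::rnorm(n_vars^2, 0, 0.2), n_vars, n_vars)
      diag(M) <- -1
      params <- glv_params(mu = stats::runif(n_vars, 0.3, 1), M = M)
      series <- simulate_glv(params, times = seq(0, by = 0.1, length.out = n_steps + 1L),
                             x0 = stats::runif(n_vars, 0.1, 1),
                             noise_sd = noise_sd, seed = seed + 1L)
      list(params = params, series = series)
    },
    cr = {
      params <- cr_params(
        growth_yield = matrix(stats::runif(n_vars^2, 0.2, 0.6), n_vars, n_vars),
        uptake_rate = matrix(stats::runif(n_vars^2, 0.2, 1), n_vars, n_vars),
        death_rate = stats::runif(n_vars, 0.05, 0.2),
        resource_supply = stats::runif(n_vars, 0.5, 1.5),
        resource_dilution = 0.1
      )
      series <- simulate_cr(params, times = seq(0, by = 0.1, length.out = n_steps + 1L),
                            x0 = stats::runif(n_vars, 0.1, 0.5),
                            r0 = stats::runif(n_vars, 0.5, 1),
                            noise_sd = noise_sd, seed = seed + 1L)
      list(params = params, series = series)
    }
  )
}
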