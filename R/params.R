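#' Parameters of the lag-1 vector-autoregressive (VAR) model
#'
#' The discrete-time linear model `X_t = A X_{t-1} + c + eps_t` with Gaussian
#' noise `eps_t ~ N(0, noise_sd^2)`. `A[i, j]` is the influence of variable
#' `j` at time `t-1` on variable `i` at time `t`.
#'
#' @param A square numeric coefficient matrix (n_vars x n_vars).
#' @param intercept numeric vector `c`, recycled to the dimension of `A`.
#'   Default 0.
#' @param noise_sd positive noise standard deviation, a scalar shared by all
#'   variables or one value per variable.
#' @return An object of class `var_params`.
#' @export
var_params <- function(A, intercept = 0, noise_sd = 1) {
  A <- as.matrix(A)
  if (!is_square(A)) abort("A must be a square matrix", type = "shape")
  check_finite(A, "A")
  n <- nrow(A)
  intercept <- rep_len(as.numeric(intercept), n)
  check_finite(intercept, "intercept")
  noise_sd <- as.numeric(noise_sd)
  if (!length(noise_sd) %in% c(1L, n))
    abort("noise_sd must be a scalar or length n_vars", type = "shape")
  if (any(!is.finite(noise_sd)) || any(noise_sd < 0))
    abort("noise_sd must be finite and non-negative", type = "validation")
  structure(list(A = A, intercept = intercept, noise_sd = rep_len(noise_sd, n)),
            class = "var_params")
}

#' Parameters of the species-metabolite MVAR model
#'
#' Two coupled regressions on the lagged change in abundances
#' `dX_{t-1} = X_{t-1} - X_{t-2}`:
#' abundances `X_t = A dX_{t-1} + c_x + eps_x` and metabolites
#' `S_t = B dX_{t-1} + c_s + eps_s`. `A` captures how past abundance changes
#' drive current abundances; `B` captures how they drive current metabolite
#' concentrations.
#'
#' @param A square matrix (n_taxa x n_taxa).
#' @param B matrix (n_metabolites x n_taxa).
#' @param intercept_x,intercept_s intercept vectors for the two equations.
#' @param noise_sd_x,noise_sd_s noise standard deviations (scalar or vector).
#' @return An object of class `mvar_params`.
#' @export
mvar_params <- function(A, B, intercept_x = 0, intercept_s = 0,
                        noise_sd_x = 1, noise_sd_s = 1) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!is_square(A)) abort("A must be a square matrix", type = "shape")
  if (ncol(B) != nrow(A))
    abort("B must have as many columns as A has rows (one per taxon)",
          type = "shape")
  check_finite(A, "A"); check_finite(B, "B")
  n <- nrow(A); m <- nrow(B)
  out <- list(
    A = A, B = B,
    intercept_x = rep_len(as.numeric(intercept_x), n),
    intercept_s = rep_len(as.numeric(intercept_s), m),
    noise_sd_x = rep_len(as.numeric(noise_sd_x), n),
    noise_sd_s = rep_len(as.numeric(noise_sd_s), m)
  )
  if (any(out$noise_sd_x < 0) || any(out$noise_sd_s < 0))
    abort("noise standard deviations must be non-negative", type = "validation")
  structure(out, class = "mvar_params")
}

#' Parameters of the generalized Lotka-Volterra (gLV) model
#'
#' The ODE `dx_i/dt = x_i (mu_i + sum_j M[i,j] x_j)`: `mu` holds intrinsic
#' per-capita growth rates (1/time) and `M[i, j]` the per-capita effect of
#' species `j` on species `i` (1/(abundance * time)); negative diagonal
#' entries encode self-limitation.
#'
#' @param mu numeric vector of growth rates.
#' @param M square interaction matrix matching `length(mu)`.
#' @return An object of class `glv_params`.
#' @export
glv_params <- function(mu, M) {
  M <- as.matrix(M)
  if (!is_square(M)) abort("M must be a square matrix", type = "shape")
  mu <- as.numeric(mu)
  if (length(mu) != nrow(M))
    abort("length(mu) must equal the dimension of M", type = "shape")
  check_finite(mu, "mu"); check_finite(M, "M")
  structure(list(mu = mu, M = M), class = "glv_params")
}

#' Parameters of the MacArthur consumer-resource (CR) model
#'
#' Species grow by consuming explicit resource pools with linear (mass-action)
#' uptake:
#' `dx_i/dt = x_i (sum_k yield[i,k] uptake[i,k] R_k - death_i)` and
#' `dR_k/dt = supply_k - dilution * R_k - sum_i uptake[i,k] x_i R_k`.
#'
#' @param growth_yield matrix (n_species x n_resources) converting uptake flux
#'   to growth.
#' @param uptake_rate non-negative matrix (n_species x n_resources).
#' @param death_rate non-negative per-species mortality vector.
#' @param resource_supply non-negative external supply vector (per resource).
#' @param resource_dilution non-negative scalar washout rate.
#' @return An object of class `cr_params`.
#' @export
cr_params <- function(growth_yield, uptake_rate, death_rate = 0,
                      resource_supply = 0, resource_dilution = 0) {
  growth_yield <- as.matrix(growth_yield)
  uptake_rate <- as.matrix(uptake_rate)
  if (!identical(dim(growth_yield), dim(uptake_rate)))
    abort("growth_yield and uptake_rate must have identical dimensions",
          type = "shape")
  ns <- nrow(uptake_rate); nr <- ncol(uptake_rate)
  death_rate <- rep_len(as.numeric(death_rate), ns)
  resource_supply <- rep_len(as.numeric(resource_supply), nr)
  if (any(uptake_rate < 0) || any(resource_supply < 0) ||
      any(death_rate < 0) || resource_dilution < 0)
    abort("uptake, supply, death and dilution rates must be non-negative",
          type = "validation")
  check_finite(growth_yield, "growth_yield")
  structure(list(growth_yield = growth_yield, uptake_rate = uptake_rate,
                 death_rate = death_rate, resource_supply = resource_supply,
                 resource_dilution = as.numeric(resource_dilution)),
            class = "cr_params")
}
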