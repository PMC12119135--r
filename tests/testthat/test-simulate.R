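test_that("zero-noise VAR reproduces hand-iterated recursions", {
  # geometric contraction
  ts <- simulate_var(var_params(matrix(0.5), noise_sd = 0), 3, x0 = 1)
  expect_equal(unname(ts$values[, 1]), c(1, 0.5, 0.25, 0.125))
  # fixed point of the identity map
  ts <- simulate_var(var_params(diag(2), noise_sd = 0), 5, x0 = c(2, 3))
  expect_true(all(ts$values[, 1] == 2) && all(ts$values[, 2] == 3))
  # period-2 swap
  ts <- simulate_var(var_params(matrix(c(0, 1, 1, 0), 2), noise_sd = 0),
                     3, x0 = c(1, 2))
  expect_equal(unname(ts$values),
               rbind(c(1, 2), c(2, 1), c(1, 2), c(2, 1)))
})

test_that("zero-noise VAR/MVAR satisfy their defining equations to machine precision", {
  set.seed(42)
  A <- matrix(rnorm(9, 0, 0.4), 3)
  cc <- rnorm(3)
  ts <- simulate_var(var_params(A, cc, noise_sd = 0), 20, x0 = rnorm(3))
  X <- ts$values
  resid <- X[-1, ] - t(A %*% t(X[-21, ])) - rep(cc, each = 20)
  expect_lt(max(abs(resid)), 1e-12)

  B <- matrix(rnorm(6, 0, 0.4), 2, 3)
  p <- mvar_params(A, B, intercept_x = cc, intercept_s = c(1, -1),
                   noise_sd_x = 0, noise_sd_s = 0)
  ms <- simulate_mvar(p, 15, x0 = rnorm(3), x1 = rnorm(3), s_init = c(0, 0))
  X <- ms$values[, ms$kinds == "taxon"]
  S <- ms$values[, ms$kinds == "metabolite"]
  for (t in 3:16) {
    dx <- X[t - 1, ] - X[t - 2, ]
    expect_lt(max(abs(X[t, ] - (A %*% dx + cc))), 1e-12)
    expect_lt(max(abs(S[t, ] - (B %*% dx + c(1, -1)))), 1e-12)
  }
})

test_that("MVAR edge cases behave as the equations dictate", {
  # null coupling: metabolites pinned at their intercept
  p <- mvar_params(matrix(0.5), B = matrix(0), intercept_s = 4,
                   noise_sd_x = 0, noise_sd_s = 0)
  ms <- simulate_mvar(p, 5, x0 = 1, x1 = 3, s_init = 4)
  expect_true(all(ms$values[, 2] == 4))
  # hand-iterated step: X2 = 1*(3-1), S2 = 2*(3-1)
  p <- mvar_params(matrix(1), matrix(2), noise_sd_x = 0, noise_sd_s = 0)
  ms <- simulate_mvar(p, 2, x0 = 1, x1 = 3, s_init = 0)
  expect_equal(unname(ms$values[3, ]), c(2, 4))
  # zero initial difference: everything collapses to the intercepts
  p <- mvar_params(matrix(0.7), matrix(1.2), intercept_x = 5, intercept_s = -2,
                   noise_sd_x = 0, noise_sd_s = 0)
  ms <- simulate_mvar(p, 4, x0 = 2, x1 = 2, s_init = 0)
  expect_equal(unname(ms$values[3, ]), c(5, -2))
})

test_that("seeded simulations are bit-reproducible", {
  p <- var_params(matrix(c(0.5, 0.1, -0.2, 0.6), 2), noise_sd = 1.5)
  a <- simulate_var(p, 50, x0 = c(0, 0), seed = 99)
  b <- simulate_var(p, 50, x0 = c(0, 0), seed = 99)
  expect_identical(a$values, b$values)
  fx1 <- generate_fixture("var", 3, 40, seed = 7)
  fx2 <- generate_fixture("var", 3, 40, seed = 7)
  expect_identical(fx1$params$A, fx2$params$A)
  expect_identical(fx1$series$values, fx2$series$values)
})

test_that("noiseless VAR trajectories contract or diverge with the spectral radius", {
  set.seed(3)
  for (k in 1:10) {
    A <- matrix(rnorm(9, 0, 0.3), 3)
    A_st <- A * 0.7 / microdyn:::spectral_radius(A)
    A_un <- A * 1.3 / microdyn:::spectral_radius(A)
    x0 <- rnorm(3)
    st <- simulate_var(var_params(A_st, noise_sd = 0), 200, x0)$values
    un <- simulate_var(var_params(A_un, noise_sd = 0), 200, x0)$values
    expect_lt(max(abs(st[201, ])), 1e-6)
    expect_gt(max(abs(un[201, ])), max(abs(x0)))
  }
})

test_that("gLV matches closed forms and a fine-step Euler oracle", {
  # pure exponential growth
  ts <- simulate_glv(glv_params(0.7, matrix(0)), times = seq(0, 3, 0.5), x0 = 2)
  expect_equal(unname(ts$values[, 1]), 2 * exp(0.7 * seq(0, 3, 0.5)),
               tolerance = 1e-6)
  # logistic carrying capacity mu + M x* = 0
  ts <- simulate_glv(glv_params(1, matrix(-1)), times = c(0, 25), x0 = 0.01)
  expect_equal(unname(ts$values[2, 1]), 1, tolerance = 1e-6)
  # two-species competition against brute-force Euler
  p <- glv_params(c(1, 1), matrix(c(-1, -0.5, -0.5, -1), 2))
  times <- seq(0, 5, 0.5)
  ts <- simulate_glv(p, times, x0 = c(0.2, 0.4))
  ref <- euler_oracle(function(x) x * (p$mu + drop(p$M %*% x)),
                      c(0.2, 0.4), times)
  expect_lt(max(abs(ts$values - ref) / pmax(abs(ref), 1e-6)), 1e-3)
  # nonnegativity from nonnegative starts
  expect_true(all(ts$values >= 0))
})

test_that("gLV blow-up raises an integration error carrying the failing time", {
  err <- tryCatch(
    simulate_glv(glv_params(1, matrix(1)), times = seq(0, 10, 0.1), x0 = 1),
    error = function(e) e)
  expect_s3_class(err, "microdyn_integration_error")
  expect_true(is.numeric(err$time))
})

test_that("consumer-resource dynamics behave mechanistically", {
  times <- seq(0, 10, 0.5)
  # decoupled: zero uptake and death keep species constant, resources relax
  # to the supply/dilution equilibrium
  p <- cr_params(growth_yield = matrix(0.5), uptake_rate = matrix(0),
                 death_rate = 0, resource_supply = 2, resource_dilution = 0.5)
  trelax <- seq(0, 30, 1)
  ts <- simulate_cr(p, trelax, x0 = 0.3, r0 = 0)
  expect_equal(unname(ts$values[, 1]), rep(0.3, length(trelax)), tolerance = 1e-8)
  expect_equal(unname(ts$values[length(trelax), 2]), 2 / 0.5, tolerance = 1e-3)
  expect_identical(ts$kinds, c("taxon", "metabolite"))
  # single species / single resource against the Euler oracle
  p <- cr_params(growth_yield = matrix(0.5), uptake_rate = matrix(0.8),
                 death_rate = 0.1, resource_supply = 1, resource_dilution = 0.2)
  ts <- simulate_cr(p, times, x0 = 0.2, r0 = 1)
  f <- function(y) {
    x <- y[1]; R <- y[2]
    c(x * (0.5 * 0.8 * R - 0.1), 1 - 0.2 * R - 0.8 * x * R)
  }
  ref <- euler_oracle(f, c(0.2, 1), times)
  expect_lt(max(abs(ts$values - ref) / pmax(abs(ref), 1e-6)), 1e-3)
  # sink-only resources are monotonically non-increasing
  p <- cr_params(growth_yield = matrix(0.5), uptake_rate = matrix(0.8),
                 death_rate = 0, resource_supply = 0, resource_dilution = 0)
  ts <- simulate_cr(p, times, x0 = 0.5, r0 = 1)
  expect_true(all(diff(ts$values[, 2]) <= 1e-10))
})

test_that("dimension mismatches are rejected with shape errors", {
  expect_error(simulate_var(var_params(diag(2), noise_sd = 0), 3, x0 = 1),
               class = "microdyn_shape_error")
  expect_error(mvar_params(diag(2), B = matrix(0, 1, 3)),
               class = "microdyn_shape_error")
  expect_error(var_params(matrix(c(1, Inf, 0, 1), 2)),
               class = "microdyn_validation_error")
})
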