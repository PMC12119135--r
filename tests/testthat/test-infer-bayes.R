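# MCMC sizes here are deliberately small: these checks are about posterior
# location, not tail quantiles.
quick_mcmc <- mcmc_control(chains = 2, tune = 400, draws = 400)

test_that("posterior medians recover a low-noise VAR and agree with OLS", {
  fx <- generate_fixture("var", 2, 300, seed = 31, noise_sd = 1e-3,
                         stability = "stable")
  post <- infer_var_bayes(fx$series, mcmc = quick_mcmc, seed = 131)
  s <- posterior_summary(post)
  expect_lt(max(abs(s$estimates$A - fx$params$A)), 0.02)
  # cross-check against the linear estimator
  ols <- infer_var_linear(fx$series)
  expect_lt(max(abs(s$estimates$A - unname(ols$estimates$A))), 0.02)
  # diagnostics populated for every scalar parameter, noise draws positive
  expect_identical(nrow(post$diagnostics), coda::nvar(post$draws))
  expect_true(all(is.finite(post$diagnostics$rhat)))
  expect_true(all(posterior_draws(post, "sigma") > 0))
})

test_that("with wide priors the posterior tracks the OLS solution", {
  fx <- generate_fixture("var", 2, 200, seed = 33, noise_sd = 0.5,
                         stability = "stable")
  wide <- prior_spec(coeff_scale = 100, intercept_scale = 100)
  post <- infer_var_bayes(fx$series, priors = wide, mcmc = quick_mcmc, seed = 17)
  ols <- infer_var_linear(fx$series)
  pooled <- posterior_draws(post, "A")
  for (i in 1:2) for (j in 1:2) {
    med <- median(pooled[, i, j])
    psd <- sd(pooled[, i, j])
    expect_lt(abs(med - ols$estimates$A[i, j]), 2 * psd)
  }
})

test_that("the horseshoe shrinks truly-zero interactions harder", {
  # sparse truth: only the diagonal is non-zero (6/9 entries are exact zeros)
  A <- diag(c(0.7, 0.5, 0.6))
  ts <- simulate_var(var_params(A, noise_sd = 0.5), 300, x0 = rnorm(3),
                     seed = 55)
  post <- infer_var_bayes(ts, priors = prior_spec(coeff = "horseshoe"),
                          mcmc = quick_mcmc, seed = 56)
  draws <- posterior_draws(post, "A")
  med <- apply(draws, c(2, 3), median)
  expect_lt(mean(abs(med[A == 0])), mean(abs(med[A != 0])))
})

test_that("MVAR inference recovers the metabolite coupling matrix", {
  fx <- generate_fixture("mvar", 2, 300, seed = 61, noise_sd = 0.3)
  post <- infer_mvar_bayes(fx$series, mcmc = quick_mcmc, seed = 62)
  s <- posterior_summary(post)
  expect_lt(max(abs(s$estimates$B - fx$params$B)), 0.1)
  expect_lt(max(abs(s$estimates$A - fx$params$A)), 0.1)
})

test_that("a constant metabolite yields B credible intervals covering zero", {
  fx <- generate_fixture("mvar", 2, 120, seed = 63, noise_sd = 0.5)
  v <- fx$series$values
  set.seed(65)
  # signal-free first metabolite: constant level plus measurement jitter
  v[, 3] <- 2.5 + rnorm(nrow(v), 0, 0.02)
  ts <- timeseries(v, times = fx$series$times, names = fx$series$names,
                   kinds = fx$series$kinds)
  post <- infer_mvar_bayes(ts, priors = prior_spec(), mcmc = quick_mcmc,
                           seed = 64)
  s <- posterior_summary(post, 0.95)
  brow <- s$table[s$table$parameter %in% c("B[1,1]", "B[1,2]"), ]
  expect_true(all(brow$lower <= 0 & brow$upper >= 0))
})

test_that("relabeling taxa permutes the inferred matrices consistently", {
  fx <- generate_fixture("mvar", 2, 250, seed = 71, noise_sd = 0.3)
  s1 <- posterior_summary(infer_mvar_bayes(fx$series, mcmc = quick_mcmc,
                                           seed = 72))
  perm <- c(2, 1)
  v <- fx$series$values[, c(perm, 3, 4)]
  ts <- timeseries(v, times = fx$series$times,
                   names = c(fx$series$names[perm], fx$series$names[3:4]),
                   kinds = fx$series$kinds)
  s2 <- posterior_summary(infer_mvar_bayes(ts, mcmc = quick_mcmc, seed = 72))
  # equivariance up to Monte Carlo error
  expect_lt(max(abs(s2$estimates$A - s1$estimates$A[perm, perm])), 0.06)
  expect_lt(max(abs(s2$estimates$B - s1$estimates$B[, perm])), 0.06)
})

test_that("MVAR inference demands both variable kinds and a seed is mandatory", {
  fx <- generate_fixture("var", 2, 30, seed = 9)
  expect_error(infer_mvar_bayes(fx$series, mcmc = quick_mcmc, seed = 1),
               class = "microdyn_validation_error")
  expect_error(infer_var_bayes(fx$series, mcmc = quick_mcmc, seed = NULL),
               class = "microdyn_config_error")
})
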