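test_that("a constant signal is predicted as that constant", {
  ts <- timeseries(matrix(3.2, 12, 1), times = 0:11, names = "bug")
  f <- gp_fit(ts, seed = 1)
  p <- gp_predict(f, seq(0, 11, 0.25))
  expect_lt(max(abs(p$mean - 3.2)), 1e-6)
})

test_that("a densely sampled noiseless sine is interpolated to high accuracy", {
  t <- seq(0, 10, 0.25)
  ts <- timeseries(matrix(sin(t)), times = t, names = "s")
  f <- gp_fit(ts, seed = 2)
  p <- gp_predict(f, t)
  expect_lt(max(abs(p$mean[, 1] - sin(t))), 1e-3)
  # the optimizer never returns worse hyperparameters than its start
  expect_gte(f$fits[[1]]$lml, f$fits[[1]]$lml_init)
})

test_that("predictions match the closed-form GP posterior oracle", {
  set.seed(4)
  t_train <- sort(runif(15, 0, 10))
  y <- sin(t_train) + rnorm(15, 0, 0.1)
  ell <- 1.3; s2 <- 0.8; nv <- 0.01
  ts <- timeseries(matrix(y), times = t_train, names = "v")
  f <- gp_fit(ts, fixed = list(lengthscale = ell, signal_var = s2,
                               noise_var = nv), seed = 1)
  tq <- c(0.7, 3.3, 8.1, 12)
  p <- gp_predict(f, tq)
  ref <- gp_posterior_oracle(t_train, y - mean(y), tq, ell, s2, nv)
  expect_equal(unname(p$mean[, 1]), ref$mean + mean(y), tolerance = 1e-7)
  expect_equal(unname(p$sd[, 1]^2), ref$var, tolerance = 1e-7)
})

test_that("a single training point reproduces the 1-point posterior formula", {
  ell <- 2; s2 <- 1.5; nv <- 0.1
  # a variable with fewer than 2 observed points is refused by name
  v <- cbind(c(1, 2, 3, 4), c(NA, 5, NA, NA))
  err <- tryCatch(gp_fit(timeseries(v, names = c("ok", "sparse")), seed = 1),
                  error = function(e) e)
  expect_s3_class(err, "microdyn_imputation_error")
  expect_match(conditionMessage(err), "sparse")
  tt <- c(0, 2)
  y <- c(1, 3)
  ts1 <- timeseries(matrix(y), times = tt, names = "v")
  f <- gp_fit(ts1, fixed = list(lengthscale = ell, signal_var = s2,
                                noise_var = nv), seed = 1)
  q <- 0.5
  p <- gp_predict(f, q)
  # hand-evaluated 2-point closed form (centered at mean(y) = 2)
  k <- function(a, b) s2 * exp(-0.5 * (a - b)^2 / ell^2)
  K <- matrix(c(k(0, 0) + nv, k(0, 2), k(2, 0), k(2, 2) + nv), 2)
  ks <- c(k(0, q), k(2, q))
  expect_equal(unname(p$mean[1, 1]),
               drop(ks %*% solve(K, y - 2)) + 2, tolerance = 1e-10)
  expect_equal(unname(p$sd[1, 1]^2),
               s2 - drop(ks %*% solve(K, ks)), tolerance = 1e-8)
})

test_that("far from the data the GP reverts to its prior", {
  set.seed(6)
  t <- 0:10
  y <- rnorm(11, 5, 1)
  ts <- timeseries(matrix(y), times = t, names = "v")
  f <- gp_fit(ts, fixed = list(lengthscale = 1, signal_var = 2,
                               noise_var = 0.1), seed = 1)
  p <- gp_predict(f, 1e4)
  expect_equal(unname(p$mean[1, 1]), mean(y), tolerance = 1e-6)
  expect_equal(unname(p$sd[1, 1]^2), 2, tolerance = 1e-6)
})

test_that("posterior variance never exceeds prior variance and bands nest", {
  set.seed(7)
  t <- sort(runif(20, 0, 8))
  ts <- timeseries(matrix(sin(t) + rnorm(20, 0, 0.2)), times = t, names = "v")
  f <- gp_fit(ts, seed = 3)
  tq <- seq(-5, 15, 0.2)
  p95 <- gp_predict(f, tq, level = 0.95)
  p50 <- gp_predict(f, tq, level = 0.5)
  expect_true(all(p95$sd^2 <= f$fits[[1]]$signal_var + 1e-9))
  expect_true(all(p95$lower <= p50$lower & p95$upper >= p50$upper))
})

test_that("interpolation is exact with zero noise variance", {
  t <- seq(0, 5)
  y <- c(1, 3, 2, 5, 4, 4.5)
  ts <- timeseries(matrix(y), times = t, names = "v")
  f <- gp_fit(ts, fixed = list(noise_var = 0), seed = 2)
  p <- gp_predict(f, t)
  expect_lt(max(abs(p$mean[, 1] - y)), 1e-4)
  expect_lt(max(p$upper[, 1] - p$lower[, 1]), 1e-3)
})

test_that("the GP posterior mean agrees with kernlab at fixed hyperparameters", {
  skip_if_not_installed("kernlab")
  set.seed(9)
  t <- seq(0, 10, 0.5)
  y <- sin(t) + rnorm(length(t), 0, 0.1)
  y <- y - mean(y)                     # both routes then use a zero prior mean
  ell <- 1.5; nv <- 0.01
  ts <- timeseries(matrix(y), times = t, names = "v")
  f <- gp_fit(ts, fixed = list(lengthscale = ell, signal_var = 1,
                               noise_var = nv), seed = 1)
  tq <- c(2.3, 5.05, 7.7)
  mine <- gp_predict(f, tq)$mean[, 1]
  kl <- kernlab::gausspr(matrix(t), y, kernel = "rbfdot",
                         kpar = list(sigma = 1 / (2 * ell^2)), var = nv,
                         scaled = FALSE)
  expect_equal(unname(mine), as.numeric(kernlab::predict(kl, matrix(tq))),
               tolerance = 1e-3)
})

test_that("impute fills exactly the masked entries and nothing else", {
  # no-op on complete data
  ts <- timeseries(matrix(rnorm(20), 10, 2))
  expect_identical(impute(ts, seed = 1), ts)
  # a masked point on a noiseless linear trend is recovered closely
  t <- 0:20
  y <- 2 + 0.5 * t
  ym <- y; ym[8] <- NA
  tsm <- timeseries(matrix(ym), times = t, names = "v")
  imp <- impute(tsm, seed = 2)
  expect_lt(abs(imp$values[8, 1] - y[8]) / y[8], 0.05)
  expect_identical(sum(!imp$mask), 0L)
  # observed entries bit-identical, provenance recorded
  expect_identical(imp$values[-8, 1], tsm$values[-8, 1])
  expect_identical(unname(attr(imp, "provenance")[8, 1]), "imputed")
  expect_true(all(attr(imp, "provenance")[-8, 1] == "observed"))
})
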