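# Independent oracles used across the suite. These deliberately take naive,
# textbook routes (explicit normal equations, characteristic polynomials,
# fixed-step Euler, dense solve() GP formulas) so agreement with the package
# is a genuine cross-check, not a tautology.

# Normal-equations least squares: coefficient matrix of Y ~ X (no intercept
# handling; callers add the 1-column themselves).
ols_oracle <- function(X, Y) solve(t(X) %*% X) %*% t(X) %*% Y

# Eigenvalues from the characteristic polynomial, for 2x2 and 3x3 only.
charpoly_eigen_oracle <- function(A) {
  d <- nrow(A)
  if (d == 2) {
    # lambda^2 - tr lambda + det
    polyroot(c(det(A), -sum(diag(A)), 1))
  } else if (d == 3) {
    tr <- sum(diag(A))
    m2 <- det(A[2:3, 2:3]) + det(A[c(1, 3), c(1, 3)]) + det(A[1:2, 1:2])
    polyroot(c(-det(A), m2, -tr, 1))
  } else stop("oracle only supports 2x2 and 3x3")
}

# Fixed-step explicit Euler for dx/dt = f(x).
euler_oracle <- function(f, x0, times, h = 1e-4) {
  out <- matrix(NA_real_, length(times), length(x0))
  x <- x0
  t <- times[1]
  out[1, ] <- x
  for (k in 2:length(times)) {
    while (t < times[k] - 1e-12) {
      step <- min(h, times[k] - t)
      x <- x + step * f(x)
      t <- t + step
    }
    out[k, ] <- x
  }
  out
}

# Dense closed-form GP posterior (zero prior mean), solve()-based.
gp_posterior_oracle <- function(t_train, y, t_query, ell, s2, noise2) {
  k <- function(a, b) s2 * exp(-0.5 * outer(a, b, "-")^2 / ell^2)
  Kinv <- solve(k(t_train, t_train) + diag(noise2, length(t_train)))
  Ks <- k(t_train, t_query)
  list(mean = drop(t(Ks) %*% Kinv %*% y),
       var = pmax(s2 - diag(t(Ks) %*% Kinv %*% Ks), 0))
}

# Build a posterior_samples object from hand-made draws (for summary and
# stability tests that need full control over the draws).
fake_posterior <- function(values, param_names, n_chains = 2,
                           matrices = list(), vectors = list()) {
  stopifnot(nrow(values) %% n_chains == 0)
  per <- nrow(values) / n_chains
  chains <- lapply(seq_len(n_chains), function(ch) {
    m <- values[(ch - 1) * per + seq_len(per), , drop = FALSE]
    colnames(m) <- param_names
    coda::mcmc(m)
  })
  microdyn:::new_posterior_samples(
    coda::mcmc.list(chains), model = "test",
    matrices = matrices, vectors = vectors, data = NULL, loglik_fn = NULL)
}
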