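#' Eigenvalue stability of a discrete-time interaction matrix
#'
#' Computes the full complex spectrum of a square matrix and classifies the
#' lag-1 linear recursion `x_t = A x_{t-1}` as stable when every eigenvalue
#' has modulus strictly below `threshold` (default 1): the spectral radius
#' governs whether noiseless trajectories contract or diverge.
#'
#' @param A square numeric matrix.
#' @param threshold stability threshold on the eigenvalue modulus, strict.
#'   Default 1.
#' @return A list with `eigenvalues` (complex), `spectral_radius` and
#'   `is_stable`.
#' @examples
#' stability_eigen(diag(0.5, 3))$is_stable   # TRUE
#' stability_eigen(diag(1.1, 3))$is_stable   # FALSE
#' @export
stability_eigen <- function(A, threshold = 1) {
  A <- as.matrix(A)
  if (!is_square(A)) abort("A must be a square matrix", type = "shape")
  check_finite(A, "A")
  ev <- eigen(A, only.values = TRUE)$values
  rho <- max(Mod(ev))
  list(eigenvalues = ev, spectral_radius = rho,
       is_stable = rho < threshold)
}

#' Stability analysis across posterior samples
#'
#' Classifies every posterior draw of an interaction matrix by the strict
#' eigenvalue criterion of [stability_eigen()] and reports the percentage of
#' stable draws (chains pooled), alongside an independent classification of
#' the element-wise posterior-median matrix. The two need not agree: a
#' stable median with a sub-100% stable fraction indicates residual
#' uncertainty about specific interactions.
#'
#' @param post a `posterior_samples` object (from [infer_var_bayes()] or
#'   [infer_mvar_bayes()]), or a 3-d array of matrices with dimensions
#'   `(n_draws, d, d)`.
#' @param matrix_name name of the square matrix block to analyze. Default
#'   `"A"`. Ignored when `post` is already an array.
#' @param threshold stability threshold (strict). Default 1.
#' @return An object of class `stability_report` with fields `eigenvalues`
#'   (per-draw list), `spectral_radius` (per-draw), `is_stable` (per-draw),
#'   `fraction_stable` (percent), `median_matrix`, `median_eigenvalues` and
#'   `median_matrix_stable`.
#' @export
posterior_stability <- function(post, matrix_name = "A", threshold = 1) {
  arr <- if (is.array(post) && length(dim(post)) == 3L) {
    if (dim(post)[2] != dim(post)[3])
      abort("draws must be square matrices", type = "shape")
    post
  } else {
    if (!inherits(post, "posterior_samples"))
      abort("post must be a posterior_samples object or a (draws, d, d) array",
            type = "validation")
    if (!matrix_name %in% names(post$matrices))
      abort(sprintf("no matrix block named '%s' in the posterior", matrix_name),
            type = "lookup")
    dm <- post$matrices[[matrix_name]]
    if (dm[1] != dm[2])
      abort(sprintf("matrix block '%s' is not square", matrix_name),
            type = "shape")
    posterior_draws(post, matrix_name)
  }
  n_draws <- dim(arr)[1]
  spectra <- lapply(seq_len(n_draws), function(k)
    eigen(arr[k, , ], only.values = TRUE)$values)
  rho <- vapply(spectra, function(ev) max(Mod(ev)), numeric(1))
  stable <- rho < threshold
  med <- apply(arr, c(2, 3), stats::median)
  med_eig <- stability_eigen(med, threshold)
  structure(list(
    matrix_name = if (is.array(post)) NA_character_ else matrix_name,
    threshold = threshold,
    n_draws = n_draws,
    eigenvalues = spectra,
    spectral_radius = rho,
    is_stable = stable,
    fraction_stable = 100 * mean(stable),
    median_matrix = med,
    median_eigenvalues = med_eig$eigenvalues,
    median_matrix_stable = med_eig$is_stable
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d posterior draws of %s (|eigenvalue| < %g)\n",
              x$n_draws,
              if (is.na(x$matrix_name)) "a matrix" else paste0("'", x$matrix_name, "'"),
              x$threshold))
  cat(sprintf("  %.2f%% of sampled matrices are stable\n", x$fraction_stable))
  cat(sprintf("  element-wise median matrix: %s (spectral radius %.4f)\n",
              if (x$median_matrix_stable) "stable" else "unstable",
              max(Mod(x$median_eigenvalues))))
  invisible(x)
}
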