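#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers (and the CLI) can branch on failure type.
# Every error raised by the package carries class "microdyn_error" plus a
# subclass naming the failure mode (shape, validation, format, estimation,
# integration, imputation, normalization, lookup, config, generator).
abort <- function(msg, type = "validation", ...) {
  stop(structure(
    class = c(paste0("microdyn_", type, "_error"), "microdyn_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

check_seed <- function(seed) {
  if (is.null(seed) || length(seed) != 1L || !is.finite(seed))
    abort("`seed` must be a single finite integer; stochastic operations require an explicit seed.",
          type = "config")
  as.integer(seed)
}

# Write-then-rename so interrupted runs never leave a truncated file.
atomic_write <- function(writer, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(pattern = ".microdyn-", tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    abort(sprintf("could not move temporary file onto '%s'", path), type = "format")
  invisible(path)
}

is_square <- function(m) is.matrix(m) && nrow(m) == ncol(m)

check_finite <- function(x, what) {
  if (!all(is.finite(x)))
    abort(sprintf("%s contains non-finite values", what), type = "validation")
  invisible(x)
}

spectral_radius <- function(A) max(Mod(eigen(A, only.values = TRUE)$values))
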