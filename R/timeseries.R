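#' Longitudinal multi-variable time series
#'
#' The container used throughout the package: a strictly increasing time grid
#' plus a matrix of observations, one row per timepoint and one column per
#' variable. Each column carries a name and a kind (`"taxon"` or
#' `"metabolite"`), and a logical mask marks which entries were actually
#' observed (`TRUE`) as opposed to missing (`FALSE`). Missing entries are
#' stored as `NA` in `values` and can be filled in with [impute()].
#'
#' @param values numeric matrix, timepoints in rows, variables in columns.
#'   A data frame or vector is coerced.
#' @param times numeric vector of sampling times, strictly increasing; defaults
#'   to `0, 1, ..., nrow - 1` (the index-based convention of the discrete-time
#'   VAR/MVAR models).
#' @param mask logical matrix the same shape as `values`; `TRUE` = observed.
#'   Defaults to `!is.na(values)`.
#' @param names character vector of variable names; defaults to column names
#'   or `V1, V2, ...`.
#' @param kinds character vector with one of `"taxon"`, `"metabolite"` per
#'   variable; a single value is recycled. Default `"taxon"`.
#' @return An object of class `microdyn_ts`.
#' @examples
#' ts <- timeseries(matrix(rnorm(20), 10, 2), names = c("sp1", "sp2"))
#' ts
#' @export
timeseries <- function(values, times = NULL, mask = NULL, names = NULL,
                       kinds = "taxon") {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) values <- matrix(values, ncol = 1L)
  storage.mode(values) <- "double"
  if (is.null(times)) times <- seq_len(nrow(values)) - 1
  times <- as.numeric(times)
  if (length(times) != nrow(values))
    abort("length(times) must equal nrow(values)", type = "shape")
  if (nrow(values) >= 2L && any(diff(times) <= 0))
    abort("`times` must be strictly increasing", type = "format")
  if (is.null(mask)) mask <- !is.na(values)
  if (!is.logical(mask) || !identical(dim(mask), dim(values)))
    abort("`mask` must be a logical matrix with the shape of `values`",
          type = "shape")
  if (is.null(names)) names <- colnames(values) %||% paste0("V", seq_len(ncol(values)))
  if (anyDuplicated(names))
    abort("duplicate variable names", type = "format")
  if (length(names) != ncol(values))
    abort("length(names) must equal ncol(values)", type = "shape")
  kinds <- rep_len(as.character(kinds), ncol(values))
  if (!all(kinds %in% c("taxon", "metabolite")))
    abort("kinds must be 'taxon' or 'metabolite'", type = "validation")
  values[!mask] <- NA_real_
  dimnames(values) <- list(NULL, names)
  dimnames(mask) <- list(NULL, names)
  structure(
    list(times = times, values = values, mask = mask,
         names = names, kinds = kinds),
    class = "microdyn_ts"
  )
}

is_timeseries <- function(x) inherits(x, "microdyn_ts")

n_times <- function(ts) length(ts$times)
n_vars <- function(ts) ncol(ts$values)

check_timeseries <- function(ts, need_complete = FALSE, min_times = 2L) {
  if (!is_timeseries(ts)) abort("expected a `microdyn_ts` object", type = "validation")
  if (n_times(ts) < min_times)
    abort(sprintf("at least %d timepoints are required", min_times),
          type = "validation")
  if (need_complete && !all(ts$mask))
    abort("time series has missing entries; impute them first (see `impute()`)",
          type = "validation")
  invisible(ts)
}

taxon_cols <- function(ts) which(ts$kinds == "taxon")
metabolite_cols <- function(ts) which(ts$kinds == "metabolite")

#' @export
print.microdyn_ts <- function(x, ...) {
  n_miss <- sum(!x$mask)
  cat(sprintf("<microdyn_ts> %d timepoints x %d variables (%d taxa, %d metabolites)\n",
              n_times(x), n_vars(x), sum(x$kinds == "taxon"),
              sum(x$kinds == "metabolite")))
  cat(sprintf("  time range [%g, %g]; %d missing entries\n",
              min(x$times), max(x$times), n_miss))
  if (!is.null(attr(x, "transform")))
    cat("  transform:", attr(x, "transform"), "\n")
  invisible(x)
}

#' @export
as.data.frame.microdyn_ts <- function(x, ...) {
  data.frame(time = x$times, x$values, check.names = FALSE)
}

#' @export
dim.microdyn_ts <- function(x) dim(x$values)
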