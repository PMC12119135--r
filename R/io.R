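#' Write a time series to tidy CSV (plus a JSON sidecar)
#'
#' Comma-delimited, UTF-8, header row, first column `time`, one column per
#' variable; missing entries are written as empty fields. Variable kinds
#' (taxon vs metabolite) go to a JSON sidecar rather than into magic column
#' names. Writes are atomic (write-then-rename).
#'
#' @param ts a [timeseries()].
#' @param path output CSV path.
#' @param sidecar path for the kinds sidecar; default `<path>.json`. `NA`
#'   suppresses it.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, sidecar = paste0(path, ".json")) {
  stopifnot(is_timeseries(ts))
  df <- as.data.frame(ts)
  atomic_write(function(tmp)
    utils::write.csv(df, tmp, row.names = FALSE, na = ""), path)
  if (!is.na(sidecar)) {
    meta <- list(names = ts$names, kinds = ts$kinds)
    if (!is.null(attr(ts, "transform"))) meta$transform <- attr(ts, "transform")
    atomic_write(function(tmp)
      jsonlite::write_json(meta, tmp, auto_unbox = FALSE, pretty = TRUE),
      sidecar)
  }
  invisible(path)
}

#' Read a time series from tidy CSV
#'
#' Inverse of [write_timeseries()]: expects a `time` column (strictly
#' increasing) followed by one column per variable; empty cells become
#' masked (missing) entries. Kinds are taken from the sidecar JSON when
#' present, otherwise every column is a taxon.
#'
#' @param path CSV path.
#' @param kinds_sidecar path of the JSON sidecar; default `<path>.json` if it
#'   exists.
#' @return A [timeseries()].
#' @export
read_timeseries <- function(path, kinds_sidecar = NULL) {
  if (!file.exists(path))
    abort(sprintf("file '%s' does not exist", path), type = "format")
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df))
    abort("CSV must have a 'time' column", type = "format")
  times <- as.numeric(df$time)
  if (anyNA(times) || (length(times) >= 2 && any(diff(times) <= 0)))
    abort("'time' column must be numeric and strictly increasing",
          type = "format")
  vars <- setdiff(names(df), "time")
  if (!length(vars)) abort("no variable columns found", type = "format")
  if (anyDuplicated(vars)) abort("duplicate variable names", type = "format")
  vals <- as.matrix(df[vars])
  storage.mode(vals) <- "double"
  kinds <- "taxon"
  sidecar <- kinds_sidecar %||%
    (if (file.exists(paste0(path, ".json"))) paste0(path, ".json") else NULL)
  if (!is.null(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$kinds)) {
      ord <- match(vars, meta$names %||% vars)
      if (anyNA(ord))
        abort("sidecar variable names do not match the CSV columns",
              type = "format")
      kinds <- meta$kinds[ord]
    }
  }
  timeseries(vals, times = times, names = vars, kinds = kinds)
}

#' Convert taxon columns to relative abundances
#'
#' Divides each row's taxon columns by that row's taxon total, leaving
#' metabolite columns untouched. The transform is recorded in the series'
#' `transform` attribute and is idempotent. Compositional data lose the
#' absolute scale, which limits identifiability of inferred interactions.
#'
#' @param ts a [timeseries()] with non-negative taxon values and at least one
#'   positive taxon value per row.
#' @return The normalized [timeseries()].
#' @examples
#' ts <- timeseries(matrix(c(2, 2, 1, 3), 2, 2, byrow = TRUE))
#' to_relative_abundance(ts)$values
#' @export
to_relative_abundance <- function(ts) {
  stopifnot(is_timeseries(ts))
  tc <- taxon_cols(ts)
  if (!length(tc)) abort("no taxon columns to normalize", type = "normalization")
  tx <- ts$values[, tc, drop = FALSE]
  if (any(tx < 0, na.rm = TRUE))
    abort("taxon values must be non-negative for relative-abundance conversion",
          type = "normalization")
  sums <- rowSums(tx, na.rm = TRUE)
  if (any(sums <= 0)) {
    bad <- which(sums <= 0)[1]
    abort(sprintf("all taxon values are zero at timepoint t = %g; cannot normalize",
                  ts$times[bad]), type = "normalization")
  }
  vals <- ts$values
  vals[, tc] <- tx / sums
  out <- timeseries(vals, times = ts$times, mask = ts$mask,
                    names = ts$names, kinds = ts$kinds)
  attr(out, "transform") <- "relative_abundance"
  out
}

#' Export posterior draws and summaries
#'
#' Writes the pooled draws as a long-format CSV (`chain`, `draw`,
#' `parameter`, `value`) and the [posterior_summary()] as a flat CSV.
#'
#' @param post a `posterior_samples` object.
#' @param draws_path path for the draws CSV; `NA` skips it.
#' @param summary_path path for the summary CSV; `NA` skips it.
#' @param level credible level for the summary. Default 0.95.
#' @return The summary `fit_summary`, invisibly.
#' @export
write_posterior <- function(post, draws_path = NA, summary_path = NA,
                            level = 0.95) {
  stopifnot(inherits(post, "posterior_samples"))
  if (!is.na(draws_path)) {
    long <- do.call(rbind, lapply(seq_along(post$draws), function(ch) {
      m <- as.matrix(post$draws[[ch]])
      data.frame(chain = ch, draw = rep(seq_len(nrow(m)), ncol(m)),
                 parameter = rep(colnames(m), each = nrow(m)),
                 value = as.vector(m))
    }))
    atomic_write(function(tmp)
      utils::write.csv(long, tmp, row.names = FALSE), draws_path)
  }
  summ <- posterior_summary(post, level = level)
  if (!is.na(summary_path))
    atomic_write(function(tmp)
      utils::write.csv(summ$table, tmp, row.names = FALSE), summary_path)
  invisible(summ)
}

#' Write a stability report to JSON
#'
#' @param report a `stability_report` from [posterior_stability()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_stability_report <- function(report, path) {
  stopifnot(inherits(report, "stability_report"))
  payload <- list(
    matrix = report$matrix_name,
    threshold = report$threshold,
    n_draws = report$n_draws,
    fraction_stable_percent = report$fraction_stable,
    median_matrix_stable = report$median_matrix_stable,
    median_spectral_radius = max(Mod(report$median_eigenvalues)),
    median_eigenvalues = data.frame(re = Re(report$median_eigenvalues),
                                    im = Im(report$median_eigenvalues)),
    per_draw_spectral_radius = report$spectral_radius,
    per_draw_stable = report$is_stable
  )
  atomic_write(function(tmp)
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE), path)
  invisible(path)
}
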