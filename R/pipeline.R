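pipeline_schema <- list(
  input = NA, kinds_sidecar = NA, out_dir = NA, seed = NA, model = NA,
  relative = NA, level = NA,
  impute = c("kernel", "n_restarts", "level", "log1p"),
  priors = c("coeff", "coeff_scale", "global_scale", "slab_scale",
             "intercept_scale", "noise_scale", "covariance"),
  mcmc = c("chains", "tune", "draws", "thin"),
  stability = c("threshold", "matrix")
)

#' Resolve and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list) describing one
#' impute-normalize-infer-stability run. Unknown keys are rejected, and a
#' seed must be given explicitly: no stage is allowed to fall back to a
#' silent random seed.
#'
#' Recognized keys: `input` (CSV path), `kinds_sidecar`, `out_dir`, `seed`,
#' `model` (`"var"` or `"mvar"`), `relative`, `level`, and the nested blocks
#' `impute` (kernel, n_restarts, level, log1p), `priors` (see
#' [prior_spec()]), `mcmc` (see [mcmc_control()]) and `stability`
#' (threshold, matrix).
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return A validated config list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      abort(sprintf("config file '%s' does not exist", config), type = "config")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a YAML file or a list", type = "config")
  unknown <- setdiff(names(config), names(pipeline_schema))
  if (length(unknown))
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          type = "config")
  for (blk in c("impute", "priors", "mcmc", "stability")) {
    extra <- setdiff(names(config[[blk]]), pipeline_schema[[blk]])
    if (length(extra))
      abort(sprintf("unknown key(s) in config block '%s': %s",
                    blk, paste(extra, collapse = ", ")), type = "config")
  }
  if (is.null(config$input)) abort("config must name an `input` CSV", type = "config")
  if (is.null(config$seed))
    abort("config must set an explicit `seed`; refusing to pick one silently",
          type = "config")
  config$seed <- check_seed(config$seed)
  config$model <- match.arg(config$model %||% "var", c("var", "mvar"))
  config$relative <- isTRUE(config$relative)
  config$out_dir <- config$out_dir %||% "."
  config$level <- config$level %||% 0.95
  structure(config, class = c("run_config", "list"))
}

#' Run the impute-normalize-infer-stability pipeline
#'
#' Executes the package's standard workflow on one input series: read the
#' CSV, impute missing entries with a Gaussian process, optionally convert
#' taxa to relative abundances, infer the interaction model by Bayesian
#' MCMC, summarize the posterior, and run the eigenvalue stability analysis
#' on the sampled interaction matrices. All artifacts are written under
#' `out_dir` along with a provenance record (config hash, seeds, package and
#' R versions). Any stage failure aborts with the stage name attached.
#'
#' @param config a [run_config()] (or path/list accepted by it).
#' @return Invisibly, a list with the fitted objects (`series`, `imputed`,
#'   `posterior`, `summary`, `stability`) and the written `paths`.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            type = "pipeline", stage = name)
    })
  }
  od <- config$out_dir
  dir.create(od, recursive = TRUE, showWarnings = FALSE)

  series <- stage("read", read_timeseries(config$input, config$kinds_sidecar))
  imp_cfg <- config$impute %||% list()
  imputed <- stage("impute", impute(
    series, kernel = imp_cfg$kernel %||% "rbf",
    n_restarts = imp_cfg$n_restarts %||% 5,
    log1p = isTRUE(imp_cfg$log1p), seed = config$seed))
  if (config$relative)
    imputed <- stage("normalize", to_relative_abundance(imputed))

  priors <- stage("priors", do.call(prior_spec, c(
    config$priors %||% list(),
    if (is.null(config$priors$covariance) && config$model == "mvar")
      list(covariance = "wishart"))))
  mcmc <- do.call(mcmc_control, config$mcmc %||% list())
  post <- stage("infer", switch(config$model,
    var = infer_var_bayes(imputed, priors, mcmc, seed = config$seed + 1L),
    mvar = infer_mvar_bayes(imputed, priors, mcmc, seed = config$seed + 1L)))

  paths <- list(
    imputed = file.path(od, "imputed.csv"),
    draws = file.path(od, "posterior_draws.csv"),
    summary = file.path(od, "posterior_summary.csv"),
    stability = file.path(od, "stability.json"),
    provenance = file.path(od, "provenance.json"))
  stage("write", write_timeseries(imputed, paths$imputed))
  summ <- stage("summarize", write_posterior(
    post, draws_path = paths$draws, summary_path = paths$summary,
    level = config$level))
  st_cfg <- config$stability %||% list()
  report <- stage("stability", posterior_stability(
    post, matrix_name = st_cfg$matrix %||% "A",
    threshold = st_cfg$threshold %||% 1))
  stage("stability", write_stability_report(report, paths$stability))

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  provenance <- list(
    config = unclass(config),
    config_md5 = unname(tools::md5sum(tmp)),
    seeds = list(pipeline = config$seed, impute = config$seed,
                 mcmc = config$seed + 1L),
    package_version = as.character(utils::packageVersion("microdyn")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"))
  unlink(tmp)
  atomic_write(function(p)
    jsonlite::write_json(provenance, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE), paths$provenance)

  invisible(list(series = series, imputed = imputed, posterior = post,
                 summary = summ, stability = report, paths = paths))
}
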