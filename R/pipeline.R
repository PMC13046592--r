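#' Read a fit configuration file
#'
#' YAML (or JSON) with optional `priors` and `mcmc` blocks whose fields
#' mirror the arguments of [prior_spec()] and [mcmc_config()]; missing
#' fields take the package defaults.
#'
#' @param path Config file path, or `NULL` for all defaults.
#' @return List with `priors` (a `prior_spec`) and `mcmc` (an
#'   `mcmc_config`).
#' @export
read_fit_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  priors <- do.call(prior_spec, raw$priors %||% list())
  mcmc <- do.call(mcmc_config, raw$mcmc %||% list())
  list(priors = priors, mcmc = mcmc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit frontier models on a panel file and write all artifacts
#'
#' End-to-end run: read the panel CSV, validate, transform, fit the
#' requested model(s), and write to `out_dir`: parameter draws
#' (`draws_<model>.csv`, iteration x named parameter), per-cell efficiency
#' tables (`efficiency_<model>.csv`), yearly summaries
#' (`efficiency_summary.csv`), inefficiency densities
#' (`density_<model>.csv`), a bias report (`bias_report.json`, when both
#' models run), and a reproducibility manifest (`manifest.json`).
#'
#' @param panel_file Panel CSV path (see [read_panel()]).
#' @param model `"fixed"`, `"random"`, or `"both"`.
#' @param out_dir Output directory (created if absent).
#' @param config_file Optional YAML/JSON config (see [read_fit_config()]).
#' @param n_outputs,n_raw_prices Panel dimensions.
#' @param verbose Progress printing interval for the samplers.
#' @return Invisibly, a list with the fitted `sfa_fit` objects and the
#'   efficiency tables.
#' @export
cli_fit <- function(panel_file, model = c("both", "fixed", "random"),
                    out_dir = ".", config_file = NULL,
                    n_outputs = 5L, n_raw_prices = 3L, verbose = 0L) {
  model <- match.arg(model)
  cfg <- read_fit_config(config_file)
  panel <- read_panel(panel_file, n_outputs, n_raw_prices)
  val <- validate_panel(panel)
  if (!val$pass) {
    bad <- val$issues[val$issues$severity == "error", , drop = FALSE]
    stop("panel validation failed: ",
         paste(sprintf("[%s/%s] %s", bad$hospital_id, bad$year, bad$issue),
               collapse = "; "))
  }
  mf <- model_frame(to_model_rows(panel))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  which_models <- if (model == "both") c("fixed", "random") else model
  fits <- list(); tables <- list()
  for (m in which_models) {
    message(sprintf("fitting %s-coefficient model (%d iterations)...",
                    m, cfg$mcmc$n_iter))
    fit <- if (m == "fixed")
      run_fixed_chain(mf, cfg$priors, cfg$mcmc, verbose = verbose)
    else run_random_chain(mf, cfg$priors, cfg$mcmc, verbose = verbose)
    fits[[m]] <- fit
    utils::write.csv(
      cbind(iteration = seq_along(fit$tau), as.data.frame(parameter_draws(fit))),
      file.path(out_dir, paste0("draws_", m, ".csv")), row.names = FALSE)
    tab <- efficiency_from_draws(fit$u, fit$cells)
    tables[[m]] <- tab
    utils::write.csv(tab$cells,
      file.path(out_dir, paste0("efficiency_", m, ".csv")), row.names = FALSE)
    utils::write.csv(inefficiency_density(tab$cells$u_mean),
      file.path(out_dir, paste0("density_", m, ".csv")), row.names = FALSE)
  }

  summ <- do.call(rbind, lapply(names(tables), function(m) {
    t <- tables[[m]]
    data.frame(model = m, year = c(t$yearly$year, "mean_cells", "mean_years"),
               ce_pct = c(t$yearly$ce_pct, t$overall_cell_mean,
                          t$overall_year_mean), stringsAsFactors = FALSE)
  }))
  utils::write.csv(summ, file.path(out_dir, "efficiency_summary.csv"),
                   row.names = FALSE)

  if (length(tables) == 2L) {
    br <- bias_report(tables$fixed$overall_cell_mean,
                      tables$random$overall_cell_mean,
                      mean(panel$cost))
    jsonlite::write_json(unclass(br), file.path(out_dir, "bias_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package = "hospsfa",
    version = as.character(utils::packageVersion("hospsfa")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    panel_file = normalizePath(panel_file),
    panel_md5 = unname(tools::md5sum(panel_file)),
    config_file = if (is.null(config_file)) NA else normalizePath(config_file),
    models = which_models,
    seed = cfg$mcmc$seed,
    mcmc = unclass(cfg$mcmc),
    priors = lapply(unclass(cfg$priors), function(x)
      if (is.matrix(x)) apply(x, 1L, as.numeric, simplify = FALSE) else x),
    n_hospitals = length(unique(panel$hospital_id)),
    n_cells = nrow(panel)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(fits = fits, tables = tables))
}

#' Generate a synthetic panel from the command-line layer
#'
#' Thin wrapper writing a generated panel (and its truth sidecar) to disk.
#'
#' @param out_file Panel CSV path.
#' @param truth_file Optional truth JSON path.
#' @param ... Passed to [generator_config()].
#' @return Invisibly, the `synthetic_panel`.
#' @export
cli_generate <- function(out_file, truth_file = NULL, ...) {
  sp <- generate_panel(generator_config(...))
  write_panel(sp, out_file, truth_file)
  invisible(sp)
}
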