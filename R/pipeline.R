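#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis in one object; a YAML
#' file with the same keys can be read with [read_pipeline_config()].
#'
#' @param seed Master integer seed for all randomness.
#' @param n_iter Residual-bootstrap iterations per replicate (default 1000).
#' @param bootstrap_mode `"permute"` or `"resample"` (see
#'   [residual_bootstrap()]).
#' @param censor_mode `"or"` or `"and"` (see [censor_no_growth()]).
#' @param censor_temp_tol Temperature-matching tolerance for the censoring
#'   rule, degrees C.
#' @param level Confidence level for every interval (default 0.95).
#' @param fit_control An [rn_fit_control()].
#' @return A list of class `rn_config`.
#' @export
pipeline_config <- function(seed = 1, n_iter = 1000,
                            bootstrap_mode = c("permute", "resample"),
                            censor_mode = c("or", "and"),
                            censor_temp_tol = 0.5,
                            level = 0.95,
                            fit_control = rn_fit_control()) {
  structure(list(seed = as.integer(seed), n_iter = as.integer(n_iter),
                 bootstrap_mode = match.arg(bootstrap_mode),
                 censor_mode = match.arg(censor_mode),
                 censor_temp_tol = censor_temp_tol, level = level,
                 fit_control = fit_control),
            class = "rn_config")
}

#' @rdname pipeline_config
#' @param path Path to a YAML file whose keys are the arguments of
#'   `pipeline_config()`.
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- c("seed", "n_iter", "bootstrap_mode", "censor_mode",
             "censor_temp_tol", "level")
  do.call(pipeline_config, x[intersect(names(x), known)])
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage `%s` failed: %s", stage,
                  conditionMessage(e)),
          class = "thermnorm_pipeline_error", parent = e)
  })
}

#' Run the full reaction-norm analysis end to end
#'
#' Censors no-growth records at the upper assay temperature, fits the
#' thermal reaction norm to every replicate population, runs the residual
#' bootstrap, performs the per-bootstrap trait linear models for T_opt and
#' T_max and the normal-theory model for mu_max, and summarizes treatment
#' cells. When `outdir` is given, tidy CSV result tables, per-replicate
#' fit JSON and a run manifest are written there.
#'
#' @param data A validated assay tibble (see [read_assay_table()]), or
#'   `NULL` to simulate from `scenario`.
#' @param scenario An `rn_scenario` used when `data` is `NULL`.
#' @param config An [pipeline_config()] object.
#' @param outdir Optional output directory; created if missing.
#' @return A list of class `rn_pipeline` with elements `design`, `fits`,
#'   `traits`, `boots`, `effects` (named list of `trait_effects` for
#'   `t_opt`, `t_max`, `mu_max`), `treatment_summary`, `censor_log`,
#'   `truth` (when simulated) and `manifest`.
#' @export
run_full_pipeline <- function(data = NULL, scenario = NULL,
                              config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "rn_config"))
  input_desc <- "user data"
  truth <- NULL
  if (is.null(data)) {
    if (is.null(scenario)) {
      abort("provide `data` or a `scenario` to simulate from.",
            class = "thermnorm_invalid_input")
    }
    sim <- pipeline_stage("simulate",
                          generate_dataset(scenario, seed = config$seed))
    data <- sim$data
    truth <- sim$truth
    input_desc <- "simulated scenario"
  }
  data <- pipeline_stage("validate", as_assay_data(data))
  n_records_in <- nrow(data)

  data <- pipeline_stage("censor",
                         censor_no_growth(data, mode = config$censor_mode,
                                          temp_tol = config$censor_temp_tol))
  censor_log <- attr(data, "censor_log")
  message(sprintf("censor: %d of %d records flagged", sum(data$censored),
                  n_records_in))

  units <- assay_units(data)
  design <- pipeline_stage("design", {
    d <- trait_design(data)
    d[match(names(units), d$replicate_id), ]
  })

  fits <- vector("list", length(units))
  for (i in seq_along(units)) {
    id <- names(units)[i]
    fits[[i]] <- pipeline_stage(paste0("fit[", id, "]"),
                                fit_reaction_norm(units[[i]],
                                                  control = config$fit_control))
  }
  names(fits) <- names(units)
  message(sprintf("fit: %d replicates fitted", length(fits)))

  traits <- dplyr::bind_rows(lapply(fits, thermal_traits))
  traits$replicate_id <- names(units)
  traits <- traits[, c("replicate_id", "t_opt", "t_max", "mu_max",
                       "mu_max_temp")]

  boots <- vector("list", length(units))
  for (i in seq_along(units)) {
    id <- names(units)[i]
    boots[[i]] <- pipeline_stage(paste0("bootstrap[", id, "]"),
      residual_bootstrap(fits[[i]], n_iter = config$n_iter,
                         seed = config$seed, mode = config$bootstrap_mode,
                         control = config$fit_control,
                         replicate_id = id, unit_index = i))
  }
  n_boot_failed <- sum(vapply(boots, function(b) b$n_failed, integer(1)))
  message(sprintf("bootstrap: %d iterations x %d replicates, %d failed refits",
                  config$n_iter, length(units), n_boot_failed))

  effects <- list(
    t_opt = pipeline_stage("infer[t_opt]",
      bootstrap_trait_inference(boots, design, "t_opt",
                                level = config$level)),
    t_max = pipeline_stage("infer[t_max]",
      bootstrap_trait_inference(boots, design, "t_max",
                                level = config$level)),
    mu_max = pipeline_stage("infer[mu_max]",
      mu_max_inference(design, traits$mu_max, level = config$level))
  )
  treatment_summary <- pipeline_stage("summarize",
    summarize_traits_by_treatment(design, traits, boots,
                                  level = config$level))

  manifest <- list(
    input = input_desc,
    package_version = as.character(utils::packageVersion("thermnorm")),
    seed = config$seed, n_iter = config$n_iter,
    bootstrap_mode = config$bootstrap_mode,
    censor_mode = config$censor_mode, level = config$level,
    n_units = length(units),
    n_records_in = n_records_in,
    n_records_censored = sum(data$censored),
    n_records_fitted = n_records_in - sum(data$censored),
    n_bootstrap_failed = n_boot_failed,
    outputs = character()
  )

  out <- structure(list(data = data, design = design, fits = fits,
                        traits = traits, boots = boots, effects = effects,
                        treatment_summary = treatment_summary,
                        censor_log = censor_log, truth = truth,
                        manifest = manifest),
                   class = "rn_pipeline")
  if (!is.null(outdir)) {
    out$manifest$outputs <- write_pipeline_results(out, outdir)
    message(sprintf("report: %d files written to %s",
                    length(out$manifest$outputs), outdir))
  }
  out
}

coefficients_table <- function(effects) {
  dplyr::bind_rows(lapply(effects, function(e) {
    tb <- e$coefficients
    tb$trait <- e$trait_name
    tb[, c("trait", "term", "estimate", "ci_lo", "ci_hi", "significant",
           "interpretable")]
  }))
}

write_pipeline_results <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    coefficients = file.path(outdir, "trait_coefficients.csv"),
    treatment_means = file.path(outdir, "treatment_means.csv"),
    traits = file.path(outdir, "replicate_traits.csv"),
    draws = file.path(outdir, "bootstrap_draws.csv"),
    fits = file.path(outdir, "replicate_fits.json"),
    manifest = file.path(outdir, "manifest.json")
  )
  readr::write_csv(coefficients_table(result$effects), paths["coefficients"])
  readr::write_csv(result$treatment_summary, paths["treatment_means"])
  readr::write_csv(result$traits, paths["traits"])
  draws <- dplyr::bind_rows(lapply(result$boots, function(b) {
    d <- b$draws
    d$replicate_id <- b$replicate_id
    d[, c("replicate_id", "iteration", "z", "w", "a", "b", "t_opt", "t_max")]
  }))
  readr::write_csv(draws, paths["draws"])
  fits_json <- lapply(result$fits, function(f) {
    list(params = unclass(f$params),
         log_likelihood = f$log_likelihood, n_obs = f$n_obs,
         converged = f$converged,
         start_points_tried = f$start_points_tried,
         fitted_values = f$fitted_values, residuals = f$residuals)
  })
  jsonlite::write_json(fits_json, paths["fits"], auto_unbox = TRUE,
                       digits = NA)
  manifest <- result$manifest
  manifest$outputs <- as.list(paths)
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA)
  paths
}

#' @export
print.rn_pipeline <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "Reaction-norm pipeline run (%s)\n  %d units, %d records (%d censored), %d bootstrap iterations (%s), seed %d\n",
    m$input, m$n_units, m$n_records_in, m$n_records_censored, m$n_iter,
    m$bootstrap_mode, m$seed))
  cat(sprintf("  adjusted R^2: T_opt %.2f, T_max %.2f, mu_max %.2f\n",
              x$effects$t_opt$adjusted_r2, x$effects$t_max$adjusted_r2,
              x$effects$mu_max$adjusted_r2))
  invisible(x)
}

#' Relative fitness as a quotient of exponential growth rates
#'
#' @param rate_selected Growth rate of the selected (e.g. warm-adapted)
#'   population, per day.
#' @param rate_control Growth rate of the reference population, per day;
#'   must be positive — when the reference shows no growth the quotient is
#'   undefined.
#' @return `rate_selected / rate_control`.
#' @export
compute_relative_fitness <- function(rate_selected, rate_control) {
  if (!is.numeric(rate_selected) || !is.numeric(rate_control)) {
    abort("rates must be numeric.", class = "thermnorm_invalid_input")
  }
  if (any(rate_control <= 0)) {
    abort("relative fitness is undefined when the reference rate is not positive.",
          class = "thermnorm_undefined_fitness")
  }
  rate_selected / rate_control
}
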