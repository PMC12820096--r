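#' Pipeline configuration
#'
#' One configuration object drives the full analysis: simulate (or read)
#' the trial dataset, apply design missingness and dropout, impute,
#' bootstrap the cost/QALY regression, summarise, and optionally run the
#' budget-impact calculator. All randomness flows from the single
#' \code{seed}; stage seeds are derived from it deterministically.
#'
#' @param sim A [sim_config()], or \code{NULL} when reading data from
#'   \code{input_csv}.
#' @param input_csv Optional path to a long-format trial CSV.
#' @param perspective \code{"healthcare"} or \code{"societal"}.
#' @param horizon Analysis horizon in years (default: last visit year).
#' @param m,max_iterations,method Imputation settings (see
#'   [imputation_spec()]).
#' @param B Bootstrap replicates per imputed dataset.
#' @param wtp_grid Willingness-to-pay grid for the CEAC.
#' @param exclude Cost categories zeroed out before analysis.
#' @param mammogram_unit_cost Optional mammogram re-costing.
#' @param run_bia Whether to run the budget-impact calculator.
#' @param bia A [bia_inputs()] (default placeholders).
#' @param seed Master seed.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(sim = sim_config(), input_csv = NULL,
                            perspective = c("healthcare", "societal"),
                            horizon = NULL, m = 25, max_iterations = 20,
                            method = "pmm", B = 5000,
                            wtp_grid = default_wtp_grid(),
                            exclude = character(0),
                            mammogram_unit_cost = NULL,
                            run_bia = TRUE, bia = bia_inputs(),
                            seed = 1L) {
  perspective <- match.arg(perspective)
  structure(list(sim = sim, input_csv = input_csv, perspective = perspective,
                 horizon = horizon, m = m, max_iterations = max_iterations,
                 method = method, B = B, wtp_grid = wtp_grid,
                 exclude = exclude, mammogram_unit_cost = mammogram_unit_cost,
                 run_bia = run_bia, bia = bia, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys mirror the [pipeline_config()] arguments; a
#' \code{sim:} block is passed to [sim_config()] and a \code{bia:} block to
#' [bia_inputs()].
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, raw$sim)
  if (!is.null(raw$bia)) raw$bia <- do.call(bia_inputs, raw$bia)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest, cost assembly, imputation, bootstrapped
#' estimation and (optionally) the budget-impact calculation, logging
#' per-stage row counts and timing to \code{stderr}. Any stage failure
#' aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage logging.
#' @return A report bundle: list with the datasets, imputation diagnostics,
#'   \code{ce_draws}, \code{ce_result}, optional \code{bia_result}, and a
#'   provenance block (seed, configuration hash, package version).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_stage <- function(stage, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("[stage:%s] %s", stage, conditionMessage(e)), call. = FALSE)
    })
    if (!quiet) {
      message(sprintf("stage %-12s %6.2fs %s", stage,
                      as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      if (is.data.frame(res)) sprintf("(%d rows)", nrow(res)) else ""))
    }
    res
  }
  seed <- config$seed
  data <- log_stage("data", {
    if (!is.null(config$input_csv)) {
      read_trial_csv(config$input_csv,
                     require_societal = config$perspective == "societal")
    } else {
      cfg <- config$sim
      cfg$seed <- seed
      d <- generate_trial(cfg)
      d <- apply_design_missingness(d)
      apply_dropout(d, cfg)
    }
  })
  vars <- if (config$perspective == "healthcare") {
    setdiff(imputable_variables(), cost_col(SOCIETAL_CATEGORIES))
  } else NULL
  ispec <- imputation_spec(m = config$m, max_iterations = config$max_iterations,
                           method = config$method, variables = vars,
                           seed = seed + 1L)
  imp <- log_stage("impute", impute(data, ispec))
  diag <- diagnostics(imp, data)
  draws <- log_stage("bootstrap", bootstrap_cea(
    imp, B = config$B, seed = seed + 2L,
    perspective = config$perspective, horizon = config$horizon,
    mammogram_unit_cost = config$mammogram_unit_cost,
    exclude = config$exclude))
  result <- summary(draws, lambda_grid = config$wtp_grid)
  bia_res <- if (isTRUE(config$run_bia)) log_stage("bia", bia_run(config$bia))
  provenance <- list(
    seed = seed,
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("ceasurv")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  structure(list(data = data, imputation = imp, diagnostics = diag,
                 draws = draws, result = result, bia = bia_res,
                 config = config, provenance = provenance),
            class = "cea_bundle")
}

#' Write / read the long-format trial CSV
#'
#' One row per patient-timepoint with the documented column dictionary
#' (see [generate_trial()]). Reading validates the schema: unknown columns,
#' negative costs (with offending row indices) and inconsistent arms within
#' a patient are rejected; missing societal columns are accepted with a
#' warning when \code{require_societal = FALSE}.
#'
#' @param data A \code{trial_data}.
#' @param path CSV path.
#' @export
write_trial_csv <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_csv
#' @param require_societal Require the nine societal cost columns.
#' @export
read_trial_csv <- function(path, require_societal = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 na.strings = c("NA", ""),
                 colClasses = c(eq5d_profile = "character"))
  required <- setdiff(trial_cols(), cost_col(SOCIETAL_CATEGORIES))
  soc_cols <- cost_col(SOCIETAL_CATEGORIES)
  missing_req <- setdiff(required, names(df))
  if (length(missing_req)) {
    abort_config(sprintf("missing required column(s): %s",
                         paste(missing_req, collapse = ", ")))
  }
  unknown <- setdiff(names(df), trial_cols())
  if (length(unknown)) {
    abort_config(sprintf("unknown column(s): %s", paste(unknown, collapse = ", ")))
  }
  missing_soc <- setdiff(soc_cols, names(df))
  if (length(missing_soc)) {
    if (require_societal) {
      abort_config(sprintf("societal perspective requires column(s): %s",
                           paste(missing_soc, collapse = ", ")))
    }
    warning(sprintf("societal column(s) absent, healthcare perspective only: %s",
                    paste(missing_soc, collapse = ", ")), call. = FALSE)
    for (cc in missing_soc) df[[cc]] <- NA_real_
  }
  for (cc in cost_col(ALL_CATEGORIES)) {
    if (!is.numeric(df[[cc]])) {
      abort_config(sprintf("non-numeric costs in column %s", cc))
    }
    bad <- which(!is.na(df[[cc]]) & df[[cc]] < 0)
    if (length(bad)) {
      abort_config(sprintf("negative cost in column %s at row(s): %s", cc,
                           paste(head(bad, 10), collapse = ", ")))
    }
  }
  arms_per_patient <- tapply(df$arm, df$patient_id, function(a) length(unique(a)))
  if (any(arms_per_patient > 1)) {
    abort_config(sprintf("arm varies within patient(s): %s",
                         paste(head(names(arms_per_patient)[arms_per_patient > 1], 10),
                               collapse = ", ")))
  }
  df$scheduled <- as.logical(df$scheduled)
  df$requested <- as.logical(df$requested)
  df$hes_observed <- as.logical(df$hes_observed)
  df <- df[, trial_cols()]
  as_trial_data(df, patients = rebuild_patients(df))
}

#' Write a report bundle to disk
#'
#' Emits the trial data and pooled draws as CSV, the CEAC as CSV, the
#' summary, diagnostics and (if run) budget impact as JSON, and a
#' \code{manifest.json} carrying the provenance block (seed, configuration
#' hash, package version) that every other file is keyed to.
#'
#' @param bundle A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cea_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    trial_data = file.path(dir, "trial_data.csv"),
    draws = file.path(dir, "ce_draws.csv"),
    ceac = file.path(dir, "ceac.csv"),
    result = file.path(dir, "ce_result.json"),
    diagnostics = file.path(dir, "imputation_diagnostics.json"),
    manifest = file.path(dir, "manifest.json")
  )
  write_trial_csv(bundle$data, paths["trial_data"])
  write.csv(as.data.frame(bundle$draws), paths["draws"], row.names = FALSE)
  write.csv(bundle$result$ceac, paths["ceac"], row.names = FALSE)
  res <- bundle$result
  res_json <- list(
    provenance = bundle$provenance,
    delta_cost = res$delta_cost, delta_cost_ci = res$delta_cost_ci,
    delta_qaly = res$delta_qaly, delta_qaly_ci = res$delta_qaly_ci,
    p_cost_saving = res$p_cost_saving, p_qaly_loss = res$p_qaly_loss,
    inmb = res$inmb, quadrants = as.list(res$quadrants),
    n_draws = res$n_draws
  )
  jsonlite::write_json(res_json, paths["result"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(list(provenance = bundle$provenance,
                            summary = bundle$diagnostics$summary,
                            trivially_valid = bundle$diagnostics$trivially_valid),
                       paths["diagnostics"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(bundle$bia)) {
    paths["bia"] <- file.path(dir, "bia_result.json")
    b <- bundle$bia
    jsonlite::write_json(list(provenance = bundle$provenance,
                              per_year = b$per_year,
                              cumulative_savings_y3 = b$cumulative_savings_y3,
                              cumulative_savings = b$cumulative_savings,
                              cumulative_mammograms_saved = b$cumulative_mammograms_saved,
                              population_patient_years = b$population_patient_years,
                              saving_patient_years = b$saving_patient_years,
                              population_unique = b$population_unique,
                              saving_unique = b$saving_unique),
                         paths["bia"], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  manifest <- c(bundle$provenance,
                list(files = as.list(setdiff(unname(paths),
                                             paths["manifest"]))))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
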