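#' Budget-impact analysis inputs
#'
#' Parameters of the deterministic cohort calculator projecting the
#' national mammographic-surveillance population and the savings from
#' reduced-frequency surveillance. Patients enter at diagnosis, receive
#' annual surveillance in years 1--3 post-diagnosis, and -- under the
#' reduced-frequency policy -- 2-yearly (conservation surgery, 0.5
#' mammograms/year) or 3-yearly (mastectomy, 1/3 per year) surveillance from
#' year 4 until exiting after the 5-year reduced-surveillance window (year
#' 8 post-diagnosis). Each cohort is thinned annually by
#' survival x (1 - attrition). No discounting is applied.
#'
#' The shipped default population figures are synthetic placeholders for
#' England-scale magnitudes, editable via [read_bia_inputs()]; they are not
#' national registry values.
#'
#' @param horizon_years Projection horizon (default 6, calendar years
#'   2024--2029).
#' @param start_year First calendar year.
#' @param new_diagnoses Annual new diagnoses entering surveillance (scalar
#'   or length \code{horizon_years}).
#' @param initial_population Prevalent population at the start of year 1 by
#'   years since diagnosis (length \code{window_years}); default a steady
#'   state of the new-diagnosis inflow under the thinning rate.
#' @param survival Annual survival probability.
#' @param attrition Annual probability of leaving surveillance for other
#'   reasons.
#' @param p_conservation Fraction with breast-conserving surgery (0.8).
#' @param unit_cost Mammogram unit cost (GBP).
#' @param savings_start_year Years since diagnosis at which reduced
#'   surveillance (and savings) begins (default 4).
#' @param window_years Total years in surveillance (default 8: three annual
#'   years then the 5-year reduced window).
#' @param reduced_rates Mammograms per year under reduced surveillance, by
#'   surgery type.
#' @return A \code{bia_inputs} list.
#' @export
bia_inputs <- function(horizon_years = 6, start_year = 2024,
                       new_diagnoses = 50000,
                       initial_population = NULL,
                       survival = 0.95, attrition = 0.05,
                       p_conservation = 0.8, unit_cost = 115.25,
                       savings_start_year = 4, window_years = 8,
                       reduced_rates = c(conservation = 0.5,
                                         mastectomy = 1 / 3)) {
  if (horizon_years < 1) abort_config("horizon must be >= 1 year")
  stopifnot_prob(survival, "survival")
  stopifnot_prob(attrition, "attrition")
  stopifnot_prob(p_conservation, "p_conservation")
  if (unit_cost < 0) abort_config("unit cost must be >= 0")
  if (savings_start_year < 1 || savings_start_year > window_years) {
    abort_config("savings_start_year must lie within the surveillance window")
  }
  thin <- survival * (1 - attrition)
  if (is.null(initial_population)) {
    initial_population <- mean(new_diagnoses) * thin^(seq_len(window_years) - 1)
  }
  if (length(initial_population) != window_years) {
    abort_config("initial_population must have one entry per window year")
  }
  if (any(initial_population < 0) || any(new_diagnoses < 0)) {
    abort_config("populations must be >= 0")
  }
  structure(list(
    horizon_years = as.integer(horizon_years), start_year = as.integer(start_year),
    new_diagnoses = rep_len(new_diagnoses, horizon_years),
    initial_population = initial_population,
    survival = survival, attrition = attrition,
    p_conservation = p_conservation, unit_cost = unit_cost,
    savings_start_year = as.integer(savings_start_year),
    window_years = as.integer(window_years),
    reduced_rates = reduced_rates
  ), class = "bia_inputs")
}

#' Read budget-impact inputs from a key-value CSV
#'
#' CSV columns \code{parameter}, \code{value}; vector parameters use
#' \code{parameter_1}, \code{parameter_2}, ... naming.
#' @param path CSV path.
#' @return A [bia_inputs()] list.
#' @export
read_bia_inputs <- function(path) {
  kv <- read.csv(path, stringsAsFactors = FALSE)
  get1 <- function(name, default) {
    hit <- kv$value[kv$parameter == name]
    if (length(hit)) as.numeric(hit[1]) else default
  }
  bia_inputs(
    horizon_years = get1("horizon_years", 6),
    start_year = get1("start_year", 2024),
    new_diagnoses = get1("new_diagnoses", 50000),
    survival = get1("survival", 0.95),
    attrition = get1("attrition", 0.05),
    p_conservation = get1("p_conservation", 0.8),
    unit_cost = get1("unit_cost", 115.25),
    savings_start_year = get1("savings_start_year", 4),
    window_years = get1("window_years", 8)
  )
}

#' Project the surveillance population
#'
#' Advances the cohort state one calendar year at a time: each cohort ages
#' by one year since diagnosis, thinned by survival x (1 - attrition);
#' cohorts exit after completing the surveillance window; a new-diagnosis
#' cohort enters each subsequent year. Fractional expected persons are
#' carried throughout (expectation-based model, no rounding).
#'
#' @param inputs A [bia_inputs()].
#' @return Data frame: one row per calendar year x years-since-diagnosis,
#'   with columns \code{year}, \code{years_since_diagnosis}, \code{n},
#'   \code{saving_phase}.
#' @export
project_population <- function(inputs) {
  if (!inherits(inputs, "bia_inputs")) abort_config("inputs must be bia_inputs")
  thin <- inputs$survival * (1 - inputs$attrition)
  state <- inputs$initial_population  # indexed by years since diagnosis
  rows <- vector("list", inputs$horizon_years)
  for (y in seq_len(inputs$horizon_years)) {
    if (y > 1) {
      state <- c(inputs$new_diagnoses[y], head(state, -1) * thin)
    }
    if (any(state < 0)) abort_config("negative population; malformed inputs")
    rows[[y]] <- data.frame(
      year = inputs$start_year + y - 1L,
      years_since_diagnosis = seq_len(inputs$window_years),
      n = state,
      saving_phase = seq_len(inputs$window_years) >= inputs$savings_start_year
    )
  }
  do.call(rbind, rows)
}

#' Annual NHS savings from reduced-frequency surveillance
#'
#' For each calendar year, savings = sum over surgery types of the saving-
#' phase population x mammograms avoided per patient-year x unit cost.
#' Mammograms avoided per patient-year are 1 - 0.5 = 0.5 (conservation,
#' 2-yearly) and 1 - 1/3 = 2/3 (mastectomy, 3-yearly). Years 1--3 since
#' diagnosis contribute nothing (annual surveillance under both policies).
#'
#' @param cohort_table Output of [project_population()].
#' @param inputs The [bia_inputs()] used.
#' @return Data frame with columns \code{year}, \code{saving_population},
#'   \code{mammograms_saved}, \code{savings}.
#' @export
annual_savings <- function(cohort_table, inputs) {
  if (is.null(inputs$unit_cost)) abort_config("missing unit cost")
  ms <- mammograms_saved(cohort_table, inputs)
  ms$savings <- ms$mammograms_saved * inputs$unit_cost
  ms
}

#' Mammograms avoided per year
#'
#' Independent of the unit cost; see [annual_savings()] for the avoided-
#' rate arithmetic.
#' @inheritParams annual_savings
#' @return Data frame with columns \code{year}, \code{saving_population},
#'   \code{mammograms_saved}.
#' @export
mammograms_saved <- function(cohort_table, inputs) {
  avoided_per_py <- inputs$p_conservation * (1 - inputs$reduced_rates[["conservation"]]) +
    (1 - inputs$p_conservation) * (1 - inputs$reduced_rates[["mastectomy"]])
  sp <- tapply(cohort_table$n[cohort_table$saving_phase],
               cohort_table$year[cohort_table$saving_phase], sum)
  years <- sort(unique(cohort_table$year))
  n_saving <- as.numeric(sp[as.character(years)])
  n_saving[is.na(n_saving)] <- 0
  data.frame(year = years, saving_population = n_saving,
             mammograms_saved = n_saving * avoided_per_py)
}

#' Run the full budget-impact calculation
#'
#' @param inputs A [bia_inputs()].
#' @return A \code{bia_result}: per-year table (population, saving-phase
#'   population, mammograms saved, savings), cumulative savings at year 3
#'   and at the horizon, cumulative mammograms saved, and both population
#'   tallies (patient-years and unique patients ever in / ever saving).
#' @export
bia_run <- function(inputs = bia_inputs()) {
  ct <- project_population(inputs)
  sv <- annual_savings(ct, inputs)
  tot <- tapply(ct$n, ct$year, sum)
  per_year <- data.frame(
    year = sv$year,
    total_population = as.numeric(tot[as.character(sv$year)]),
    saving_population = sv$saving_population,
    mammograms_saved = sv$mammograms_saved,
    savings = sv$savings
  )
  thin <- inputs$survival * (1 - inputs$attrition)
  # unique patients: everyone present in year 1 plus later entrants; unique
  # contributors: entrants into the saving phase within the horizon
  uniq_total <- sum(inputs$initial_population) +
    sum(inputs$new_diagnoses[-1])
  h <- inputs$horizon_years
  s <- inputs$savings_start_year
  # per-cohort: size when the cohort first appears in the saving phase
  # within the horizon (initial cohorts at years-since-diagnosis a, then
  # each year's entrant cohort at a = 1)
  saving_entry <- function(n0, first_year, a) {
    y_star <- if (a >= s) first_year else first_year + (s - a)
    if (y_star > h || n0 <= 0) return(0)
    n0 * thin^(y_star - first_year)
  }
  new_savers <- vapply(seq_len(inputs$window_years), function(a) {
    saving_entry(inputs$initial_population[a], 1L, a)
  }, numeric(1))
  if (h > 1) {
    new_savers <- c(new_savers, vapply(2:h, function(e) {
      saving_entry(inputs$new_diagnoses[e], e, 1L)
    }, numeric(1)))
  }
  structure(list(
    per_year = per_year,
    cumulative_savings_y3 = sum(per_year$savings[seq_len(min(3, h))]),
    cumulative_savings = sum(per_year$savings),
    cumulative_mammograms_saved = sum(per_year$mammograms_saved),
    population_patient_years = sum(per_year$total_population),
    saving_patient_years = sum(per_year$saving_population),
    population_unique = uniq_total,
    saving_unique = sum(new_savers),
    inputs = inputs
  ), class = "bia_result")
}

#' @export
print.bia_result <- function(x, ...) {
  py <- x$per_year
  py[-1] <- lapply(py[-1], round)
  print(py)
  cat(sprintf("Cumulative savings (year 3): GBP %s\n",
              format(round(x$cumulative_savings_y3), big.mark = ",")))
  cat(sprintf("Cumulative savings (horizon): GBP %s\n",
              format(round(x$cumulative_savings), big.mark = ",")))
  cat(sprintf("Cumulative mammograms saved: %s\n",
              format(round(x$cumulative_mammograms_saved), big.mark = ",")))
  invisible(x)
}

#' One-way deterministic sensitivity analysis
#'
#' Recomputes cumulative savings with each parameter set to its low and
#' high bound, everything else fixed, producing a tornado table sorted by
#' output range. Parameters the model does not use yield zero range and are
#' flagged inactive.
#'
#' @param inputs A [bia_inputs()].
#' @param parameter_ranges Data frame with columns \code{parameter},
#'   \code{low}, \code{high}.
#' @return Tornado data frame sorted by decreasing output range, with
#'   columns \code{parameter}, \code{low}, \code{high},
#'   \code{savings_low}, \code{savings_high}, \code{range}, \code{inactive}.
#' @export
one_way_dsa <- function(inputs, parameter_ranges) {
  need <- c("parameter", "low", "high")
  if (!all(need %in% names(parameter_ranges))) {
    abort_config("parameter_ranges needs columns parameter, low, high")
  }
  base <- bia_run(inputs)$cumulative_savings
  scalar_fields <- c("new_diagnoses", "survival", "attrition",
                     "p_conservation", "unit_cost", "initial_population_scale")
  eval_at <- function(param, value) {
    mod <- inputs
    if (param == "initial_population_scale") {
      mod$initial_population <- mod$initial_population * value
    } else if (param %in% names(mod)) {
      mod[[param]] <- if (param == "new_diagnoses") {
        rep_len(value, mod$horizon_years)
      } else value
    } else {
      return(base)  # unknown to the model: no effect
    }
    bia_run(mod)$cumulative_savings
  }
  rows <- lapply(seq_len(nrow(parameter_ranges)), function(i) {
    p <- parameter_ranges$parameter[i]
    lo <- eval_at(p, parameter_ranges$low[i])
    hi <- eval_at(p, parameter_ranges$high[i])
    data.frame(parameter = p, low = parameter_ranges$low[i],
               high = parameter_ranges$high[i],
               savings_low = lo, savings_high = hi,
               range = abs(hi - lo),
               inactive = !(p %in% scalar_fields) || abs(hi - lo) < 1e-9,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$range), , drop = FALSE]
}

#' Mammogram unit-cost scenarios
#'
#' Savings rescale linearly in the unit cost; mammogram counts are
#' unchanged.
#'
#' @param inputs A [bia_inputs()].
#' @param unit_cost_list Unit costs (>= 0) to evaluate.
#' @return Data frame: \code{unit_cost}, \code{cumulative_savings},
#'   \code{cumulative_mammograms_saved}.
#' @export
scenario_unit_cost <- function(inputs, unit_cost_list) {
  if (any(unit_cost_list < 0)) abort_config("unit costs must be >= 0")
  rows <- lapply(unit_cost_list, function(uc) {
    mod <- inputs
    mod$unit_cost <- uc
    r <- bia_run(mod)
    data.frame(unit_cost = uc, cumulative_savings = r$cumulative_savings,
               cumulative_mammograms_saved = r$cumulative_mammograms_saved)
  })
  do.call(rbind, rows)
}
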