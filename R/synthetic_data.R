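#' Simulation configuration for a two-arm surveillance trial
#'
#' Defines the data-generating process for a synthetic two-arm trial of
#' annual versus less frequent mammographic surveillance: stratified
#' patients, visit timepoints 4..8 (nominal years 1..5 from randomisation,
#' with the randomisation mammogram at timepoint 3), right-skewed
#' zero-inflated costs per category, EQ-5D utilities with a ceiling mass at
#' 1 and small downward drift, exponential survival, design-driven
#' questionnaire availability in the less-frequent arm and declining
#' questionnaire return over time.
#'
#' Cost categories are parameterised by their 5-visit-window total mean and
#' SD in the annual arm, a per-category arm difference, and a per-visit
#' probability of zero spend; positive spends are lognormal with a
#' patient-level multiplicative random effect. When
#' \code{true_effects$delta_cost} is set, the four non-mammogram healthcare
#' category differences are shifted equally so that the implied total
#' healthcare cost difference (including the schedule-driven expected
#' mammogram difference) equals the target. The utility arm difference is
#' set so the implied QALY difference over the horizon equals
#' \code{true_effects$delta_qaly}.
#'
#' @param n_per_arm Patients per arm.
#' @param timepoints Visit indices (default \code{4:8}; use \code{4:9} for
#'   the extended 6-year follow-up). Nominal years from randomisation are
#'   \code{timepoints - 3}.
#' @param strata_probs Named list of named probability vectors for
#'   age band, disease type, surgery type (conservation probability 0.8 by
#'   default), hormone therapy and ER status.
#' @param cost_models Data frame with columns \code{category},
#'   \code{mean_total}, \code{sd_total}, \code{diff} (less-frequent minus
#'   annual), \code{p_zero}; one row per non-mammogram category.
#' @param utility_means Annual-arm mean EQ-5D index per visit position.
#' @param utility_ceiling Probability mass at full health (index 1).
#' @param utility_kappa Beta concentration for the sub-ceiling component,
#'   supported on (-0.594, 1).
#' @param utility_sd_patient SD of the patient-level shift on the beta mean.
#' @param cost_sd_patient SD (log scale) of the patient-level cost effect.
#' @param true_effects List with \code{delta_cost} (GBP) and
#'   \code{delta_qaly} (years); \code{NULL} entries leave the per-category /
#'   per-visit parameters as given.
#' @param death_hazard Per-year death hazard (may be length 2, one per arm).
#' @param recurrence_hazard Per-year probability of recurrence onset.
#' @param dropout Per-visit questionnaire non-return probability.
#' @param request_prob Per-visit probability that a less-frequent-arm
#'   patient requests an unscheduled mammogram at a non-scheduled visit.
#' @param hes_final_missing Fraction of final-visit hospital-record costs
#'   missing (later recruits with incomplete records).
#' @param mammogram_unit_cost GBP per mammogram.
#' @param value_set Value-set table used to quantise generated utilities to
#'   EQ-5D-5L profiles (default [synthetic_value_set()]).
#' @param seed Integer RNG seed.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_per_arm = 2500,
                       timepoints = 4:8,
                       strata_probs = list(
                         age_band = c("53-55" = 0.08, "56-75" = 0.83, "76+" = 0.09),
                         disease_type = c(invasive = 0.87, DCIS = 0.13),
                         surgery = c(conservation = 0.8, mastectomy = 0.2),
                         hormone_therapy = c(yes = 0.7, no = 0.3),
                         er_status = c(positive = 0.85, negative = 0.15)
                       ),
                       cost_models = default_cost_models(),
                       utility_means = c(0.784, 0.779, 0.768, 0.760, 0.739, 0.728),
                       utility_ceiling = 0.20,
                       utility_kappa = 5,
                       utility_sd_patient = 0.08,
                       cost_sd_patient = 0.5,
                       true_effects = list(delta_cost = -544, delta_qaly = -0.02),
                       death_hazard = 0.0113,
                       recurrence_hazard = 0.01,
                       dropout = c(0.10, 0.20, 0.30, 0.40, 0.50, 0.55),
                       request_prob = c(0.0667, 0.01, 0, 0.01, 0.02, 0.01),
                       hes_final_missing = 0.3,
                       mammogram_unit_cost = 115.25,
                       value_set = NULL,
                       seed = 20250101L) {
  if (length(n_per_arm) != 1 || is.na(n_per_arm) || n_per_arm < 0) {
    abort_config("n_per_arm must be a single non-negative number")
  }
  if (is.unsorted(timepoints, strictly = TRUE)) {
    abort_config("timepoint years must be strictly increasing")
  }
  for (nm in names(strata_probs)) {
    p <- strata_probs[[nm]]
    stopifnot_prob(p, sprintf("strata_probs$%s", nm))
    if (abs(sum(p) - 1) > 1e-8) {
      abort_config(sprintf("strata_probs$%s must sum to 1", nm))
    }
  }
  cost_models <- validate_cost_models(cost_models)
  nt <- length(timepoints)
  if (length(utility_means) < nt) {
    abort_config("utility_means must cover every timepoint")
  }
  stopifnot_prob(utility_ceiling, "utility_ceiling")
  stopifnot_prob(dropout, "dropout probabilities")
  stopifnot_prob(request_prob, "request probabilities")
  stopifnot_prob(hes_final_missing, "hes_final_missing")
  if (any(death_hazard < 0) || recurrence_hazard < 0) {
    abort_config("hazards must be >= 0")
  }
  if (length(dropout) < nt || length(request_prob) < nt) {
    abort_config("dropout and request_prob must cover every timepoint")
  }
  cfg <- list(
    n_per_arm = as.integer(n_per_arm), timepoints = as.integer(timepoints),
    years = as.numeric(timepoints - 3L), strata_probs = strata_probs,
    cost_models = cost_models, utility_means = utility_means[seq_len(nt)],
    utility_ceiling = utility_ceiling, utility_kappa = utility_kappa,
    utility_sd_patient = utility_sd_patient, cost_sd_patient = cost_sd_patient,
    true_effects = true_effects,
    death_hazard = rep_len(death_hazard, 2L),
    recurrence_hazard = recurrence_hazard,
    dropout = dropout[seq_len(nt)], request_prob = request_prob[seq_len(nt)],
    hes_final_missing = hes_final_missing,
    mammogram_unit_cost = mammogram_unit_cost,
    value_set = value_set, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Default per-category cost model
#'
#' Annual-arm 5-visit-window total mean and SD per category, arm difference
#' (less-frequent minus annual) and per-visit zero-spend probability.
#' Categories whose reference median is zero carry large zero inflation.
#' @return Data frame, one row per non-mammogram cost category.
#' @export
default_cost_models <- function() {
  data.frame(
    category = setdiff(ALL_CATEGORIES, "mammogram"),
    mean_total = c(960, 43, 3579, 2864, 23, 372, 214, 219, 47, 634, 570, 2347, 150),
    sd_total   = c(1431, 205, 8058, 2976, 113, 2237, 1402, 370, 133, 2641, 2819, 7608, 1507),
    diff       = c(41, -6, -26, -234, -3, -139, -42, -31, -3, -135, -86, -499, -63),
    p_zero     = c(0.25, 0.85, 0.35, 0.10, 0.85, 0.90, 0.85, 0.30, 0.50, 0.85, 0.90, 0.80, 0.92),
    stringsAsFactors = FALSE
  )
}

validate_cost_models <- function(cm) {
  need <- c("category", "mean_total", "sd_total", "diff", "p_zero")
  if (!all(need %in% names(cm))) {
    abort_config(sprintf("cost_models needs columns: %s", paste(need, collapse = ", ")))
  }
  if (!setequal(cm$category, setdiff(ALL_CATEGORIES, "mammogram"))) {
    abort_config("cost_models must contain exactly the 13 non-mammogram categories")
  }
  if (any(cm$mean_total < 0) || any(cm$sd_total <= 0)) {
    abort_config("malformed cost distribution parameters")
  }
  stopifnot_prob(cm$p_zero, "cost_models$p_zero")
  if (any(cm$mean_total + cm$diff < 0)) {
    abort_config("less-frequent arm category mean would be negative")
  }
  cm[match(setdiff(ALL_CATEGORIES, "mammogram"), cm$category), , drop = FALSE]
}

# Deterministic mammogram schedule. The randomisation-time mammogram sits at
# timepoint 3, so under the stated rules the less-frequent arm is scheduled
# 2-yearly after conservation surgery (timepoints 5, 7, 9) and 3-yearly
# after mastectomy (timepoints 6, 9); the annual arm at every timepoint.
visit_scheduled <- function(arm, surgery, timepoint) {
  n <- max(length(arm), length(surgery), length(timepoint))
  arm <- rep_len(arm, n)
  surgery <- rep_len(surgery, n)
  timepoint <- rep_len(timepoint, n)
  ifelse(arm == "annual", TRUE,
    ifelse(surgery == "conservation", (timepoint - 3L) %% 2L == 0L,
      ifelse(surgery == "mastectomy", (timepoint - 3L) %% 3L == 0L, NA)))
}

# Arm-difference adjustment so that the implied totals match true_effects.
# Works on the zero-death approximation (see configured_effects).
resolve_effects <- function(cfg) {
  cm <- cfg$cost_models
  nt <- length(cfg$timepoints)
  te <- cfg$true_effects
  if (!is.null(te$delta_cost)) {
    hc <- cm$category %in% setdiff(HEALTHCARE_CATEGORIES, "mammogram")
    sched_diff <- expected_mammograms("less_frequent", cfg) -
      expected_mammograms("annual", cfg)
    implied <- sum(cm$diff[hc]) * nt / 5 + sched_diff * cfg$mammogram_unit_cost
    cm$diff[hc] <- cm$diff[hc] + (te$delta_cost - implied) / sum(hc) * 5 / nt
  }
  u_offset <- if (is.null(te$delta_qaly)) 0 else te$delta_qaly / max(cfg$years)
  list(cost_models = cm, utility_offset = u_offset)
}

# Expected mammograms per patient over the window (no deaths), averaging
# over the surgery mix and including expected unscheduled requests at
# non-scheduled visits for the less-frequent arm.
expected_mammograms <- function(arm, cfg) {
  p_cons <- cfg$strata_probs$surgery[["conservation"]]
  if (arm == "annual") return(length(cfg$timepoints))
  nt <- length(cfg$timepoints)
  per_type <- vapply(c("conservation", "mastectomy"), function(s) {
    sched <- visit_scheduled("less_frequent", s, cfg$timepoints)
    sum(sched) + sum(cfg$request_prob[seq_len(nt)][!sched])
  }, numeric(1))
  p_cons * per_type[["conservation"]] + (1 - p_cons) * per_type[["mastectomy"]]
}

#' Arm differences implied by a simulation configuration
#'
#' Analytic total-cost and QALY arm differences implied by the configured
#' cost models, mammogram schedule and utility offset, under a zero-death
#' approximation (with a non-zero death hazard the realised differences are
#' attenuated slightly because both arms lose visits). Used as the ground
#' truth in parameter-recovery experiments.
#'
#' @param config A [sim_config()].
#' @return List with \code{delta_cost_healthcare}, \code{delta_cost_societal}
#'   and \code{delta_qaly}.
#' @export
configured_effects <- function(config) {
  re <- resolve_effects(config)
  cm <- re$cost_models
  nt <- length(config$timepoints)
  mam_diff <- (expected_mammograms("less_frequent", config) -
                 expected_mammograms("annual", config)) * config$mammogram_unit_cost
  hc <- cm$category %in% setdiff(HEALTHCARE_CATEGORIES, "mammogram")
  list(
    delta_cost_healthcare = sum(cm$diff[hc]) * nt / 5 + mam_diff,
    delta_cost_societal = sum(cm$diff) * nt / 5 + mam_diff,
    delta_qaly = re$utility_offset * max(config$years)
  )
}

trial_cols <- function() {
  c("patient_id", "arm", "age_band", "disease_type", "surgery",
    "hormone_therapy", "er_status", "timepoint", "years", "recurrence",
    "death_time", "censor_time", "scheduled", "requested", "mammograms",
    "quest_status", "hes_observed", "eq5d_profile", "eq5d_index",
    cost_col(ALL_CATEGORIES))
}

with_preserved_rng <- function(expr, seed) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a complete synthetic trial dataset
#'
#' Draws the full (pre-missingness) long-format dataset: one row per
#' patient-timepoint while the patient is alive, with strata, recurrence,
#' EQ-5D-5L profile and index, mammogram counts from the arm/surgery
#' schedule plus unscheduled patient requests, and all 14 cost categories.
#' Identical configurations (including seed) yield identical datasets.
#'
#' @param config A [sim_config()].
#' @return A \code{trial_data} data.frame with a \code{patients} attribute
#'   (one row per randomised patient, retained even if the patient died
#'   before the first visit) and a \code{config} attribute.
#' @export
generate_trial <- function(config) {
  if (!inherits(config, "sim_config")) abort_config("config must be a sim_config")
  with_preserved_rng(generate_trial_impl(config), config$seed)
}

generate_trial_impl <- function(cfg) {
  n <- cfg$n_per_arm
  vs <- cfg$value_set %||% synthetic_value_set()
  tp <- cfg$timepoints
  yrs <- cfg$years
  nt <- length(tp)
  horizon <- max(yrs)
  re <- resolve_effects(cfg)

  empty <- function() {
    d <- as.data.frame(sapply(trial_cols(), function(x) logical(0),
                              simplify = FALSE))
    pcols <- c("patient_id", "arm", "age_band", "disease_type", "surgery",
               "hormone_therapy", "er_status", "death_time", "censor_time")
    as_trial_data(d, patients = d[, pcols], config = cfg)
  }
  if (n == 0) return(empty())

  npat <- 2L * n
  arm <- rep(c("annual", "less_frequent"), each = n)
  strata <- lapply(cfg$strata_probs, function(p) {
    sample(names(p), npat, replace = TRUE, prob = p)
  })
  hz <- cfg$death_hazard[ifelse(arm == "annual", 1L, 2L)]
  death_raw <- ifelse(hz > 0, rexp(npat, rate = pmax(hz, 1e-12)), Inf)
  death_time <- ifelse(death_raw <= horizon, death_raw, NA_real_)
  censor_time <- ifelse(is.na(death_time), horizon, NA_real_)
  recurrence_onset <- if (cfg$recurrence_hazard > 0) {
    rexp(npat, rate = cfg$recurrence_hazard)
  } else rep(Inf, npat)
  patients <- data.frame(
    patient_id = seq_len(npat), arm = arm,
    age_band = strata$age_band, disease_type = strata$disease_type,
    surgery = strata$surgery, hormone_therapy = strata$hormone_therapy,
    er_status = strata$er_status,
    death_time = death_time, censor_time = censor_time,
    stringsAsFactors = FALSE
  )

  # long skeleton: visit rows while alive
  idx <- rep(seq_len(npat), each = nt)
  rows <- data.frame(
    patient_id = idx, arm = arm[idx],
    age_band = strata$age_band[idx], disease_type = strata$disease_type[idx],
    surgery = strata$surgery[idx], hormone_therapy = strata$hormone_therapy[idx],
    er_status = strata$er_status[idx],
    timepoint = rep(tp, npat), years = rep(yrs, npat),
    death_time = death_time[idx], censor_time = censor_time[idx],
    stringsAsFactors = FALSE
  )
  alive <- is.na(rows$death_time) | rows$years < rows$death_time
  rows <- rows[alive, , drop = FALSE]
  nr <- nrow(rows)
  rows$recurrence <- as.integer(rows$years >= recurrence_onset[rows$patient_id])

  rows$scheduled <- visit_scheduled(rows$arm, rows$surgery, rows$timepoint)
  tp_pos <- match(rows$timepoint, tp)
  can_request <- rows$arm == "less_frequent" & !rows$scheduled
  rows$requested <- can_request &
    runif(nr) < cfg$request_prob[tp_pos]
  rows$mammograms <- as.integer(rows$scheduled | rows$requested)
  rows$cost_mammogram <- rows$mammograms * cfg$mammogram_unit_cost

  # EQ-5D: mixture of ceiling mass at 1 and scaled beta on (-0.594, 1),
  # quantised to the nearest profile of the value set.
  m_base <- cfg$utility_means[tp_pos] +
    ifelse(rows$arm == "less_frequent", re$utility_offset, 0)
  p1 <- cfg$utility_ceiling
  mb <- (m_base - p1) / (1 - p1)
  z_pat <- rnorm(npat, 0, cfg$utility_sd_patient)
  mu_beta <- pmin(pmax((mb + 0.594) / 1.594 + z_pat[rows$patient_id], 0.02), 0.98)
  at_ceiling <- runif(nr) < p1
  a <- mu_beta * cfg$utility_kappa
  b <- (1 - mu_beta) * cfg$utility_kappa
  u_raw <- ifelse(at_ceiling, 1, -0.594 + 1.594 * rbeta(nr, a, b))
  ord <- order(vs$index)
  vs_idx_sorted <- vs$index[ord]
  vs_prof_sorted <- vs$profile[ord]
  nearest <- findInterval(u_raw, vs_idx_sorted, all.inside = TRUE)
  use_upper <- abs(vs_idx_sorted[nearest + 1] - u_raw) <
    abs(vs_idx_sorted[nearest] - u_raw)
  nearest <- nearest + as.integer(use_upper)
  rows$eq5d_profile <- vs_prof_sorted[nearest]
  rows$eq5d_index <- vs_idx_sorted[nearest]

  # Costs: per-visit zero-inflated lognormal with patient-level effect
  cm <- re$cost_models
  sdb <- cfg$cost_sd_patient
  for (i in seq_len(nrow(cm))) {
    cat_i <- cm$category[i]
    m_tot <- cm$mean_total[i] + ifelse(rows$arm == "less_frequent", cm$diff[i], 0)
    p0 <- cm$p_zero[i]
    eln <- m_tot / (5 * (1 - p0))
    v_visit <- cm$sd_total[i]^2 / 5
    vln <- pmax((v_visit - (1 - p0) * p0 * eln^2) / (1 - p0), (0.25 * eln)^2)
    sig2 <- log(1 + vln / eln^2)
    mu <- log(eln) - sig2 / 2
    b_pat <- rnorm(npat, -sdb^2 / 2, sdb)
    amt <- (runif(nr) >= p0) *
      exp(rnorm(nr, mu, sqrt(sig2)) + b_pat[rows$patient_id])
    rows[[cost_col(cat_i)]] <- amt
  }
  rows$quest_status <- "observed"
  rows$hes_observed <- TRUE
  rows <- rows[, trial_cols()]
  rows <- rows[order(rows$patient_id, rows$timepoint), , drop = FALSE]
  as_trial_data(rows, patients = patients, config = cfg)
}

as_trial_data <- function(rows, patients, config = NULL) {
  rownames(rows) <- NULL
  structure(rows, class = c("trial_data", "data.frame"),
            patients = patients, config = config)
}

#' @export
print.trial_data <- function(x, ...) {
  pats <- attr(x, "patients")
  cat(sprintf("<trial_data> %d rows, %d patients, timepoints %s\n",
              nrow(x), if (is.null(pats)) length(unique(x$patient_id)) else nrow(pats),
              paste(sort(unique(x$timepoint)), collapse = ",")))
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Apply design-driven questionnaire missingness
#'
#' In the less-frequent arm, questionnaires (EQ-5D and all
#' questionnaire-collected cost categories) are administered only at
#' scheduled mammogram visits or unscheduled requested mammograms; all other
#' visits are flagged missing-by-design and their questionnaire fields set
#' to \code{NA}. Annual-arm rows are untouched. The flags are a
#' deterministic function of the dataset, so re-application is idempotent.
#'
#' @param data A \code{trial_data}.
#' @return The dataset with \code{quest_status} updated.
#' @export
apply_design_missingness <- function(data) {
  if (!all(data$surgery %in% c("conservation", "mastectomy"))) {
    abort_config("unknown surgery type; expected conservation or mastectomy")
  }
  sched <- visit_scheduled(data$arm, data$surgery, data$timepoint)
  hide <- data$arm == "less_frequent" & !sched & !data$requested
  data$quest_status[hide] <- "design_missing"
  qcols <- c("eq5d_profile", "eq5d_index", cost_col(QUESTIONNAIRE_CATEGORIES))
  for (cc in qcols) data[[cc]][hide] <- NA
  data
}

#' Apply stochastic questionnaire non-return and late hospital-record gaps
#'
#' Questionnaires that were administered (status \code{"observed"} after
#' [apply_design_missingness()]) are independently not returned with the
#' per-visit probability \code{config$dropout}; hospital-record (admitted /
#' outpatient) costs at the final timepoint are missing with probability
#' \code{config$hes_final_missing}, reflecting incomplete records for later
#' recruits. Reproducible: reseeded from \code{config$seed}.
#'
#' @param data A \code{trial_data} with design missingness applied.
#' @param config The [sim_config()].
#' @return The dataset with additional missingness.
#' @export
apply_dropout <- function(data, config) {
  stopifnot_prob(config$dropout, "dropout probabilities")
  with_preserved_rng({
    tp_pos <- match(data$timepoint, config$timepoints)
    p <- config$dropout[tp_pos]
    drop <- data$quest_status == "observed" & runif(nrow(data)) < p
    data$quest_status[drop] <- "not_returned"
    qcols <- c("eq5d_profile", "eq5d_index", cost_col(QUESTIONNAIRE_CATEGORIES))
    for (cc in qcols) data[[cc]][drop] <- NA
    last_tp <- max(config$timepoints)
    hes_gap <- data$timepoint == last_tp &
      runif(nrow(data)) < config$hes_final_missing
    data$hes_observed[hes_gap] <- FALSE
    for (cc in cost_col(HES_CATEGORIES)) data[[cc]][hes_gap] <- NA
    data
  }, config$seed + 104729L)
}

#' Write / read simulation configuration
#'
#' Serialises a [sim_config()] to a YAML file (tables as column lists) and
#' back.
#' @param config A \code{sim_config}.
#' @param path File path.
#' @export
write_sim_config <- function(config, path) {
  out <- unclass(config)
  out$cost_models <- as.list(out$cost_models)
  # named vectors must become maps or YAML drops the names
  out$strata_probs <- lapply(out$strata_probs, as.list)
  out$value_set <- NULL  # regenerated or supplied separately
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$cost_models <- as.data.frame(raw$cost_models, stringsAsFactors = FALSE)
  raw$strata_probs <- lapply(raw$strata_probs, unlist)
  do.call(sim_config, raw[setdiff(names(raw), "years")])
}
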