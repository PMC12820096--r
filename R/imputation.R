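#' Specification for multiple imputation by chained equations
#'
#' Controls the per-arm chained-equations engine. Defaults follow the trial
#' analysis: 25 imputed datasets with up to 20 iterations each, skewed costs
#' modelled on the log scale, and a predictor hierarchy in which observed
#' healthcare costs and EQ-5D index predict missing healthcare and societal
#' costs, while societal costs never predict healthcare costs or the EQ-5D
#' index. Repeated measures are handled with a two-level approximation:
#' each patient's observed-value means enter every conditional model as
#' cluster-level predictors.
#'
#' @param m Number of imputed datasets (>= 2).
#' @param max_iterations Chained-equation iterations per dataset.
#' @param method \code{"pmm"} (two-level predictive mean matching, default)
#'   or \code{"norm"} (two-level normal on the log scale for costs).
#' @param k_donors PMM donor pool size.
#' @param log_offset Offset \eqn{\delta} for \eqn{\log(x + \delta)}
#'   transforms of zero-inflated costs (GBP).
#' @param variables Analysis variables to impute; default all imputable
#'   variables (EQ-5D index, questionnaire cost categories, final-visit
#'   hospital-record costs). Restrict to speed up perspective-specific runs.
#' @param seed Integer seed.
#' @return An \code{imputation_spec} list.
#' @export
imputation_spec <- function(m = 25, max_iterations = 20,
                            method = c("pmm", "norm"), k_donors = 5,
                            log_offset = 0.01, variables = NULL,
                            seed = 1L) {
  method <- match.arg(method)
  if (m < 2) abort_config("m must be >= 2")
  if (max_iterations < 1) abort_config("max_iterations must be >= 1")
  if (k_donors < 1) abort_config("k_donors must be >= 1")
  all_vars <- imputable_variables()
  variables <- variables %||% all_vars
  if (!all(variables %in% all_vars)) {
    abort_config(sprintf("unknown imputation variable(s): %s",
                         paste(setdiff(variables, all_vars), collapse = ", ")))
  }
  structure(list(m = as.integer(m), max_iterations = as.integer(max_iterations),
                 method = method, k_donors = as.integer(k_donors),
                 log_offset = log_offset, variables = variables,
                 seed = as.integer(seed)),
            class = "imputation_spec")
}

imputable_variables <- function() {
  c("eq5d_index", cost_col(c("community", "prescribed")),
    cost_col(HES_CATEGORIES), cost_col(SOCIETAL_CATEGORIES))
}

# Visit sequence: EQ-5D first, then healthcare costs, then societal costs,
# mirroring the predictor hierarchy.
impute_sequence <- function(vars) {
  ord <- c("eq5d_index", cost_col(c("community", "prescribed")),
           cost_col(HES_CATEGORIES), cost_col(SOCIETAL_CATEGORIES))
  ord[ord %in% vars]
}

# Allowed same-row predictors for a target (self excluded; societal costs
# never predict healthcare costs or EQ-5D).
predictor_vars <- function(target) {
  hc <- c("eq5d_index", cost_col(c("community", "prescribed", "admitted",
                                   "outpatient", "mammogram")))
  soc <- cost_col(SOCIETAL_CATEGORIES)
  allowed <- if (target %in% soc) c(hc, soc) else hc
  setdiff(allowed, target)
}

is_cost_variable <- function(v) startsWith(v, "cost_")

#' Posterior draw for a normal linear model
#'
#' Least-squares fit with an approximate Bayesian parameter draw:
#' \eqn{\sigma^2} from the scaled inverse chi-square at the residual degrees
#' of freedom, then \eqn{\beta} from its normal sampling distribution.
#' Rank-deficient columns are dropped. Engine behind each chained-equation
#' step.
#' @noRd
norm_draw <- function(y, X) {
  q0 <- qr(X)
  r <- q0$rank
  keep <- sort(q0$pivot[seq_len(r)])
  Xk <- X[, keep, drop = FALSE]
  qk <- qr(Xk)
  beta_hat <- qr.coef(qk, y)
  res <- qr.resid(qk, y)
  df <- max(length(y) - r, 1)
  sigma2 <- sum(res^2) / rchisq(1, df)
  R <- qr.R(qk)
  beta_draw <- beta_hat + backsolve(R, rnorm(r)) * sqrt(sigma2)
  list(beta_hat = beta_hat, beta_draw = beta_draw,
       sigma = sqrt(sigma2), keep = keep)
}

#' Predictive mean matching draw
#'
#' Each missing case receives the observed outcome of one of its
#' \code{k_donors} nearest observed neighbours by fitted value, chosen
#' uniformly at random (type-1 matching: observed fitted values from the
#' least-squares estimate, missing fitted values from the parameter draw).
#'
#' @param observed_y Observed outcomes (donor pool), original scale.
#' @param fitted_obs Fitted values for the observed cases.
#' @param fitted_mis Fitted values for the missing cases.
#' @param k_donors Donor pool size per missing case.
#' @return Imputed values, one per element of \code{fitted_mis}.
#' @export
pmm_draw <- function(observed_y, fitted_obs, fitted_mis, k_donors = 5L) {
  n_obs <- length(observed_y)
  if (k_donors < 1) abort_config("k_donors must be >= 1")
  if (n_obs < k_donors) {
    abort_config(sprintf("only %d observed cases for %d donors requested",
                         n_obs, k_donors))
  }
  if (length(fitted_obs) != n_obs) {
    abort_config("fitted_obs must match observed_y in length")
  }
  o <- order(fitted_obs)
  fs <- fitted_obs[o]
  ys <- observed_y[o]
  k <- as.integer(k_donors)
  pos <- findInterval(fitted_mis, fs)
  vapply(seq_along(fitted_mis), function(i) {
    lo <- max(1L, pos[i] - k + 1L)
    hi <- min(n_obs, pos[i] + k)
    win <- lo:hi
    d <- abs(fs[win] - fitted_mis[i])
    donors <- win[order(d)[seq_len(k)]]
    ys[donors[sample.int(k, 1L)]]
  }, numeric(1))
}

#' Multiple imputation of a trial dataset
#'
#' Runs chained-equations imputation separately by trial arm. Conditional
#' models regress each incomplete variable on the trial stratification
#' variables (age band, disease type, surgery type, hormone therapy, ER
#' status), time, recurrence status, the allowed same-visit variables under
#' the predictor hierarchy, and patient-level means of observed values
#' (two-level structure for the repeated measures). Skewed costs are
#' modelled on the \eqn{\log(x+\delta)} scale; PMM donors return observed
#' values, so imputed costs are always non-negative. Observed cells are
#' never altered.
#'
#' @param data A \code{trial_data} with missingness flags set.
#' @param spec An [imputation_spec()].
#' @return An \code{imputed_set}: list with \code{imputations} (m completed
#'   \code{trial_data} copies), \code{traces} (chain means per variable,
#'   chain and iteration), \code{n_missing}, and the \code{spec} used.
#' @export
impute <- function(data, spec = imputation_spec()) {
  if (!inherits(spec, "imputation_spec")) abort_config("spec must be an imputation_spec")
  vars <- impute_sequence(spec$variables)
  n_missing <- vapply(vars, function(v) sum(is.na(data[[v]])), integer(1))
  for (a in unique(data$arm)) {
    all_na <- vapply(vars, function(v) all(is.na(data[[v]][data$arm == a])),
                     logical(1))
    if (any(all_na)) {
      abort_config(sprintf(
        "variable(s) 100%% missing in arm '%s', no donors: %s",
        a, paste(vars[all_na], collapse = ", ")))
    }
  }
  with_preserved_rng(impute_impl(data, spec, vars, n_missing), spec$seed)
}

impute_impl <- function(data, spec, vars, n_missing) {
  arms <- unique(data$arm)
  base_design <- impute_base_design(data)
  cmeans <- cluster_means(data, vars, arms)
  miss_idx <- lapply(vars, function(v) which(is.na(data[[v]])))
  names(miss_idx) <- vars

  imputations <- vector("list", spec$m)
  traces <- list()
  for (chain in seq_len(spec$m)) {
    work <- as.data.frame(data)
    # initial fill: random draws from the arm's observed values
    for (v in vars) {
      for (a in arms) {
        mi <- intersect(miss_idx[[v]], which(data$arm == a))
        if (!length(mi)) next
        obs <- work[[v]][data$arm == a & !is.na(data[[v]])]
        work[[v]][mi] <- sample(obs, length(mi), replace = TRUE)
      }
    }
    for (it in seq_len(spec$max_iterations)) {
      for (v in vars) {
        if (!length(miss_idx[[v]])) next
        for (a in arms) {
          rows_a <- data$arm == a
          mi <- intersect(miss_idx[[v]], which(rows_a))
          if (!length(mi)) next
          oi <- setdiff(which(rows_a & !is.na(data[[v]])), mi)
          X <- impute_design(work, v, base_design, cmeans, spec$log_offset)
          y_obs <- work[[v]][oi]
          t_obs <- transform_target(y_obs, v, spec$log_offset)
          nd <- norm_draw(t_obs, X[oi, , drop = FALSE])
          Xm <- X[mi, nd$keep, drop = FALSE]
          if (spec$method == "pmm") {
            fitted_obs <- drop(X[oi, nd$keep, drop = FALSE] %*% nd$beta_hat)
            fitted_mis <- drop(Xm %*% nd$beta_draw)
            work[[v]][mi] <- pmm_draw(y_obs, fitted_obs, fitted_mis,
                                      min(spec$k_donors, length(oi)))
          } else {
            t_draw <- drop(Xm %*% nd$beta_draw) + rnorm(length(mi), 0, nd$sigma)
            work[[v]][mi] <- back_transform(t_draw, v, spec$log_offset)
          }
          traces[[length(traces) + 1L]] <- data.frame(
            arm = a, variable = v, chain = chain, iteration = it,
            mean_imputed = mean(work[[v]][mi]), stringsAsFactors = FALSE)
        }
      }
    }
    out <- data
    for (v in vars) out[[v]][miss_idx[[v]]] <- work[[v]][miss_idx[[v]]]
    imputations[[chain]] <- out
  }
  structure(list(imputations = imputations,
                 traces = do.call(rbind, traces),
                 n_missing = n_missing, spec = spec),
            class = "imputed_set")
}

transform_target <- function(y, v, offset) {
  if (is_cost_variable(v)) log(y + offset) else y
}

back_transform <- function(t, v, offset) {
  if (is_cost_variable(v)) pmax(exp(t) - offset, 0) else pmin(t, 1)
}

impute_base_design <- function(data) {
  fac <- c("age_band", "disease_type", "surgery", "hormone_therapy",
           "er_status")
  df <- as.data.frame(data)[, c(fac, "years", "recurrence", "mammograms")]
  for (cc in fac) df[[cc]] <- factor(df[[cc]])
  # constant factors (e.g. within a subgroup) carry no information
  keep <- c(fac[vapply(df[fac], nlevels, integer(1)) > 1],
            "years", "recurrence", "mammograms")
  model.matrix(reformulate(keep), df)
}

cluster_means <- function(data, vars, arms) {
  out <- matrix(NA_real_, nrow(data), length(vars),
                dimnames = list(NULL, paste0("pm_", vars)))
  for (j in seq_along(vars)) {
    v <- vars[j]
    ok <- !is.na(data[[v]])
    pm <- tapply(data[[v]][ok], data$patient_id[ok], mean)
    val <- pm[as.character(data$patient_id)]
    for (a in arms) {
      fallback <- mean(data[[v]][ok & data$arm == a])
      ai <- data$arm == a & is.na(val)
      val[ai] <- fallback
    }
    out[, j] <- val
  }
  out
}

impute_design <- function(work, target, base_design, cmeans, offset) {
  preds <- intersect(predictor_vars(target), names(work))
  pm_cols <- intersect(paste0("pm_", c(target, preds)), colnames(cmeans))
  pred_mat <- vapply(preds, function(p) {
    transform_target(work[[p]], p, offset)
  }, numeric(nrow(work)))
  cbind(base_design, pred_mat, cmeans[, pm_cols, drop = FALSE])
}

#' Imputation diagnostics
#'
#' Observed-versus-imputed distribution summaries, chain-mean traces, and
#' fraction-of-missing-information (FMI) estimates for each imputed
#' variable's mean, via the usual combination of within- and
#' between-imputation variance.
#'
#' @param imp An [impute()] result.
#' @param data The original (incomplete) dataset the imputation was run on;
#'   defaults to reconstructing observed cells from the imputations.
#' @return An \code{imputation_diagnostics} list with \code{summary} (per
#'   variable), \code{traces} and \code{trivially_valid} (TRUE when there
#'   was nothing to impute).
#' @export
diagnostics <- function(imp, data = NULL) {
  vars <- names(imp$n_missing)
  m <- imp$spec$m
  triv <- all(imp$n_missing == 0)
  rows <- lapply(vars, function(v) {
    first <- imp$imputations[[1]]
    if (is.null(data)) {
      # observed cells are identical across imputations; imputed cells vary
      # across chains almost surely, so recover the observed mask by equality
      same <- Reduce(`&`, lapply(imp$imputations[-1],
                                 function(d) d[[v]] == first[[v]]))
      obs_mask <- same
    } else {
      obs_mask <- !is.na(data[[v]])
    }
    obs <- first[[v]][obs_mask]
    imp_vals <- unlist(lapply(imp$imputations, function(d) d[[v]][!obs_mask]))
    per_imp_mean <- vapply(imp$imputations, function(d) mean(d[[v]]), numeric(1))
    per_imp_se2 <- vapply(imp$imputations,
                          function(d) var(d[[v]]) / length(d[[v]]), numeric(1))
    W <- mean(per_imp_se2)
    B <- if (m > 1) var(per_imp_mean) else 0
    Tv <- W + (1 + 1 / m) * B
    data.frame(
      variable = v, n_missing = imp$n_missing[[v]],
      observed_mean = mean(obs), observed_sd = sd(obs),
      imputed_mean = if (length(imp_vals)) mean(imp_vals) else NA_real_,
      imputed_sd = if (length(imp_vals) > 1) sd(imp_vals) else NA_real_,
      pooled_mean = mean(per_imp_mean),
      fmi = if (Tv > 0) (1 + 1 / m) * B / Tv else 0,
      stringsAsFactors = FALSE)
  })
  structure(list(summary = do.call(rbind, rows), traces = imp$traces,
                 trivially_valid = triv),
            class = "imputation_diagnostics")
}

#' @export
print.imputation_diagnostics <- function(x, ...) {
  if (x$trivially_valid) cat("No missing data: diagnostics trivially valid.\n")
  print(x$summary, digits = 4)
  invisible(x)
}
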