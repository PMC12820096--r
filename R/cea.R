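#' Per-patient analysis totals
#'
#' Collapses a *complete* long-format dataset to one row per patient with
#' total cost under the chosen perspective, QALYs by the area-under-the-
#' curve method, life years, mammogram count, arm and stratification
#' variables. Utility trajectories are anchored at randomisation by carrying
#' the first observed utility back to time 0 (\code{anchor = "carry_back"},
#' default) or started at the first observation (\code{"first_obs"}).
#' Patients who died before their first visit are anchored at the arm mean
#' first-visit utility and decline linearly to zero at death.
#'
#' @param data Complete \code{trial_data} (one imputation, or synthetic
#'   pre-missingness data).
#' @param perspective \code{"healthcare"} or \code{"societal"}.
#' @param horizon Analysis horizon in years (default: last visit year).
#' @param death_rule,anchor QALY construction switches (see [qaly_auc()]).
#' @param mammogram_unit_cost Optional re-costing of the mammogram category.
#' @param exclude Cost categories to zero out (e.g. \code{"outpatient"}).
#' @return Data frame, one row per patient.
#' @export
patient_totals <- function(data, perspective = c("healthcare", "societal"),
                           horizon = NULL,
                           death_rule = c("linear_to_zero", "locf"),
                           anchor = c("carry_back", "first_obs"),
                           mammogram_unit_cost = NULL,
                           exclude = character(0)) {
  perspective <- match.arg(perspective)
  death_rule <- match.arg(death_rule)
  anchor <- match.arg(anchor)
  horizon <- horizon %||% max(data$years)
  pats <- attr(data, "patients")
  if (is.null(pats)) pats <- rebuild_patients(data)

  bd <- cost_breakdown(data, mammogram_unit_cost = mammogram_unit_cost)
  for (cat_i in exclude) bd <- exclude_category(bd, cat_i)
  # restrict to perspective columns before checking completeness
  cats <- if (perspective == "healthcare") HEALTHCARE_CATEGORIES else ALL_CATEGORIES
  total_cost <- assemble_perspective(bd[, c("patient_id", cost_col(cats))],
                                     perspective)
  cost_by_id <- setNames(total_cost, bd$patient_id)
  mam <- tapply(data$mammograms, data$patient_id, sum)

  qaly <- qaly_by_patient(data, pats, horizon, death_rule, anchor)
  end_time <- ifelse(is.na(pats$death_time), pats$censor_time, pats$death_time)
  out <- data.frame(
    patient_id = pats$patient_id, arm = pats$arm,
    age_band = pats$age_band, disease_type = pats$disease_type,
    surgery = pats$surgery, hormone_therapy = pats$hormone_therapy,
    er_status = pats$er_status,
    total_cost = unname(cost_by_id[as.character(pats$patient_id)]),
    qaly = qaly,
    life_years = life_years(0, end_time, horizon = horizon),
    mammograms = unname(ifelse(is.na(mam[as.character(pats$patient_id)]), 0,
                               mam[as.character(pats$patient_id)])),
    stringsAsFactors = FALSE
  )
  out$total_cost[is.na(out$total_cost)] <- 0  # zero-visit patients accrued nothing
  out
}

# Vectorised per-patient QALY with the same semantics as qaly_auc()
# (which serves as the scalar reference in the tests). Assumes observation
# years <= horizon, as produced by the generator/pipeline.
qaly_by_patient <- function(data, pats, horizon, death_rule, anchor) {
  ord <- order(data$patient_id, data$years)
  pid <- data$patient_id[ord]
  tt <- data$years[ord]
  uu <- data$eq5d_index[ord]
  if (anyNA(uu)) abort_config("utilities incomplete; run impute() first")
  if (any(tt > horizon)) {
    abort_config("observation years beyond the analysis horizon")
  }
  n <- length(pid)
  first <- c(TRUE, pid[-1] != pid[-n])
  last <- c(first[-1], TRUE)
  # interior trapezoids
  seg <- c(0, 0.5 * (uu[-1] + uu[-n]) * (tt[-1] - tt[-n]))
  seg[first] <- 0
  q <- rowsum(seg, pid)
  q_by_id <- setNames(drop(q), rownames(q))
  # anchor at randomisation: carry the first utility back to time 0
  if (anchor == "carry_back") {
    q_by_id <- q_by_id + setNames(uu[first] * tt[first], pid[first])[names(q_by_id)]
  }
  # death tail from the last observation, truncated at the horizon
  dt_all <- pats$death_time[match(as.numeric(names(q_by_id)), pats$patient_id)]
  u_last <- setNames(uu[last], pid[last])[names(q_by_id)]
  t_last <- setNames(tt[last], pid[last])[names(q_by_id)]
  has_death <- !is.na(dt_all) & dt_all > t_last
  if (any(has_death)) {
    tail_end <- pmin(dt_all, horizon)
    if (death_rule == "linear_to_zero") {
      u_end <- u_last * (dt_all - tail_end) / (dt_all - t_last)
      tail_q <- 0.5 * (u_last + u_end) * (tail_end - t_last)
    } else {
      tail_q <- u_last * (tail_end - t_last)
    }
    q_by_id[has_death] <- q_by_id[has_death] + tail_q[has_death]
  }
  # patients with no visit rows (death before first visit): anchor at the
  # arm mean first-visit utility, declining to zero at death
  qaly <- rep(NA_real_, nrow(pats))
  hit <- match(pats$patient_id, as.numeric(names(q_by_id)))
  qaly[!is.na(hit)] <- q_by_id[hit[!is.na(hit)]]
  if (anyNA(qaly)) {
    arm_anchor <- tapply(uu[first],
                         pats$arm[match(pid[first], pats$patient_id)], mean)
    for (i in which(is.na(qaly))) {
      u0 <- arm_anchor[[pats$arm[i]]]
      qaly[i] <- qaly_auc(0, u0, death_time = pats$death_time[i],
                          death_rule = death_rule, horizon = horizon)
    }
  }
  qaly
}

rebuild_patients <- function(data) {
  first <- !duplicated(data$patient_id)
  data.frame(
    patient_id = data$patient_id[first], arm = data$arm[first],
    age_band = data$age_band[first], disease_type = data$disease_type[first],
    surgery = data$surgery[first], hormone_therapy = data$hormone_therapy[first],
    er_status = data$er_status[first],
    death_time = data$death_time[first], censor_time = data$censor_time[first],
    stringsAsFactors = FALSE
  )
}

DEFAULT_COVARIATES <- c("age_band", "disease_type", "surgery",
                        "hormone_therapy", "er_status")

sur_design <- function(totals, covariates = DEFAULT_COVARIATES) {
  df <- totals
  df$arm <- factor(df$arm, levels = c("annual", "less_frequent"))
  keep <- covariates[vapply(covariates,
                            function(v) length(unique(df[[v]])) > 1, logical(1))]
  for (v in keep) df[[v]] <- factor(df[[v]])
  f <- reformulate(c("arm", keep))
  model.matrix(f, df)
}

#' Seemingly unrelated regression of total costs and QALYs
#'
#' Two-equation system (total cost; QALY) on a treatment-arm indicator and
#' the trial stratification covariates, estimated by feasible generalised
#' least squares: per-equation OLS, residual cross-equation covariance, then
#' the joint GLS solve. With identical regressors in both equations the GLS
#' solution coincides with per-equation OLS (Kruskal's theorem); the
#' estimated residual covariance still quantifies the cost--QALY
#' correlation. The arm coefficients are the incremental cost
#' \eqn{\Delta C} and incremental QALY \eqn{\Delta Q} (less frequent minus
#' annual).
#'
#' @param totals One row per patient ([patient_totals()] output).
#' @param covariates Stratification covariates to control for; constant
#'   columns are dropped automatically (e.g. within a subgroup).
#' @return A \code{sur_fit}: coefficients (matrix, equations in columns),
#'   residual covariance \code{sigma}, coefficient covariance \code{vcov},
#'   \code{delta_cost}, \code{delta_qaly} with standard errors.
#' @export
fit_sur <- function(totals, covariates = DEFAULT_COVARIATES) {
  X <- sur_design(totals, covariates)
  Y <- cbind(cost = totals$total_cost, qaly = totals$qaly)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    abort_config(sprintf("rank-deficient design; collinear column(s): %s",
                         paste(bad, collapse = ", ")))
  }
  n <- nrow(X); p <- ncol(X)
  # stage 1: per-equation OLS for the residual covariance
  B_ols <- qr.coef(q, Y)
  E <- Y - X %*% B_ols
  S <- crossprod(E) / (n - p)
  # stage 2: joint GLS on the stacked system; with a (near-)singular
  # residual covariance (degenerate data) the OLS solution already solves
  # the system and is kept as-is
  XtX <- crossprod(X)
  XtXi <- solve(XtX)
  if (rcond(S) > 1e-12) {
    Sinv <- solve(S)
    A <- rbind(cbind(Sinv[1, 1] * XtX, Sinv[1, 2] * XtX),
               cbind(Sinv[2, 1] * XtX, Sinv[2, 2] * XtX))
    rhs <- c(crossprod(X, Y %*% Sinv[, 1]), crossprod(X, Y %*% Sinv[, 2]))
    beta <- solve(A, rhs)
    B <- matrix(beta, ncol = 2, dimnames = list(colnames(X), c("cost", "qaly")))
    V <- solve(A)
  } else {
    B <- B_ols
    dimnames(B) <- list(colnames(X), c("cost", "qaly"))
    V <- kronecker(S, XtXi)
  }
  arm_row <- match("armless_frequent", colnames(X))
  se <- sqrt(diag(V))
  structure(list(
    coefficients = B, sigma = S, vcov = V, n = n,
    residual_correlation = S[1, 2] / sqrt(S[1, 1] * S[2, 2]),
    delta_cost = B[arm_row, "cost"], delta_qaly = B[arm_row, "qaly"],
    se_delta_cost = se[arm_row], se_delta_qaly = se[p + arm_row]
  ), class = "sur_fit")
}

#' @export
print.sur_fit <- function(x, ...) {
  cat(sprintf("SUR fit (n = %d)\n  delta cost: %.2f (SE %.2f)\n  delta QALY: %.4f (SE %.4f)\n  residual correlation: %.3f\n",
              x$n, x$delta_cost, x$se_delta_cost, x$delta_qaly,
              x$se_delta_qaly, x$residual_correlation))
  invisible(x)
}

# Fast arm-coefficient fit used inside the bootstrap: shared design in both
# equations, so GLS = OLS and one QR serves both outcomes.
fast_arm_fit <- function(X, Y, arm_row) {
  qr.coef(qr(X), Y)[arm_row, ]
}

#' Bootstrapped joint estimation of incremental costs and QALYs
#'
#' For each completed (imputed) dataset, resamples patients with replacement
#' -- stratified by arm, so both arms appear in every replicate -- and
#' refits the cost/QALY regression, collecting one
#' \eqn{(\Delta C, \Delta Q)} pair per replicate. Draws are concatenated
#' over the imputed datasets into a single empirical distribution.
#'
#' @param imp An \code{imputed_set}, or a single complete \code{trial_data}.
#' @param B Bootstrap replicates per imputed dataset.
#' @param seed Integer seed.
#' @param covariates Stratification covariates in the regression.
#' @param ... Passed to [patient_totals()] (perspective, horizon,
#'   mammogram_unit_cost, exclude, ...).
#' @return A \code{ce_draws} data frame with columns \code{imputation},
#'   \code{replicate}, \code{delta_cost}, \code{delta_qaly}; per-imputation
#'   full-sample point estimates in \code{attr(, "point")}.
#' @export
bootstrap_cea <- function(imp, B = 5000, seed = 1L,
                          covariates = DEFAULT_COVARIATES, ...) {
  if (inherits(imp, "trial_data")) imp <- list(imputations = list(imp))
  datasets <- imp$imputations
  if (B < 1) abort_config("B must be >= 1")
  with_preserved_rng({
    draws <- vector("list", length(datasets))
    points <- vector("list", length(datasets))
    for (d in seq_along(datasets)) {
      totals <- patient_totals(datasets[[d]], ...)
      X <- sur_design(totals, covariates)
      Y <- cbind(totals$total_cost, totals$qaly)
      arm_row <- match("armless_frequent", colnames(X))
      if (is.na(arm_row)) abort_config("both arms must be present")
      fit <- fit_sur(totals, covariates)
      points[[d]] <- data.frame(imputation = d, delta_cost = fit$delta_cost,
                                delta_qaly = fit$delta_qaly,
                                var_cost = fit$se_delta_cost^2,
                                var_qaly = fit$se_delta_qaly^2)
      by_arm <- split(seq_len(nrow(totals)), totals$arm)
      dc <- numeric(B); dq <- numeric(B)
      for (b in seq_len(B)) {
        repeat {
          idx <- unlist(lapply(by_arm, function(ii)
            ii[sample.int(length(ii), length(ii), replace = TRUE)]),
            use.names = FALSE)
          if (length(unique(totals$arm[idx])) == 2L) break  # cannot fail: stratified
        }
        cf <- fast_arm_fit(X[idx, , drop = FALSE], Y[idx, , drop = FALSE],
                           arm_row)
        dc[b] <- cf[1]; dq[b] <- cf[2]
      }
      draws[[d]] <- data.frame(imputation = d, replicate = seq_len(B),
                               delta_cost = dc, delta_qaly = dq)
    }
    structure(do.call(rbind, draws),
              class = c("ce_draws", "data.frame"),
              point = do.call(rbind, points), seed = seed,
              m = length(datasets), B = B)
  }, seed)
}

#' Incremental net monetary benefit
#'
#' \eqn{\mathrm{INMB}(\lambda) = \lambda \, \Delta Q - \Delta C}: positive
#' values favour the less frequent arm at willingness-to-pay \eqn{\lambda}.
#'
#' @param delta_cost Incremental cost (GBP).
#' @param delta_qaly Incremental QALYs.
#' @param lambda Willingness-to-pay threshold (GBP per QALY).
#' @return INMB in GBP (vectorised).
#' @export
inmb <- function(delta_cost, delta_qaly, lambda = 20000) {
  lambda * delta_qaly - delta_cost
}

#' Default willingness-to-pay grid
#'
#' 0 to 50,000 GBP/QALY in 500 GBP steps (includes the 20,000 and 30,000
#' reference thresholds).
#' @export
default_wtp_grid <- function() seq(0, 50000, by = 500)

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of bootstrap draws with
#' strictly positive INMB (ties at exactly zero count as not
#' cost-effective).
#'
#' @param draws A \code{ce_draws}.
#' @param lambda_grid Willingness-to-pay values (GBP/QALY).
#' @return Data frame with columns \code{lambda} and \code{probability}.
#' @export
ceac <- function(draws, lambda_grid = default_wtp_grid()) {
  if (!nrow(draws)) abort_config("no draws")
  if (!length(lambda_grid)) abort_config("empty willingness-to-pay grid")
  prob <- vapply(lambda_grid, function(l) {
    mean(inmb(draws$delta_cost, draws$delta_qaly, l) > 0)
  }, numeric(1))
  data.frame(lambda = lambda_grid, probability = prob)
}

#' Summarise bootstrap cost-effectiveness draws
#'
#' Point estimates are means over the pooled draws with percentile 95%
#' intervals; INMB summaries at the key thresholds; the CEAC over the WTP
#' grid; cost-effectiveness-plane quadrant proportions; and Rubin's-rules
#' pooling of the per-imputation full-sample point estimates as the
#' deterministic companion summary.
#'
#' @param object A \code{ce_draws}.
#' @param lambda_grid WTP grid for the CEAC.
#' @param wtp_key Thresholds for the INMB summary (default 20,000 and
#'   30,000 GBP/QALY).
#' @param ... Unused.
#' @return A \code{ce_result} list.
#' @export
summary.ce_draws <- function(object, lambda_grid = default_wtp_grid(),
                             wtp_key = c(20000, 30000), ...) {
  stopifnot(nrow(object) > 0)
  dc <- object$delta_cost; dq <- object$delta_qaly
  ci <- function(x) unname(quantile(x, c(0.025, 0.975)))
  inmb_tab <- do.call(rbind, lapply(wtp_key, function(l) {
    v <- inmb(dc, dq, l)
    data.frame(lambda = l, inmb = mean(v), lower = ci(v)[1], upper = ci(v)[2],
               probability_cost_effective = mean(v > 0))
  }))
  quadrants <- c(
    NE = mean(dq > 0 & dc >= 0), SE = mean(dq > 0 & dc < 0),
    SW = mean(dq <= 0 & dc < 0), NW = mean(dq <= 0 & dc >= 0)
  )
  pt <- attr(object, "point")
  rubin <- NULL
  if (!is.null(pt)) {
    m <- nrow(pt)
    pool <- function(est, w) {
      qbar <- mean(est)
      Bv <- if (m > 1) var(est) else 0
      Tv <- mean(w) + (1 + 1 / m) * Bv
      c(estimate = qbar, se = sqrt(Tv))
    }
    rubin <- rbind(delta_cost = pool(pt$delta_cost, pt$var_cost),
                   delta_qaly = pool(pt$delta_qaly, pt$var_qaly))
  }
  structure(list(
    delta_cost = mean(dc), delta_cost_ci = ci(dc),
    delta_qaly = mean(dq), delta_qaly_ci = ci(dq),
    p_cost_saving = mean(dc < 0), p_qaly_loss = mean(dq < 0),
    inmb = inmb_tab, ceac = ceac(object, lambda_grid),
    quadrants = quadrants, rubin = rubin,
    n_draws = nrow(object), m = attr(object, "m"), B = attr(object, "B")
  ), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("Incremental cost:  %.2f (95%% CI %.2f to %.2f)\n",
              x$delta_cost, x$delta_cost_ci[1], x$delta_cost_ci[2]))
  cat(sprintf("Incremental QALYs: %.4f (95%% CI %.4f to %.4f)\n",
              x$delta_qaly, x$delta_qaly_ci[1], x$delta_qaly_ci[2]))
  cat(sprintf("P(cost saving) = %.3f; P(QALY loss) = %.3f\n",
              x$p_cost_saving, x$p_qaly_loss))
  for (i in seq_len(nrow(x$inmb))) {
    r <- x$inmb[i, ]
    cat(sprintf("INMB at %s/QALY: %.2f (95%% CI %.2f to %.2f); P(CE) = %.3f\n",
                format(r$lambda, big.mark = ","), r$inmb, r$lower, r$upper,
                r$probability_cost_effective))
  }
  invisible(x)
}

#' Subgroup cost-effectiveness analyses
#'
#' Re-runs imputation and bootstrapped estimation within each level of a
#' stratification variable, dropping that variable from the regression
#' design. Subgroups smaller than \code{min_n} patients are flagged and not
#' estimated.
#'
#' @param data Incomplete \code{trial_data}.
#' @param imp_spec An [imputation_spec()].
#' @param subgroup_var One of the stratification variables (e.g.
#'   \code{"surgery"}, \code{"age_band"}).
#' @param B,seed Bootstrap settings.
#' @param min_n Minimum patients per subgroup.
#' @param ... Passed to [bootstrap_cea()] / [patient_totals()].
#' @return Named list (one element per level) of \code{ce_result}s, or for
#'   flagged subgroups a list with \code{estimated = FALSE} and the count.
#' @export
subgroup_cea <- function(data, imp_spec, subgroup_var, B = 1000, seed = 1L,
                         min_n = 50, ...) {
  if (!subgroup_var %in% DEFAULT_COVARIATES) {
    abort_config("subgroup_var must be a stratification variable")
  }
  pats <- attr(data, "patients") %||% rebuild_patients(data)
  levels_ <- sort(unique(pats[[subgroup_var]]))
  out <- lapply(levels_, function(lv) {
    ids <- pats$patient_id[pats[[subgroup_var]] == lv]
    if (length(ids) < min_n) {
      return(list(estimated = FALSE, n = length(ids),
                  reason = sprintf("fewer than %d patients", min_n)))
    }
    sub <- data[data$patient_id %in% ids, , drop = FALSE]
    sub <- as_trial_data(sub, patients = pats[pats[[subgroup_var]] == lv, ],
                         config = attr(data, "config"))
    imp <- impute(sub, imp_spec)
    draws <- bootstrap_cea(imp, B = B, seed = seed,
                           covariates = setdiff(DEFAULT_COVARIATES, subgroup_var),
                           ...)
    res <- summary(draws)
    res$n <- length(ids)
    res$estimated <- TRUE
    res
  })
  names(out) <- levels_
  structure(out, class = "subgroup_cea", subgroup_var = subgroup_var)
}

#' Mammogram unit-cost sensitivity analysis
#'
#' Re-costs the mammogram category at each unit cost on the grid, re-runs
#' the bootstrap pipeline under the same seed, and reports the INMB at the
#' given threshold per grid point. When the less-frequent arm undergoes
#' fewer mammograms, the INMB is non-decreasing in the unit cost.
#'
#' @param imp An \code{imputed_set} (or complete \code{trial_data}).
#' @param unit_costs Grid of mammogram unit costs (defaults: the 33 /
#'   115.25 / 272 GBP low, base and high estimates).
#' @param lambda Willingness-to-pay threshold for the INMB.
#' @param B,seed Bootstrap settings.
#' @param ... Passed to [bootstrap_cea()].
#' @return Data frame: one row per unit cost with incremental cost/QALY and
#'   INMB (bootstrap means).
#' @export
unit_cost_sensitivity <- function(imp, unit_costs = c(33, 115.25, 272),
                                  lambda = 20000, B = 1000, seed = 1L, ...) {
  if (any(unit_costs < 0)) abort_config("unit costs must be >= 0")
  rows <- lapply(unit_costs, function(uc) {
    draws <- bootstrap_cea(imp, B = B, seed = seed,
                           mammogram_unit_cost = uc, ...)
    data.frame(unit_cost = uc,
               delta_cost = mean(draws$delta_cost),
               delta_qaly = mean(draws$delta_qaly),
               inmb = mean(inmb(draws$delta_cost, draws$delta_qaly, lambda)),
               lambda = lambda)
  })
  do.call(rbind, rows)
}

#' Cost-effectiveness plane / CEAC plots
#'
#' @param draws A \code{ce_draws}.
#' @param wtp Thresholds drawn as reference lines on the plane.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(draws, wtp = c(20000, 30000)) {
  df <- as.data.frame(draws)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_qaly,
                                        y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (GBP)")
  for (l in wtp) p <- p + ggplot2::geom_abline(slope = l, intercept = 0,
                                               linetype = "dashed")
  p
}

#' @rdname plot_ce_plane
#' @param ceac_df Output of [ceac()].
#' @export
plot_ceac <- function(ceac_df) {
  ggplot2::ggplot(ceac_df, ggplot2::aes(x = .data$lambda,
                                        y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (GBP/QALY)",
                  y = "Probability cost-effective")
}
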