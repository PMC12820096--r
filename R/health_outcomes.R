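#' QALYs by the area-under-the-curve method
#'
#' Integrates a patient's utility trajectory over follow-up by the
#' trapezoidal rule. Utilities between visits are linearly interpolated.
#' Death handling: utility is 0 from death onwards; between the last
#' observation and death the default rule interpolates linearly down to 0 at
#' the time of death (\code{death_rule = "linear_to_zero"}); the alternative
#' carries the last observed utility forward to death
#' (\code{death_rule = "locf"}). Patients alive at last contact (censored)
#' contribute up to their final observation -- no extrapolation beyond it.
#'
#' @param times Numeric vector of observation times (years from
#'   randomisation), strictly increasing.
#' @param utilities Utility index at each time (complete; run imputation
#'   first if values are missing).
#' @param death_time Time of death in years, or \code{NA} if alive at last
#'   contact.
#' @param death_rule \code{"linear_to_zero"} (default) or \code{"locf"}.
#' @param horizon Optional analysis horizon in years; integration is
#'   truncated there (default \code{Inf}, no truncation).
#' @return QALYs (years).
#' @examples
#' qaly_auc(c(0, 1, 2), c(0.8, 0.8, 0.6))            # 1.5
#' qaly_auc(c(0, 1), c(0.8, 0.6), death_time = 1.5)  # 0.85
#' @export
qaly_auc <- function(times, utilities, death_time = NA_real_,
                     death_rule = c("linear_to_zero", "locf"),
                     horizon = Inf) {
  death_rule <- match.arg(death_rule)
  if (length(times) != length(utilities) || length(times) < 1) {
    abort_config("times and utilities must be equal-length, non-empty")
  }
  if (anyNA(utilities)) abort_config("utilities contain missing values; impute first")
  if (is.unsorted(times, strictly = TRUE)) {
    abort_config("observation times must be strictly increasing")
  }
  if (!is.na(death_time) && death_time < max(times)) {
    abort_config("observations recorded after death_time")
  }
  tt <- times
  uu <- utilities
  if (!is.na(death_time) && death_time > max(times)) {
    # append the death segment under the chosen rule, then utility 0 onwards
    if (death_rule == "locf") {
      tt <- c(tt, death_time, death_time)
      uu <- c(uu, uu[length(uu)], 0)
    } else {
      tt <- c(tt, death_time)
      uu <- c(uu, 0)
    }
  }
  if (is.finite(horizon)) {
    if (horizon <= tt[1]) return(0)
    if (horizon < max(tt)) {
      u_h <- approx(tt, uu, xout = horizon, ties = "ordered")$y
      keep <- tt < horizon
      tt <- c(tt[keep], horizon)
      uu <- c(uu[keep], u_h)
    }
  }
  if (length(tt) < 2) return(0)
  sum(diff(tt) * (head(uu, -1) + uu[-1]) / 2)
}

#' Life years during follow-up
#'
#' Years alive between trial entry and death or censoring, truncated at the
#' analysis horizon (5 years in the base case, 6 in the extended analysis).
#'
#' @param entry_time Entry time in years (0 at randomisation).
#' @param death_or_censor_time Death or censoring time in years.
#' @param horizon Analysis horizon in years from entry (default 5).
#' @return Years alive during follow-up.
#' @export
life_years <- function(entry_time, death_or_censor_time, horizon = 5) {
  if (any(death_or_censor_time < entry_time)) {
    abort_config("death/censor time precedes entry time")
  }
  pmin(death_or_censor_time, entry_time + horizon) - entry_time
}
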