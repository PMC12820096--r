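#' Unit costs and inflation indices
#'
#' Unit-cost and inflation tables are external, editable resources with
#' shipped defaults. The default surveillance-mammogram unit cost is the
#' NHS Cost Collection screening-mammogram cost of 115.25 GBP (2023), with
#' sensitivity bounds of 33 and 272 GBP reflecting the range reported by
#' participating trusts. Healthcare amounts are inflated with the NHS Cost
#' Inflation Index (NHSCII); out-of-pocket and productivity amounts with the
#' ONS Consumer Price Inflation index (CPI). The shipped index series are
#' illustrative placeholders, not the national compendia, which are not
#' redistributed.
#'
#' @name cost-tables
NULL

#' @rdname cost-tables
#' @return [default_unit_costs()]: data.frame with columns \code{item},
#'   \code{unit_cost_gbp}, \code{price_year}, \code{index_type}.
#' @export
default_unit_costs <- function() {
  read_unit_costs(system.file("extdata", "unit_costs.csv",
                              package = "ceasurv", mustWork = TRUE))
}

#' @rdname cost-tables
#' @param path CSV path.
#' @export
read_unit_costs <- function(path) {
  uc <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("item", "unit_cost_gbp", "price_year", "index_type")
  if (!all(need %in% names(uc))) {
    abort_config(sprintf("unit-cost table needs columns: %s",
                         paste(need, collapse = ", ")))
  }
  if (any(uc$unit_cost_gbp < 0)) abort_config("unit costs must be >= 0")
  uc
}

#' @rdname cost-tables
#' @return [default_inflation_index()]: data.frame with columns
#'   \code{index_type}, \code{year}, \code{value}.
#' @export
default_inflation_index <- function() {
  ix <- read.csv(system.file("extdata", "inflation_indices.csv",
                             package = "ceasurv", mustWork = TRUE),
                 stringsAsFactors = FALSE)
  if (any(ix$value <= 0)) abort_config("inflation index values must be positive")
  ix
}

#' Inflate an amount between price years
#'
#' \code{amount * index(to_year) / index(from_year)} under the named index
#' series (\code{"NHSCII"} for healthcare costs, \code{"CPI"} for
#' non-healthcare expenses).
#'
#' @param amount Amount in GBP.
#' @param from_year,to_year Price years; both must be covered by the index.
#' @param index Inflation-index table ([default_inflation_index()] format).
#' @param type Index series name.
#' @return Inflated amount in GBP.
#' @export
inflate <- function(amount, from_year, to_year,
                    index = default_inflation_index(), type = "NHSCII") {
  sub <- index[index$index_type == type, , drop = FALSE]
  if (nrow(sub) == 0) abort_config(sprintf("unknown index type '%s'", type))
  v_from <- sub$value[match(from_year, sub$year)]
  v_to <- sub$value[match(to_year, sub$year)]
  if (anyNA(v_from) || anyNA(v_to)) {
    abort_config(sprintf("index '%s' does not cover years %s",
                         type, paste(unique(c(from_year, to_year)), collapse = ", ")))
  }
  amount * v_to / v_from
}

#' Cost of surveillance mammograms
#'
#' Mammogram visit counts (scheduled and patient-requested alike) are costed
#' at a single unit cost per mammogram.
#'
#' @param visits Non-negative mammogram counts.
#' @param unit_cost Unit cost in GBP (default 115.25).
#' @return Cost in GBP, same length as \code{visits}.
#' @export
cost_mammograms <- function(visits, unit_cost = 115.25) {
  if (any(visits < 0)) abort_config("mammogram counts must be >= 0")
  if (unit_cost < 0) abort_config("unit cost must be >= 0")
  visits * unit_cost
}

#' Per-patient cost breakdown over follow-up
#'
#' Sums each of the 14 cost categories over a patient's timepoints,
#' producing one row per patient. Requires complete cost data (run
#' imputation first, or pass a complete synthetic dataset).
#'
#' @param data A \code{trial_data} long-format dataset.
#' @param mammogram_unit_cost If non-\code{NULL}, the mammogram category is
#'   re-costed as \code{mammograms x unit cost} (used by the unit-cost
#'   sensitivity analysis); otherwise the stored \code{cost_mammogram}
#'   amounts are summed as-is.
#' @return A \code{cost_breakdown}: data.frame with \code{patient_id} and
#'   one \code{cost_<category>} column per category.
#' @export
cost_breakdown <- function(data, mammogram_unit_cost = NULL) {
  cols <- cost_col(ALL_CATEGORIES)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort_config(sprintf("dataset lacks cost columns: %s",
                         paste(missing_cols, collapse = ", ")))
  }
  d <- as.data.frame(data)
  if (!is.null(mammogram_unit_cost)) {
    d$cost_mammogram <- cost_mammograms(d$mammograms, mammogram_unit_cost)
  }
  agg <- aggregate(d[cols], by = list(patient_id = d$patient_id), FUN = sum)
  agg <- agg[order(agg$patient_id), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, class = c("cost_breakdown", "data.frame"),
            excluded = character(0))
}

#' Total cost under a costing perspective
#'
#' The healthcare (NHS + Personal Social Services) perspective sums
#' community-based health/social care, prescribed medications, admitted
#' patient care, outpatient care and mammograms. The societal perspective
#' adds the nine patient- and productivity-cost categories.
#'
#' @param breakdown A [cost_breakdown()].
#' @param perspective \code{"healthcare"} or \code{"societal"}.
#' @return Numeric vector of per-patient totals (GBP), aligned with
#'   \code{breakdown} rows.
#' @export
assemble_perspective <- function(breakdown,
                                 perspective = c("healthcare", "societal")) {
  perspective <- match.arg(perspective)
  cats <- switch(perspective,
                 healthcare = HEALTHCARE_CATEGORIES,
                 societal = ALL_CATEGORIES)
  cols <- cost_col(cats)
  m <- as.matrix(as.data.frame(breakdown)[, cols, drop = FALSE])
  if (anyNA(m)) abort_config("unpriced (missing) category values in breakdown")
  unname(rowSums(m))
}

#' Zero out a cost category (sensitivity analyses)
#'
#' Returns the breakdown with the named category set to zero; the exclusion
#' is recorded in the \code{excluded} attribute for provenance. Used e.g.
#' for the analysis excluding outpatient-care costs.
#'
#' @param breakdown A [cost_breakdown()].
#' @param category One of the 14 category names (e.g. \code{"outpatient"}).
#' @return Modified \code{cost_breakdown}.
#' @export
exclude_category <- function(breakdown, category) {
  if (!category %in% ALL_CATEGORIES) {
    abort_config(sprintf("unknown cost category '%s'", category))
  }
  breakdown[[cost_col(category)]] <- 0
  attr(breakdown, "excluded") <- union(attr(breakdown, "excluded"), category)
  breakdown
}
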