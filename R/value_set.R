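#' EQ-5D-5L profiles and value-set tables
#'
#' An EQ-5D-5L profile records one level (1 = no problems ... 5 = extreme
#' problems) on each of five dimensions: mobility, self-care, usual
#' activities, pain/discomfort and anxiety/depression, giving 5^5 = 3,125
#' possible health states. A value set maps every profile to a utility index
#' anchored at 1 for full health (profile \code{"11111"}), with values below
#' 0 representing states valued as worse than dead.
#'
#' @name value-set
NULL

#' Enumerate all EQ-5D-5L profiles
#'
#' @return Character vector of the 3,125 five-digit profile strings, in
#'   lexicographic order (\code{"11111"} first, \code{"55555"} last).
#' @export
eq5d_profiles <- function() {
  g <- expand.grid(ad = 1:5, pd = 1:5, ua = 1:5, sc = 1:5, mo = 1:5)
  sort(paste0(g$mo, g$sc, g$ua, g$pd, g$ad))
}

#' Synthetic EQ-5D-5L to 3L-scale value set
#'
#' Builds a complete value-set table covering all 3,125 EQ-5D-5L profiles
#' using an additive decrement model. This is a *synthetic* stand-in for the
#' published (licensed) 5L-to-3L crosswalk: it reproduces the anchors and
#' range of the UK 3L scale -- profile \code{11111} maps to 1.0 and profile
#' \code{55555} maps to -0.594, the floor of the 3L value set -- with
#' monotone, dimension-specific decrements in between. It is suitable for
#' simulation and testing; analyses of real trial data should supply the
#' licensed crosswalk via [read_value_set()].
#'
#' @param max_decrements Named numeric vector of length 5: utility loss at
#'   level 5 for each dimension (mobility, self-care, usual activities,
#'   pain/discomfort, anxiety/depression). Must sum to 1.594 for the default
#'   anchors to hold.
#' @param level_weights Fraction of the maximum decrement incurred at levels
#'   1--5 (monotone non-decreasing, 0 at level 1, 1 at level 5).
#' @return A \code{value_set} object: data.frame with columns \code{profile}
#'   (5-digit string) and \code{index} (numeric utility).
#' @export
synthetic_value_set <- function(max_decrements = c(mobility = 0.30,
                                                   self_care = 0.29,
                                                   usual_activities = 0.25,
                                                   pain = 0.40,
                                                   anxiety = 0.354),
                                level_weights = c(0, 0.22, 0.45, 0.78, 1)) {
  if (length(max_decrements) != 5 || any(max_decrements < 0)) {
    abort_config("max_decrements must be 5 non-negative values")
  }
  if (length(level_weights) != 5 || is.unsorted(level_weights) ||
      level_weights[1] != 0 || level_weights[5] != 1) {
    abort_config("level_weights must be non-decreasing from 0 to 1 over 5 levels")
  }
  profiles <- eq5d_profiles()
  lv <- matrix(as.integer(unlist(strsplit(profiles, ""))),
               ncol = 5, byrow = TRUE)
  dec <- matrix(level_weights[lv], ncol = 5) *
    matrix(max_decrements, nrow = nrow(lv), ncol = 5, byrow = TRUE)
  vs <- data.frame(profile = profiles, index = 1 - rowSums(dec),
                   stringsAsFactors = FALSE)
  validate_value_set(vs)
}

validate_value_set <- function(vs) {
  if (!all(c("profile", "index") %in% names(vs))) {
    abort_config("value set needs columns 'profile' and 'index'")
  }
  vs$profile <- as.character(vs$profile)
  if (anyDuplicated(vs$profile)) abort_config("duplicated profiles in value set")
  if (!setequal(vs$profile, eq5d_profiles())) {
    abort_config("value set must cover all 3,125 EQ-5D-5L profiles exactly")
  }
  if (any(vs$index > 1 + 1e-12)) abort_config("utility indices must not exceed 1")
  if (abs(vs$index[match("11111", vs$profile)] - 1) > 1e-12) {
    abort_config("profile 11111 must map to 1.0")
  }
  vs <- vs[order(vs$profile), , drop = FALSE]
  rownames(vs) <- NULL
  structure(vs, class = c("value_set", "data.frame"))
}

#' Read / write a value-set table
#'
#' CSV format: columns \code{profile} (5-digit string) and \code{index}.
#' @param path File path.
#' @param vs A \code{value_set}.
#' @return [read_value_set()] returns a validated \code{value_set}.
#' @export
read_value_set <- function(path) {
  vs <- read.csv(path, colClasses = c(profile = "character"))
  validate_value_set(vs)
}

#' @rdname read_value_set
#' @export
write_value_set <- function(vs, path) {
  write.csv(as.data.frame(vs)[, c("profile", "index")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Look up utility indices for EQ-5D-5L profiles
#'
#' Pure table lookup (no interpolation) of the utility index for each
#' profile, as used when mapping 5L descriptive-system responses onto a 3L
#' value-set scale.
#'
#' @param profile Character vector of 5-digit profiles, or an integer matrix
#'   with 5 columns of levels in 1..5.
#' @param table A \code{value_set}.
#' @return Numeric utility indices, same length as \code{profile}.
#' @export
crosswalk_index <- function(profile, table) {
  if (is.matrix(profile)) {
    if (ncol(profile) != 5) abort_config("profile matrix needs 5 columns")
    profile <- apply(profile, 1, paste0, collapse = "")
  }
  profile <- as.character(profile)
  bad <- !grepl("^[1-5]{5}$", profile) & !is.na(profile)
  if (any(bad)) {
    abort_config(sprintf("invalid EQ-5D-5L profile(s): %s",
                         paste(unique(profile[bad]), collapse = ", ")))
  }
  idx <- match(profile, table$profile)
  if (any(is.na(idx) & !is.na(profile))) {
    abort_config("profile absent from value-set table")
  }
  table$index[idx]
}
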