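# Shift arithmetic and small shared helpers.
#
# Shifts are 12-hour rotations anchored at 07:00 and 19:00 wall clock:
# day = [07:00, 19:00), night = [19:00, 07:00). Internally every wall-clock
# time maps to an absolute shift index (number of 07:00/19:00 boundaries
# since the epoch); even indices are day shifts, odd are night shifts.

SHIFT_MINUTES <- 720L
DAY_START_MIN <- 420L   # 07:00 as minute-of-day

#' Absolute shift index of a wall-clock time
#'
#' @param wall POSIXct vector (UTC recommended).
#' @return Integer vector; consecutive shifts have consecutive indices, and
#'   even parity corresponds to day shifts.
#' @keywords internal
shift_index <- function(wall) {
  m <- as.numeric(wall) / 60  # minutes since epoch
  as.integer(floor((m - DAY_START_MIN) / SHIFT_MINUTES))
}

#' Shift type ("day"/"night") of an absolute shift index
#' @keywords internal
shift_type_of_index <- function(idx) {
  ifelse(idx %% 2L == 0L, "day", "night")
}

#' Is a wall-clock time within the day shift window [07:00, 19:00)?
#' @keywords internal
is_day_clock <- function(wall) {
  mod <- as.POSIXlt(wall, tz = "UTC")
  mins <- mod$hour * 60L + mod$min
  mins >= DAY_START_MIN & mins < (DAY_START_MIN + SHIFT_MINUTES)
}

# Generic-role abbreviations used to build functional-role labels
# (service prefix + "_" + abbreviation), following the conventions of
# clinical network diagrams (AT attending, R resident, RN nurse, ...).
ROLE_ABBREV <- c(
  attending                = "AT",
  resident                 = "R",
  fellow                   = "F",
  registered_nurse         = "RN",
  nurse_practitioner       = "NP",
  physician_assistant      = "PA",
  radiology_technician     = "Rad_Tech",
  nurse_technician         = "RN_Tech",
  social_worker            = "SW",
  child_life_specialist    = "CLS",
  case_manager             = "CM",
  dietitian                = "DT",
  pharmacist               = "Pharm",
  physical_therapist       = "PT",
  occupational_therapist   = "OT",
  home_care_coordinator    = "HCC",
  imaging_data_coordinator = "IDC",
  chaplain                 = "Chap"
)

# Location-bound services: care locations double as the service prefix for
# unit-based staff (nurses, unit NPs, allied professionals).
LOCATION_SERVICE <- c(ED = "ED", FLOOR = "Floor", PICU = "PICU")

ACTIVITY_TYPES <- c("note", "procedure_order", "medication_order",
                    "flowsheet", "medication_admin")

CARE_LOCATIONS <- c("ED", "FLOOR", "PICU")

#' Abbreviate a generic clinical role
#' @keywords internal
role_abbrev <- function(generic_role) {
  ab <- ROLE_ABBREV[generic_role]
  ifelse(is.na(ab), toupper(generic_role), ab)
}

#' Percentage of a count over a denominator, rounded for reporting
#'
#' Convenience used throughout reports so printed percentages always
#' recompute exactly from the underlying counts.
#'
#' @param n numerator count(s).
#' @param d denominator count.
#' @param digits decimal places (default 1).
#' @return Numeric vector of percentages on the 0-100 scale.
#' @export
#' @examples
#' pct(272, 413)        # 65.9
#' pct(749000, 837318, 2)
pct <- function(n, d, digits = 1) {
  round(100 * n / d, digits)
}

#' Mode with deterministic tie-breaking
#'
#' Returns the most frequent value; ties are broken by smallest `order_key`
#' (e.g. earliest timestamp) and then lexicographically.
#'
#' @param x character vector of values.
#' @param order_key optional numeric of same length; among tied values the
#'   one whose minimum key is smallest wins. Use negative keys to prefer the
#'   most recent instead.
#' @keywords internal
modal_value <- function(x, order_key = NULL) {
  x <- as.character(x)
  keep <- !is.na(x)
  x <- x[keep]
  if (length(x) == 0L) return(NA_character_)
  if (!is.null(order_key)) order_key <- order_key[keep]
  tab <- table(x)
  cand <- names(tab)[tab == max(tab)]
  if (length(cand) == 1L) return(cand)
  if (!is.null(order_key)) {
    first_key <- vapply(cand, function(v) min(order_key[x == v]), numeric(1))
    cand <- cand[first_key == min(first_key)]
  }
  sort(cand)[1L]
}

#' Canonical undirected edge key
#' @keywords internal
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sample that never surprises with the 1:n expansion of sample(x).
sample_vec <- function(x, size = 1L, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}
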