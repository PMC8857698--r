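# Natural-break segmentation: each shift's events are partitioned into
# segments wherever the gap between adjacent events reaches the chosen break
# interval. The interval is selected on a 30-120 minute grid (5-minute
# steps) by two-class Jenks natural-breaks optimization of the pooled
# inter-event gap distribution: the grid point whose split of the gaps into
# {gap < c} vs {gap >= c} maximizes the goodness of variance fit.

#' Collect consecutive-event gaps per (encounter, shift)
#'
#' One gap per adjacent same-shift event pair; same-time fan-out events
#' contribute zero gaps. Input must be sorted by (encounter, shift, t_norm).
#'
#' @param master_log a master event log.
#' @return data.table with `encounter_id`, `shift_number`, `gap` (minutes).
#' @export
collect_gaps <- function(master_log) {
  log <- data.table::as.data.table(master_log)
  unsorted <- log[, any(diff(t_norm) < 0), by = .(encounter_id, shift_number)]
  if (any(unsorted$V1)) {
    stop("collect_gaps: events must be sorted by t_norm within each ",
         "(encounter, shift)")
  }
  gaps <- log[, if (.N > 1L) .(gap = diff(t_norm)) else NULL,
              by = .(encounter_id, shift_number)]
  if (nrow(gaps) == 0L) {
    gaps <- data.table::data.table(encounter_id = character(),
                                   shift_number = integer(), gap = numeric())
  }
  gaps[]
}

#' Goodness of variance fit of a two-class split at a boundary
#'
#' GVF(c) = 1 - SSD_within / SSD_total for the split {gap < c}, {gap >= c},
#' where SSD is the sum of squared deviations from the class (or global)
#' mean; an empty class contributes 0.
#'
#' @param gaps numeric vector of gaps.
#' @param boundary class boundary c.
#' @return GVF in [0, 1]; NaN when SSD_total is 0.
#' @export
gvf_two_class <- function(gaps, boundary) {
  ssd <- function(x) if (length(x) == 0L) 0 else sum((x - mean(x))^2)
  total <- ssd(gaps)
  if (total == 0) return(NaN)
  lo <- gaps[gaps < boundary]
  hi <- gaps[gaps >= boundary]
  1 - (ssd(lo) + ssd(hi)) / total
}

#' Select the natural-break interval by Jenks optimization on a grid
#'
#' Evaluates the two-class GVF at every candidate boundary and returns the
#' smallest candidate attaining the maximum (ties broken towards the finest
#' segmentation consistent with the 30-minute minimum break).
#'
#' @param gaps a gap table from [collect_gaps()], or a numeric vector.
#' @param grid candidate boundaries in minutes (default 30 to 120 by 5).
#' @return Object of class `break_selection`: list with `candidate_grid`,
#'   `gvf_by_candidate`, `chosen_interval`, `degenerate` flag.
#' @export
select_break_interval <- function(gaps, grid = seq(30, 120, by = 5)) {
  g <- if (is.numeric(gaps)) gaps else data.table::as.data.table(gaps)$gap
  if (length(g) == 0L) stop("select_break_interval: no gaps to classify")
  gvf <- vapply(grid, function(c) gvf_two_class(g, c), numeric(1))
  degenerate <- all(is.nan(gvf))
  if (degenerate) {
    warning("select_break_interval: all gaps identical (SSD_total = 0); ",
            "returning the grid minimum")
    chosen <- min(grid)
  } else {
    chosen <- grid[which.max(gvf)]  # first max = smallest candidate
  }
  structure(list(candidate_grid = grid, gvf_by_candidate = gvf,
                 chosen_interval = chosen, degenerate = degenerate),
            class = "break_selection")
}

#' @export
print.break_selection <- function(x, ...) {
  cat("Natural-break selection: chosen interval", x$chosen_interval,
      "min over grid", min(x$candidate_grid), "-", max(x$candidate_grid),
      if (x$degenerate) "(degenerate gaps)" else "", "\n")
  invisible(x)
}

#' Partition each shift's events into natural-break segments
#'
#' A new segment starts exactly when the gap to the previous event reaches
#' the chosen interval (a gap equal to the interval is a break). Segment ids
#' are dense from 0 within each (encounter, shift).
#'
#' @param master_log a master event log sorted by (encounter, shift, time).
#' @param chosen_interval break interval in minutes.
#' @return The log with `segment_id` filled.
#' @export
segment_shifts <- function(master_log, chosen_interval) {
  log <- data.table::copy(data.table::as.data.table(master_log))
  log[, segment_id := {
    g <- c(0, diff(t_norm))
    as.integer(cumsum(g >= chosen_interval))
  }, by = .(encounter_id, shift_number)]
  log[]
}

#' Summarize segments (membership, span, roles present)
#'
#' @param segmented_log log with `segment_id` filled.
#' @return data.table with one row per (encounter, shift, segment): event
#'   count, time span, max internal gap, and roles present.
#' @export
segment_table <- function(segmented_log) {
  log <- data.table::as.data.table(segmented_log)
  log[, .(n_events = .N,
          t_start = min(t_norm), t_end = max(t_norm),
          max_internal_gap = if (.N > 1L) max(diff(t_norm)) else 0,
          roles = list(sort(unique(functional_role)))),
      by = .(encounter_id, shift_number, segment_id)]
}
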