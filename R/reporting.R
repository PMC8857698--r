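# Cohort day/night comparison, sublog composition profiles, and network
# summaries.

#' Day/night split of encounter arrivals
#'
#' @param encounters encounter table with `arrival_clock`.
#' @return data.table with `shift_type`, `n`, `pct` (percentages recompute
#'   exactly from the counts).
#' @export
shift_split <- function(encounters) {
  enc <- data.table::as.data.table(encounters)
  st <- ifelse(is_day_clock(enc$arrival_clock), "day", "night")
  out <- data.table::data.table(shift_type = c("day", "night"),
                                n = c(sum(st == "day"), sum(st == "night")))
  out[, pct := pct(n, sum(n))]
  out[]
}

default_cohort_variables <- function() {
  list(
    interval = c("age_years", "iss", "gcs", "ed_los_minutes", "hosp_los_hours"),
    categorical = c("sex", "activation_level", "origin", "injury_type",
                    "picu_admission", "mortality"))
}

#' Compare day- and night-arrival encounters
#'
#' Interval variables are summarized as median (IQR) and compared with the
#' two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction, no continuity correction); categorical variables as n (%)
#' per level with the Pearson chi-square test without continuity correction.
#' Tests on tables with any expected cell below 5 are flagged unreliable;
#' levels with zero total are dropped with a warning.
#'
#' @param encounters encounter table with `arrival_clock`.
#' @param variables list with `interval` and `categorical` character vectors
#'   naming encounter columns (defaults cover the generator's schema).
#' @return data.table: one row per variable (interval) or per level
#'   (categorical) with day/night summaries, test, statistic, p-value, and a
#'   `reliable` flag.
#' @export
compare_cohort <- function(encounters, variables = default_cohort_variables()) {
  enc <- data.table::as.data.table(encounters)
  is_day <- is_day_clock(enc$arrival_clock)
  n_day <- sum(is_day); n_night <- sum(!is_day)
  rows <- list()

  med_iqr <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    sprintf("%g (%g-%g)", q[2], q[1], q[3])
  }

  for (v in intersect(variables$interval, names(enc))) {
    xd <- enc[[v]][is_day]; xn <- enc[[v]][!is_day]
    wt <- stats::wilcox.test(xd, xn, exact = FALSE, correct = FALSE)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      variable = v, type = "interval", level = NA_character_,
      day = med_iqr(xd), night = med_iqr(xn),
      test = "wilcoxon_rank_sum",
      statistic = unname(wt$statistic), p_value = wt$p.value,
      reliable = TRUE)
  }

  for (v in intersect(variables$categorical, names(enc))) {
    # factors keep their declared levels so empty levels are reported/dropped
    x <- if (is.factor(enc[[v]])) enc[[v]] else as.character(enc[[v]])
    tab <- table(factor(ifelse(is_day, "day", "night"),
                        levels = c("day", "night")), x)
    zero <- colSums(tab) == 0
    if (any(zero)) {
      warning("compare_cohort: dropping empty level(s) of ", v, ": ",
              paste(colnames(tab)[zero], collapse = ", "))
      tab <- tab[, !zero, drop = FALSE]
    }
    if (ncol(tab) < 2L) {
      ct <- list(statistic = NA_real_, p.value = NA_real_, expected = tab)
      reliable <- FALSE
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      reliable <- all(ct$expected >= 5)
    }
    for (lev in colnames(tab)) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        variable = v, type = "categorical", level = lev,
        day = sprintf("%d (%s%%)", tab["day", lev],
                      pct(tab["day", lev], n_day)),
        night = sprintf("%d (%s%%)", tab["night", lev],
                        pct(tab["night", lev], n_night)),
        test = "pearson_chi_square",
        statistic = unname(ct$statistic), p_value = ct$p.value,
        reliable = reliable)
    }
  }
  data.table::rbindlist(rows)
}

#' Activity-type composition of the six sublogs
#'
#' @param segmented_log a segmented master log (events outside ED/floor/PICU
#'   are ignored).
#' @return data.table with `location`, `shift_type`, `activity_type`, `n`,
#'   `frac`; fractions sum to 1 within each non-empty sublog. Empty sublogs
#'   yield all-zero rows and a message.
#' @export
sublog_composition <- function(segmented_log) {
  log <- data.table::as.data.table(segmented_log)
  log <- log[care_location %in% CARE_LOCATIONS]
  grid <- data.table::CJ(location = CARE_LOCATIONS,
                         shift_type = c("day", "night"),
                         activity_type = ACTIVITY_TYPES)
  counts <- log[, .(n = .N), by = .(location = care_location, shift_type,
                                    activity_type)]
  out <- merge(grid, counts, all.x = TRUE,
               by = c("location", "shift_type", "activity_type"))
  out[is.na(n), n := 0L]
  out[, frac := if (sum(n) > 0) n / sum(n) else rep(0, .N),
      by = .(location, shift_type)]
  empty <- out[, .(tot = sum(n)), by = .(location, shift_type)][tot == 0]
  if (nrow(empty)) {
    message("sublog_composition: empty sublog(s): ",
            paste(empty$location, empty$shift_type, sep = "/", collapse = ", "))
  }
  data.table::setorder(out, location, shift_type, activity_type)
  out[]
}

#' Per-sublog network summary
#'
#' @param pruned a pruned `collab_network`.
#' @param lc the matching `link_communities` (or NULL).
#' @param curve the matching `threshold_curve` (or NULL).
#' @return One-row data.table of headline counts.
#' @export
network_summary <- function(pruned, lc = NULL, curve = NULL) {
  data.table::data.table(
    sublog = pruned$key,
    n_nodes = length(pruned$connected_nodes),
    n_edges = nrow(pruned$edges),
    threshold = pruned$threshold,
    n_communities = if (is.null(lc)) NA_integer_ else length(lc$communities),
    partition_density = if (is.null(lc)) NA_real_ else lc$D,
    roles_in_all_communities = if (is.null(lc)) NA_character_ else
      paste(roles_in_all_communities(lc), collapse = ";"))
}
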