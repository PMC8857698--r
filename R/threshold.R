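# Shared-shift edge thresholding. Sweeping the threshold from 2 to 20
# removes trivial and spurious edges; the rate of change of the total number
# of edges removed is smoothed with locally weighted regression (LOWESS) and
# the elbow -- the smallest threshold at which the rate of change becomes
# insignificant or constant -- is taken as the operating threshold.

#' Threshold-selection configuration
#'
#' @param t_min,t_max sweep range of shared-shift thresholds (default 2-20).
#' @param lowess_fraction LOWESS smoother span f in (0, 1].
#' @param elbow_epsilon insignificance fraction: the elbow is the smallest
#'   threshold from which all smoothed rates stay at or below
#'   `elbow_epsilon * max(smoothed rate)`.
#' @return List of class `threshold_config`.
#' @export
threshold_config <- function(t_min = 2L, t_max = 20L,
                             lowess_fraction = 0.5, elbow_epsilon = 0.10) {
  stopifnot(lowess_fraction > 0, lowess_fraction <= 1,
            elbow_epsilon > 0, elbow_epsilon < 1, t_min < t_max)
  structure(list(t_min = as.integer(t_min), t_max = as.integer(t_max),
                 lowess_fraction = lowess_fraction,
                 elbow_epsilon = elbow_epsilon),
            class = "threshold_config")
}

#' Sweep shared-shift thresholds over a network
#'
#' Thresholding uses the raw `co_segment_shifts` counts (not the normalized
#' weights). At each threshold t, edges with count >= t remain. The first
#' sweep point already removes singleton (count 1) edges; their total is
#' kept in the `n_singleton` field for transparency.
#'
#' @param network a `collab_network`.
#' @param config a [threshold_config()].
#' @return Object of class `threshold_curve`: data.table `curve`
#'   (`threshold`, `edges_remaining`, `edges_removed`, `removed_delta`),
#'   plus `n_edges_total`, `n_singleton`; `smoothed_delta` and `elbow` are
#'   filled by [smooth_curve()] / [detect_elbow()].
#' @export
sweep_thresholds <- function(network, config = threshold_config()) {
  stopifnot(inherits(network, "collab_network"))
  counts <- network$edges$co_segment_shifts
  thresholds <- seq(config$t_min, config$t_max)
  remaining <- vapply(thresholds, function(t) sum(counts >= t), integer(1))
  removed <- length(counts) - remaining
  curve <- data.table::data.table(
    threshold = thresholds,
    edges_remaining = remaining,
    edges_removed = removed,
    removed_delta = c(removed[1L], diff(removed)))
  structure(list(key = network$key, curve = curve,
                 n_edges_total = length(counts),
                 n_singleton = sum(counts == 1L),
                 config = config, elbow = NA_integer_),
            class = "threshold_curve")
}

#' LOWESS-smooth the rate-of-change curve
#'
#' Locally weighted linear regression of `removed_delta` against threshold
#' with span `lowess_fraction`; smoothed values are clipped at 0. With fewer
#' than 3 sweep points the raw deltas are used unchanged, with a warning.
#'
#' @param tcurve a `threshold_curve` from [sweep_thresholds()].
#' @param config a [threshold_config()] (defaults to the one used in the
#'   sweep).
#' @return The curve with a `smoothed_delta` column.
#' @export
smooth_curve <- function(tcurve, config = tcurve$config) {
  stopifnot(inherits(tcurve, "threshold_curve"))
  cv <- tcurve$curve
  if (nrow(cv) < 3L) {
    warning("smooth_curve: fewer than 3 points; using raw deltas")
    cv[, smoothed_delta := as.numeric(removed_delta)]
  } else {
    # iter = 0: plain locally weighted regression. Robustness iterations
    # would treat the initial removal spike -- the very feature the elbow
    # is judged against -- as an outlier and erase it.
    sm <- stats::lowess(cv$threshold, cv$removed_delta,
                        f = config$lowess_fraction, iter = 0)
    cv[, smoothed_delta := pmax(0, sm$y)]
  }
  tcurve$curve <- cv
  tcurve
}

#' Detect the elbow of a smoothed threshold curve
#'
#' The elbow is the smallest threshold t such that the smoothed rate of
#' change at every t' >= t is at most `elbow_epsilon` times its maximum --
#' the point from which further threshold increases remove a negligible
#' number of edges. An (approximately) constant rate of change has no elbow
#' structure and yields `t_min`; when the rate never becomes insignificant
#' the detector falls back to `t_max` with a warning.
#'
#' @param tcurve a smoothed `threshold_curve`.
#' @param config a [threshold_config()].
#' @return The curve with `elbow` set.
#' @export
detect_elbow <- function(tcurve, config = tcurve$config) {
  stopifnot(inherits(tcurve, "threshold_curve"))
  cv <- tcurve$curve
  if (!"smoothed_delta" %in% names(cv)) {
    stop("detect_elbow: smooth the curve first (smooth_curve)")
  }
  s <- cv$smoothed_delta
  mx <- max(s)
  if (mx == 0) {
    warning("detect_elbow: rate of change identically zero; elbow at t_min")
    tcurve$elbow <- cv$threshold[1L]
    return(tcurve)
  }
  if (mx - min(s) <= config$elbow_epsilon * mx) {
    # constant rate of change: no elbow structure, keep the smallest threshold
    tcurve$elbow <- cv$threshold[1L]
    return(tcurve)
  }
  suffix_max <- rev(cummax(rev(s)))
  ok <- suffix_max <= config$elbow_epsilon * mx
  if (!any(ok)) {
    warning("detect_elbow: rate of change never becomes insignificant; ",
            "elbow at t_max")
    tcurve$elbow <- cv$threshold[nrow(cv)]
  } else {
    tcurve$elbow <- cv$threshold[which(ok)[1L]]
  }
  tcurve
}

#' Apply a shared-shift threshold to a network
#'
#' Keeps edges with `co_segment_shifts >= threshold` (weights unchanged) and
#' drops nodes left isolated.
#'
#' @param network a `collab_network`.
#' @param threshold integer threshold, typically the detected elbow.
#' @return The pruned `collab_network` with `threshold` recorded.
#' @export
apply_threshold <- function(network, threshold) {
  stopifnot(inherits(network, "collab_network"))
  edges <- network$edges[co_segment_shifts >= threshold]
  new_collab_network(network$key,
                     sort(unique(c(edges$role_a, edges$role_b))),
                     edges, network$n_events, threshold = as.integer(threshold))
}

#' Select and apply the elbow threshold in one call
#'
#' @param network a `collab_network`.
#' @param config a [threshold_config()].
#' @return List with `network` (pruned), `curve` (smoothed, elbow set).
#' @export
threshold_network <- function(network, config = threshold_config()) {
  tc <- detect_elbow(smooth_curve(sweep_thresholds(network, config), config),
                     config)
  list(network = apply_threshold(network, tc$elbow), curve = tc)
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat("Threshold sweep", if (!is.na(x$key %||% NA)) paste0("[", x$key, "]") else "",
      ": ", x$n_edges_total, " edges (", x$n_singleton, " singleton); elbow ",
      ifelse(is.na(x$elbow), "not set", x$elbow), "\n", sep = "")
  invisible(x)
}

#' Plot a threshold rate-of-change curve
#'
#' Raw rate of change (points), LOWESS curve (line), and the selected elbow
#' (vertical line), mirroring the visual threshold-selection workflow.
#'
#' @param x a `threshold_curve`; @param ... passed to `plot`.
#' @export
plot.threshold_curve <- function(x, ...) {
  cv <- x$curve
  plot(cv$threshold, cv$removed_delta, type = "p", pch = 16, col = "grey50",
       xlab = "threshold (shared shifts)", ylab = "edges removed per step",
       main = x$key %||% "", ...)
  if ("smoothed_delta" %in% names(cv)) {
    graphics::lines(cv$threshold, cv$smoothed_delta, lwd = 2)
  }
  if (!is.na(x$elbow)) graphics::abline(v = x$elbow, col = "red")
  invisible(x)
}
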