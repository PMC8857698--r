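# Sublog splitting and construction of the weighted "working closely
# together" networks. The counting unit is the patient-shift: functional
# roles involved in the care of the same patient during the same shift had
# the opportunity to work together; roles captured within the same natural-
# break segment were working closely together. Edge weight =
# (shifts in which the pair shared a segment) /
# (shifts in which both roles were involved).

sublog_keys <- function() {
  data.table::CJ(location = CARE_LOCATIONS, shift_type = c("day", "night"))
}

#' Split a segmented master log into the six sublogs
#'
#' Partitions by (care location, shift type); events at locations other than
#' ED/FLOOR/PICU are dropped (count reported via the `"n_dropped"`
#' attribute).
#'
#' @param segmented_log master log with `segment_id` filled.
#' @return Named list of six data.tables keyed `"<location>.<shift_type>"`,
#'   e.g. `"ED.night"`; class `sublogs`.
#' @export
split_sublogs <- function(segmented_log) {
  log <- data.table::as.data.table(segmented_log)
  in_scope <- !is.na(log$care_location) & log$care_location %in% CARE_LOCATIONS
  n_dropped <- sum(!in_scope)
  log <- log[in_scope]
  keys <- sublog_keys()
  out <- lapply(seq_len(nrow(keys)), function(i) {
    log[care_location == keys$location[i] & shift_type == keys$shift_type[i]]
  })
  names(out) <- paste(keys$location, keys$shift_type, sep = ".")
  data.table::setattr(out, "n_dropped", n_dropped)
  class(out) <- c("sublogs", class(out))
  out
}

#' Build the collaboration network of one sublog
#'
#' For every segment, all pairwise combinations of the distinct functional
#' roles present are marked as co-segmented for that (encounter, shift); a
#' pair co-segmented several times within one shift counts once. Edge counts:
#' `co_segment_shifts` = distinct (encounter, shift) pairs sharing a
#' segment; `co_present_shifts` = distinct (encounter, shift) pairs where
#' both roles have at least one event in this sublog; `weight` = the ratio.
#'
#' @param sublog one element of [split_sublogs()] output.
#' @param key optional sublog key label (e.g. `"ED.night"`).
#' @return Object of class `collab_network`: list with `key`, `nodes` (all
#'   roles seen), `connected_nodes`, `edges` (data.table `role_a`, `role_b`,
#'   `co_segment_shifts`, `co_present_shifts`, `weight`), `n_events`,
#'   `threshold` (NA until pruning).
#' @export
build_collaboration_network <- function(sublog, key = NA_character_) {
  log <- data.table::as.data.table(sublog)
  log <- log[!is.na(functional_role)]
  nodes <- sort(unique(log$functional_role))

  if (nrow(log) == 0L) {
    return(new_collab_network(key, nodes, empty_edges(), 0L))
  }

  pair_expand <- function(dt) {
    # dt: one row per (group, role); emit all role pairs per group
    dt[, if (.N > 1L) {
      cmb <- utils::combn(sort(role), 2L)
      .(role_a = cmb[1L, ], role_b = cmb[2L, ])
    } else NULL, by = .(encounter_id, shift_number)]
  }

  seg_roles <- unique(log[, .(encounter_id, shift_number, segment_id,
                              role = functional_role)])
  co_seg <- seg_roles[, if (.N > 1L) {
    cmb <- utils::combn(sort(unique(role)), 2L)
    if (ncol(cmb)) .(role_a = cmb[1L, ], role_b = cmb[2L, ]) else NULL
  } else NULL, by = .(encounter_id, shift_number, segment_id)]
  if (nrow(co_seg) == 0L) {
    return(new_collab_network(key, nodes, empty_edges(), nrow(log)))
  }
  co_seg <- unique(co_seg[, .(encounter_id, shift_number, role_a, role_b)])
  seg_counts <- co_seg[, .(co_segment_shifts = .N), by = .(role_a, role_b)]

  shift_roles <- unique(log[, .(encounter_id, shift_number,
                                role = functional_role)])
  co_pres <- pair_expand(shift_roles)
  pres_counts <- co_pres[, .(co_present_shifts = .N), by = .(role_a, role_b)]

  edges <- merge(seg_counts, pres_counts, by = c("role_a", "role_b"))
  edges[, weight := co_segment_shifts / co_present_shifts]
  data.table::setorder(edges, role_a, role_b)
  new_collab_network(key, nodes, edges, nrow(log))
}

empty_edges <- function() {
  data.table::data.table(role_a = character(), role_b = character(),
                         co_segment_shifts = integer(),
                         co_present_shifts = integer(), weight = numeric())
}

new_collab_network <- function(key, nodes, edges, n_events,
                               threshold = NA_integer_) {
  structure(list(key = key, nodes = nodes,
                 connected_nodes = sort(unique(c(edges$role_a, edges$role_b))),
                 edges = edges, n_events = n_events, threshold = threshold),
            class = "collab_network")
}

#' @export
print.collab_network <- function(x, ...) {
  cat("Collaboration network", if (!is.na(x$key)) paste0("[", x$key, "]") else "",
      ":", length(x$connected_nodes), "connected nodes (",
      length(x$nodes), "seen ),", nrow(x$edges), "edges",
      if (!is.na(x$threshold)) paste0("; threshold ", x$threshold) else "",
      "\n")
  invisible(x)
}

#' Convert a collaboration network to an igraph object
#'
#' @param network a `collab_network`.
#' @param include_isolated keep roles never co-segmented with anyone
#'   (default FALSE, matching figure conventions that show connected roles).
#' @return An igraph undirected weighted graph with edge attributes
#'   `weight`, `co_segment_shifts`, `co_present_shifts`.
#' @export
as_igraph <- function(network, include_isolated = FALSE) {
  stopifnot(inherits(network, "collab_network"))
  verts <- if (include_isolated) network$nodes else network$connected_nodes
  igraph::graph_from_data_frame(
    network$edges[, .(from = role_a, to = role_b, weight,
                      co_segment_shifts, co_present_shifts)],
    directed = FALSE,
    vertices = data.frame(name = verts))
}

#' Write a network as GraphML and edge-list CSV
#'
#' @param network a `collab_network`.
#' @param path_base file path without extension; writes
#'   `<path_base>.graphml` and `<path_base>_edges.csv`.
#' @return Invisibly, the two paths.
#' @export
write_network <- function(network, path_base) {
  g <- as_igraph(network, include_isolated = TRUE)
  graphml <- paste0(path_base, ".graphml")
  csv <- paste0(path_base, "_edges.csv")
  igraph::write_graph(g, graphml, format = "graphml")
  data.table::fwrite(network$edges, csv)
  invisible(c(graphml = graphml, edges = csv))
}
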