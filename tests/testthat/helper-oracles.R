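# Independent brute-force oracles. These deliberately re-derive each
# quantity from first principles (sums, exhaustive enumeration) without
# touching the package's implementation paths.

# Two-class goodness of variance fit, written directly from the definition.
oracle_gvf <- function(gaps, boundary) {
  ssd <- function(x) if (!length(x)) 0 else sum((x - mean(x))^2)
  tot <- ssd(gaps)
  if (tot == 0) return(NaN)
  1 - (ssd(gaps[gaps < boundary]) + ssd(gaps[gaps >= boundary])) / tot
}

# Exhaustive grid maximization of the GVF; smallest argmax.
oracle_break_interval <- function(gaps, grid = seq(30, 120, by = 5)) {
  g <- vapply(grid, function(b) oracle_gvf(gaps, b), numeric(1))
  if (all(is.nan(g))) return(min(grid))
  grid[which.max(g)]
}

# Exhaustive co-occurrence counts for a sublog: loops over every
# (encounter, shift, segment) and every role pair.
oracle_collab_counts <- function(sublog) {
  sublog <- as.data.frame(sublog)
  sublog <- sublog[!is.na(sublog$functional_role), ]
  seg_pairs <- list()
  pres_pairs <- list()
  for (enc in unique(sublog$encounter_id)) {
    enc_rows <- sublog[sublog$encounter_id == enc, ]
    for (sh in unique(enc_rows$shift_number)) {
      sh_rows <- enc_rows[enc_rows$shift_number == sh, ]
      roles_present <- sort(unique(sh_rows$functional_role))
      if (length(roles_present) >= 2) {
        cmb <- combn(roles_present, 2)
        for (c in seq_len(ncol(cmb))) {
          k <- paste(cmb[1, c], cmb[2, c], sep = "|")
          pres_pairs[[k]] <- c(pres_pairs[[k]], paste(enc, sh))
        }
      }
      for (sg in unique(sh_rows$segment_id)) {
        roles <- sort(unique(sh_rows$functional_role[sh_rows$segment_id == sg]))
        if (length(roles) < 2) next
        cmb <- combn(roles, 2)
        for (c in seq_len(ncol(cmb))) {
          k <- paste(cmb[1, c], cmb[2, c], sep = "|")
          seg_pairs[[k]] <- c(seg_pairs[[k]], paste(enc, sh))
        }
      }
    }
  }
  named0 <- stats::setNames(integer(0), character(0))
  co_seg <- vapply(seg_pairs, function(v) length(unique(v)), integer(1))
  co_pres <- vapply(pres_pairs, function(v) length(unique(v)), integer(1))
  list(co_segment = if (length(co_seg)) co_seg else named0,
       co_present = if (length(co_pres)) co_pres else named0)
}

# Partition density computed straight from the formula on an edge data.frame
# (role_a, role_b) and a membership vector.
oracle_partition_density <- function(edges, membership) {
  M <- nrow(edges)
  terms <- vapply(unique(membership), function(cm) {
    e <- edges[membership == cm, ]
    m_c <- nrow(e)
    n_c <- length(unique(c(e$role_a, e$role_b)))
    if (n_c == 2) 0 else m_c * (m_c - (n_c - 1)) / ((n_c - 2) * (n_c - 1))
  }, numeric(1))
  (2 / M) * sum(terms)
}

# Best partition density over every cut of an edge dendrogram, evaluated
# independently. A cut lives at a height: the realizable partitions are the
# all-singletons one plus, for each distinct merge height, the partition
# after all merges up to that height.
oracle_best_cut_density <- function(dendrogram, network) {
  edges <- as.data.frame(network$edges)
  edges <- edges[order(edges$role_a, edges$role_b), ]
  ids <- paste(edges$role_a, edges$role_b, sep = "|")
  ord <- match(dendrogram$edge_ids, ids)
  best <- oracle_partition_density(edges, seq_len(nrow(edges)))
  h <- dendrogram$heights
  if (length(h)) {
    cut_steps <- which(!duplicated(h, fromLast = TRUE))
    for (s in cut_steps) {
      memb <- integer(nrow(edges))
      memb[ord] <- dendrogram$memberships[s, ]
      best <- max(best, oracle_partition_density(edges, memb))
    }
  }
  best
}

# Small deterministic master-log builder for unit tests: events is a list of
# (t, role [, location]) per encounter/shift.
make_log <- function(events) {
  dt <- data.table::rbindlist(lapply(events, event_row))
  data.table::setorder(dt, encounter_id, shift_number, t_norm)
  dt
}

event_row <- function(e) {
  data.table::data.table(
    encounter_id = e$enc %||% "E1",
    t_norm = e$t,
    activity_type = e$type %||% "note",
    hcp_id = e$hcp %||% paste0("H_", e$role),
    functional_role = e$role,
    care_location = e$loc %||% "ED",
    shift_number = e$shift %||% 0L,
    shift_type = e$shift_type %||% "day",
    segment_id = e$segment %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny synthetic configuration for fast tests.
tiny_config <- function(...) {
  synth_config(n_encounters = 25L, seed = 11L, ...)
}

# A small hand-built collaboration network from an edge table.
make_network <- function(edges_df, key = "test") {
  edges <- data.table::as.data.table(edges_df)
  if (!"co_segment_shifts" %in% names(edges)) edges[, co_segment_shifts := 1L]
  if (!"co_present_shifts" %in% names(edges)) {
    edges[, co_present_shifts := co_segment_shifts]
  }
  if (!"weight" %in% names(edges)) {
    edges[, weight := co_segment_shifts / co_present_shifts]
  }
  carenet:::new_collab_network(key,
                               sort(unique(c(edges$role_a, edges$role_b))),
                               edges[order(role_a, role_b)],
                               n_events = 0L)
}
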