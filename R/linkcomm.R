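# Overlapping community detection by edge clustering. Edges (not nodes) are
# clustered, so a role can belong to several communities: similarity between
# adjacent edges is a weighted Tanimoto coefficient over inclusive
# neighborhoods, the edge dendrogram is built with WPGMA (McQuitty) linkage
# so that edge weights are taken into account, and the dendrogram is cut at
# the level that maximizes the partition density.

#' Weighted similarity between adjacent edges
#'
#' For edges e = (i, k) and f = (j, k) sharing node k,
#' S(e, f) = a_i . a_j / (|a_i|^2 + |a_j|^2 - a_i . a_j), where a_i is the
#' weight vector from i to its inclusive neighborhood, with self-entry
#' a_i(i) equal to the mean weight of i's incident edges. With uniform
#' weights this reduces to the Jaccard index of the inclusive neighborhoods.
#' Only adjacent edge pairs are listed; non-adjacent pairs have similarity
#' 0 by convention and are absent.
#'
#' @param network a pruned, weighted `collab_network`.
#' @return Object of class `edge_similarity`: list with `edge_ids`
#'   (canonical `"A|B"` labels, sorted) and `pairs` (data.table `e1`, `e2`,
#'   `sim`, with `e1 < e2`).
#' @export
edge_similarity <- function(network) {
  stopifnot(inherits(network, "collab_network"))
  edges <- data.table::copy(network$edges)
  data.table::setorder(edges, role_a, role_b)
  edge_ids <- edge_key(edges$role_a, edges$role_b)
  if (anyDuplicated(edge_ids)) {
    stop("edge_similarity: parallel edges violate the canonical-key contract")
  }
  nodes <- sort(unique(c(edges$role_a, edges$role_b)))
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  ia <- match(edges$role_a, nodes)
  ib <- match(edges$role_b, nodes)
  A[cbind(ia, ib)] <- edges$weight
  A[cbind(ib, ia)] <- edges$weight
  # inclusive self-entry: mean incident edge weight
  deg <- rowSums(A > 0)
  diag(A) <- ifelse(deg > 0, rowSums(A) / pmax(deg, 1), 0)
  dots <- tcrossprod(A)
  norms2 <- diag(dots)

  pair_list <- vector("list", n)
  for (k in seq_len(n)) {
    inc <- which(ia == k | ib == k)
    if (length(inc) < 2L) next
    others <- ifelse(ia[inc] == k, ib[inc], ia[inc])
    cmb <- utils::combn(seq_along(inc), 2L)
    i <- others[cmb[1L, ]]
    j <- others[cmb[2L, ]]
    num <- dots[cbind(i, j)]
    s <- num / (norms2[i] + norms2[j] - num)
    e1 <- edge_ids[inc[cmb[1L, ]]]
    e2 <- edge_ids[inc[cmb[2L, ]]]
    pair_list[[k]] <- data.table::data.table(
      e1 = pmin(e1, e2), e2 = pmax(e1, e2), sim = s)
  }
  pairs <- data.table::rbindlist(pair_list)
  if (nrow(pairs) == 0L) {
    pairs <- data.table::data.table(e1 = character(), e2 = character(),
                                    sim = numeric())
  } else {
    data.table::setorder(pairs, e1, e2)
  }
  structure(list(edge_ids = sort(edge_ids), pairs = pairs),
            class = "edge_similarity")
}

#' Cluster edges with WPGMA (McQuitty) linkage
#'
#' Agglomerative clustering on distance d = 1 - S. After merging clusters A
#' and B, the distance to any C is (d(A,C) + d(B,C)) / 2. Edge pairs with no
#' listed similarity (non-adjacent edges, or edges in different components)
#' are at distance 1. Ties are broken by the smallest canonical edge-pair
#' key, so the dendrogram is invariant to input order.
#'
#' @param similarity an `edge_similarity`.
#' @return Object of class `edge_dendrogram`: `edge_ids` (leaves),
#'   `heights` (non-decreasing merge heights), `memberships` (one row per
#'   merge: cluster id per edge after that merge), `merges` (data.table with
#'   the representative edge keys of the two clusters merged at each step).
#' @export
cluster_edges_wpgma <- function(similarity) {
  stopifnot(inherits(similarity, "edge_similarity"))
  ids <- similarity$edge_ids
  n <- length(ids)
  if (n == 0L) stop("cluster_edges_wpgma: empty edge set")
  if (n == 1L) {
    return(structure(list(edge_ids = ids, heights = numeric(0),
                          memberships = matrix(integer(0), 0, 1),
                          merges = data.table::data.table(
                            step = integer(), rep_a = character(),
                            rep_b = character(), height = numeric())),
                     class = "edge_dendrogram"))
  }
  D <- matrix(1, n, n)
  diag(D) <- NA_real_
  if (nrow(similarity$pairs)) {
    i1 <- match(similarity$pairs$e1, ids)
    i2 <- match(similarity$pairs$e2, ids)
    D[cbind(i1, i2)] <- 1 - similarity$pairs$sim
    D[cbind(i2, i1)] <- 1 - similarity$pairs$sim
  }
  active <- rep(TRUE, n)
  reps <- ids
  membership <- seq_len(n)
  heights <- numeric(n - 1L)
  memberships <- matrix(NA_integer_, n - 1L, n)
  merges <- data.table::data.table(step = seq_len(n - 1L),
                                   rep_a = character(n - 1L),
                                   rep_b = character(n - 1L),
                                   height = numeric(n - 1L))
  for (s in seq_len(n - 1L)) {
    act <- which(active)
    sub <- D[act, act, drop = FALSE]
    mn <- min(sub, na.rm = TRUE)
    hit <- which(sub == mn, arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    gi <- act[hit[, 1L]]
    gj <- act[hit[, 2L]]
    ka <- pmin(reps[gi], reps[gj])
    kb <- pmax(reps[gi], reps[gj])
    pick <- order(ka, kb)[1L]
    i <- gi[pick]; j <- gj[pick]
    if (reps[j] < reps[i]) { tmp <- i; i <- j; j <- tmp }
    h <- if (s > 1L) max(mn, heights[s - 1L]) else mn  # guard fp inversions
    heights[s] <- h
    merges[s, `:=`(rep_a = reps[i], rep_b = reps[j], height = h)]
    other <- setdiff(act, c(i, j))
    if (length(other)) {
      newd <- (D[i, other] + D[j, other]) / 2
      D[i, other] <- newd
      D[other, i] <- newd
    }
    active[j] <- FALSE
    membership[membership == j] <- i
    memberships[s, ] <- membership
  }
  structure(list(edge_ids = ids, heights = heights,
                 memberships = memberships, merges = merges),
            class = "edge_dendrogram")
}

#' Partition density of an edge partition
#'
#' D = (2/M) * sum_c m_c * (m_c - (n_c - 1)) / ((n_c - 2) * (n_c - 1)),
#' where M is the total edge count and m_c, n_c are the edge and node counts
#' of community c. Communities with n_c = 2 (single links / matchings)
#' contribute 0. D = 1 exactly when every community is a clique spanning its
#' nodes.
#'
#' @param network a `collab_network` whose edges (in canonical order) the
#'   partition refers to.
#' @param edge_partition integer/character vector: community label per edge,
#'   aligned with the canonically sorted edge list.
#' @return List with `D` and `per_community` (data.table `community`,
#'   `m_c`, `n_c`, `density_term`).
#' @export
partition_density <- function(network, edge_partition) {
  edges <- data.table::copy(network$edges)
  data.table::setorder(edges, role_a, role_b)
  M <- nrow(edges)
  stopifnot(length(edge_partition) == M)
  dt <- data.table::data.table(role_a = edges$role_a, role_b = edges$role_b,
                               community = edge_partition)
  per <- dt[, {
    n_c <- length(unique(c(role_a, role_b)))
    m_c <- .N
    if (n_c < 2L) stop("partition_density: community with fewer than 2 nodes")
    term <- if (n_c == 2L) 0 else m_c * (m_c - (n_c - 1)) / ((n_c - 2) * (n_c - 1))
    .(m_c = m_c, n_c = n_c, density_term = term)
  }, by = community]
  list(D = (2 / M) * sum(per$density_term), per_community = per[])
}

#' Cut the edge dendrogram at maximum partition density
#'
#' Evaluates the partition density at every distinct merge height (and at
#' the all-singletons level) and cuts where D is maximal; ties go to the cut
#' with more communities. Clusters with at least 2 edges are reported as
#' communities; single-edge clusters are labeled background. Node
#' memberships and pie fractions (per-node proportion of incident edges in
#' each community) are derived from the reported communities.
#'
#' @param dendrogram an `edge_dendrogram`.
#' @param network the `collab_network` it was built from.
#' @return Object of class `link_communities`: `communities` (list of lists
#'   with `edges`, `nodes`, `m_c`, `n_c`), `background_edges`, `cut_height`,
#'   `D`, `density_profile` (data.table `height`, `n_clusters`, `D`),
#'   `node_memberships` (named list), `pie_fractions` (named list of named
#'   numeric vectors summing to 1).
#' @export
cut_at_max_density <- function(dendrogram, network) {
  stopifnot(inherits(dendrogram, "edge_dendrogram"))
  edges <- data.table::copy(network$edges)
  data.table::setorder(edges, role_a, role_b)
  ids <- edge_key(edges$role_a, edges$role_b)
  stopifnot(identical(sort(ids), dendrogram$edge_ids))
  ord <- match(dendrogram$edge_ids, ids)  # dendrogram leaves -> edge rows
  M <- length(ids)

  candidate_partitions <- list(seq_len(M))
  candidate_heights <- 0
  if (length(dendrogram$heights)) {
    last_at_height <- !duplicated(rev(dendrogram$heights))
    steps <- rev(seq_along(dendrogram$heights))[last_at_height]
    steps <- sort(steps)
    for (s in steps) {
      candidate_partitions[[length(candidate_partitions) + 1L]] <-
        dendrogram$memberships[s, ]
      candidate_heights <- c(candidate_heights, dendrogram$heights[s])
    }
  }

  profile <- data.table::data.table(height = numeric(), n_clusters = integer(),
                                    D = numeric())
  best <- NULL
  for (ci in seq_along(candidate_partitions)) {
    memb_leaf <- candidate_partitions[[ci]]
    memb_edges <- integer(M)
    memb_edges[ord] <- memb_leaf  # align leaf order with edge rows
    pd <- partition_density(network, memb_edges)
    ncl <- length(unique(memb_leaf))
    profile <- rbind(profile, data.table::data.table(
      height = candidate_heights[ci], n_clusters = ncl, D = pd$D))
    if (is.null(best) || pd$D > best$D + 1e-12 ||
        (abs(pd$D - best$D) <= 1e-12 && ncl > best$ncl)) {
      best <- list(D = pd$D, ncl = ncl, memb = memb_edges,
                   height = candidate_heights[ci])
    }
  }

  comm_split <- split(seq_len(M), best$memb)
  sizes <- vapply(comm_split, length, integer(1))
  reported_raw <- comm_split[sizes >= 2L]
  background <- unlist(comm_split[sizes < 2L], use.names = FALSE)
  # order reported communities by size (desc), then smallest edge key
  if (length(reported_raw)) {
    first_key <- vapply(reported_raw, function(e) min(ids[e]), character(1))
    o <- order(-vapply(reported_raw, length, integer(1)), first_key)
    reported_raw <- reported_raw[o]
  }
  communities <- lapply(seq_along(reported_raw), function(c) {
    e <- reported_raw[[c]]
    nodes <- sort(unique(c(edges$role_a[e], edges$role_b[e])))
    list(id = c, edges = ids[e], nodes = nodes,
         m_c = length(e), n_c = length(nodes))
  })

  all_nodes <- sort(unique(c(edges$role_a, edges$role_b)))
  edge_comm <- rep(0L, M)  # 0 = background
  for (c in seq_along(reported_raw)) edge_comm[reported_raw[[c]]] <- c
  node_memberships <- list()
  pie_fractions <- list()
  for (v in all_nodes) {
    inc <- which(edges$role_a == v | edges$role_b == v)
    comms <- edge_comm[inc]
    tab <- table(comms) / length(inc)
    labs <- ifelse(names(tab) == "0", "background",
                   paste0("community_", names(tab)))
    fr <- as.numeric(tab)
    names(fr) <- labs
    node_memberships[[v]] <- sort(unique(comms[comms > 0L]))
    pie_fractions[[v]] <- fr
  }

  structure(list(key = network$key, communities = communities,
                 background_edges = ids[background],
                 cut_height = best$height, D = best$D,
                 density_profile = profile,
                 node_memberships = node_memberships,
                 pie_fractions = pie_fractions),
            class = "link_communities")
}

#' Detect overlapping link communities in one call
#'
#' [edge_similarity()] then [cluster_edges_wpgma()] then
#' [cut_at_max_density()].
#'
#' @param network a pruned `collab_network` with at least one edge.
#' @return A `link_communities` object.
#' @export
find_link_communities <- function(network) {
  sim <- edge_similarity(network)
  dend <- cluster_edges_wpgma(sim)
  cut_at_max_density(dend, network)
}

#' Roles belonging to every reported community
#'
#' @param lc a `link_communities` result.
#' @return Character vector (empty when there are no reported communities).
#' @export
roles_in_all_communities <- function(lc) {
  k <- length(lc$communities)
  if (k == 0L) return(character())
  names(lc$node_memberships)[vapply(lc$node_memberships,
                                    function(m) length(m) == k, logical(1))]
}

#' @export
print.link_communities <- function(x, ...) {
  cat("Link communities", if (!is.na(x$key %||% NA)) paste0("[", x$key, "]") else "",
      ": ", length(x$communities), " communities (",
      length(x$background_edges), " background edges), D = ",
      round(x$D, 3), " at height ", round(x$cut_height, 3), "\n", sep = "")
  for (cm in x$communities) {
    cat("  community ", cm$id, ": ", cm$m_c, " edges, nodes: ",
        paste(cm$nodes, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
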