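test_that("edge similarity reproduces hand-computed Jaccard cases", {
  # path i - k - j, unit weights: inclusive neighborhoods {i,k} and {j,k}
  path <- make_network(data.frame(role_a = c("i", "j"), role_b = c("k", "k"),
                                  weight = c(1, 1)))
  sim <- edge_similarity(path)
  expect_equal(nrow(sim$pairs), 1L)
  expect_equal(sim$pairs$sim, 1 / 3)

  # triangle, unit weights: the two edges at any shared node compare the
  # remaining endpoints, whose inclusive neighborhoods are identical
  tri <- make_network(data.frame(role_a = c("a", "a", "b"),
                                 role_b = c("b", "c", "c"), weight = 1))
  sim_tri <- edge_similarity(tri)
  expect_equal(nrow(sim_tri$pairs), 3L)
  expect_equal(sim_tri$pairs$sim, rep(1, 3))
})

test_that("uniform weights reduce the similarity to the unweighted Jaccard", {
  set.seed(303)
  for (rep in 1:5) {
    nodes <- letters[1:7]
    cmb <- t(combn(nodes, 2))
    pick <- cmb[runif(nrow(cmb)) < 0.5, , drop = FALSE]
    if (nrow(pick) < 3) next
    w <- 0.37  # any uniform weight
    net <- make_network(data.frame(role_a = pick[, 1], role_b = pick[, 2],
                                   weight = w))
    sim <- edge_similarity(net)
    # independent Jaccard of inclusive neighborhoods
    nbr <- lapply(nodes, function(v)
      unique(c(v, pick[pick[, 1] == v, 2], pick[pick[, 2] == v, 1])))
    names(nbr) <- nodes
    for (r in seq_len(nrow(sim$pairs))) {
      e <- strsplit(sim$pairs$e1[r], "|", fixed = TRUE)[[1]]
      f <- strsplit(sim$pairs$e2[r], "|", fixed = TRUE)[[1]]
      k <- intersect(e, f)
      i <- setdiff(e, k); j <- setdiff(f, k)
      jac <- length(intersect(nbr[[i]], nbr[[j]])) /
        length(union(nbr[[i]], nbr[[j]]))
      expect_equal(sim$pairs$sim[r], jac, tolerance = 1e-12)
    }
  }
})

test_that("WPGMA merges at averaged distances with deterministic ties", {
  # two edges, S = 0.4 -> single merge at 0.6
  sim <- structure(list(edge_ids = c("a|b", "b|c"),
                        pairs = data.table::data.table(
                          e1 = "a|b", e2 = "b|c", sim = 0.4)),
                   class = "edge_similarity")
  d <- cluster_edges_wpgma(sim)
  expect_equal(d$heights, 0.6)

  # three leaves: d(1,2)=0.2, d(1,3)=d(2,3)=0.8 -> merge at 0.2, then 0.8
  sim3 <- structure(list(edge_ids = c("a|b", "a|c", "a|d"),
                         pairs = data.table::data.table(
                           e1 = c("a|b", "a|b", "a|c"),
                           e2 = c("a|c", "a|d", "a|d"),
                           sim = c(0.8, 0.2, 0.2))),
                    class = "edge_similarity")
  d3 <- cluster_edges_wpgma(sim3)
  expect_equal(d3$heights, c(0.2, 0.8))
  expect_equal(d3$merges$rep_a[1], "a|b")
  expect_equal(d3$merges$rep_b[1], "a|c")
  expect_true(all(diff(d3$heights) >= 0))
})

test_that("dendrogram is invariant to the input order of edges", {
  set.seed(304)
  edges <- data.frame(role_a = c("a", "a", "b", "c", "c", "d"),
                      role_b = c("b", "c", "c", "d", "e", "e"),
                      weight = round(runif(6, 0.2, 1), 2))
  d1 <- cluster_edges_wpgma(edge_similarity(make_network(edges)))
  shuffled <- edges[sample(nrow(edges)), ]
  d2 <- cluster_edges_wpgma(edge_similarity(make_network(shuffled)))
  expect_equal(d1$heights, d2$heights)
  expect_equal(d1$merges, d2$merges)
})

test_that("partition density matches closed forms on cliques and single edges", {
  tri <- make_network(data.frame(role_a = c("a", "a", "b"),
                                 role_b = c("b", "c", "c")))
  pd <- partition_density(tri, rep(1L, 3))
  expect_equal(pd$D, 1)
  expect_equal(pd$per_community$density_term, 1.5)

  k4 <- t(combn(letters[1:4], 2))
  k4net <- make_network(data.frame(role_a = k4[, 1], role_b = k4[, 2]))
  expect_equal(partition_density(k4net, rep(1L, 6))$D, 1)

  # single-edge communities contribute 0
  two <- make_network(data.frame(role_a = c("a", "c"), role_b = c("b", "d")))
  expect_equal(partition_density(two, c(1L, 2L))$D, 0)
})

test_that("max-density cut separates disjoint cliques and derives pie fractions", {
  # two triangles sharing node x: 2 clique communities, D = 1,
  # x splits its 4 incident edges 2/2
  edges <- data.frame(
    role_a = c("a", "a", "b", "c", "c", "d"),
    role_b = c("b", "x", "x", "d", "x", "x"),
    weight = 1)
  net <- make_network(edges)
  lc <- find_link_communities(net)
  expect_equal(length(lc$communities), 2L)
  expect_equal(lc$D, 1)
  expect_setequal(lc$node_memberships[["x"]], c(1L, 2L))
  expect_equal(sort(unname(lc$pie_fractions[["x"]])), c(0.5, 0.5))
  expect_equal(sum(lc$pie_fractions[["a"]]), 1)
  # every edge in exactly one community
  all_edges <- c(unlist(lapply(lc$communities, `[[`, "edges")),
                 lc$background_edges)
  expect_equal(sort(all_edges),
               sort(paste(edges$role_a, edges$role_b, sep = "|")))
})

test_that("max-density cut equals brute force over all cuts on small networks", {
  set.seed(305)
  for (rep in 1:20) {
    nodes <- letters[1:6]
    cmb <- t(combn(nodes, 2))
    m <- sample(3:8, 1)
    pick <- cmb[sample(nrow(cmb), m), , drop = FALSE]
    net <- make_network(data.frame(role_a = pick[, 1], role_b = pick[, 2],
                                   weight = round(runif(m, 0.2, 1), 2)))
    dend <- cluster_edges_wpgma(edge_similarity(net))
    lc <- cut_at_max_density(dend, net)
    expect_equal(lc$D, oracle_best_cut_density(dend, net), tolerance = 1e-12)
  }
})

test_that("node membership counts equal the communities among incident edges", {
  edges <- data.frame(
    role_a = c("a", "a", "b", "c", "c", "d", "e"),
    role_b = c("b", "x", "x", "d", "x", "x", "x"),
    weight = 1)
  net <- make_network(edges)
  lc <- find_link_communities(net)
  for (v in names(lc$node_memberships)) {
    inc <- which(edges$role_a == v | edges$role_b == v)
    inc_keys <- paste(pmin(edges$role_a[inc], edges$role_b[inc]),
                      pmax(edges$role_a[inc], edges$role_b[inc]), sep = "|")
    comm_of <- vapply(inc_keys, function(k) {
      hit <- which(vapply(lc$communities, function(cm) k %in% cm$edges,
                          logical(1)))
      if (length(hit)) hit else 0L
    }, integer(1))
    expect_setequal(lc$node_memberships[[v]], unique(comm_of[comm_of > 0]))
    expect_equal(sum(lc$pie_fractions[[v]]), 1)
  }
})
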