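count_network <- function(counts) {
  make_network(data.frame(
    role_a = paste0("A", seq_along(counts)),
    role_b = paste0("B", seq_along(counts)),
    co_segment_shifts = as.integer(counts),
    co_present_shifts = as.integer(counts) + 1L))
}

test_that("threshold sweep counts edges exactly", {
  net <- count_network(c(1, 2, 2, 3, 9, 10))
  tc <- sweep_thresholds(net)
  cv <- tc$curve
  expect_equal(cv$threshold, 2:20)
  expect_equal(cv[threshold == 2, edges_remaining], 5L)  # count-1 edge gone
  expect_equal(cv[threshold == 3, edges_remaining], 3L)
  expect_equal(cv[threshold == 10, edges_remaining], 1L)
  expect_equal(tc$n_singleton, 1L)
  # brute-force recount per threshold
  for (t in 2:20) {
    expect_equal(cv[threshold == t, edges_remaining],
                 sum(net$edges$co_segment_shifts >= t))
  }
  expect_true(all(diff(cv$edges_remaining) <= 0))
  expect_true(all(cv$removed_delta >= 0))

  flat <- sweep_thresholds(count_network(rep(25, 4)))
  expect_true(all(flat$curve$removed_delta == 0))
})

test_that("the smoother reproduces constants and tracks the raw curve at small spans", {
  net <- count_network(rep(c(2, 5), each = 10))
  tc <- sweep_thresholds(net)
  tc$curve$removed_delta <- rep(4L, nrow(tc$curve))
  sm <- smooth_curve(tc)
  expect_equal(sm$curve$smoothed_delta, rep(4, nrow(sm$curve)))

  # a small span makes each local fit essentially interpolating
  tc2 <- sweep_thresholds(net, threshold_config(lowess_fraction = 0.15))
  tc2$curve$removed_delta <- as.integer(round(seq(40, 4, length.out = 19)))
  sm2 <- smooth_curve(tc2, threshold_config(lowess_fraction = 0.15))
  expect_equal(sm2$curve$smoothed_delta, as.numeric(tc2$curve$removed_delta),
               tolerance = 0.05)
  # monotone input stays monotone within numerical tolerance
  expect_true(all(diff(sm2$curve$smoothed_delta) <= 1e-8))
})

test_that("elbow detection applies the suffix-insignificance rule", {
  fake_curve <- function(smoothed, eps = 0.1) {
    structure(list(
      key = "t", curve = data.table::data.table(
        threshold = seq(2, length.out = length(smoothed)),
        removed_delta = smoothed, smoothed_delta = as.numeric(smoothed)),
      config = threshold_config(elbow_epsilon = eps),
      n_edges_total = 0L, n_singleton = 0L, elbow = NA_integer_),
      class = "threshold_curve")
  }
  # suffix from the value 3 onwards is <= 0.1 * 50
  tc <- detect_elbow(fake_curve(c(50, 30, 18, 10, 3, 1, 1, 1, 0, 0)))
  expect_equal(tc$elbow, 6L)

  # constant rate -> elbow at t_min
  expect_warning(flat <- detect_elbow(fake_curve(rep(0, 10))), "zero")
  expect_equal(flat$elbow, 2L)
  same <- detect_elbow(fake_curve(rep(7, 10)))
  expect_equal(same$elbow, 2L)

  # single spike at the end -> no insignificant suffix -> t_max with warning
  expect_warning(spike <- detect_elbow(fake_curve(c(rep(0, 9), 50))),
                 "t_max")
  expect_equal(spike$elbow, 11L)
})

test_that("applying a threshold keeps >= boundary edges, drops isolated nodes, and is idempotent", {
  net <- count_network(c(8, 9, 12))
  pruned <- apply_threshold(net, 9)
  expect_equal(pruned$edges$co_segment_shifts, c(9L, 12L))
  expect_false("A1" %in% pruned$nodes)  # its only edge was removed
  expect_equal(pruned$threshold, 9L)
  again <- apply_threshold(pruned, 9)
  expect_equal(again$edges, pruned$edges)
  # weights unchanged by pruning
  expect_equal(pruned$edges$weight, net$edges[co_segment_shifts >= 9, weight])
})

test_that("constant-rate case: elbow at t_min via full chain", {
  net <- count_network(rep(c(7, 3), times = 6))
  th <- suppressWarnings(threshold_network(net))
  expect_true(th$curve$elbow >= 2 && th$curve$elbow <= 20)
  expect_true(all(th$network$edges$co_segment_shifts >= th$curve$elbow))
})
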