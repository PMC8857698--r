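test_that("generation is bit-reproducible for identical config and seed", {
  cfg <- tiny_config()
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$encounters, s2$encounters)
  expect_identical(s1$roster, s2$roster)
  expect_identical(s1$adt, s2$adt)
  expect_identical(s1$records, s2$records)
})

test_that("day_fraction controls arrival shifts exactly and in distribution", {
  all_day <- generate_cohort(synth_config(n_encounters = 100, day_fraction = 1,
                                          seed = 5))
  lt <- as.POSIXlt(all_day$encounters$arrival_clock, tz = "UTC")
  mins <- lt$hour * 60 + lt$min
  expect_true(all(mins >= 420 & mins < 1140))

  # binomial bound: n=413, p=0.659 -> day count within 3 SD of 272
  coh <- generate_cohort(synth_config(n_encounters = 413, day_fraction = 0.659,
                                      seed = 7))
  n_day <- shift_split(coh$encounters)[shift_type == "day", n]
  expect_lt(abs(n_day - 272), 3 * sqrt(413 * 0.659 * 0.341))
})

test_that("ADT timelines are contiguous, non-overlapping, and start at zero", {
  st <- generate_cohort(tiny_config())
  for (enc in unique(st$adt$encounter_id)) {
    tl <- st$adt[encounter_id == enc][order(start_minute)]
    expect_equal(tl$start_minute[1], 0)
    if (nrow(tl) > 1) {
      expect_equal(tl$start_minute[-1], tl$end_minute[-nrow(tl)])
    }
    expect_true(all(tl$end_minute > tl$start_minute))
  }
})

test_that("within-shift gaps respect the burst-gap separation", {
  # single location so shift windows are not split across units
  cfg <- synth_config(n_encounters = 15, locations = "ED",
                      unresolved_role_fraction = 0,
                      student_system_fraction = 0, seed = 21)
  st <- generate_study(cfg)
  rec <- merge(st$records,
               st$encounters[, .(encounter_id, arrival_clock)],
               by = "encounter_id")
  rec[, shift_idx := floor((as.numeric(timestamp) / 60 - 420) / 720)]
  data.table::setorder(rec, encounter_id, timestamp)
  gaps <- rec[, if (.N > 1)
    .(gap = diff(as.numeric(timestamp)) / 60), by = .(encounter_id, shift_idx)]
  # every gap is within-burst (< 30) or separates bursts (>= the 125-min
  # floor shared by planted spacing and spurious-burst placement)
  expect_true(all(gaps$gap < 30 | gaps$gap >= 125))
  expect_gt(max(gaps$gap), 120)  # a recoverable break scale exists
})

test_that("student/system flags hit the configured rate within binomial error", {
  # pool several generator replicates into one binomial draw for power
  n <- 0L; flagged <- 0L
  for (sd in 9:11) {
    cfg <- synth_config(n_encounters = 30, student_system_fraction = 0.1,
                        unresolved_role_fraction = 0, seed = sd)
    st <- generate_study(cfg)
    n <- n + nrow(st$records)
    flagged <- flagged + st$records[, sum(student | system_initiated)]
  }
  expect_lt(abs(flagged / n - 0.1), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("zero noise and disjoint communities never mix roles within a burst", {
  gt <- list(ED = list(communities = list(c("ED_AT", "ED_R"),
                                          c("ED_RN", "ED_Rad_Tech")),
                       hubs = character(0)))
  cfg <- synth_config(n_encounters = 15, locations = "ED",
                      ground_truth_day = gt, ground_truth_night = gt,
                      noise_coocc_rate = 0, unresolved_role_fraction = 0,
                      student_system_fraction = 0, seed = 13)
  st <- generate_study(cfg)
  rec <- merge(st$records, st$roster[, .(hcp_id, role_label)], by = "hcp_id")
  data.table::setorder(rec, encounter_id, timestamp)
  # bursts = runs separated by >= 150 min within an encounter
  rec[, burst := cumsum(c(0, diff(as.numeric(timestamp)) / 60 >= 150)),
      by = encounter_id]
  comm_of <- c(ED_AT = 1L, ED_R = 1L, ED_RN = 2L, ED_Rad_Tech = 2L)
  mixes <- rec[, data.table::uniqueN(comm_of[role_label]),
               by = .(encounter_id, burst)]
  expect_true(all(mixes$V1 == 1L))
})

test_that("ground-truth roles missing from the roster raise a generation error", {
  gt <- list(ED = list(communities = list(c("Cardiology_AT", "ED_R")),
                       hubs = character(0)))
  expect_error(
    generate_cohort(synth_config(ground_truth_night = gt, locations = "ED")),
    "Cardiology_AT")
})

test_that("invalid configurations name the offending field", {
  expect_error(synth_config(day_fraction = 1.3), "day_fraction")
  expect_error(synth_config(within_burst_gap_minutes = c(1, 200)),
               "within_burst")
  expect_error(synth_config(locations = "WARD"), "locations")
})

test_that("raw datasets round-trip losslessly through write/read", {
  st <- generate_study(tiny_config())
  dir <- withr::local_tempdir()
  write_raw_dataset(st, dir)
  back <- read_raw_dataset(dir)
  expect_equal(as.data.frame(back$encounters), as.data.frame(st$encounters))
  expect_equal(as.data.frame(back$roster), as.data.frame(st$roster))
  expect_equal(as.data.frame(back$adt), as.data.frame(st$adt))
  expect_equal(as.data.frame(back$records), as.data.frame(st$records))
  # community labels identical to the in-memory ground truth
  expect_identical(back$truth, st$truth)
})

test_that("an empty record set still writes valid, readable files", {
  st <- generate_cohort(tiny_config())  # records not yet generated
  dir <- withr::local_tempdir()
  write_raw_dataset(st, dir)
  back <- read_raw_dataset(dir)
  expect_equal(nrow(back$records), 0L)
  expect_equal(nrow(back$encounters), nrow(st$encounters))
})
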