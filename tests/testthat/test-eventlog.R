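enc_tbl <- function(ids = "E1", clock = "2017-03-01 08:00:00") {
  data.table::data.table(
    encounter_id = ids,
    arrival_clock = as.POSIXct(clock, tz = "UTC"))
}

raw_record <- function(enc = "E1", t = "2017-03-01 08:00:00",
                       type = "note", hcp = "H1", role = "attending",
                       service = NA_character_, loc = NA_character_,
                       cos_id = NA_character_, cos_svc = NA_character_,
                       system = FALSE, student = FALSE) {
  data.table::data.table(
    encounter_id = enc, timestamp = as.POSIXct(t, tz = "UTC"),
    activity_type = type, hcp_id = hcp, generic_role = role,
    service = service, care_location = loc,
    cosigner_hcp_id = cos_id, cosigner_service = cos_svc,
    system_initiated = system, student = student)
}

test_that("timestamp normalization is exact, order-preserving, and drops pre-arrival records", {
  enc <- enc_tbl()
  rec <- rbind(
    raw_record(t = "2017-03-01 08:00:00"),
    raw_record(t = "2017-03-01 08:01:30"),
    raw_record(t = "2017-03-01 07:50:00"))
  expect_message(norm <- normalize_timestamps(rec, enc), "1 record")
  expect_equal(norm$t_norm, c(0, 1.5))
  expect_equal(attr(norm, "n_pre_arrival"), 1L)

  # translation invariance: shifting the arrival clock leaves gaps unchanged
  enc2 <- enc_tbl(clock = "2017-03-01 03:00:00")
  norm2 <- normalize_timestamps(rec, enc2)
  expect_equal(diff(norm2$t_norm)[2], 1.5)

  expect_error(normalize_timestamps(raw_record(enc = "EX"), enc), "unknown")
})

test_that("exclusions partition the input with machine-readable reasons", {
  enc <- enc_tbl()
  rec <- rbind(
    raw_record(hcp = "H1"),
    raw_record(hcp = "H2", student = TRUE),
    raw_record(hcp = "H3", system = TRUE),
    raw_record(hcp = NA_character_))
  norm <- normalize_timestamps(rec, enc)
  ex <- apply_exclusions(norm)
  expect_equal(nrow(ex$kept) + nrow(ex$excluded), nrow(norm))
  expect_equal(ex$kept$hcp_id, "H1")
  expect_setequal(ex$excluded$reason, c("student", "system", "incomplete"))
  expect_equal(ex$excluded[is.na(hcp_id), reason], "incomplete")
})

test_that("location inference uses half-open intervals and clamps past the end", {
  tl <- data.table::data.table(location = c("ED", "PICU"),
                               start_minute = c(0, 120),
                               end_minute = c(120, 3000))
  expect_equal(infer_location(60, tl), "ED")
  expect_equal(infer_location(120, tl), "PICU")   # boundary belongs right
  expect_equal(infer_location(5000, tl), "PICU")  # clamp to last location
  expect_equal(infer_location(c(0, 119.9, 120), tl), c("ED", "ED", "PICU"))
  expect_error(infer_location(-1, tl), "non-negative")
})

test_that("role resolution follows the class-specific service rules", {
  enc <- enc_tbl(c("E1", "E2"), c("2017-03-01 08:00:00", "2017-03-05 09:00:00"))
  adt <- data.table::data.table(
    encounter_id = c("E1", "E1", "E2"),
    location = c("ED", "PICU", "ED"),
    start_minute = c(0, 200, 0), end_minute = c(200, 4000, 4000))
  rec <- rbind(
    # resident: cosigned by neurosurgery in E1, orthopaedics in E2
    raw_record("E1", "2017-03-01 08:10:00", hcp = "R1", role = "resident",
               cos_id = "A1", cos_svc = "Neurosurg"),
    raw_record("E2", "2017-03-05 09:10:00", hcp = "R1", role = "resident",
               cos_id = "A2", cos_svc = "Ortho"),
    # nurse: 3 activities in the ED, 1 in the PICU -> ED_RN everywhere,
    # and the off-base flowsheet is excluded
    raw_record("E1", "2017-03-01 08:05:00", type = "flowsheet", hcp = "N1",
               role = "registered_nurse"),
    raw_record("E1", "2017-03-01 08:20:00", type = "flowsheet", hcp = "N1",
               role = "registered_nurse"),
    raw_record("E1", "2017-03-01 09:00:00", type = "medication_admin",
               hcp = "N1", role = "registered_nurse", loc = "ED"),
    raw_record("E1", "2017-03-01 16:00:00", type = "flowsheet", hcp = "N1",
               role = "registered_nurse"),
    # attending with service evidence
    raw_record("E1", "2017-03-01 08:30:00", hcp = "A9", role = "attending",
               service = "GPS"),
    # attending with no service evidence anywhere -> unresolved
    raw_record("E1", "2017-03-01 08:40:00", type = "procedure_order",
               hcp = "A0", role = "attending", loc = "ED"))
  norm <- normalize_timestamps(rec, enc)
  located <- assign_locations(apply_exclusions(norm)$kept, adt)
  res <- resolve_functional_roles(located)

  r1 <- res$kept[hcp_id == "R1"]
  expect_equal(r1[encounter_id == "E1", functional_role], "Neurosurg_R")
  expect_equal(r1[encounter_id == "E2", functional_role], "Ortho_R")

  n1 <- res$kept[hcp_id == "N1"]
  expect_true(all(n1$functional_role == "ED_RN"))
  off <- res$excluded[hcp_id == "N1"]
  expect_equal(off$reason, "off_base_unit")  # the 16:00 PICU flowsheet
  expect_equal(off$care_location, "PICU")

  expect_equal(res$kept[hcp_id == "A9", functional_role], "GPS_AT")
  expect_equal(res$excluded[hcp_id == "A0", reason], "unresolved_role")
  expect_equal(nrow(res$kept) + nrow(res$excluded), nrow(located))
})

test_that("master log fans out cosigned notes and labels shifts from wall clock", {
  enc <- enc_tbl(c("E1", "E2"), c("2017-03-01 08:00:00", "2017-03-01 18:50:00"))
  rec <- rbind(
    raw_record("E1", "2017-03-01 08:00:00", hcp = "R1", role = "resident",
               cos_id = "A1", cos_svc = "GPS"),
    raw_record("E1", "2017-03-01 19:40:00", type = "procedure_order",
               hcp = "R1", role = "resident", loc = "ED"),
    raw_record("E2", "2017-03-01 19:05:00", type = "procedure_order",
               hcp = "R2", role = "resident", loc = "ED"))
  norm <- normalize_timestamps(rec, enc)
  norm[, `:=`(resolved_service = "GPS", functional_role = "GPS_R")]
  log <- build_master_log(norm, enc)

  # the note yields two same-time events: author and cosigning attending
  note_events <- log[encounter_id == "E1" & t_norm == 0]
  expect_equal(nrow(note_events), 2L)
  expect_setequal(note_events$functional_role, c("GPS_R", "GPS_AT"))

  # arrival 08:00: t=0 is day shift 0; t=700 (19:40) is night shift 1
  expect_equal(log[encounter_id == "E1" & t_norm == 0, unique(shift_number)], 0L)
  expect_equal(log[encounter_id == "E1" & t_norm == 0, unique(shift_type)], "day")
  expect_equal(log[encounter_id == "E1" & t_norm == 700, shift_number], 1L)
  expect_equal(log[encounter_id == "E1" & t_norm == 700, shift_type], "night")

  # arrival 18:50: t=15 crosses 19:00 -> shift 1, night
  expect_equal(log[encounter_id == "E2", shift_number], 1L)
  expect_equal(log[encounter_id == "E2", shift_type], "night")

  # shifting arrivals by +24 h leaves all shift labels unchanged
  enc24 <- data.table::copy(enc)[, arrival_clock := arrival_clock + 86400]
  rec24 <- data.table::copy(norm)
  log24 <- build_master_log(rec24, enc24)
  expect_equal(log24$shift_type, log$shift_type)
  expect_equal(log24$shift_number, log$shift_number)
})
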