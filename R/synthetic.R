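# Synthetic EHR event-log generator with planted diurnal team structure.
#
# The generator emulates the metadata schema of a paediatric trauma EHR
# extract: an encounter table (arrival wall-clock time, demographics, trauma
# activation level), an HCP roster, per-encounter ADT location timelines, and
# raw activity records (notes, orders, flow sheets, medication
# administrations) emitted in bursts within shifts. Collaboration structure
# is planted per (shift type, care location): bursts draw the roles of one
# planted community (plus intermittently-present hub roles), so downstream
# segmentation and network construction can be validated against known truth.

#' Default HCP roster specification
#'
#' One row per functional role: the generic clinical role, the service that
#' resolution should recover (NA for unit-based staff, whose service is their
#' base location), the base location for unit-based staff, and the number of
#' individual HCPs occupying the role.
#'
#' @return data.table with columns `role_label`, `generic_role`, `service`,
#'   `base_location`, `n_hcps`.
#' @export
default_roster_spec <- function() {
  rs <- rbind(
    data.frame(role_label = "ED_AT",        generic_role = "attending",             service = "ED",        base_location = NA,      n_hcps = 4L),
    data.frame(role_label = "ED_R",         generic_role = "resident",              service = "ED",        base_location = NA,      n_hcps = 6L),
    data.frame(role_label = "ED_RN",        generic_role = "registered_nurse",      service = NA,          base_location = "ED",    n_hcps = 8L),
    data.frame(role_label = "ED_Rad_Tech",  generic_role = "radiology_technician",  service = "ED",        base_location = NA,      n_hcps = 3L),
    data.frame(role_label = "ED_SW",        generic_role = "social_worker",         service = NA,          base_location = "ED",    n_hcps = 2L),
    data.frame(role_label = "ED_CLS",       generic_role = "child_life_specialist", service = NA,          base_location = "ED",    n_hcps = 2L),
    data.frame(role_label = "GPS_AT",       generic_role = "attending",             service = "GPS",       base_location = NA,      n_hcps = 3L),
    data.frame(role_label = "GPS_R",        generic_role = "resident",              service = "GPS",       base_location = NA,      n_hcps = 5L),
    data.frame(role_label = "Neurosurg_AT", generic_role = "attending",             service = "Neurosurg", base_location = NA,      n_hcps = 2L),
    data.frame(role_label = "Neurosurg_R",  generic_role = "resident",              service = "Neurosurg", base_location = NA,      n_hcps = 3L),
    data.frame(role_label = "Ortho_AT",     generic_role = "attending",             service = "Ortho",     base_location = NA,      n_hcps = 2L),
    data.frame(role_label = "Ortho_R",      generic_role = "resident",              service = "Ortho",     base_location = NA,      n_hcps = 3L),
    data.frame(role_label = "Oto_AT",       generic_role = "attending",             service = "Oto",       base_location = NA,      n_hcps = 2L),
    data.frame(role_label = "Oto_R",        generic_role = "resident",              service = "Oto",       base_location = NA,      n_hcps = 3L),
    data.frame(role_label = "Plastic_AT",   generic_role = "attending",             service = "Plastic",   base_location = NA,      n_hcps = 2L),
    data.frame(role_label = "Plastic_R",    generic_role = "resident",              service = "Plastic",   base_location = NA,      n_hcps = 3L),
    data.frame(role_label = "Peds_AT",      generic_role = "attending",             service = "Peds",      base_location = NA,      n_hcps = 2L),
    data.frame(role_label = "Peds_R",       generic_role = "resident",              service = "Peds",      base_location = NA,      n_hcps = 3L),
    data.frame(role_label = "PPS_AT",       generic_role = "attending",             service = "PPS",       base_location = NA,      n_hcps = 2L),
    data.frame(role_label = "PPS_NP",       generic_role = "nurse_practitioner",    service = "PPS",       base_location = NA,      n_hcps = 2L),
    data.frame(role_label = "Neuro_AT",     generic_role = "attending",             service = "Neuro",     base_location = NA,      n_hcps = 2L),
    data.frame(role_label = "Neuro_R",      generic_role = "resident",              service = "Neuro",     base_location = NA,      n_hcps = 3L),
    data.frame(role_label = "Floor_RN",     generic_role = "registered_nurse",      service = NA,          base_location = "FLOOR", n_hcps = 8L),
    data.frame(role_label = "Floor_NP",     generic_role = "nurse_practitioner",    service = NA,          base_location = "FLOOR", n_hcps = 3L),
    data.frame(role_label = "Floor_SW",     generic_role = "social_worker",         service = NA,          base_location = "FLOOR", n_hcps = 2L),
    data.frame(role_label = "Floor_CM",     generic_role = "case_manager",          service = NA,          base_location = "FLOOR", n_hcps = 2L),
    data.frame(role_label = "Floor_CLS",    generic_role = "child_life_specialist", service = NA,          base_location = "FLOOR", n_hcps = 2L),
    data.frame(role_label = "Floor_DT",     generic_role = "dietitian",             service = NA,          base_location = "FLOOR", n_hcps = 2L),
    data.frame(role_label = "PICU_AT",      generic_role = "attending",             service = "PICU",      base_location = NA,      n_hcps = 3L),
    data.frame(role_label = "PICU_F",       generic_role = "fellow",                service = "PICU",      base_location = NA,      n_hcps = 3L),
    data.frame(role_label = "PICU_R",       generic_role = "resident",              service = "PICU",      base_location = NA,      n_hcps = 4L),
    data.frame(role_label = "PICU_RN",      generic_role = "registered_nurse",      service = NA,          base_location = "PICU",  n_hcps = 8L),
    data.frame(role_label = "PICU_SW",      generic_role = "social_worker",         service = NA,          base_location = "PICU",  n_hcps = 2L),
    data.frame(role_label = "PICU_CM",      generic_role = "case_manager",          service = NA,          base_location = "PICU",  n_hcps = 2L)
  )
  data.table::as.data.table(rs)
}

#' Default planted ground truth
#'
#' Day shifts carry a single merged community per location; night shifts
#' carry five specialty communities in the ED and on the floor (sharing the
#' general paediatric surgery attending and resident as hub roles) and a
#' single community in the PICU.
#'
#' @param shift_type "day" or "night".
#' @return Named list by location; each entry has `communities` (list of
#'   role-label vectors, hubs excluded) and `hubs`.
#' @export
default_ground_truth <- function(shift_type = c("day", "night")) {
  shift_type <- match.arg(shift_type)
  hubs <- c("GPS_AT", "GPS_R")
  if (shift_type == "day") {
    list(
      ED = list(communities = list(c(
        "ED_AT", "ED_R", "ED_RN", "ED_Rad_Tech",
        "Neurosurg_AT", "Neurosurg_R", "Ortho_AT", "Ortho_R",
        "ED_SW", "ED_CLS")), hubs = hubs),
      FLOOR = list(communities = list(c(
        "Floor_RN", "Floor_NP",
        "Neurosurg_AT", "Neurosurg_R", "Ortho_AT", "Ortho_R",
        "Peds_AT", "Peds_R",
        "Floor_SW", "Floor_CM", "Floor_CLS", "Floor_DT")), hubs = hubs),
      PICU = list(communities = list(c(
        "PICU_AT", "PICU_F", "PICU_R", "PICU_RN",
        "Neurosurg_AT", "Neurosurg_R", "Neuro_AT", "Neuro_R",
        "PICU_SW", "PICU_CM")), hubs = hubs)
    )
  } else {
    list(
      ED = list(communities = list(
        c("ED_AT", "ED_R", "ED_RN", "ED_Rad_Tech"),
        c("Neurosurg_AT", "Neurosurg_R"),
        c("Ortho_AT", "Ortho_R"),
        c("Oto_AT", "Oto_R"),
        c("Plastic_AT", "Plastic_R")), hubs = hubs),
      FLOOR = list(communities = list(
        c("Floor_RN", "Floor_NP"),
        c("Neurosurg_AT", "Neurosurg_R"),
        c("Ortho_AT", "Ortho_R"),
        c("Peds_AT", "Peds_R"),
        c("PPS_AT", "PPS_NP")), hubs = hubs),
      PICU = list(communities = list(c(
        "PICU_AT", "PICU_F", "PICU_R", "PICU_RN",
        "Neurosurg_AT", "Neurosurg_R")), hubs = hubs)
    )
  }
}

#' Synthetic-study generator configuration
#'
#' Defaults reproduce the study conditions the generator emulates: 413
#' encounters over one year, 65.9% arriving during day shifts, bursty
#' within-shift activity (within-burst gaps far below, between-burst gaps far
#' above, the 30-120 minute natural-break grid), five planted night
#' communities in the ED and on the floor sharing two hub roles, and single
#' merged day communities.
#'
#' @param n_encounters number of encounters.
#' @param day_fraction probability that an encounter arrives during a day
#'   shift (07:00-18:59).
#' @param locations ordered subset of `c("ED","FLOOR","PICU")`; encounters
#'   flow ED, then optionally PICU, then floor, restricted to this set.
#' @param roster_spec see [default_roster_spec()].
#' @param ground_truth_day,ground_truth_night see [default_ground_truth()].
#' @param bursts_per_shift integer range `c(min,max)` of activity bursts per
#'   shift-location window.
#' @param within_burst_gap_minutes uniform range for consecutive gaps inside
#'   a burst; support must lie strictly below `between_burst_gap_minutes`.
#' @param between_burst_gap_minutes uniform range for burst-to-burst gaps;
#'   support must exceed the 120-minute top of the break grid so planted
#'   bursts are recoverable as segments.
#' @param noise_coocc_rate per-window probability of a spurious one-off
#'   pairing of roles from different communities.
#' @param unresolved_role_fraction per-record probability that the actor's
#'   service is unrecoverable.
#' @param student_system_fraction per-record probability that the record is
#'   student- or system-initiated.
#' @param member_include_prob per-burst inclusion probability of a community
#'   member role.
#' @param hub_include_prob per-burst inclusion probability of a hub role;
#'   deliberately below `member_include_prob` so hub edges carry intermediate
#'   weights, as coordinating services round with each specialty team
#'   intermittently rather than continuously.
#' @param events_per_role integer range of records a role emits per burst.
#' @param ed_los_minutes,floor_los_hours,picu_los_days uniform ranges for
#'   lengths of stay; `picu_fraction` of encounters pass through the PICU.
#' @param picu_fraction probability of PICU admission.
#' @param seed integer seed; identical config + seed is bit-reproducible.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_encounters = 413L,
                         day_fraction = 0.659,
                         locations = c("ED", "FLOOR", "PICU"),
                         roster_spec = default_roster_spec(),
                         ground_truth_day = default_ground_truth("day"),
                         ground_truth_night = default_ground_truth("night"),
                         bursts_per_shift = c(1L, 3L),
                         within_burst_gap_minutes = c(1, 10),
                         between_burst_gap_minutes = c(150, 240),
                         noise_coocc_rate = 0.3,
                         unresolved_role_fraction = 0.002,
                         student_system_fraction = 0.05,
                         member_include_prob = 0.9,
                         hub_include_prob = 0.65,
                         events_per_role = c(1L, 2L),
                         ed_los_minutes = c(180, 360),
                         floor_los_hours = c(24, 96),
                         picu_los_days = c(1, 3),
                         picu_fraction = 0.17,
                         seed = 1L) {
  cfg <- list(
    n_encounters = as.integer(n_encounters), day_fraction = day_fraction,
    locations = locations, roster_spec = data.table::as.data.table(roster_spec),
    ground_truth_day = ground_truth_day, ground_truth_night = ground_truth_night,
    bursts_per_shift = as.integer(bursts_per_shift),
    within_burst_gap_minutes = within_burst_gap_minutes,
    between_burst_gap_minutes = between_burst_gap_minutes,
    noise_coocc_rate = noise_coocc_rate,
    unresolved_role_fraction = unresolved_role_fraction,
    student_system_fraction = student_system_fraction,
    member_include_prob = member_include_prob,
    hub_include_prob = hub_include_prob,
    events_per_role = as.integer(events_per_role),
    ed_los_minutes = ed_los_minutes, floor_los_hours = floor_los_hours,
    picu_los_days = picu_los_days, picu_fraction = picu_fraction,
    seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  probs <- c(day_fraction = cfg$day_fraction,
             noise_coocc_rate = cfg$noise_coocc_rate,
             unresolved_role_fraction = cfg$unresolved_role_fraction,
             student_system_fraction = cfg$student_system_fraction,
             member_include_prob = cfg$member_include_prob,
             hub_include_prob = cfg$hub_include_prob,
             picu_fraction = cfg$picu_fraction)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad)) {
    stop("synth_config: field(s) out of [0,1]: ", paste(bad, collapse = ", "))
  }
  if (!all(cfg$locations %in% CARE_LOCATIONS) || length(cfg$locations) == 0L) {
    stop("synth_config: locations must be a non-empty subset of ",
         paste(CARE_LOCATIONS, collapse = "/"))
  }
  if (max(cfg$within_burst_gap_minutes) >= min(cfg$between_burst_gap_minutes)) {
    stop("synth_config: within_burst_gap_minutes support must lie strictly ",
         "below between_burst_gap_minutes support")
  }
  if (cfg$n_encounters < 1L) stop("synth_config: n_encounters must be >= 1")
  invisible(cfg)
}

# Ground-truth spec for one shift type / location, or NULL.
truth_spec_for <- function(cfg, shift_type, location) {
  gt <- if (shift_type == "day") cfg$ground_truth_day else cfg$ground_truth_night
  gt[[location]]
}

#' Planted role pairs for one sublog
#'
#' All within-community pairs (community members together with that shift
#' spec's hub roles) in canonical order; the complement of this set within a
#' sublog's edges is, by construction, noise.
#'
#' @param truth a ground-truth list as stored in a `synth_study`.
#' @param shift_type "day" or "night"; @param location care location.
#' @return data.table with `role_a`, `role_b` (role_a < role_b).
#' @export
planted_pairs <- function(truth, shift_type, location) {
  spec <- truth[[shift_type]][[location]]
  if (is.null(spec)) {
    return(data.table::data.table(role_a = character(), role_b = character()))
  }
  pair_list <- lapply(spec$communities, function(members) {
    roles <- sort(unique(c(members, spec$hubs)))
    if (length(roles) < 2L) return(NULL)
    cmb <- utils::combn(roles, 2L)
    data.table::data.table(role_a = cmb[1L, ], role_b = cmb[2L, ])
  })
  unique(data.table::rbindlist(pair_list))
}

#' Generate the synthetic cohort, roster, and ADT timelines
#'
#' @param config a [synth_config()].
#' @return Object of class `synth_study` with `encounters`, `roster`, `adt`,
#'   `truth`, and an empty `records` slot.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  check_truth_covered(config)
  set.seed(config$seed)
  n <- config$n_encounters

  # Arrival wall-clock: date uniform over 2017, minute-of-day uniform within
  # the sampled shift window.
  is_day <- runif(n) < config$day_fraction
  day0 <- as.POSIXct("2017-01-01 00:00:00", tz = "UTC")
  doy <- sample.int(365L, n, replace = TRUE) - 1L
  mod <- ifelse(is_day,
                DAY_START_MIN + runif(n) * SHIFT_MINUTES,
                (DAY_START_MIN + SHIFT_MINUTES + runif(n) * SHIFT_MINUTES) %% 1440)
  arrival <- day0 + doy * 86400 + round(mod) * 60

  act_p_day <- c(alpha = 0.096, bravo = 0.816, critical_transfer = 0.088)
  act_p_night <- c(alpha = 0.036, bravo = 0.702, critical_transfer = 0.262)
  activation <- vapply(is_day, function(d) {
    sample(names(act_p_day), 1L, prob = if (d) act_p_day else act_p_night)
  }, character(1))
  origin <- vapply(is_day, function(d) {
    sample(c("scene", "transfer", "other"), 1L,
           prob = if (d) c(0.92, 0.04, 0.04) else c(0.72, 0.27, 0.01))
  }, character(1))
  injury <- vapply(is_day, function(d) {
    sample(c("blunt", "penetrating", "other"), 1L,
           prob = if (d) c(0.952, 0.018, 0.030) else c(0.894, 0.078, 0.028))
  }, character(1))

  ed_los <- runif(n, config$ed_los_minutes[1], config$ed_los_minutes[2])
  has_picu <- "PICU" %in% config$locations &
    runif(n) < config$picu_fraction
  picu_los <- ifelse(has_picu,
                     runif(n, config$picu_los_days[1], config$picu_los_days[2]) * 1440,
                     0)
  has_floor <- "FLOOR" %in% config$locations
  floor_los <- if (has_floor) {
    runif(n, config$floor_los_hours[1], config$floor_los_hours[2]) * 60
  } else rep(0, n)

  encounters <- data.table::data.table(
    encounter_id = sprintf("E%04d", seq_len(n)),
    arrival_clock = arrival,
    age_years = pmin(17L, rpois(n, ifelse(is_day, 7, 10))),
    sex = ifelse(runif(n) < ifelse(is_day, 0.677, 0.589), "male", "female"),
    activation_level = activation,
    origin = origin,
    injury_type = injury,
    iss = rpois(n, 5L),
    gcs = sample(c(15L, 14L, 13L, 8L), n, replace = TRUE,
                 prob = c(0.85, 0.08, 0.04, 0.03)),
    ed_los_minutes = round(ed_los, 1),
    picu_admission = has_picu,
    mortality = runif(n) < ifelse(is_day, 0.026, 0.014)
  )
  encounters[, hosp_los_hours := round((ed_los + picu_los + floor_los) / 60, 2)]

  adt <- data.table::rbindlist(lapply(seq_len(n), function(i) {
    locs <- "ED"
    ends <- ed_los[i]
    if (has_picu[i]) { locs <- c(locs, "PICU"); ends <- c(ends, ends[length(ends)] + picu_los[i]) }
    if (has_floor)   { locs <- c(locs, "FLOOR"); ends <- c(ends, ends[length(ends)] + floor_los[i]) }
    starts <- c(0, head(ends, -1L))
    data.table::data.table(encounter_id = encounters$encounter_id[i],
                           location = locs,
                           start_minute = round(starts, 2),
                           end_minute = round(ends, 2))
  }))

  roster <- build_roster(config$roster_spec)
  truth <- list(
    day = config$ground_truth_day,
    night = config$ground_truth_night
  )
  study <- list(encounters = encounters, roster = roster, adt = adt,
                records = empty_records(), truth = truth, config_seed = config$seed)
  class(study) <- "synth_study"
  study
}

check_truth_covered <- function(config) {
  needed <- unique(unlist(lapply(c(config$ground_truth_day, config$ground_truth_night),
                                 function(sp) c(unlist(sp$communities), sp$hubs))))
  missing <- setdiff(needed, config$roster_spec$role_label)
  if (length(missing)) {
    stop("ground-truth roles absent from roster_spec: ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

build_roster <- function(roster_spec) {
  rows <- roster_spec[rep(seq_len(.N), n_hcps)]
  rows[, hcp_id := sprintf("H%04d", seq_len(.N))]
  roster <- rows[, .(hcp_id, generic_role, role_label,
                     true_service = ifelse(is.na(service),
                                           LOCATION_SERVICE[base_location], service),
                     base_location, resolvable = TRUE)]
  extra <- data.table::data.table(
    hcp_id = c(sprintf("U%03d", 1:6), sprintf("S%03d", 1:10), "SYSTEM"),
    generic_role = c(rep("attending", 6), rep("medical_student", 10), "system"),
    role_label = NA_character_,
    true_service = NA_character_,
    base_location = NA_character_,
    resolvable = FALSE)
  rbind(roster, extra)
}

empty_records <- function() {
  data.table::data.table(
    encounter_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
    activity_type = character(), hcp_id = character(),
    generic_role = character(), service = character(),
    care_location = character(), cosigner_hcp_id = character(),
    cosigner_service = character(), system_initiated = logical(),
    student = logical())
}

# Shift-by-location windows of one encounter: the overlaps of its ADT
# intervals (minutes from arrival) with its 12-hour shift intervals.
encounter_windows <- function(arrival, adt_enc) {
  total <- max(adt_enc$end_minute)
  idx0 <- shift_index(arrival)
  # minutes from arrival to the end of shift 0
  first_end <- (idx0 + 1L) * SHIFT_MINUTES + DAY_START_MIN - as.numeric(arrival) / 60
  bounds <- c(0, seq(first_end, total + SHIFT_MINUTES, by = SHIFT_MINUTES))
  bounds <- bounds[bounds < total]
  shift_starts <- bounds
  shift_ends <- c(bounds[-1L], total)
  out <- list()
  for (s in seq_along(shift_starts)) {
    for (r in seq_len(nrow(adt_enc))) {
      lo <- max(shift_starts[s], adt_enc$start_minute[r])
      hi <- min(shift_ends[s], adt_enc$end_minute[r])
      if (hi - lo >= 30) {
        out[[length(out) + 1L]] <- data.table::data.table(
          shift_number = s - 1L,
          shift_type = shift_type_of_index(idx0 + s - 1L),
          location = adt_enc$location[r],
          w_start = lo, w_end = hi)
      }
    }
  }
  data.table::rbindlist(out)
}

# Records of one activity burst: included roles each emit 1..k records; the
# first record of physicians is a note (service-carrying or cosigned) so that
# role resolution has evidence to work with.
burst_records <- function(roles, roster, location, t_start, config,
                          noise = FALSE) {
  recs <- list()
  for (rl in roles) {
    pool <- roster[role_label == rl]
    h <- pool[sample.int(nrow(pool), 1L)]
    n_rec <- sample(seq(config$events_per_role[1], config$events_per_role[2]), 1L)
    for (j in seq_len(n_rec)) {
      gr <- h$generic_role
      if (gr %in% c("attending", "fellow", "physician_assistant") ||
          (gr == "nurse_practitioner" && !is.na(h$true_service) &&
           !h$true_service %in% LOCATION_SERVICE)) {
        type <- if (j == 1L) "note" else sample_vec(c("note", "procedure_order", "medication_order"))
        svc <- if (type == "note") h$true_service else NA_character_
        cos_id <- NA_character_; cos_svc <- NA_character_
      } else if (gr %in% c("resident", "radiology_technician")) {
        type <- if (j == 1L) "note" else sample_vec(c("procedure_order", "medication_order"))
        svc <- NA_character_
        if (type == "note") {
          at_pool <- roster[generic_role == "attending" & true_service == h$true_service &
                              !is.na(true_service)]
          cos_id <- if (nrow(at_pool)) at_pool$hcp_id[sample.int(nrow(at_pool), 1L)] else NA_character_
          cos_svc <- h$true_service
        } else { cos_id <- NA_character_; cos_svc <- NA_character_ }
      } else if (gr %in% c("registered_nurse", "nurse_practitioner", "nurse_technician")) {
        # one-off records away from the base unit are order-type, so they
        # carry their location rather than being inferred and base-checked
        type <- if (noise) "medication_admin" else
          sample_vec(c("flowsheet", "flowsheet", "medication_admin"))
        svc <- NA_character_; cos_id <- NA_character_; cos_svc <- NA_character_
      } else {  # allied professionals
        type <- sample_vec(c("flowsheet", "note"))
        svc <- NA_character_; cos_id <- NA_character_; cos_svc <- NA_character_
      }
      loc <- if (type %in% c("procedure_order", "medication_order", "medication_admin")) {
        location
      } else NA_character_
      recs[[length(recs) + 1L]] <- data.table::data.table(
        activity_type = type, hcp_id = h$hcp_id, generic_role = gr,
        service = svc, care_location = loc,
        cosigner_hcp_id = cos_id, cosigner_service = cos_svc)
    }
  }
  dt <- data.table::rbindlist(recs)
  dt <- dt[sample.int(nrow(dt))]  # interleave roles within the burst
  gaps <- runif(nrow(dt) - 1L, config$within_burst_gap_minutes[1],
                config$within_burst_gap_minutes[2])
  dt[, t_offset := t_start + cumsum(c(0, gaps))]
  dt
}

#' Populate a cohort with raw activity records
#'
#' Bursty, community-structured activity: each shift-location window carries
#' one planted community; its member roles (at `member_include_prob`) and the
#' hub roles (at `hub_include_prob`) emit records in bursts whose internal
#' gaps come from the within-burst distribution and whose spacing comes from
#' the between-burst distribution. Spurious cross-community pairings are
#' added at `noise_coocc_rate` per window, and individual records are
#' reassigned to unresolvable actors or flagged student-/system-initiated at
#' the configured rates.
#'
#' @param study a `synth_study` from [generate_cohort()].
#' @param config the same [synth_config()].
#' @return The study with `records` populated.
#' @export
generate_activity_records <- function(study, config) {
  stopifnot(inherits(study, "synth_study"))
  check_truth_covered(config)
  set.seed(config$seed + 1L)
  roster <- study$roster
  noise_pools <- build_noise_pools(config)
  all_recs <- vector("list", nrow(study$encounters))

  for (i in seq_len(nrow(study$encounters))) {
    enc <- study$encounters[i]
    adt_enc <- study$adt[encounter_id == enc$encounter_id]
    wins <- encounter_windows(enc$arrival_clock, adt_enc)
    if (nrow(wins) == 0L) next
    enc_recs <- list()
    for (w in seq_len(nrow(wins))) {
      win <- wins[w]
      spec <- truth_spec_for(config, win$shift_type, win$location)
      if (is.null(spec)) next
      comm <- spec$communities[[sample.int(length(spec$communities), 1L)]]
      n_bursts <- sample(seq(config$bursts_per_shift[1], config$bursts_per_shift[2]), 1L)
      t_cur <- win$w_start + runif(1, 0, 10)
      last_end <- t_cur
      for (b in seq_len(n_bursts)) {
        if (t_cur > win$w_end - 15) break
        members <- comm[runif(length(comm)) < config$member_include_prob]
        hubs_in <- spec$hubs[runif(length(spec$hubs)) < config$hub_include_prob]
        roles <- unique(c(members, hubs_in))
        if (length(roles) == 0L) roles <- sample_vec(comm)
        dt <- burst_records(roles, roster, win$location, t_cur, config)
        dt <- dt[t_offset < win$w_end]
        if (nrow(dt)) {
          enc_recs[[length(enc_recs) + 1L]] <- dt
          last_end <- max(dt$t_offset)
        }
        t_cur <- last_end + runif(1, config$between_burst_gap_minutes[1],
                                  config$between_burst_gap_minutes[2])
      }
      # spurious one-off pairing in its own segment after the last burst
      if (runif(1) < config$noise_coocc_rate) {
        pair <- pop_noise_pair(noise_pools, win$shift_type, win$location)
        t_noise <- last_end + runif(1, NOISE_GAP_RANGE[1], NOISE_GAP_RANGE[2])
        if (!is.null(pair) && t_noise < win$w_end - 15) {
          dt <- burst_records(pair, roster, win$location, t_noise, config,
                              noise = TRUE)
          dt <- dt[t_offset < win$w_end]
          if (nrow(dt)) enc_recs[[length(enc_recs) + 1L]] <- dt
        }
      }
    }
    if (length(enc_recs) == 0L) next
    dt <- data.table::rbindlist(enc_recs)
    dt[, encounter_id := enc$encounter_id]
    dt[, timestamp := enc$arrival_clock + round(t_offset * 60)]
    all_recs[[i]] <- dt
  }

  rec <- data.table::rbindlist(all_recs)
  if (nrow(rec) == 0L) {
    study$records <- empty_records()
    return(study)
  }
  rec[, `:=`(system_initiated = FALSE, student = FALSE)]

  # Per-record corruption: unresolvable actor, or student/system initiation.
  u <- runif(nrow(rec))
  f <- config$unresolved_role_fraction
  s <- config$student_system_fraction
  unres <- which(u < f)
  if (length(unres)) {
    pool <- roster[grepl("^U", hcp_id)]
    rec[unres, `:=`(hcp_id = pool$hcp_id[sample.int(nrow(pool), length(unres), replace = TRUE)],
                    generic_role = "attending", service = NA_character_,
                    cosigner_hcp_id = NA_character_, cosigner_service = NA_character_)]
  }
  ss <- which(u >= f & u < f + s)
  if (length(ss)) {
    half <- runif(length(ss)) < 0.5
    stud <- ss[half]; sysr <- ss[!half]
    if (length(stud)) {
      pool <- roster[grepl("^S", hcp_id) & generic_role == "medical_student"]
      rec[stud, `:=`(student = TRUE,
                     hcp_id = pool$hcp_id[sample.int(nrow(pool), length(stud), replace = TRUE)],
                     generic_role = "medical_student", service = NA_character_,
                     cosigner_hcp_id = NA_character_, cosigner_service = NA_character_)]
    }
    if (length(sysr)) {
      rec[sysr, `:=`(system_initiated = TRUE, hcp_id = "SYSTEM",
                     generic_role = "system", service = NA_character_,
                     cosigner_hcp_id = NA_character_, cosigner_service = NA_character_)]
    }
  }

  rec[, t_offset := NULL]
  data.table::setcolorder(rec, names(empty_records()))
  data.table::setorder(rec, encounter_id, timestamp, hcp_id, activity_type)
  study$records <- rec
  study
}

# Spurious pairings are near-one-off: for each (shift type, location) a
# pool of candidate role pairs, each present NOISE_MAX_REPEATS times, is
# drawn down without replacement, so a spurious pair can recur at most that
# many times and never accumulates enough shared shifts to pass a plausible
# threshold. Candidates are
# non-hub roles from the whole roster (incidental documentation overlap
# routinely crosses units, e.g. a PICU nurse recording during transport
# through the ED) that do not sit inside a planted community of the shift
# type. Residents and radiology technicians are excluded: their service is
# resolved per encounter from cosigned notes, so a one-off appearance would
# either be unresolvable or drag their cosigning attending in with them;
# allied professionals are excluded because their note/flow-sheet records
# away from the base unit are dropped by the off-base-unit rule.
NOISE_GENERIC_ROLES <- c("attending", "fellow", "nurse_practitioner",
                         "physician_assistant", "registered_nurse",
                         "nurse_technician")
NOISE_MAX_REPEATS <- 3L

# Spurious bursts are placed this long after the last planted burst: just
# beyond the top of the 30-120 minute break grid, so they always form their
# own segment yet still fit short shift-location windows (e.g. ED stays).
NOISE_GAP_RANGE <- c(125, 150)

build_noise_pools <- function(config) {
  pools <- new.env(parent = emptyenv())
  truth <- list(day = config$ground_truth_day, night = config$ground_truth_night)
  for (st in c("day", "night")) {
    for (loc in config$locations) {
      spec <- truth_spec_for(config, st, loc)
      if (is.null(spec)) next
      universe <- sort(setdiff(
        config$roster_spec[generic_role %in% NOISE_GENERIC_ROLES, role_label],
        spec$hubs))
      if (length(universe) < 2L) next
      cmb <- utils::combn(universe, 2L)
      keys <- edge_key(cmb[1L, ], cmb[2L, ])
      within <- planted_pairs(truth, st, loc)
      keep <- !keys %in% edge_key(within$role_a, within$role_b)
      pool <- data.table::data.table(role_a = cmb[1L, keep],
                                     role_b = cmb[2L, keep])
      assign(paste(st, loc, sep = "."),
             pool[rep(seq_len(.N), NOISE_MAX_REPEATS)],
             envir = pools)
    }
  }
  pools
}

pop_noise_pair <- function(pools, shift_type, location) {
  key <- paste(shift_type, location, sep = ".")
  if (!exists(key, envir = pools)) return(NULL)
  pool <- get(key, envir = pools)
  if (nrow(pool) == 0L) return(NULL)
  i <- sample.int(nrow(pool), 1L)
  pair <- c(pool$role_a[i], pool$role_b[i])
  assign(key, pool[-i], envir = pools)
  pair
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: [generate_cohort()] then
#' [generate_activity_records()].
#'
#' @param config a [synth_config()].
#' @return A populated `synth_study`.
#' @export
generate_study <- function(config = synth_config()) {
  generate_activity_records(generate_cohort(config), config)
}

#' @export
print.synth_study <- function(x, ...) {
  cat("Synthetic EHR study:", nrow(x$encounters), "encounters,",
      nrow(x$roster), "HCPs,", nrow(x$records), "activity records\n")
  invisible(x)
}

# ---- raw dataset serialization ------------------------------------------

TIME_FMT <- "%Y-%m-%dT%H:%M:%S"

#' Write a synthetic study as a raw CSV/JSON dataset
#'
#' Emits `encounters.csv`, `roster.csv`, `adt.csv`, `records.csv` (RFC-4180,
#' header row, ISO-8601 timestamps, UTF-8, empty string for missing values)
#' and `truth.json`. The dataset round-trips losslessly through
#' [read_raw_dataset()].
#'
#' @param study a populated `synth_study`.
#' @param directory output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
write_raw_dataset <- function(study, directory) {
  stopifnot(inherits(study, "synth_study"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  paths <- c(encounters = file.path(directory, "encounters.csv"),
             roster = file.path(directory, "roster.csv"),
             adt = file.path(directory, "adt.csv"),
             records = file.path(directory, "records.csv"),
             truth = file.path(directory, "truth.json"))
  enc <- data.table::copy(study$encounters)
  enc[, arrival_clock := format(arrival_clock, TIME_FMT, tz = "UTC")]
  data.table::fwrite(enc, paths["encounters"], na = "")
  data.table::fwrite(study$roster, paths["roster"], na = "")
  data.table::fwrite(study$adt, paths["adt"], na = "")
  rec <- data.table::copy(study$records)
  rec[, timestamp := format(timestamp, TIME_FMT, tz = "UTC")]
  data.table::fwrite(rec, paths["records"], na = "")
  jsonlite::write_json(study$truth, paths["truth"], auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(paths)
}

#' Read a raw dataset written by [write_raw_dataset()]
#'
#' Also the entry point for user-supplied data in the same CSV dialect
#' (`truth.json` and `roster.csv` are optional for user data).
#'
#' @param directory dataset directory.
#' @return A `synth_study` (with `truth = NULL` if no truth.json present).
#' @export
read_raw_dataset <- function(directory) {
  read_csv_dt <- function(p) data.table::fread(p, na.strings = "", colClasses = NULL)
  enc <- read_csv_dt(file.path(directory, "encounters.csv"))
  enc[, arrival_clock := as.POSIXct(arrival_clock, format = TIME_FMT, tz = "UTC")]
  rec_path <- file.path(directory, "records.csv")
  rec <- read_csv_dt(rec_path)
  if (nrow(rec)) {
    rec[, timestamp := as.POSIXct(timestamp, format = TIME_FMT, tz = "UTC")]
    for (col in c("system_initiated", "student")) {
      if (!is.logical(rec[[col]])) rec[, (col) := as.logical(get(col))]
    }
    for (col in c("service", "care_location", "cosigner_hcp_id", "cosigner_service")) {
      if (!is.character(rec[[col]])) rec[, (col) := as.character(get(col))]
    }
  } else {
    rec <- empty_records()
  }
  adt <- read_csv_dt(file.path(directory, "adt.csv"))
  roster_path <- file.path(directory, "roster.csv")
  roster <- if (file.exists(roster_path)) read_csv_dt(roster_path) else NULL
  truth_path <- file.path(directory, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::fromJSON(truth_path, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  } else NULL
  study <- list(encounters = enc, roster = roster, adt = adt,
                records = rec, truth = truth)
  class(study) <- "synth_study"
  study
}
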