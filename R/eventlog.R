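# Master event log preparation: timestamp normalization, exclusions,
# location inference from ADT, functional-role resolution, multi-HCP
# fan-out, and shift labeling.

#' Normalize record timestamps to minutes from ED arrival
#'
#' Replaces wall-clock timestamps with `t_norm`, real-valued minutes from the
#' encounter's ED arrival. Records timestamped before arrival
#' (pre-registration artifacts) are dropped, with their count reported via a
#' message and the `"n_pre_arrival"` attribute.
#'
#' @param records raw activity records (data.table).
#' @param encounters encounter table with `encounter_id`, `arrival_clock`.
#' @return Records with a `t_norm` column, ordered by encounter and time.
#' @export
normalize_timestamps <- function(records, encounters) {
  records <- data.table::as.data.table(records)
  unknown <- setdiff(records$encounter_id, encounters$encounter_id)
  if (length(unknown)) {
    stop("records reference unknown encounter_id(s): ",
         paste(head(unknown, 5), collapse = ", "))
  }
  out <- data.table::copy(records)
  out[encounters, arrival_clock := i.arrival_clock, on = "encounter_id"]
  out[, t_norm := as.numeric(difftime(timestamp, arrival_clock, units = "mins"))]
  n_pre <- sum(out$t_norm < 0, na.rm = TRUE)
  if (n_pre > 0) {
    message("normalize_timestamps: dropping ", n_pre,
            " record(s) timestamped before ED arrival")
  }
  out <- out[is.na(t_norm) | t_norm >= 0]
  out[, arrival_clock := NULL]
  data.table::setorder(out, encounter_id, t_norm, na.last = TRUE)
  data.table::setattr(out, "n_pre_arrival", n_pre)
  out[]
}

#' Apply record-level exclusions
#'
#' Drops system-initiated records, records by student roles, and records
#' without a full complement of data (missing encounter, time, activity
#' type, actor, or generic role). Kept and excluded partition the input;
#' every exclusion carries a machine-readable reason.
#'
#' @param records normalized records.
#' @return List with `kept` and `excluded` (the latter with a `reason`
#'   column: `"system"`, `"student"`, or `"incomplete"`).
#' @export
apply_exclusions <- function(records) {
  records <- data.table::as.data.table(records)
  reason <- rep(NA_character_, nrow(records))
  incomplete <- is.na(records$encounter_id) | is.na(records$t_norm) |
    is.na(records$activity_type) | is.na(records$hcp_id) |
    records$hcp_id == "" | is.na(records$generic_role)
  reason[incomplete] <- "incomplete"
  reason[!is.na(records$student) & records$student] <- "student"
  reason[!is.na(records$system_initiated) & records$system_initiated] <- "system"
  keep <- is.na(reason)
  excluded <- records[!keep]
  data.table::set(excluded, j = "reason", value = reason[!keep])
  list(kept = records[keep], excluded = excluded)
}

#' Infer the care location of a time point from an ADT timeline
#'
#' Intervals are half-open `[start, end)`; times at or beyond the final
#' interval's end clamp to the last location (documentation continuing after
#' discharge from the last recorded unit).
#'
#' @param t_norm non-negative minutes from ED arrival (vectorized).
#' @param timeline data.table with `location`, `start_minute`, `end_minute`,
#'   contiguous and starting at 0.
#' @return Character vector of locations.
#' @export
infer_location <- function(t_norm, timeline) {
  if (any(t_norm < 0, na.rm = TRUE)) {
    stop("infer_location: t_norm must be non-negative")
  }
  if (nrow(timeline) == 0L) stop("infer_location: empty timeline")
  tl <- data.table::as.data.table(timeline)
  data.table::setorder(tl, start_minute)
  idx <- findInterval(t_norm, tl$start_minute)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(tl)] <- nrow(tl)
  tl$location[idx]
}

#' Fill in care locations for notes and flow sheets from ADT data
#'
#' Order and medication records already carry their care location; note and
#' flow-sheet records have theirs inferred from the encounter's ADT timeline
#' via [infer_location()].
#'
#' @param records normalized, exclusion-filtered records.
#' @param adt ADT intervals for all encounters.
#' @return Records with `care_location` completed.
#' @export
assign_locations <- function(records, adt) {
  out <- data.table::copy(data.table::as.data.table(records))
  adt <- data.table::as.data.table(adt)
  need <- which(out$activity_type %in% c("note", "flowsheet"))
  if (!length(need)) return(out[])
  sub <- data.table::data.table(encounter_id = out$encounter_id[need],
                                t_norm = out$t_norm[need],
                                row_id = need)
  sub[, care_location := infer_location(t_norm, adt[encounter_id == .BY[[1]]]),
      by = encounter_id]
  out[sub$row_id, care_location := sub$care_location]
  out[]
}

# Generic-role classes for service resolution.
FIXED_SERVICE_ROLES <- c("attending", "fellow", "physician_assistant")
ENCOUNTER_SERVICE_ROLES <- c("resident", "radiology_technician")

#' Resolve functional roles (service-prefixed generic roles)
#'
#' Service resolution follows the role class:
#' \itemize{
#'   \item attendings, fellows, physician assistants, and specialty nurse
#'     practitioners: the modal service recorded on their own notes, applied
#'     globally;
#'   \item residents and radiology technicians: per encounter, the modal
#'     cosigning-attending service of their notes in that encounter (ties
#'     broken towards the most recent note);
#'   \item nurses, unit nurse practitioners, and allied professionals: the
#'     service bound to the modal location of all their activities across the
#'     dataset (ties broken by earliest occurrence, then lexicographically).
#' }
#' Records of HCPs (or HCP-encounters) without resolvable service are
#' excluded with reason `"unresolved_role"`; note/flow-sheet records of
#' unit-based staff whose inferred location differs from their base unit are
#' excluded with reason `"off_base_unit"`.
#'
#' @param records location-completed records.
#' @param roster optional roster with `hcp_id`, `generic_role` (used to fill
#'   missing generic roles; service evidence always comes from the records).
#' @return List with `kept` (records gaining `resolved_service`,
#'   `functional_role`) and `excluded` (with `reason`).
#' @export
resolve_functional_roles <- function(records, roster = NULL) {
  rec <- data.table::copy(data.table::as.data.table(records))
  if (!is.null(roster) && any(is.na(rec$generic_role))) {
    roster <- data.table::as.data.table(roster)
    rec[is.na(generic_role), generic_role :=
          roster$generic_role[match(hcp_id, roster$hcp_id)]]
  }

  # Specialty NPs are those with service evidence on their notes; the rest
  # are unit-based.
  np_has_service <- rec[generic_role == "nurse_practitioner",
                        .(has = any(!is.na(service))), by = hcp_id]
  fixed_ids <- unique(c(
    rec[generic_role %in% FIXED_SERVICE_ROLES, hcp_id],
    np_has_service[has == TRUE, hcp_id]))
  enc_ids <- unique(rec[generic_role %in% ENCOUNTER_SERVICE_ROLES, hcp_id])
  loc_ids <- setdiff(unique(rec$hcp_id), c(fixed_ids, enc_ids))

  rec[, resolved_service := NA_character_]
  rec[, base_unit := NA_character_]

  if (length(fixed_ids)) {
    fix <- rec[hcp_id %in% fixed_ids,
               .(svc = modal_value(service, t_norm)), by = hcp_id]
    rec[fix, resolved_service := i.svc, on = "hcp_id"]
  }
  if (length(enc_ids)) {
    pe <- rec[hcp_id %in% enc_ids & activity_type == "note" &
                !is.na(cosigner_service),
              # most-recent-note tie-break: negate time so the later note's
              # service wins among equally frequent services
              .(svc = modal_value(cosigner_service, -t_norm)),
              by = .(hcp_id, encounter_id)]
    rec[pe, resolved_service := i.svc, on = c("hcp_id", "encounter_id")]
  }
  if (length(loc_ids)) {
    lo <- rec[hcp_id %in% loc_ids & !is.na(care_location),
              .(svc_loc = modal_value(care_location, t_norm)), by = hcp_id]
    lo[, svc := LOCATION_SERVICE[svc_loc]]
    rec[lo, `:=`(resolved_service = i.svc, base_unit = i.svc_loc),
        on = "hcp_id"]
  }

  reason <- rep(NA_character_, nrow(rec))
  reason[is.na(rec$resolved_service)] <- "unresolved_role"
  off <- !is.na(rec$base_unit) &
    rec$activity_type %in% c("note", "flowsheet") &
    !is.na(rec$care_location) & rec$care_location != rec$base_unit
  reason[is.na(reason) & off] <- "off_base_unit"

  rec[, functional_role := ifelse(is.na(resolved_service), NA_character_,
                                  paste0(resolved_service, "_",
                                         role_abbrev(generic_role)))]
  keep <- is.na(reason)
  excluded <- rec[!keep]
  data.table::set(excluded, j = "reason", value = reason[!keep])
  kept <- rec[keep]
  kept[, base_unit := NULL]
  list(kept = kept, excluded = excluded)
}

#' Build the master event log
#'
#' One event per (record, involved HCP): notes with a cosigning attending
#' fan out into two same-time events, the cosigner carrying the
#' attending functional role of the cosigning service. Note creation time is
#' used as the note's event time. Each event is labeled with its shift
#' number (0 for the arrival shift, incrementing at every 07:00/19:00
#' boundary crossed) and shift type.
#'
#' @param records role-resolved records.
#' @param encounters encounter table with `arrival_clock`.
#' @return `master_log` data.table sorted by (encounter, t_norm, stable
#'   input order) with columns `encounter_id`, `t_norm`, `activity_type`,
#'   `hcp_id`, `functional_role`, `care_location`, `shift_number`,
#'   `shift_type`, `segment_id` (NA until segmentation).
#' @export
build_master_log <- function(records, encounters) {
  rec <- data.table::copy(data.table::as.data.table(records))
  rec[, .input_order := .I]
  base_cols <- c("encounter_id", "t_norm", "activity_type", "hcp_id",
                 "functional_role", "care_location", ".input_order")
  events <- rec[, ..base_cols]

  cos <- rec[activity_type == "note" & !is.na(cosigner_hcp_id) &
               !is.na(cosigner_service)]
  if (nrow(cos)) {
    cos_ev <- cos[, .(encounter_id, t_norm, activity_type, hcp_id = cosigner_hcp_id,
                      functional_role = paste0(cosigner_service, "_AT"),
                      care_location, .input_order = .input_order + 0.5)]
    events <- rbind(events, cos_ev)
  }

  enc <- data.table::as.data.table(encounters)
  events[enc, arrival_clock := i.arrival_clock, on = "encounter_id"]
  wall <- events$arrival_clock + round(events$t_norm * 60)
  idx <- shift_index(wall)
  idx0 <- shift_index(events$arrival_clock)
  events[, shift_number := idx - idx0]
  events[, shift_type := shift_type_of_index(idx)]
  events[, `:=`(arrival_clock = NULL)]
  events[, segment_id := NA_integer_]
  data.table::setorder(events, encounter_id, t_norm, .input_order)
  events[, .input_order := NULL]
  events[]
}

#' Prepare a master event log from a raw study in one call
#'
#' Chains [normalize_timestamps()], [apply_exclusions()],
#' [assign_locations()], [resolve_functional_roles()], and
#' [build_master_log()], collecting all exclusions.
#'
#' @param study a `synth_study` (or compatible list of tables).
#' @return List with `master_log`, `exclusions`, and `counts` (records in,
#'   events out, exclusions by reason).
#' @export
prepare_master_log <- function(study) {
  norm <- normalize_timestamps(study$records, study$encounters)
  ex1 <- apply_exclusions(norm)
  located <- assign_locations(ex1$kept, study$adt)
  ex2 <- resolve_functional_roles(located, study$roster)
  log <- build_master_log(ex2$kept, study$encounters)
  common <- intersect(names(ex1$excluded), names(ex2$excluded))
  exclusions <- rbind(ex1$excluded[, common, with = FALSE],
                      ex2$excluded[, common, with = FALSE])
  counts <- list(
    n_records_in = nrow(study$records),
    n_pre_arrival = attr(norm, "n_pre_arrival") %||% 0L,
    n_excluded = nrow(exclusions),
    excluded_by_reason = if (nrow(exclusions)) {
      as.list(table(exclusions$reason))
    } else list(),
    n_events = nrow(log))
  list(master_log = log, exclusions = exclusions, counts = counts)
}
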