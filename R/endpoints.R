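# Endpoint ascertainment: in-hospital death, 30-day all-cause death,
# 30-day rehospitalization and recurrent VTE, and their composite.
#
# Day arithmetic is inclusive: "within 30 days of admission" means
# event_date <= admit_date + 30 calendar days. Members not discharged within
# the window are not evaluable for rehospitalization and recurrent VTE
# (their stay occupies the whole window); they contribute to the composite
# through death only.

#' In-hospital death
#'
#' True when the index claim's discharge status is `expired` or the death
#' file places the death inside the hospitalization (either source suffices;
#' claims discharge status and death-master-file linkage are independently
#' incomplete).
#'
#' @param events Cohort/event table with `member_id`, `admit_date`,
#'   `discharge_date`, `discharge_status`.
#' @param members Member table with `member_id`, `death_date`.
#' @return Logical vector.
#' @export
in_hospital_death <- function(events, members) {
  death <- members$death_date[match(events$member_id, members$member_id)]
  events$discharge_status == "expired" |
    (!is.na(death) & death >= events$admit_date & death <= events$discharge_date)
}

#' Death within the 30-day window
#'
#' True when the member died in hospital with the death inside the window, or
#' died (any location) on or before `admit_date + window_days`. An in-hospital
#' death on day 35 of a long stay counts as in-hospital death but not as
#' 30-day death, which is why the two 2x2 panels can differ in both margins.
#'
#' @inheritParams in_hospital_death
#' @param window_days Window length in days from admission (inclusive).
#' @return Logical vector.
#' @export
death_within_30d <- function(events, members, window_days = 30) {
  death <- members$death_date[match(events$member_id, members$member_id)]
  inh <- in_hospital_death(events, members)
  in_window <- !is.na(death) & death <= events$admit_date + window_days
  # discharge-status-only deaths (no death-file date) are taken to have
  # occurred during the stay: in-window iff discharge is
  (inh & is.na(death) & events$discharge_date <= events$admit_date + window_days) |
    in_window
}

#' 30-day rehospitalization
#'
#' A new all-cause inpatient claim admitted strictly after the index
#' discharge and no later than `admit_date + window_days`. Members not
#' discharged within the window are not evaluable (`NA`).
#'
#' @param events Event table (`member_id`, `claim_id`, `admit_date`,
#'   `discharge_date`).
#' @param claims Claims table.
#' @param window_days Window length in days from the index admission.
#' @return Logical vector with `NA` for non-evaluable members.
#' @export
rehospitalization_30d <- function(events, claims, window_days = 30) {
  out <- rep(FALSE, nrow(events))
  out[events$discharge_date > events$admit_date + window_days] <- NA
  ip <- claims[claims$setting == "inpatient" &
                 !(claims$claim_id %in% events$claim_id), , drop = FALSE]
  if (nrow(ip)) {
    idx <- match(ip$member_id, events$member_id)
    ok <- !is.na(idx) &
      ip$admit_date > events$discharge_date[idx] &
      ip$admit_date <= events$admit_date[idx] + window_days
    hit <- events$member_id %in% unique(ip$member_id[ok])
    out[hit & !is.na(out)] <- TRUE
  }
  out
}

#' 30-day recurrent venous thromboembolism
#'
#' A PE or DVT diagnosis code on an emergency-department or inpatient claim
#' admitted strictly after the index discharge (recurrence requires a new
#' encounter) and within the window; outpatient claims never qualify. Same
#' evaluability rule as [rehospitalization_30d()]. The window is anchored at
#' the index admission by default (`anchor = "admission"`), parallel to the
#' rehospitalization endpoint; `"discharge"` anchors it at index discharge.
#'
#' @inheritParams rehospitalization_30d
#' @param registry A `code_registry` (supplies the `pe` and `dvt` sets).
#' @param anchor `"admission"` or `"discharge"`.
#' @return Logical vector with `NA` for non-evaluable members.
#' @export
recurrent_vte_30d <- function(events, claims, registry, window_days = 30,
                              anchor = c("admission", "discharge")) {
  anchor <- match.arg(anchor)
  out <- rep(FALSE, nrow(events))
  out[events$discharge_date > events$admit_date + window_days] <- NA
  cl <- claims[claims$setting %in% c("inpatient", "emergency") &
                 !(claims$claim_id %in% events$claim_id), , drop = FALSE]
  if (nrow(cl)) {
    dx <- split_codes(cl$diagnosis_codes)
    pe <- registry_set(registry, "pe")
    dvt <- registry_set(registry, "dvt")
    vte_claim <- vapply(dx, function(v) {
      length(v) > 0L && any(code_matches(v, pe) | code_matches(v, dvt))
    }, logical(1))
    cl <- cl[vte_claim, , drop = FALSE]
    idx <- match(cl$member_id, events$member_id)
    anchor_date <- if (anchor == "admission") events$admit_date else events$discharge_date
    ok <- !is.na(idx) &
      cl$admit_date > events$discharge_date[idx] &
      cl$admit_date <= anchor_date[idx] + window_days
    hit <- events$member_id %in% unique(cl$member_id[ok])
    out[hit & !is.na(out)] <- TRUE
  }
  out
}

#' 30-day composite outcome
#'
#' Death within 30 days, rehospitalization, or recurrent VTE. Non-evaluable
#' rehospitalization/VTE indicators contribute only through death, so the
#' composite is defined (never `NA`) for every cohort member.
#'
#' @param outcomes Data frame with `death_30d`, `rehospitalization_30d`,
#'   `recurrent_vte_30d`.
#' @return Logical vector.
#' @export
composite_30d <- function(outcomes) {
  outcomes$death_30d |
    outcomes$rehospitalization_30d %in% TRUE |
    outcomes$recurrent_vte_30d %in% TRUE
}

#' Length of stay in whole days
#'
#' @param events Event table with `admit_date`, `discharge_date`.
#' @return Integer days (`discharge - admit`; same-day discharge is 0).
#' @export
length_of_stay <- function(events) {
  as.integer(events$discharge_date - events$admit_date)
}

#' Ascertain all endpoints for a cohort
#'
#' @param events Included cohort events (see [included_events()]).
#' @param claims,members Raw tables.
#' @param registry A `code_registry`.
#' @param window_days 30-day window length (days from admission, inclusive).
#' @param vte_anchor Anchor for the recurrent-VTE window.
#' @return Data frame, one row per event: `member_id`, `in_hospital_death`,
#'   `death_30d`, `discharged_within_30d`, `rehospitalization_30d`,
#'   `recurrent_vte_30d` (both `NA` when not evaluable), `composite_30d`,
#'   `length_of_stay`.
#' @export
ascertain_endpoints <- function(events, claims, members, registry,
                                window_days = 30, vte_anchor = "admission") {
  out <- data.frame(
    member_id = events$member_id,
    in_hospital_death = in_hospital_death(events, members),
    death_30d = death_within_30d(events, members, window_days),
    discharged_within_30d =
      events$discharge_date <= events$admit_date + window_days,
    rehospitalization_30d = rehospitalization_30d(events, claims, window_days),
    recurrent_vte_30d = recurrent_vte_30d(events, claims, registry,
                                          window_days, vte_anchor),
    stringsAsFactors = FALSE
  )
  out$composite_30d <- composite_30d(out)
  out$length_of_stay <- length_of_stay(events)
  out
}
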