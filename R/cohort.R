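# Index-event identification and inclusion/exclusion.
#
# An inpatient claim qualifies as a candidate index PE hospitalization when
# PE (415.1x) is coded in the primary position, or in a secondary position
# together with a primary PE-complication diagnosis or a complication
# procedure (thrombolysis, intubation, mechanical ventilation) anywhere on
# the claim. The earliest qualifying admission per member is the candidate.
# Inclusion then requires adult age, continuous enrollment for six calendar
# months before admission and three months after discharge (or until death),
# and a community (non-transfer) admission.

#' Find candidate index PE events
#'
#' @param claims Claims table.
#' @param registry A `code_registry`.
#' @return Data frame of candidate events, one per member with any qualifying
#'   admission: `member_id`, `claim_id`, `admit_date`, `discharge_date`,
#'   `qualifying_rule` (`primary_pe` / `secondary_pe_with_complication`),
#'   `admission_source`, `discharge_status`.
#' @export
find_candidate_events <- function(claims, registry) {
  stopifnot(inherits(registry, "code_registry"))
  ip <- claims[claims$setting == "inpatient", , drop = FALSE]
  empty <- data.frame(member_id = character(), claim_id = character(),
                      admit_date = as.Date(character()),
                      discharge_date = as.Date(character()),
                      qualifying_rule = character(),
                      admission_source = character(),
                      discharge_status = character(), stringsAsFactors = FALSE)
  if (nrow(ip) == 0L) return(empty)

  pe <- registry_set(registry, "pe")
  comp_dx <- registry_set(registry, "pe_complication")
  comp_pr <- registry_set(registry, "pe_complication_procedure")

  dx <- split_codes(ip$diagnosis_codes)
  pr <- split_codes(ip$procedure_codes)
  primary <- vapply(dx, function(v) if (length(v)) v[1L] else NA_character_,
                    character(1))
  has <- function(codes, set) length(codes) > 0L && any(code_matches(codes, set))

  primary_pe <- !is.na(primary) & code_matches_safe(primary, pe)
  secondary_pe <- mapply(function(v) length(v) > 1L && any(code_matches(v[-1L], pe)),
                         dx)
  comp_primary <- !is.na(primary) & code_matches_safe(primary, comp_dx)
  comp_proc <- vapply(pr, has, logical(1), set = comp_pr)
  qualifies <- primary_pe | (secondary_pe & (comp_primary | comp_proc))
  if (!any(qualifies)) return(empty)

  cand <- ip[qualifies, , drop = FALSE]
  cand$qualifying_rule <- ifelse(primary_pe[qualifies], "primary_pe",
                                 "secondary_pe_with_complication")
  cand <- cand[order(cand$member_id, cand$admit_date, cand$claim_id), , drop = FALSE]
  cand <- cand[!duplicated(cand$member_id), , drop = FALSE]
  out <- cand[, c("member_id", "claim_id", "admit_date", "discharge_date",
                  "qualifying_rule", "admission_source", "discharge_status")]
  row.names(out) <- NULL
  out
}

# code_matches on a vector that may contain NA (claims without diagnoses)
code_matches_safe <- function(codes, set) {
  out <- logical(length(codes))
  ok <- !is.na(codes) & nzchar(codes)
  if (any(ok)) out[ok] <- code_matches(codes[ok], set)
  out
}

#' Age in completed years at a date
#'
#' @param birth_date,at_date Date vectors (recycled).
#' @return Integer vector of whole years completed at `at_date`.
#' @examples
#' age_at(as.Date("1950-06-01"), as.Date("2010-05-31"))  # 59
#' age_at(as.Date("1950-06-01"), as.Date("2010-06-01"))  # 60
#' @export
age_at <- function(birth_date, at_date) {
  stopifnot(inherits(birth_date, "Date"), inherits(at_date, "Date"))
  y <- lubridate::year(at_date) - lubridate::year(birth_date)
  before_bday <- (lubridate::month(at_date) < lubridate::month(birth_date)) |
    (lubridate::month(at_date) == lubridate::month(birth_date) &
       lubridate::day(at_date) < lubridate::day(birth_date))
  as.integer(y - before_bday)
}

# merge enrollment spans that are separated by <= allowable_gap_days, then
# test whether any merged span contains [from, to]
covered <- function(starts, ends, from, to, allowable_gap_days = 0L) {
  if (to < from) return(TRUE)   # empty requirement
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1L]; me <- ends[1L]
  for (i in seq_along(starts)[-1L]) {
    if (as.integer(starts[i] - me) <= allowable_gap_days + 1L) {
      me <- max(me, ends[i])
    } else {
      if (ms <= from && me >= to) return(TRUE)
      ms <- starts[i]; me <- ends[i]
    }
  }
  ms <= from && me >= to
}

#' Apply inclusion and exclusion criteria to candidate events
#'
#' Keeps candidates aged 18 or more at admission, with enrollment continuously
#' covering the `pre_window_months` calendar months before admission and the
#' `post_window_months` months after discharge -- the post-discharge
#' requirement is waived from the date of death when the member dies inside
#' that window ("or until death") -- and excludes admissions transferred from
#' another facility. Each candidate's ledger entry records the first failed
#' criterion in the fixed order `not_adult`, `insufficient_pre_coverage`,
#' `insufficient_post_coverage`, `transfer`; included members carry `none`.
#'
#' @param candidates Output of [find_candidate_events()].
#' @param members Member table (`member_id`, `birth_date`, `death_date`).
#' @param enrollment Enrollment spans (`member_id`, `span_start`, `span_end`).
#' @param post_window_months,pre_window_months Coverage windows in calendar
#'   months (same day-of-month, clamped to month end).
#' @param allowable_gap_days Enrollment gaps up to this many days are bridged
#'   when testing continuity (0 = strict, the default).
#' @return An object of class `cohort_table`: the candidate table plus
#'   `age_at_admission` and `exclusion`.
#' @export
apply_inclusion <- function(candidates, members, enrollment,
                            post_window_months = 3, pre_window_months = 6,
                            allowable_gap_days = 0L) {
  mi <- match(candidates$member_id, members$member_id)
  if (anyNA(mi)) {
    stop("linkage error: candidate member(s) without a member record: ",
         paste(utils::head(candidates$member_id[is.na(mi)], 3), collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(candidates)
  age <- age_at(members$birth_date[mi], candidates$admit_date)
  death <- members$death_date[mi]

  pre_from <- lubridate::add_with_rollback(candidates$admit_date,
                                           lubridate::period(-as.integer(pre_window_months), "months"))
  post_to <- lubridate::add_with_rollback(candidates$discharge_date,
                                          lubridate::period(as.integer(post_window_months), "months"))
  # "or until death": truncate the post requirement at death
  post_to_eff <- post_to
  trunc <- !is.na(death) & death < post_to
  post_to_eff[trunc] <- death[trunc]

  e_ord <- enrollment[order(enrollment$member_id, enrollment$span_start), ,
                      drop = FALSE]
  runs <- rle(e_ord$member_id)
  first_row <- match(candidates$member_id, e_ord$member_id)
  n_spans <- runs$lengths[match(candidates$member_id, runs$values)]

  pre_ok <- post_ok <- logical(n)
  single <- !is.na(first_row) & n_spans == 1L
  s <- first_row[single]
  pre_ok[single] <- e_ord$span_start[s] <= pre_from[single] &
    e_ord$span_end[s] >= candidates$admit_date[single]
  post_ok[single] <- (post_to_eff[single] < candidates$discharge_date[single]) |
    (e_ord$span_start[s] <= candidates$discharge_date[single] &
       e_ord$span_end[s] >= post_to_eff[single])
  for (i in which(!is.na(first_row) & n_spans > 1L)) {
    rows <- first_row[i]:(first_row[i] + n_spans[i] - 1L)
    pre_ok[i] <- covered(e_ord$span_start[rows], e_ord$span_end[rows],
                         pre_from[i], candidates$admit_date[i], allowable_gap_days)
    post_ok[i] <- covered(e_ord$span_start[rows], e_ord$span_end[rows],
                          candidates$discharge_date[i], post_to_eff[i],
                          allowable_gap_days)
  }

  exclusion <- rep("none", n)
  exclusion[candidates$admission_source == "transfer"] <- "transfer"
  exclusion[!post_ok] <- "insufficient_post_coverage"
  exclusion[!pre_ok] <- "insufficient_pre_coverage"
  exclusion[age < 18] <- "not_adult"

  out <- candidates
  out$age_at_admission <- age
  out$exclusion <- factor(exclusion,
                          levels = c("none", "not_adult",
                                     "insufficient_pre_coverage",
                                     "insufficient_post_coverage", "transfer"))
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Included events of a cohort table
#'
#' @param cohort A `cohort_table`.
#' @return The rows with exclusion ledger entry `none`.
#' @export
included_events <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  out <- cohort[cohort$exclusion == "none", , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Build a cohort from raw tables
#'
#' Convenience wrapper: [find_candidate_events()] then [apply_inclusion()].
#'
#' @inheritParams find_candidate_events
#' @inheritParams apply_inclusion
#' @return A `cohort_table`.
#' @export
build_cohort <- function(claims, members, enrollment, registry,
                         post_window_months = 3, pre_window_months = 6,
                         allowable_gap_days = 0L) {
  cand <- find_candidate_events(claims, registry)
  apply_inclusion(cand, members, enrollment,
                  post_window_months = post_window_months,
                  pre_window_months = pre_window_months,
                  allowable_gap_days = allowable_gap_days)
}
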