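# The IMPACT prediction rule: a logistic model mapping age plus eleven
# claims-coded comorbidities to an absolute early-mortality risk, with
# low/high classification at a 1.5 % predicted-risk threshold.

#' Load IMPACT model coefficients
#'
#' The rule's linear predictor is
#' `x = intercept + age_per_year * age + sum(coef_j * flag_j)` over the eleven
#' comorbidity flags of [impact_comorbidities()], and the predicted absolute
#' risk is `1 / (1 + exp(-x))`. Coefficients are data, not code: the packaged
#' default file carries the published values (intercept -5.833, 0.026 per year
#' of age, eleven positive comorbidity log-odds) and the 0.015 low-risk
#' threshold; recalibrated variants can be loaded from any file with the same
#' schema.
#'
#' @param path Path to a coefficient JSON file; `NULL` loads the packaged
#'   defaults.
#' @return An object of class `impact_coefficients`: list with `intercept`,
#'   `age_per_year`, `terms` (named numeric, one per comorbidity),
#'   `low_risk_threshold`.
#' @export
impact_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "impact_coefficients.json", package = "impactpe")
  }
  raw <- jsonlite::fromJSON(path)
  terms <- unlist(raw$terms)
  missing <- setdiff(impact_comorbidities(), names(terms))
  if (length(missing)) {
    stop("coefficient file missing term(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  thr <- raw$low_risk_threshold
  if (!is.numeric(thr) || thr <= 0 || thr >= 1) {
    stop("low_risk_threshold must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(intercept = raw$intercept, age_per_year = raw$age_per_year,
         terms = terms[impact_comorbidities()], low_risk_threshold = thr),
    class = "impact_coefficients"
  )
}

#' @export
print.impact_coefficients <- function(x, ...) {
  cat("<impact_coefficients>\n")
  cat(sprintf("  intercept    %+.3f\n  age_per_year %+.3f\n", x$intercept, x$age_per_year))
  for (nm in names(x$terms)) cat(sprintf("  %-22s %+.3f\n", nm, x$terms[[nm]]))
  cat(sprintf("  low_risk_threshold %.3f\n", x$low_risk_threshold))
  invisible(x)
}

#' IMPACT linear predictor
#'
#' @param profile A comorbidity profile: data frame (or list) with numeric
#'   `age` and one logical/0-1 column per name in [impact_comorbidities()].
#'   Vectorized over rows.
#' @param coef An `impact_coefficients` object.
#' @return Numeric vector of log-odds.
#' @examples
#' coef <- impact_coefficients()
#' p <- data.frame(age = 70, myocardial_infarction = FALSE,
#'   chronic_lung_disease = FALSE, stroke = FALSE, prior_major_bleeding = FALSE,
#'   atrial_fibrillation = FALSE, cognitive_impairment = FALSE,
#'   heart_failure = TRUE, renal_failure = FALSE, liver_disease = FALSE,
#'   coagulopathy = FALSE, cancer = TRUE)
#' linear_predictor(p, coef)  # -5.833 + 0.026*70 + 0.554 + 1.068
#' @export
linear_predictor <- function(profile, coef = impact_coefficients()) {
  stopifnot(inherits(coef, "impact_coefficients"))
  flags <- impact_comorbidities()
  missing <- setdiff(c("age", flags), names(profile))
  if (length(missing)) {
    stop("profile missing field(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- coef$intercept + coef$age_per_year * as.numeric(profile[["age"]])
  for (nm in flags) x <- x + coef$terms[[nm]] * as.numeric(profile[[nm]])
  x
}

#' Predicted absolute risk from the linear predictor
#'
#' The logistic transform `1 / (1 + exp(-x))`.
#'
#' @param x Numeric log-odds.
#' @return Probabilities in (0, 1).
#' @export
predicted_risk <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  stats::plogis(x)
}

#' Classify predicted risk as low or high
#'
#' Low risk is defined inclusively: predicted risk less than or equal to the
#' threshold (default 1.5 %).
#'
#' @param risk Numeric probabilities.
#' @param threshold Low-risk cut-off on the probability scale.
#' @return Factor with levels `low`, `high`.
#' @export
classify_risk <- function(risk, threshold = 0.015) {
  stopifnot(is.numeric(risk), all(risk > 0 & risk < 1), threshold > 0, threshold < 1)
  factor(ifelse(risk <= threshold, "low", "high"), levels = c("low", "high"))
}

#' Ascertain the IMPACT comorbidity profile for cohort members
#'
#' A comorbidity flag is set when any claim of the member dated within the
#' ascertainment window carries a diagnosis code matching that comorbidity's
#' registry set. The window runs from `lookback_months` calendar months before
#' the index admission through the index discharge; claims of the index
#' hospitalization itself are included by default (`include_index_claims`).
#' A member with no claims in the window gets an all-false profile.
#'
#' @param events Cohort table (or any data frame with `member_id`,
#'   `admit_date`, `discharge_date`, `age_at_admission`, and optionally
#'   `claim_id` identifying the index claim).
#' @param claims Claims table (see [simulate_population()] for the schema).
#' @param registry A `code_registry`.
#' @param lookback_months Length of the pre-admission baseline window.
#' @param include_index_claims Whether the index hospitalization's own claim
#'   contributes codes.
#' @return Data frame: `member_id`, `age`, one logical column per comorbidity.
#' @export
ascertain_profile <- function(events, claims, registry, lookback_months = 6,
                              include_index_claims = TRUE) {
  stopifnot(inherits(registry, "code_registry"))
  flags <- impact_comorbidities()
  prof <- data.frame(member_id = events$member_id,
                     age = events$age_at_admission)
  for (nm in flags) prof[[nm]] <- logical(nrow(prof))
  if (nrow(prof) == 0L || nrow(claims) == 0L) return(prof)

  cl <- claims[claims$member_id %in% events$member_id, , drop = FALSE]
  idx <- match(cl$member_id, events$member_id)
  win_lo <- lubridate::add_with_rollback(events$admit_date,
                                         lubridate::period(-as.integer(lookback_months), "months"))
  keep <- cl$admit_date >= win_lo[idx] & cl$admit_date <= events$discharge_date[idx]
  if (!include_index_claims && !is.null(events$claim_id)) {
    keep <- keep & !(cl$claim_id %in% events$claim_id)
  }
  cl <- cl[keep, , drop = FALSE]
  if (nrow(cl) == 0L) return(prof)

  dx <- split_codes(cl$diagnosis_codes)
  long <- data.frame(member_id = rep(cl$member_id, lengths(dx)),
                     code = unlist(dx), stringsAsFactors = FALSE)
  for (nm in flags) {
    hit <- code_matches(long$code, registry_set(registry, nm))
    prof[[nm]] <- prof$member_id %in% unique(long$member_id[hit])
  }
  prof
}

#' Score a cohort with the IMPACT rule
#'
#' @param profiles Output of [ascertain_profile()].
#' @param coef An `impact_coefficients` object.
#' @return Data frame: `member_id`, `x` (log-odds), `risk` (probability),
#'   `risk_class` (`low`/`high`).
#' @export
score_profiles <- function(profiles, coef = impact_coefficients()) {
  x <- linear_predictor(profiles, coef)
  risk <- predicted_risk(x)
  data.frame(member_id = profiles$member_id, x = x, risk = risk,
             risk_class = classify_risk(risk, coef$low_risk_threshold))
}

# ";"-separated code lists <-> character vectors
split_codes <- function(x) {
  out <- strsplit(as.character(x), ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

join_codes <- function(lst) {
  vapply(lst, paste, character(1), collapse = ";")
}
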