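# Synthetic administrative-claims generator.
#
# Emits member/enrollment/claims/death tables with the structure the pipeline
# assumes -- index PE hospitalizations coded in the primary or
# secondary-with-complication position, comorbidity claims inside the
# six-month baseline window, transfers, enrollment gaps, in-hospital and
# post-discharge deaths, 30-day rehospitalizations and recurrent-VTE
# encounters -- together with a ground-truth table that records every latent
# flag and sampled outcome, so each downstream stage can be checked in a
# closed loop. In-hospital death is sampled from the IMPACT model itself
# (probability logistic(calibration_scale * x)), so with calibration_scale = 1
# the generated population is perfectly calibrated to the rule by
# construction.

#' Simulation configuration
#'
#' Default demographics and comorbidity prevalences reproduce the margins of a
#' large published US claims validation cohort of adult PE hospitalizations
#' (age 67.1 +/- 15.0 years; chronic lung disease 34.2 %, heart failure
#' 23.1 %, atrial fibrillation 16.4 %, cancer 15.3 %, ...). Comorbidities are
#' sampled independently (marginal prevalences are all that published baseline
#' tables report), optionally tilted by a shared log-odds-per-year age
#' association. Post-discharge event probabilities and length-of-stay medians
#' are per risk class (`low`, `high`).
#'
#' @param n_members Number of members to simulate.
#' @param seed Integer RNG seed; all randomness derives from it.
#' @param age_mean,age_sd,age_bounds Truncated-normal age model (years).
#' @param comorbidity_prevalence Named probabilities, one per
#'   [impact_comorbidities()].
#' @param comorbidity_age_association Shared log-odds shift per year of age
#'   applied to every comorbidity (0 = independence of age).
#' @param calibration_scale Multiplier on the IMPACT linear predictor used to
#'   sample in-hospital death; 1 gives a perfectly calibrated population.
#' @param post_discharge_death_prob,rehosp_prob,recurrent_vte_prob Named
#'   (`low`, `high`) probabilities of post-discharge events inside the 30-day
#'   window, among members discharged alive within 30 days of admission.
#' @param los_median_days,los_sdlog Named (`low`, `high`) parameters of the
#'   discretized log-normal length-of-stay model.
#' @param transfer_fraction Probability of admission from another facility.
#' @param enrollment_gap_fraction Probability of a coverage gap inside the
#'   six-month baseline window (violating inclusion).
#' @param secondary_pe_fraction Probability that the index claim codes PE in a
#'   secondary position with a qualifying primary complication (or
#'   complication procedure) instead of primary-position PE.
#' @param index_date_range Dates between which index admissions are drawn.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_members = 10000L,
                       seed = 1L,
                       age_mean = 67.1,
                       age_sd = 15.0,
                       age_bounds = c(18, 100),
                       comorbidity_prevalence = c(
                         myocardial_infarction = 0.035,
                         chronic_lung_disease  = 0.342,
                         stroke                = 0.046,
                         prior_major_bleeding  = 0.131,
                         atrial_fibrillation   = 0.164,
                         cognitive_impairment  = 0.137,
                         heart_failure         = 0.231,
                         renal_failure         = 0.146,
                         liver_disease         = 0.030,
                         coagulopathy          = 0.060,
                         cancer                = 0.153),
                       comorbidity_age_association = 0,
                       calibration_scale = 1,
                       post_discharge_death_prob = c(low = 0.0005, high = 0.02),
                       rehosp_prob = c(low = 0.09, high = 0.10),
                       recurrent_vte_prob = c(low = 0.02, high = 0.03),
                       los_median_days = c(low = 4, high = 5),
                       los_sdlog = c(low = 0.55, high = 0.70),
                       transfer_fraction = 0.05,
                       enrollment_gap_fraction = 0.05,
                       secondary_pe_fraction = 0.10,
                       index_date_range = as.Date(c("2008-07-01", "2014-11-30"))) {
  cfg <- list(
    n_members = as.integer(n_members), seed = as.integer(seed),
    age_mean = age_mean, age_sd = age_sd, age_bounds = age_bounds,
    comorbidity_prevalence = comorbidity_prevalence,
    comorbidity_age_association = comorbidity_age_association,
    calibration_scale = calibration_scale,
    post_discharge_death_prob = post_discharge_death_prob,
    rehosp_prob = rehosp_prob, recurrent_vte_prob = recurrent_vte_prob,
    los_median_days = los_median_days, los_sdlog = los_sdlog,
    transfer_fraction = transfer_fraction,
    enrollment_gap_fraction = enrollment_gap_fraction,
    secondary_pe_fraction = secondary_pe_fraction,
    index_date_range = as.Date(index_date_range)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_members <= 0L) stop("configuration error: n_members must be > 0", call. = FALSE)
  if (cfg$age_sd < 0) stop("configuration error: age_sd must be >= 0", call. = FALSE)
  if (length(cfg$age_bounds) != 2L || diff(cfg$age_bounds) < 0) {
    stop("configuration error: degenerate age bounds", call. = FALSE)
  }
  probs <- c(cfg$comorbidity_prevalence, cfg$post_discharge_death_prob,
             cfg$rehosp_prob, cfg$recurrent_vte_prob, cfg$transfer_fraction,
             cfg$enrollment_gap_fraction, cfg$secondary_pe_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("configuration error: probabilities must lie in [0, 1]", call. = FALSE)
  }
  missing <- setdiff(impact_comorbidities(), names(cfg$comorbidity_prevalence))
  if (length(missing)) {
    stop("configuration error: missing prevalence for ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

# truncated-normal draw by rejection; degenerate sd gives the clamped mean
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Simulate a synthetic claims population
#'
#' Every member receives one index inpatient PE hospitalization; a member's
#' true comorbidity flags are planted as one baseline outpatient claim per
#' flag, coded with a claim code unique to that comorbidity's registry set.
#' In-hospital death is Bernoulli with probability
#' `logistic(calibration_scale * x)` where `x` is the member's IMPACT linear
#' predictor; post-discharge deaths, rehospitalizations and recurrent-VTE
#' encounters are sampled per risk class inside the 30-day window. A
#' configurable fraction of members are admitted as transfers or carry an
#' enrollment gap that violates the six-month baseline coverage requirement;
#' ground truth records these planted exclusions.
#'
#' Output is deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param registry A `code_registry` supplying the claim codes.
#' @param coef The `impact_coefficients` used for the latent risk model.
#' @return An object of class `claims_population`: list of data frames
#'   `members`, `enrollment`, `claims`, `deaths`, `ground_truth`, plus the
#'   `config`.
#' @export
simulate_population <- function(config = sim_config(),
                                registry = load_registry(),
                                coef = impact_coefficients()) {
  validate_sim_config(config)
  stopifnot(inherits(registry, "code_registry"))
  set.seed(config$seed)
  n <- config$n_members
  flags_nm <- impact_comorbidities()

  member_id <- sprintf("M%07d", seq_len(n))
  admit <- config$index_date_range[1] +
    sample.int(as.integer(diff(config$index_date_range)) + 1L, n, replace = TRUE) - 1L
  age <- as.integer(floor(rtruncnorm(n, config$age_mean, config$age_sd,
                          config$age_bounds[1], config$age_bounds[2])))
  birth <- lubridate::add_with_rollback(admit, -lubridate::years(age)) -
    sample.int(361L, n, replace = TRUE) + 1L
  sex <- sample(c("F", "M"), n, replace = TRUE)

  # latent comorbidities, optionally age-tilted on the log-odds scale
  flags <- matrix(FALSE, n, length(flags_nm), dimnames = list(NULL, flags_nm))
  for (nm in flags_nm) {
    p <- stats::plogis(stats::qlogis(config$comorbidity_prevalence[[nm]]) +
                       config$comorbidity_age_association * (age - config$age_mean))
    flags[, nm] <- stats::runif(n) < p
  }

  x <- coef$intercept + coef$age_per_year * age +
    as.numeric(flags %*% coef$terms[flags_nm])
  risk <- stats::plogis(x)
  risk_class <- classify_risk(risk, coef$low_risk_threshold)
  cls <- as.character(risk_class)

  los <- pmax(0L, as.integer(round(stats::rlnorm(
    n, log(config$los_median_days[cls]), config$los_sdlog[cls]))))
  discharge <- admit + los
  discharged_30d <- discharge <= admit + 30L

  transfer <- stats::runif(n) < config$transfer_fraction
  gap <- stats::runif(n) < config$enrollment_gap_fraction
  minor <- age < 18

  # outcomes
  inhosp_death <- stats::runif(n) < stats::plogis(config$calibration_scale * x)
  death_date <- as.Date(rep(NA, n))
  dd_off <- integer(n)
  if (any(inhosp_death)) {
    dd_off[inhosp_death] <- floor(stats::runif(sum(inhosp_death)) * (los[inhosp_death] + 1L))
    death_date[inhosp_death] <- admit[inhosp_death] + dd_off[inhosp_death]
  }
  pd_eligible <- !inhosp_death & discharge < admit + 30L
  pd_death <- pd_eligible & stats::runif(n) < config$post_discharge_death_prob[cls]
  if (any(pd_death)) {
    span <- as.integer(admit[pd_death] + 30L - discharge[pd_death])  # >= 1
    death_date[pd_death] <- discharge[pd_death] + 1L +
      floor(stats::runif(sum(pd_death)) * span)
  }
  death_30d <- (inhosp_death & death_date <= admit + 30L) %in% TRUE | pd_death

  alive_window <- !inhosp_death & !pd_death & discharge < admit + 30L
  rehosp <- ifelse(discharged_30d,
                   alive_window & stats::runif(n) < config$rehosp_prob[cls], NA)
  vte <- ifelse(discharged_30d,
                alive_window & stats::runif(n) < config$recurrent_vte_prob[cls], NA)
  # a recurrent-VTE event managed as an inpatient stay is also, by
  # definition, an all-cause rehospitalization
  vte_setting <- ifelse(vte %in% TRUE,
                        sample(c("emergency", "inpatient"), n, replace = TRUE),
                        NA)
  rehosp[vte_setting %in% "inpatient"] <- TRUE
  composite <- death_30d | rehosp %in% TRUE | vte %in% TRUE

  # ---- claims ------------------------------------------------------------
  rep_code <- vapply(flags_nm, function(nm) representative_code(registry, nm),
                     character(1))
  dvt_code <- representative_code(registry, "dvt")

  secondary <- stats::runif(n) < config$secondary_pe_fraction
  proc_route <- secondary & stats::runif(n) < 0.3
  dx <- ifelse(!secondary, "41519",
        ifelse(proc_route, "78609;41519", "51881;41511"))
  pc <- ifelse(proc_route, "9910", "")
  index_claims <- data.frame(
    member_id = member_id, setting = "inpatient",
    admit_date = admit, discharge_date = discharge,
    diagnosis_codes = dx, procedure_codes = pc,
    discharge_status = ifelse(inhosp_death, "expired", "alive"),
    admission_source = ifelse(transfer, "transfer", "community"),
    stringsAsFactors = FALSE
  )

  w <- which(flags, arr.ind = TRUE)
  como_claims <- data.frame(
    member_id = member_id[w[, 1L]], setting = character(nrow(w)),
    admit_date = admit[w[, 1L]] -
      (10L + floor(stats::runif(nrow(w)) * 161)),  # 10..170 days pre-index
    discharge_date = as.Date(rep(NA, nrow(w))),
    diagnosis_codes = rep_code[w[, 2L]],
    procedure_codes = character(nrow(w)),
    discharge_status = character(nrow(w)),
    admission_source = character(nrow(w)),
    stringsAsFactors = FALSE
  )
  if (nrow(como_claims)) {
    como_claims$setting <- "outpatient"
    como_claims$discharge_status <- "other"
    como_claims$admission_source <- "community"
  }

  rh <- which(rehosp %in% TRUE)
  rh_admit <- discharge[rh] + 1L +
    floor(stats::runif(length(rh)) * as.integer(admit[rh] + 30L - discharge[rh]))
  rehosp_claims <- data.frame(
    member_id = member_id[rh], setting = "inpatient",
    admit_date = rh_admit,
    discharge_date = rh_admit + 1L + floor(stats::runif(length(rh)) * 5),
    diagnosis_codes = "486", procedure_codes = "",
    discharge_status = "alive", admission_source = "community",
    stringsAsFactors = FALSE
  )

  rv <- which(vte %in% TRUE)
  rv_admit <- discharge[rv] + 1L +
    floor(stats::runif(length(rv)) * as.integer(admit[rv] + 30L - discharge[rv]))
  rv_setting <- vte_setting[rv]
  vte_claims <- data.frame(
    member_id = member_id[rv], setting = rv_setting,
    admit_date = rv_admit,
    discharge_date = as.Date(ifelse(rv_setting == "inpatient",
                                    rv_admit + 2L, NA), origin = "1970-01-01"),
    diagnosis_codes = dvt_code, procedure_codes = "",
    discharge_status = "alive", admission_source = "community",
    stringsAsFactors = FALSE
  )

  claims <- rbind(index_claims, como_claims, rehosp_claims, vte_claims)
  claims <- claims[order(claims$member_id, claims$admit_date, claims$setting), ]
  claims <- data.frame(claim_id = sprintf("C%08d", seq_len(nrow(claims))), claims,
                       row.names = NULL, stringsAsFactors = FALSE)

  # ---- enrollment: continuous span, or a 30-day gap inside the baseline ---
  died <- !is.na(death_date)
  span_end <- as.Date(ifelse(died, death_date, discharge + 120L), origin = "1970-01-01")
  e1 <- data.frame(member_id = member_id, span_start = admit - 250L,
                   span_end = span_end, stringsAsFactors = FALSE)
  if (any(gap)) {
    e1$span_end[gap] <- admit[gap] - 120L
    e2 <- data.frame(member_id = member_id[gap], span_start = admit[gap] - 90L,
                     span_end = span_end[gap], stringsAsFactors = FALSE)
    e1 <- rbind(e1, e2)
  }
  enrollment <- e1[order(e1$member_id, e1$span_start), ]
  row.names(enrollment) <- NULL

  members <- data.frame(member_id = member_id, birth_date = birth, sex = sex,
                        death_date = death_date, stringsAsFactors = FALSE)
  deaths <- members[died, c("member_id", "death_date")]
  row.names(deaths) <- NULL

  ground_truth <- data.frame(
    member_id = member_id, age = age, flags,
    x = x, risk = risk, risk_class = risk_class,
    length_of_stay = los,
    in_hospital_death = inhosp_death, death_30d = death_30d,
    discharged_within_30d = discharged_30d,
    rehospitalization_30d = as.logical(rehosp),
    recurrent_vte_30d = as.logical(vte),
    composite_30d = composite,
    transfer = transfer, enrollment_gap = gap, minor = minor,
    stringsAsFactors = FALSE
  )

  structure(list(members = members, enrollment = enrollment, claims = claims,
                 deaths = deaths, ground_truth = ground_truth, config = config),
            class = "claims_population")
}

#' @export
print.claims_population <- function(x, ...) {
  cat(sprintf("<claims_population> %d members, %d claims, %d deaths (seed %d)\n",
              nrow(x$members), nrow(x$claims), nrow(x$deaths), x$config$seed))
  invisible(x)
}

# table schemas used by the delimited round-trip (column -> reader class)
.pop_schemas <- list(
  members = c(member_id = "character", birth_date = "Date", sex = "character",
              death_date = "Date"),
  enrollment = c(member_id = "character", span_start = "Date", span_end = "Date"),
  claims = c(claim_id = "character", member_id = "character",
             setting = "character", admit_date = "Date",
             discharge_date = "Date", diagnosis_codes = "character",
             procedure_codes = "character", discharge_status = "character",
             admission_source = "character"),
  deaths = c(member_id = "character", death_date = "Date"),
  ground_truth = c(member_id = "character", age = "integer",
                   stats::setNames(rep("logical", 11), impact_comorbidities()),
                   x = "numeric", risk = "numeric", risk_class = "character",
                   length_of_stay = "integer", in_hospital_death = "logical",
                   death_30d = "logical", discharged_within_30d = "logical",
                   rehospitalization_30d = "logical",
                   recurrent_vte_30d = "logical", composite_30d = "logical",
                   transfer = "logical", enrollment_gap = "logical",
                   minor = "logical")
)

#' Write a population to delimited tables
#'
#' One CSV per table (ISO-8601 dates, full-precision numerics) plus the
#' configuration as JSON and a manifest of row counts, under `path`.
#'
#' @param pop A `claims_population`.
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_tables <- function(pop, path) {
  stopifnot(inherits(pop, "claims_population"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(.pop_schemas)) {
    df <- pop[[nm]]
    for (col in names(df)) {
      if (is.numeric(df[[col]]) && !is.integer(df[[col]])) {
        df[[col]] <- sprintf("%.17g", df[[col]])
      }
    }
    utils::write.csv(df, file.path(path, paste0(nm, ".csv")), row.names = FALSE,
                     quote = FALSE)
  }
  cfg <- pop$config
  cfg$index_date_range <- format(cfg$index_date_range)
  jsonlite::write_json(unclass(cfg), file.path(path, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest <- c(list(seed = pop$config$seed),
                lapply(pop[names(.pop_schemas)], nrow))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a population from delimited tables
#'
#' Validates each table against the expected schema and reports the first
#' offending column on mismatch. Inverse of [write_tables()].
#'
#' @param path Directory written by [write_tables()].
#' @return A `claims_population`.
#' @export
read_tables <- function(path) {
  out <- list()
  for (nm in names(.pop_schemas)) {
    schema <- .pop_schemas[[nm]]
    file <- file.path(path, paste0(nm, ".csv"))
    if (!file.exists(file)) stop("format error: missing table file ", file, call. = FALSE)
    header <- names(utils::read.csv(file, nrows = 1, check.names = FALSE))
    missing <- setdiff(names(schema), header)
    if (length(missing)) {
      stop("format error in ", nm, ".csv: missing column '", missing[1L], "'",
           call. = FALSE)
    }
    df <- utils::read.csv(file, colClasses = schema, check.names = FALSE)
    out[[nm]] <- df[, names(schema), drop = FALSE]
  }
  out$ground_truth$risk_class <- factor(out$ground_truth$risk_class,
                                        levels = c("low", "high"))
  cfg_file <- file.path(path, "config.json")
  if (file.exists(cfg_file)) {
    raw <- jsonlite::fromJSON(cfg_file)
    raw$index_date_range <- as.Date(raw$index_date_range)
    for (nm in grep("_prob$|prevalence|los_", names(raw), value = TRUE)) {
      raw[[nm]] <- unlist(raw[[nm]])
    }
    out$config <- structure(raw, class = "sim_config")
  }
  structure(out, class = "claims_population")
}
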