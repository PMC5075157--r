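# Pipeline orchestration: simulate -> build cohort -> ascertain comorbidity
# profiles -> score -> ascertain endpoints -> evaluate -> report, with a
# reproducibility manifest. A counts-only mode evaluates packaged reference
# 2x2 panels without any simulation.

#' Reference validation 2x2 counts
#'
#' The packaged classification-vs-outcome counts reported by a published
#' external validation of the IMPACT rule in a US commercial/Medicare claims
#' cohort of 47,531 adult PE hospitalizations: one panel per endpoint
#' (in-hospital death, 30-day death, 30-day composite of recurrent VTE,
#' rehospitalization or death), plus the cohort margins.
#'
#' @param path Optional path to an alternative counts JSON file.
#' @return List with `cohort_n`, `low_risk_n`, `high_risk_n`, and `panels`
#'   (named list of `two_by_two`).
#' @export
reference_validation_counts <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "validation_counts.json", package = "impactpe")
  }
  raw <- jsonlite::fromJSON(path)
  panels <- lapply(raw$panels, function(p) {
    two_by_two(tp = p$tp, fp = p$fp, tn = p$tn, fn = p$fn)
  })
  list(cohort_n = raw$cohort_n, low_risk_n = raw$low_risk_n,
       high_risk_n = raw$high_risk_n, panels = panels,
       provenance = raw$provenance)
}

#' Accuracy metrics from count panels alone
#'
#' @param counts Output of [reference_validation_counts()] (or a list with the
#'   same shape).
#' @param level Confidence level.
#' @param ci_method CI method, see [binom_ci()].
#' @return Named list of `accuracy_metrics`, one per panel.
#' @export
metrics_from_counts <- function(counts = reference_validation_counts(),
                                level = 0.95, ci_method = "wilson") {
  lapply(counts$panels, accuracy_metrics, level = level, ci_method = ci_method)
}

#' Pipeline run configuration
#'
#' @param out_dir Run directory for all stage outputs.
#' @param sim A [sim_config()] (its `seed` drives all randomness).
#' @param registry_file,coefficient_file Optional overrides of the packaged
#'   registry / coefficient files.
#' @param lookback_months,include_index_claims Comorbidity ascertainment
#'   window, see [ascertain_profile()].
#' @param pre_window_months,post_window_months,allowable_gap_days Inclusion
#'   windows, see [apply_inclusion()].
#' @param window_days,vte_anchor Endpoint windows, see
#'   [ascertain_endpoints()].
#' @param ci_method CI method for the evaluation stage.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, sim = sim_config(),
                       registry_file = NULL, coefficient_file = NULL,
                       lookback_months = 6, include_index_claims = TRUE,
                       pre_window_months = 6, post_window_months = 3,
                       allowable_gap_days = 0L,
                       window_days = 30, vte_anchor = "admission",
                       ci_method = "wilson") {
  if (!is.null(registry_file) && !file.exists(registry_file)) {
    stop("registry file not found: ", registry_file, call. = FALSE)
  }
  if (!is.null(coefficient_file) && !file.exists(coefficient_file)) {
    stop("coefficient file not found: ", coefficient_file, call. = FALSE)
  }
  structure(list(out_dir = out_dir, sim = sim,
                 registry_file = registry_file,
                 coefficient_file = coefficient_file,
                 lookback_months = lookback_months,
                 include_index_claims = include_index_claims,
                 pre_window_months = pre_window_months,
                 post_window_months = post_window_months,
                 allowable_gap_days = allowable_gap_days,
                 window_days = window_days, vte_anchor = vte_anchor,
                 ci_method = ci_method),
            class = "run_config")
}

stage_msg <- function(quiet, ...) if (!quiet) message(sprintf(...))

#' Run the full validation pipeline
#'
#' Executes every stage in order, writes each stage's table under
#' `config$out_dir`, and finishes with `metrics.json`, `report.md` and a
#' `manifest.json` recording the seed, a hash of the configuration, row
#' counts per stage (candidates -> included -> scored -> evaluated, so
#' exclusion attrition is auditable) and all derived metrics. Identical
#' configuration and seed give a byte-identical metrics file.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with all in-memory stage outputs.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  registry <- load_registry(config$registry_file)
  coef <- impact_coefficients(config$coefficient_file)

  stage_msg(quiet, "[simulate] n_members = %d, seed = %d",
            config$sim$n_members, config$sim$seed)
  pop <- simulate_population(config$sim, registry, coef)
  write_tables(pop, config$out_dir)

  stage_msg(quiet, "[build-cohort]")
  cohort <- build_cohort(pop$claims, pop$members, pop$enrollment, registry,
                         post_window_months = config$post_window_months,
                         pre_window_months = config$pre_window_months,
                         allowable_gap_days = config$allowable_gap_days)
  events <- included_events(cohort)
  utils::write.csv(cohort, file.path(config$out_dir, "cohort.csv"),
                   row.names = FALSE)
  stage_msg(quiet, "  candidates %d -> included %d (excluded %d)",
            nrow(cohort), nrow(events), nrow(cohort) - nrow(events))

  stage_msg(quiet, "[score]")
  profiles <- ascertain_profile(events, pop$claims, registry,
                                lookback_months = config$lookback_months,
                                include_index_claims = config$include_index_claims)
  scores <- score_profiles(profiles, coef)
  utils::write.csv(profiles, file.path(config$out_dir, "profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(scores, file.path(config$out_dir, "risk.csv"),
                   row.names = FALSE)

  stage_msg(quiet, "[endpoints]")
  outcomes <- ascertain_endpoints(events, pop$claims, pop$members, registry,
                                  window_days = config$window_days,
                                  vte_anchor = config$vte_anchor)
  utils::write.csv(outcomes, file.path(config$out_dir, "outcomes.csv"),
                   row.names = FALSE)

  stage_msg(quiet, "[evaluate]")
  endpoints <- c("in_hospital_death", "death_30d", "composite_30d")
  metrics <- lapply(endpoints, function(ep) {
    accuracy_metrics(two_by_two(scores$risk_class, outcomes[[ep]]),
                     risks = scores$risk, outcomes = outcomes[[ep]],
                     ci_method = config$ci_method)
  })
  names(metrics) <- endpoints
  calibration <- calibration_by_stratum(scores$risk,
                                        outcomes$in_hospital_death)
  baseline <- describe_cohort(profiles, scores)

  metrics_json <- metrics_to_json(metrics)
  jsonlite::write_json(metrics_json, file.path(config$out_dir, "metrics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report <- render_report(metrics, baseline, calibration)
  writeLines(report, file.path(config$out_dir, "report.md"))

  cfg_file <- file.path(config$out_dir, "run_config.json")
  jsonlite::write_json(serialize_run_config(config), cfg_file,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest <- list(
    seed = config$sim$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    rows = list(members = nrow(pop$members), claims = nrow(pop$claims),
                candidates = nrow(cohort), included = nrow(events),
                scored = nrow(scores), evaluated = nrow(outcomes)),
    exclusions = as.list(table(cohort$exclusion)),
    metrics = metrics_json
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage_msg(quiet, "[done] %s", config$out_dir)

  invisible(list(population = pop, cohort = cohort, events = events,
                 profiles = profiles, scores = scores, outcomes = outcomes,
                 metrics = metrics, calibration = calibration,
                 baseline = baseline, manifest = manifest))
}

serialize_run_config <- function(config) {
  out <- unclass(config)
  out$sim <- unclass(out$sim)
  out$sim$index_date_range <- format(out$sim$index_date_range)
  out
}

metrics_to_json <- function(metrics) {
  lapply(metrics, function(m) {
    prop <- function(p) list(point = p$point, lower = p$lower, upper = p$upper,
                             numerator = p$numerator,
                             denominator = p$denominator)
    out <- list(
      counts = list(tp = m$table$tp, fp = m$table$fp,
                    tn = m$table$tn, fn = m$table$fn),
      prevalence = m$prevalence,
      sensitivity = prop(m$sensitivity), specificity = prop(m$specificity),
      ppv = prop(m$ppv), npv = prop(m$npv)
    )
    if (!is.null(m$auc)) {
      out$auc <- list(point = m$auc$auc, lower = m$auc$lower,
                      upper = m$auc$upper)
    }
    out
  })
}

#' Render a markdown evaluation report
#'
#' Sections: accuracy metrics per endpoint (2x2 counts plus sensitivity /
#' specificity / NPV / PPV / AUC), baseline characteristics by risk class,
#' and calibration by predicted-risk stratum. Sections whose inputs are
#' absent are replaced with an explicit notice.
#'
#' @param metrics Named list of `accuracy_metrics` (per endpoint).
#' @param baseline Optional `baseline_table`.
#' @param calibration Optional `calibration_table`.
#' @return Character vector of markdown lines.
#' @export
render_report <- function(metrics, baseline = NULL, calibration = NULL) {
  fmt <- function(p) sprintf("%.1f (%.1f–%.1f)", 100 * p$point,
                             100 * p$lower, 100 * p$upper)
  lines <- c("# IMPACT validation report", "")

  lines <- c(lines, "## Prognostic accuracy", "",
             "| Endpoint | TP | FP | TN | FN | Sensitivity % | Specificity % | NPV % | PPV % | AUC |",
             "|---|---|---|---|---|---|---|---|---|---|")
  for (nm in names(metrics)) {
    m <- metrics[[nm]]
    auc_txt <- if (is.null(m$auc)) "—" else
      sprintf("%.2f (%.2f–%.2f)", m$auc$auc, m$auc$lower, m$auc$upper)
    lines <- c(lines, sprintf(
      "| %s | %d | %d | %d | %d | %s | %s | %s | %s | %s |",
      nm, m$table$tp, m$table$fp, m$table$tn, m$table$fn,
      fmt(m$sensitivity), fmt(m$specificity), fmt(m$npv), fmt(m$ppv), auc_txt))
  }
  lines <- c(lines, "")

  lines <- c(lines, "## Baseline characteristics", "")
  if (is.null(baseline)) {
    lines <- c(lines, "_Not available for this run (counts-only input)._", "")
  } else {
    n <- attr(baseline, "n")
    lines <- c(lines,
               sprintf("Total n = %d; low-risk n = %d; high-risk n = %d.",
                       n[["total"]], n[["low"]], n[["high"]]), "",
               "| Characteristic | Overall | Low-risk | High-risk | p |",
               "|---|---|---|---|---|")
    for (i in seq_len(nrow(baseline))) {
      p_txt <- if (is.na(baseline$p_value[i])) "—" else
        format.pval(baseline$p_value[i], digits = 2, eps = 1e-3)
      lines <- c(lines, sprintf("| %s | %s | %s | %s | %s |",
                                baseline$characteristic[i], baseline$overall[i],
                                baseline$low_risk[i], baseline$high_risk[i],
                                p_txt))
    }
    lines <- c(lines, "")
  }

  lines <- c(lines, "## Calibration (in-hospital death)", "")
  if (is.null(calibration)) {
    lines <- c(lines, "_Not available for this run (counts-only input)._", "")
  } else {
    lines <- c(lines, "| Stratum | n | Mean predicted | Observed (95% CI) |",
               "|---|---|---|---|")
    for (i in seq_len(nrow(calibration))) {
      lines <- c(lines, sprintf(
        "| %s | %d | %.4f | %.4f (%.4f–%.4f) |",
        calibration$stratum[i], calibration$n[i],
        calibration$mean_predicted[i], calibration$observed[i],
        calibration$observed_lower[i], calibration$observed_upper[i]))
    }
    lines <- c(lines, "")
  }
  lines
}
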