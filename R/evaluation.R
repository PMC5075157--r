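# Prognostic-accuracy evaluation: 2x2 tables, sensitivity / specificity /
# predictive values with binomial CIs, rank-based AUC with DeLong variance,
# risk-stratified calibration, and baseline descriptive comparisons.
#
# Orientation is fixed throughout: a "positive" prediction is the high-risk
# class, so tp = high-risk members with the event and fn = low-risk members
# with the event, and sensitivity is the fraction of events occurring in
# high-risk members.

#' Construct a 2x2 classification-vs-outcome table
#'
#' @param risk_class Factor/character vector (`low`/`high`), or `NULL` when
#'   building directly from counts.
#' @param outcome Logical vector, paired with `risk_class`.
#' @param tp,fp,tn,fn Direct counts (used when `risk_class` is `NULL`).
#' @return An object of class `two_by_two` with fields `tp`, `fp`, `tn`, `fn`.
#' @examples
#' two_by_two(tp = 3585, fp = 34687, tn = 9077, fn = 182)
#' @export
two_by_two <- function(risk_class = NULL, outcome = NULL,
                       tp = NULL, fp = NULL, tn = NULL, fn = NULL) {
  if (!is.null(risk_class)) {
    stopifnot(length(risk_class) == length(outcome), !anyNA(outcome))
    high <- as.character(risk_class) == "high"
    tp <- sum(high & outcome);  fp <- sum(high & !outcome)
    fn <- sum(!high & outcome); tn <- sum(!high & !outcome)
  }
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  structure(as.list(counts), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  cat("<two_by_two>            event   no event\n")
  cat(sprintf("  high-risk (pos.) %8d %10d\n", x$tp, x$fp))
  cat(sprintf("  low-risk  (neg.) %8d %10d\n", x$fn, x$tn))
  invisible(x)
}

total_2x2 <- function(t) t$tp + t$fp + t$tn + t$fn

#' Binomial proportion with confidence interval
#'
#' The default Wilson score interval inverts the score test,
#' `(p_hat + z^2/2n +/- z sqrt(p_hat(1-p_hat)/n + z^2/4n^2)) / (1 + z^2/n)`,
#' and is well behaved near 0 and 1; `wald` and `exact` (Clopper-Pearson via
#' `stats::binom.test`) are available as alternatives.
#'
#' @param numerator,denominator Counts, `0 <= numerator <= denominator`,
#'   `denominator >= 1`.
#' @param level Confidence level.
#' @param method `"wilson"`, `"wald"` or `"exact"`.
#' @return An object of class `proportion_ci`: `point`, `lower`, `upper`,
#'   `level`, `numerator`, `denominator`, `method`.
#' @examples
#' wilson_ci(3585, 3767)   # 0.952 (0.944-0.958)
#' @export
binom_ci <- function(numerator, denominator, level = 0.95,
                     method = c("wilson", "wald", "exact")) {
  method <- match.arg(method)
  stopifnot(denominator >= 1, numerator >= 0, numerator <= denominator,
            level > 0, level < 1)
  p <- numerator / denominator
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "wilson") {
    n <- denominator
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lo <- max(0, centre - half); hi <- min(1, centre + half)
  } else if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / denominator)
    lo <- max(0, p - half); hi <- min(1, p + half)
  } else {
    ci <- stats::binom.test(numerator, denominator,
                            conf.level = level)$conf.int
    lo <- ci[1]; hi <- ci[2]
  }
  structure(list(point = p, lower = lo, upper = hi, level = level,
                 numerator = numerator, denominator = denominator,
                 method = method),
            class = "proportion_ci")
}

#' @rdname binom_ci
#' @export
wilson_ci <- function(numerator, denominator, level = 0.95) {
  binom_ci(numerator, denominator, level, method = "wilson")
}

#' @export
print.proportion_ci <- function(x, digits = 1, ...) {
  cat(sprintf("%.*f%% (%.*f-%.*f) [%d/%d, %s, %g%% CI]\n",
              digits, 100 * x$point, digits, 100 * x$lower,
              digits, 100 * x$upper, x$numerator, x$denominator,
              x$method, 100 * x$level))
  invisible(x)
}

metric_ci <- function(num, den, what, level, method) {
  if (den == 0) {
    stop("undefined metric: ", what, " has a zero denominator", call. = FALSE)
  }
  binom_ci(num, den, level, method)
}

#' Prognostic accuracy measures from a 2x2 table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)`, each as a
#' [binom_ci()] proportion. A zero denominator raises an error rather than
#' returning a silent zero.
#'
#' @param t A `two_by_two`.
#' @param level Confidence level.
#' @param method CI method, see [binom_ci()].
#' @return A `proportion_ci`.
#' @export
sensitivity <- function(t, level = 0.95, method = "wilson") {
  metric_ci(t$tp, t$tp + t$fn, "sensitivity", level, method)
}

#' @rdname sensitivity
#' @export
specificity <- function(t, level = 0.95, method = "wilson") {
  metric_ci(t$tn, t$tn + t$fp, "specificity", level, method)
}

#' @rdname sensitivity
#' @export
ppv <- function(t, level = 0.95, method = "wilson") {
  metric_ci(t$tp, t$tp + t$fp, "ppv", level, method)
}

#' @rdname sensitivity
#' @export
npv <- function(t, level = 0.95, method = "wilson") {
  metric_ci(t$tn, t$tn + t$fn, "npv", level, method)
}

#' Rank-based AUC with DeLong confidence interval
#'
#' The Mann-Whitney estimator: the fraction of (event, non-event) pairs in
#' which the event member has the higher predicted risk, ties counted one
#' half. The variance is DeLong's, from the empirical placement values of
#' events among non-events and vice versa.
#'
#' @param risks Numeric predicted risks.
#' @param outcomes Logical event indicators.
#' @param level Confidence level.
#' @return An object of class `auc_estimate`: `auc`, `lower`, `upper`, `se`,
#'   `n_events`, `n_nonevents`.
#' @export
auc_rank <- function(risks, outcomes, level = 0.95) {
  stopifnot(length(risks) == length(outcomes), !anyNA(risks), !anyNA(outcomes))
  outcomes <- as.logical(outcomes)
  m <- sum(outcomes); n <- sum(!outcomes)
  if (m == 0L || n == 0L) {
    stop("undefined metric: AUC needs at least one event and one non-event",
         call. = FALSE)
  }
  r <- rank(risks)
  auc <- (sum(r[outcomes]) - m * (m + 1) / 2) / (m * n)
  # DeLong: placements of each event among non-events and conversely
  rx <- rank(risks[outcomes])
  ry <- rank(risks[!outcomes])
  v10 <- (r[outcomes] - rx) / n          # P(risk_nonevent < risk_event_i)
  v01 <- 1 - (r[!outcomes] - ry) / m     # P(risk_nonevent_j < risk_event)
  se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(auc = auc, lower = max(0, auc - z * se),
                 upper = min(1, auc + z * se), se = se,
                 n_events = m, n_nonevents = n, level = level),
            class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.3f-%.3f), %d events / %d non-events\n",
              x$auc, x$lower, x$upper, x$n_events, x$n_nonevents))
  invisible(x)
}

#' Full accuracy-metric block for one endpoint
#'
#' @param t A `two_by_two`.
#' @param risks,outcomes Optional member-level predicted risks and outcomes;
#'   when supplied, a continuous-score AUC is attached (the 2x2 alone only
#'   bounds the AUC of the binary classification at `(sens + spec)/2`).
#' @param level Confidence level.
#' @param ci_method CI method for the proportions, see [binom_ci()].
#' @return An object of class `accuracy_metrics`.
#' @export
accuracy_metrics <- function(t, risks = NULL, outcomes = NULL, level = 0.95,
                             ci_method = "wilson") {
  out <- list(
    table = t,
    sensitivity = sensitivity(t, level, ci_method),
    specificity = specificity(t, level, ci_method),
    ppv = ppv(t, level, ci_method),
    npv = npv(t, level, ci_method),
    prevalence = (t$tp + t$fn) / total_2x2(t),
    auc = if (!is.null(risks)) auc_rank(risks, outcomes, level)
  )
  structure(out, class = "accuracy_metrics")
}

#' @export
print.accuracy_metrics <- function(x, ...) {
  fmt <- function(p) sprintf("%.1f (%.1f-%.1f)", 100 * p$point,
                             100 * p$lower, 100 * p$upper)
  cat(sprintf("n = %d, event prevalence %.1f%%\n",
              total_2x2(x$table), 100 * x$prevalence))
  cat(sprintf("  sensitivity %s\n  specificity %s\n  PPV         %s\n  NPV         %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv), fmt(x$npv)))
  if (!is.null(x$auc)) print(x$auc)
  invisible(x)
}

#' Observed vs predicted risk by stratum
#'
#' Partitions the cohort by predicted risk (default: decile cut points) and
#' reports per-stratum size, mean predicted risk and observed event
#' proportion -- the calibration pattern a well-calibrated rule shows as
#' observed risk rising with predicted risk.
#'
#' @param risks Numeric predicted risks.
#' @param outcomes Logical event indicators.
#' @param bin_edges Optional explicit interior cut points; default decile
#'   quantiles of `risks` (duplicates collapsed).
#' @return Data frame of class `calibration_table`: `stratum`, `n`,
#'   `mean_predicted`, `observed`, plus Wilson bounds on the observed
#'   proportion.
#' @export
calibration_by_stratum <- function(risks, outcomes, bin_edges = NULL) {
  stopifnot(length(risks) == length(outcomes))
  if (is.null(bin_edges)) {
    bin_edges <- unique(stats::quantile(risks, probs = seq(0.1, 0.9, by = 0.1),
                                        names = FALSE))
  }
  edges <- unique(c(-Inf, sort(bin_edges), Inf))
  bin <- cut(risks, breaks = edges, include.lowest = TRUE)
  strata <- levels(bin)[tabulate(bin, nbins = length(levels(bin))) > 0]
  rows <- lapply(strata, function(s) {
    in_s <- bin == s
    ci <- wilson_ci(sum(outcomes[in_s]), sum(in_s))
    data.frame(stratum = s, n = sum(in_s),
               mean_predicted = mean(risks[in_s]),
               observed = ci$point, observed_lower = ci$lower,
               observed_upper = ci$upper, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' Baseline characteristics by risk class
#'
#' Age and comorbidity prevalences per risk class with two-group comparisons
#' (Welch t test for means, chi-square for proportions) and the mean +/- SD
#' of predicted risk per class.
#'
#' @param profiles Output of [ascertain_profile()].
#' @param scores Output of [score_profiles()] (same members).
#' @return Data frame of class `baseline_table`: one row per characteristic
#'   with overall / low / high summaries and a p-value. Empty classes are
#'   marked explicitly.
#' @export
describe_cohort <- function(profiles, scores) {
  stopifnot(identical(profiles$member_id, scores$member_id))
  cls <- as.character(scores$risk_class)
  n_low <- sum(cls == "low"); n_high <- sum(cls == "high")
  empty <- if (n_low == 0L) "low" else if (n_high == 0L) "high" else NA_character_

  mean_sd <- function(v) {
    if (length(v) == 0L) return("(empty group)")
    sprintf("%.1f ± %.1f", mean(v), stats::sd(v))
  }
  n_pct <- function(v) {
    if (length(v) == 0L) return("(empty group)")
    sprintf("%d (%.1f)", sum(v), 100 * mean(v))
  }
  welch_p <- function(v) {
    if (is.na(empty)) stats::t.test(v[cls == "low"], v[cls == "high"])$p.value
    else NA_real_
  }
  chisq_p <- function(v) {
    if (!is.na(empty) || length(unique(v)) < 2L) return(NA_real_)
    suppressWarnings(stats::chisq.test(table(cls, v))$p.value)
  }

  rows <- list(data.frame(
    characteristic = "age_years", overall = mean_sd(profiles$age),
    low_risk = mean_sd(profiles$age[cls == "low"]),
    high_risk = mean_sd(profiles$age[cls == "high"]),
    p_value = welch_p(profiles$age), stringsAsFactors = FALSE))
  for (nm in impact_comorbidities()) {
    v <- profiles[[nm]]
    rows[[nm]] <- data.frame(
      characteristic = nm, overall = n_pct(v),
      low_risk = n_pct(v[cls == "low"]), high_risk = n_pct(v[cls == "high"]),
      p_value = chisq_p(v), stringsAsFactors = FALSE)
  }
  rows$risk <- data.frame(
    characteristic = "predicted_risk_pct",
    overall = mean_sd(100 * scores$risk),
    low_risk = mean_sd(100 * scores$risk[cls == "low"]),
    high_risk = mean_sd(100 * scores$risk[cls == "high"]),
    p_value = welch_p(100 * scores$risk), stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  attr(out, "n") <- c(total = length(cls), low = n_low, high = n_high)
  class(out) <- c("baseline_table", "data.frame")
  out
}
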