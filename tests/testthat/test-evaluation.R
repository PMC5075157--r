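ref <- function() reference_validation_counts()

test_that("2x2 construction is exact and permutation-invariant", {
  t_ref <- ref()$panels$in_hospital_death
  # rebuild the in-hospital panel from member-level vectors
  cls <- c(rep("high", t_ref$tp + t_ref$fp), rep("low", t_ref$fn + t_ref$tn))
  out <- c(rep(TRUE, t_ref$tp), rep(FALSE, t_ref$fp),
           rep(TRUE, t_ref$fn), rep(FALSE, t_ref$tn))
  t1 <- two_by_two(cls, out)
  expect_equal(unclass(t1)[c("tp", "fp", "tn", "fn")],
               unclass(t_ref)[c("tp", "fp", "tn", "fn")])
  set.seed(4)
  perm <- sample(length(cls))
  t2 <- two_by_two(cls[perm], out[perm])
  expect_equal(unclass(t2), unclass(t1))
  # degenerate case: all low, no events
  t3 <- two_by_two(rep("low", 10), rep(FALSE, 10))
  expect_equal(unlist(unclass(t3)), c(tp = 0, fp = 0, tn = 10, fn = 0))
})

test_that("reference panels reproduce the published accuracy estimates", {
  pct <- function(p) round(100 * p$point, 1)
  m <- metrics_from_counts(ref())
  expect_equal(pct(m$in_hospital_death$sensitivity), 95.2)
  expect_equal(pct(m$in_hospital_death$specificity), 20.7)
  expect_equal(pct(m$in_hospital_death$npv), 98.0)
  expect_equal(pct(m$in_hospital_death$ppv), 9.4)
  expect_equal(pct(m$death_30d$sensitivity), 95.9)
  expect_equal(pct(m$death_30d$specificity), 21.1)
  expect_equal(pct(m$death_30d$ppv), 11.1)
  expect_equal(pct(m$death_30d$npv), 98.0)
  expect_equal(pct(m$composite_30d$specificity), 21.6)
  expect_equal(pct(m$composite_30d$npv), 87.8)
  expect_equal(pct(m$composite_30d$ppv), 22.8)
  # composite sensitivity computes to 88.56 %
  expect_equal(100 * m$composite_30d$sensitivity$point, 88.56, tolerance = 1e-3)
})

test_that("the prevalence identity links PPV to sensitivity and specificity", {
  for (t in ref()$panels) {
    m <- accuracy_metrics(t)
    pi <- m$prevalence
    sens <- m$sensitivity$point; spec <- m$specificity$point
    expect_equal(m$ppv$point,
                 sens * pi / (sens * pi + (1 - spec) * (1 - pi)),
                 tolerance = 1e-12)
  }
})

test_that("degenerate denominators raise undefined-metric errors", {
  t <- two_by_two(tp = 0, fp = 0, tn = 5, fn = 0)
  expect_error(sensitivity(t), "undefined metric")
  expect_error(ppv(t), "undefined metric")
  expect_equal(npv(t)$point, 1)
  t2 <- two_by_two(tp = 3, fp = 0, tn = 0, fn = 2)
  expect_equal(sensitivity(t2)$point, 0.6)
  # fn = 0 gives sensitivity exactly 1
  t3 <- two_by_two(tp = 3, fp = 1, tn = 1, fn = 0)
  expect_equal(sensitivity(t3)$point, 1)
})

test_that("Wilson intervals behave at the boundaries and mirror about 0.5", {
  ci0 <- wilson_ci(0, 10)
  expect_equal(ci0$point, 0)
  expect_equal(ci0$lower, 0)
  expect_lt(ci0$upper, 1)
  for (k in c(1, 4, 7)) {
    a <- wilson_ci(k, 10); b <- wilson_ci(10 - k, 10)
    expect_equal(a$lower, 1 - b$upper, tolerance = 1e-12)
    expect_equal(a$upper, 1 - b$lower, tolerance = 1e-12)
  }
})

test_that("Wilson matches the score interval of prop.test", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(10:5000, 1)
    k <- sample(0:n, 1)
    ours <- wilson_ci(k, n)
    ref_ci <- stats::prop.test(k, n, correct = FALSE)$conf.int
    expect_equal(c(ours$lower, ours$upper), as.numeric(ref_ci), tolerance = 1e-9)
  }
})

test_that("Wilson coverage is near nominal for n = 500, p = 0.2", {
  set.seed(2024)
  k <- stats::rbinom(2000, 500, 0.2)
  covered <- vapply(k, function(ki) {
    ci <- wilson_ci(ki, 500)
    ci$lower <= 0.2 && 0.2 <= ci$upper
  }, logical(1))
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("alternative CI methods are available and differ as expected", {
  w <- binom_ci(3585, 3767, method = "wald")
  e <- binom_ci(3585, 3767, method = "exact")
  wi <- binom_ci(3585, 3767, method = "wilson")
  expect_equal(round(100 * c(w$lower, w$upper), 1), c(94.5, 95.9))
  expect_equal(round(100 * c(wi$lower, wi$upper), 1), c(94.4, 95.8))
  expect_true(e$lower <= e$point && e$point <= e$upper)
})

test_that("rank AUC equals the all-pairs oracle and known identities", {
  expect_equal(auc_rank(c(0.9, 0.1), c(TRUE, FALSE))$auc, 1)
  # binary marker: AUC = (sens + spec)/2
  cls <- c(rep(1, 30), rep(0, 70))
  out <- as.logical(c(rep(TRUE, 25), rep(FALSE, 5), rep(TRUE, 10), rep(FALSE, 60)))
  t <- two_by_two(ifelse(cls == 1, "high", "low"), out)
  expect_equal(auc_rank(cls, out)$auc,
               (sensitivity(t)$point + specificity(t)$point) / 2,
               tolerance = 1e-12)
  # random instances, with ties, equal brute force
  set.seed(17)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    risks <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    outc <- stats::runif(n) < 0.4
    if (!any(outc) || all(outc)) next
    expect_equal(auc_rank(risks, outc)$auc, auc_brute_force(risks, outc))
  }
  expect_error(auc_rank(c(0.5, 0.6), c(TRUE, TRUE)), "undefined metric")
})

test_that("AUC and DeLong interval agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(23)
  risks <- stats::runif(300)
  outc <- stats::runif(300) < stats::plogis(3 * risks - 2)
  ours <- auc_rank(risks, outc)
  roc <- pROC::roc(response = outc, predictor = risks, quiet = TRUE,
                   direction = "<")
  ci <- pROC::ci.auc(roc, method = "delong")
  expect_equal(ours$auc, as.numeric(pROC::auc(roc)), tolerance = 1e-12)
  expect_equal(c(ours$lower, ours$upper), as.numeric(ci[c(1, 3)]),
               tolerance = 1e-9)
})

test_that("calibration strata partition the cohort", {
  set.seed(3)
  risks <- stats::runif(500, 0.001, 0.3)
  outc <- stats::runif(500) < risks
  tab <- calibration_by_stratum(risks, outc)
  expect_equal(sum(tab$n), 500)
  expect_true(all(tab$observed >= tab$observed_lower &
                    tab$observed <= tab$observed_upper))
  # constant risks occupy a single stratum
  tab1 <- calibration_by_stratum(rep(0.05, 50), rep(FALSE, 50))
  expect_equal(nrow(tab1), 1)
  expect_equal(tab1$n, 50)
  # a marker thresholded at the median yields non-decreasing observed rates
  risks2 <- seq(0.01, 0.99, length.out = 200)
  outc2 <- risks2 > stats::median(risks2)
  tab2 <- calibration_by_stratum(risks2, outc2)
  expect_true(all(diff(tab2$observed) >= 0))
})

test_that("baseline description compares risk classes sensibly", {
  pop <- small_population()
  reg <- default_registry()
  ev <- included_events(build_cohort(pop$claims, pop$members, pop$enrollment, reg))
  prof <- ascertain_profile(ev, pop$claims, reg)
  scores <- score_profiles(prof)
  tab <- describe_cohort(prof, scores)
  n <- attr(tab, "n")
  expect_equal(unname(n[["total"]]), nrow(prof))
  # low-risk members are younger on average (the dominant age effect)
  age_low <- mean(prof$age[scores$risk_class == "low"])
  age_high <- mean(prof$age[scores$risk_class == "high"])
  expect_lt(age_low, age_high)
  expect_equal(nrow(tab), 13)  # age + 11 comorbidities + predicted risk
  expect_true(all(!is.na(tab$p_value[tab$characteristic == "age_years"])))

  # an empty class is marked, not an error
  high_only <- scores$risk_class == "high"
  tab2 <- describe_cohort(prof[high_only, ], scores[high_only, ])
  expect_true(any(grepl("empty group", tab2$low_risk)))
})
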