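members_fixture <- function() {
  data.frame(
    member_id = c("A", "B", "C"),
    birth_date = as.Date(c("1942-01-10", "1950-06-01", "1992-01-01")),
    sex = "F",
    death_date = as.Date(c(NA, NA, NA)),
    stringsAsFactors = FALSE
  )
}

full_enrollment <- function(ids, admit = as.Date("2012-03-01")) {
  data.frame(member_id = ids, span_start = admit - 400, span_end = admit + 400,
             stringsAsFactors = FALSE)
}

test_that("index claims qualify by primary PE or secondary PE with complication", {
  reg <- default_registry()
  claims <- rbind(
    claim_row("A", "415.19", claim_id = "C1"),
    claim_row("B", "518.81;415.11", claim_id = "C2"),
    claim_row("C", "486;415.19", claim_id = "C3"),              # no complication
    claim_row("D", "486;415.19", proc = "99.10", claim_id = "C4"),  # procedure route
    claim_row("E", "518.81", claim_id = "C5"),                  # complication, no PE
    claim_row("F", "415.19", setting = "outpatient", claim_id = "C6")
  )
  cand <- find_candidate_events(claims, reg)
  expect_setequal(cand$member_id, c("A", "B", "D"))
  expect_equal(cand$qualifying_rule[cand$member_id == "A"], "primary_pe")
  expect_equal(cand$qualifying_rule[cand$member_id == "B"],
               "secondary_pe_with_complication")
  expect_equal(cand$qualifying_rule[cand$member_id == "D"],
               "secondary_pe_with_complication")
  expect_equal(nrow(find_candidate_events(claims[0, ], reg)), 0)
})

test_that("the earliest qualifying admission is the index event", {
  reg <- default_registry()
  claims <- rbind(
    claim_row("A", "415.19", admit = as.Date("2012-06-01"), claim_id = "C1"),
    claim_row("A", "415.19", admit = as.Date("2012-02-01"), claim_id = "C2")
  )
  cand <- find_candidate_events(claims, reg)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$claim_id, "C2")
})

test_that("qualifying rule re-derives under a brute-force code scan", {
  pop <- small_population()
  reg <- default_registry()
  cand <- find_candidate_events(pop$claims, reg)
  idx <- pop$claims[match(cand$claim_id, pop$claims$claim_id), ]
  pe <- registry_set(reg, "pe")
  for (i in seq_len(nrow(idx))) {
    dx <- strsplit(idx$diagnosis_codes[i], ";")[[1]]
    rule <- if (code_matches(dx[1], pe)) "primary_pe" else "secondary_pe_with_complication"
    expect_equal(cand$qualifying_rule[i], rule)
  }
})

test_that("age in completed years handles birthday boundaries", {
  expect_equal(age_at(as.Date("1950-06-01"), as.Date("2010-05-31")), 59L)
  expect_equal(age_at(as.Date("1950-06-01"), as.Date("2010-06-01")), 60L)
  expect_equal(age_at(as.Date("1992-01-01"), as.Date("2009-12-31")), 17L)
})

test_that("inclusion applies age, coverage and transfer rules in ledger order", {
  reg <- default_registry()
  admit <- as.Date("2012-03-01")
  claims <- rbind(
    claim_row("A", "415.19", admit = admit, claim_id = "C1"),
    claim_row("B", "415.19", admit = admit, claim_id = "C2"),
    claim_row("C", "415.19", admit = admit, claim_id = "C3")
  )
  cand <- find_candidate_events(claims, reg)
  members <- members_fixture()

  # full coverage, community admission, adult -> included
  cohort <- apply_inclusion(cand, members, full_enrollment(c("A", "B", "C")))
  expect_equal(as.character(cohort$exclusion[cohort$member_id == "A"]), "none")
  # C is 20 at admission here, included; born 1992 admitted 2009 would not be
  expect_equal(cohort$age_at_admission[cohort$member_id == "C"], 20L)

  # minor -> not_adult
  claims_minor <- claim_row("C", "415.19", admit = as.Date("2009-12-31"),
                            claim_id = "C9")
  cand_minor <- find_candidate_events(claims_minor, reg)
  cohort_minor <- apply_inclusion(cand_minor, members,
                                  full_enrollment("C", as.Date("2009-12-31")))
  expect_equal(as.character(cohort_minor$exclusion), "not_adult")

  # coverage ending one month post-discharge, alive -> insufficient_post_coverage
  enr <- data.frame(member_id = "A", span_start = admit - 400,
                    span_end = admit + 5 + 30, stringsAsFactors = FALSE)
  cohort2 <- apply_inclusion(cand[cand$member_id == "A", ], members, enr)
  expect_equal(as.character(cohort2$exclusion), "insufficient_post_coverage")

  # same truncated coverage but death at coverage end -> included ("or until death")
  members_d <- members
  members_d$death_date[members_d$member_id == "A"] <- admit + 35
  cohort3 <- apply_inclusion(cand[cand$member_id == "A", ], members_d, enr)
  expect_equal(as.character(cohort3$exclusion), "none")

  # transfers are excluded
  claims_t <- claim_row("B", "415.19", admit = admit, source = "transfer",
                        claim_id = "C8")
  cand_t <- find_candidate_events(claims_t, reg)
  cohort4 <- apply_inclusion(cand_t, members, full_enrollment("B"))
  expect_equal(as.character(cohort4$exclusion), "transfer")

  # a candidate without a member record is a linkage error
  expect_error(apply_inclusion(cand, members[members$member_id != "B", ],
                               full_enrollment(c("A", "C"))),
               "linkage error")
})

test_that("excluded members equal the planted transfer/gap/minor flags", {
  pop <- small_population()
  reg <- default_registry()
  cohort <- build_cohort(pop$claims, pop$members, pop$enrollment, reg)
  gt <- pop$ground_truth
  planted <- gt$member_id[gt$transfer | gt$enrollment_gap | gt$minor]
  observed <- cohort$member_id[cohort$exclusion != "none"]
  expect_setequal(observed, planted)
  # one candidate per member, all members are candidates
  expect_identical(sort(cohort$member_id), sort(pop$members$member_id))
})

test_that("shortening the post-coverage requirement never removes members", {
  pop <- small_population()
  reg <- default_registry()
  cand <- find_candidate_events(pop$claims, reg)
  inc3 <- apply_inclusion(cand, pop$members, pop$enrollment, post_window_months = 3)
  inc1 <- apply_inclusion(cand, pop$members, pop$enrollment, post_window_months = 1)
  in3 <- included_events(inc3)$member_id
  in1 <- included_events(inc1)$member_id
  expect_true(all(in3 %in% in1))
})

test_that("an allowable-gap setting bridges short enrollment gaps", {
  reg <- default_registry()
  admit <- as.Date("2012-03-01")
  cand <- find_candidate_events(claim_row("A", "415.19", admit = admit,
                                          claim_id = "C1"), reg)
  enr <- data.frame(member_id = "A",
                    span_start = c(admit - 400, admit - 90),
                    span_end = c(admit - 120, admit + 400),
                    stringsAsFactors = FALSE)
  strict <- apply_inclusion(cand, members_fixture(), enr)
  expect_equal(as.character(strict$exclusion), "insufficient_pre_coverage")
  lenient <- apply_inclusion(cand, members_fixture(), enr,
                             allowable_gap_days = 45L)
  expect_equal(as.character(lenient$exclusion), "none")
})
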