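defs <- condition_defs()
study_window <- c(as.Date("2009-01-01"), as.Date("2014-12-31"))
no_hosp <- hospital_row()[0, ]
no_claims <- claim_row()[0, ]

test_that("a single hospital diagnosis classifies; claim pairs need the window", {
  hyp <- defs$hypertension
  one_hosp <- hospital_row(icd10_codes = "I10", admit_date = "2013-04-01")
  expect_true(classify_condition(hyp, no_claims, one_hosp, study_window)$classified)
  # claims 1,247 days apart: outside the 730-day window
  far <- dplyr::bind_rows(claim_row(icd9_code = "401.1", service_date = "2010-01-01"),
                          claim_row(icd9_code = "401.1", service_date = "2013-06-01"))
  expect_false(classify_condition(hyp, far, no_hosp, study_window)$classified)
  # 517 days apart: inside
  near <- dplyr::bind_rows(claim_row(icd9_code = "401.1", service_date = "2012-01-01"),
                           claim_row(icd9_code = "401.1", service_date = "2013-06-01"))
  res <- classify_condition(hyp, near, no_hosp, study_window)
  expect_true(res$classified)
  expect_equal(res$first_qualifying_date, as.Date("2013-06-01"))
  # one claim alone never qualifies; two same-day claims count as a pair
  expect_false(classify_condition(hyp, near[1, ], no_hosp, study_window)$classified)
  sameday <- dplyr::bind_rows(near[1, ], near[1, ])
  expect_true(classify_condition(hyp, sameday, no_hosp, study_window)$classified)
})

test_that("classification equals the all-pairs oracle on random event streams", {
  set.seed(31)
  hyp <- defs$hypertension
  for (i in 1:200) {
    n <- sample(0:6, 1)
    dates <- as.Date("2009-01-01") + sample.int(2100, max(n, 1))[seq_len(n)]
    cl <- if (n == 0) no_claims else dplyr::bind_rows(lapply(
      seq_len(n), function(j) claim_row(icd9_code = "401.1",
                                        service_date = dates[j])))
    has_hosp <- runif(1) < 0.2
    hx <- if (has_hosp) hospital_row(icd10_codes = "I10",
                                     admit_date = "2012-06-01") else no_hosp
    got <- classify_condition(hyp, cl, hx, study_window)$classified
    want <- comorbidity_oracle(dates, 730, has_hosp)
    expect_identical(got, want, label = paste("stream", i))
  }
})

test_that("enlarging the window never declassifies", {
  set.seed(5)
  for (i in 1:30) {
    n <- sample(2:5, 1)
    dates <- as.Date("2009-01-01") + sample.int(2100, n)
    cl <- dplyr::bind_rows(lapply(seq_len(n), function(j)
      claim_row(icd9_code = "401.1", service_date = dates[j])))
    short <- defs$hypertension; short$window_days <- 200L
    long <- defs$hypertension; long$window_days <- 1000L
    got_s <- classify_condition(short, cl, no_hosp, study_window)$classified
    got_l <- classify_condition(long, cl, no_hosp, study_window)$classified
    expect_true(got_l >= got_s)
  }
})

test_that("depression needs a one-year pair and index-year treatment to persist", {
  dep <- defs$depression
  no_rx <- rx_row()[0, ]
  # two claims 200 days apart, both in the index year
  recent <- dplyr::bind_rows(
    claim_row(icd9_code = "311", service_date = "2014-02-01"),
    claim_row(icd9_code = "311", service_date = "2014-08-20"))
  expect_true(classify_depression(dep, recent, no_hosp, no_rx, 2014,
                                  study_window))
  # 400 days apart never qualifies under the 365-day window
  wide <- dplyr::bind_rows(
    claim_row(icd9_code = "311", service_date = "2013-01-01"),
    claim_row(icd9_code = "311", service_date = "2014-02-05"))
  expect_false(classify_depression(dep, wide, no_hosp, no_rx, 2014,
                                   study_window))
  # qualified in 2011 with no treatment evidence in 2014: declassified
  old <- dplyr::bind_rows(
    claim_row(icd9_code = "311", service_date = "2011-02-01"),
    claim_row(icd9_code = "311", service_date = "2011-07-01"))
  expect_false(classify_depression(dep, old, no_hosp, no_rx, 2014,
                                   study_window))
  # one antidepressant dispensation in 2014 preserves the classification
  n06a <- rx_row(atc_code = "N06AB04", dispense_date = "2014-05-01")
  expect_true(classify_depression(dep, old, no_hosp, n06a, 2014, study_window))
  # a depression claim in 2014 also counts as treatment evidence
  treated <- dplyr::bind_rows(old, claim_row(icd9_code = "311",
                                             service_date = "2014-03-03"))
  expect_true(classify_depression(dep, treated, no_hosp, no_rx, 2014,
                                  study_window))
})

test_that("condition counts band as 0-1 / 2 / 3+", {
  flags <- rbind(rep(FALSE, 8),
                 c(TRUE, rep(FALSE, 7)),
                 c(TRUE, TRUE, rep(FALSE, 6)),
                 c(rep(TRUE, 5), rep(FALSE, 3)))
  cc <- count_conditions(flags)
  expect_equal(cc$count, c(0, 1, 2, 5))
  expect_equal(as.character(cc$band), c("0-1", "0-1", "2", "3+"))
})

test_that("bulk classification agrees with the per-person operations", {
  g <- generate_cohort(sim_config(300, seed = 23))
  cw <- link_deterministic(g$emr, g$admin)
  coh <- build_cohort(g$emr, g$admin, cw, 2014)
  bulk <- classify_conditions(g$admin, coh, 2014, defs)
  members <- coh[coh$included, ]
  ab <- g$admin
  win <- c(as.Date("2009-01-01"), as.Date("2014-12-31"))
  for (i in sample(seq_len(nrow(members)), min(40, nrow(members)))) {
    id <- members$admin_person_id[i]
    cl <- ab$claims[ab$claims$person_id == id, ]
    hx <- ab$hospitals[ab$hospitals$person_id == id, ]
    rx <- ab$prescriptions[ab$prescriptions$person_id == id, ]
    row <- bulk[bulk$scrambled_id == members$scrambled_id[i], ]
    for (nm in names(defs)) {
      want <- if (isTRUE(defs[[nm]]$persistence)) {
        classify_depression(defs[[nm]], cl, hx, rx, 2014, win)
      } else {
        classify_condition(defs[[nm]], cl, hx, win)$classified
      }
      expect_identical(row[[nm]], want, label = paste(id, nm))
    }
  }
})
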