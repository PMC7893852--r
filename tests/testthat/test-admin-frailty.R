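cfg <- admin_rule_config()

test_that("LTC residence fires on any day of overlap with the index year", {
  # episode entirely in the prior year
  e1 <- ltc_row(start_date = "2013-01-01", end_date = "2013-12-31")
  expect_length(rule_ltc(e1, 2014), 0)
  # open-ended episode starting earlier overlaps
  e2 <- ltc_row(start_date = "2012-05-01", end_date = NA)
  expect_equal(rule_ltc(e2, 2014), "P1")
  # randomized fixtures against the brute-force day-overlap oracle
  set.seed(8)
  for (i in 1:40) {
    s <- as.Date("2012-01-01") + sample.int(1400, 1)
    e <- if (runif(1) < 0.3) as.Date(NA) else s + sample.int(700, 1)
    got <- length(rule_ltc(ltc_row(start_date = s, end_date = e), 2014)) > 0
    expect_identical(got, ltc_overlap_oracle(s, e, 2014),
                     label = sprintf("%s..%s", s, e))
  }
})

test_that("terminal-illness coding counts only inside the index year", {
  h14 <- hospital_row(admit_date = "2014-03-01", discharge_date = "2014-03-05",
                      icd10_codes = "Z51.5")
  cl <- claim_row(icd9_code = "V66.7", service_date = "2013-06-01")
  empty_cl <- claim_row()[0, ]
  expect_equal(rule_terminal(empty_cl, h14, 2014, cfg), "P1")
  expect_length(rule_terminal(cl, h14[0, ], 2014, cfg), 0) # 2013 only
  expect_length(rule_terminal(empty_cl, h14[0, ], 2014, cfg), 0)
  empty_cfg <- cfg
  empty_cfg$terminal_icd9 <- character(0)
  empty_cfg$terminal_icd10 <- character(0)
  expect_warning(
    res <- rule_terminal(cl, h14, 2014, empty_cfg), "empty")
  expect_length(res, 0)
})

test_that("EFS indices count distinct domains, never repeated events", {
  # two falls claims: one domain only
  falls2 <- dplyr::bind_rows(
    claim_row(icd9_code = "E88.8", service_date = "2014-02-01"),
    claim_row(icd9_code = "E88.5", service_date = "2014-07-01"))
  r <- rule_efs_indices(falls2, hospital_row()[0, ], rx_row()[0, ], 2014, cfg)
  expect_equal(r$efs_count, 1)
  expect_false(r$hit)
  # cognition code + polypharmacy (6 distinct ATC): two domains
  cogn <- claim_row(icd9_code = "290.0", service_date = "2014-03-01")
  rx6 <- dplyr::bind_rows(lapply(
    c("A02BC01", "B01AA03", "C07AB02", "C10AA01", "N02BE01", "R03AC02"),
    function(a) rx_row(atc_code = a, dispense_date = "2014-05-01")))
  r2 <- rule_efs_indices(cogn, hospital_row()[0, ], rx6, 2014, cfg)
  expect_equal(r2$efs_count, 2)
  expect_true(r2$hit)
  # duplicating every event leaves the count unchanged
  r3 <- rule_efs_indices(dplyr::bind_rows(cogn, cogn), hospital_row()[0, ],
                         dplyr::bind_rows(rx6, rx6), 2014, cfg)
  expect_equal(r3$efs_count, r2$efs_count)
  # all domains firing counts every domain
  all_claims <- dplyr::bind_rows(lapply(
    c("290.0", "296.3", "788.3", "E88.8", "783.2", "V46.0", "V60.4"),
    function(code) claim_row(icd9_code = code, service_date = "2014-06-01")))
  r4 <- rule_efs_indices(all_claims, hospital_row()[0, ], rx6, 2014, cfg)
  expect_equal(r4$efs_count, length(cfg$efs_domains))
})

test_that("the admin definition is the OR of its three rules on a generated cohort", {
  g <- generate_cohort(sim_config(400, seed = 13))
  cw <- link_deterministic(g$emr, g$admin)
  coh <- build_cohort(g$emr, g$admin, cw, 2014)
  calls <- apply_admin_definition(g$admin, coh, 2014, cfg)
  expect_identical(calls$frail,
                   calls$rule_ltc | calls$rule_terminal | calls$rule_efs)
  # per-person brute-force re-evaluation of each rule
  members <- coh[coh$included, ]
  ab <- g$admin
  for (i in sample(seq_len(nrow(members)), min(60, nrow(members)))) {
    id <- members$admin_person_id[i]
    want_ltc <- id %in% rule_ltc(ab$ltc[ab$ltc$person_id == id, ], 2014)
    want_term <- id %in% rule_terminal(
      ab$claims[ab$claims$person_id == id, ],
      ab$hospitals[ab$hospitals$person_id == id, ], 2014, cfg)
    efs <- rule_efs_indices(ab$claims[ab$claims$person_id == id, ],
                            ab$hospitals[ab$hospitals$person_id == id, ],
                            ab$prescriptions[ab$prescriptions$person_id == id, ],
                            2014, cfg)
    want_efs <- isTRUE(efs$hit[efs$person_id == id])
    row <- calls[calls$scrambled_id == members$scrambled_id[i], ]
    expect_identical(row$frail, want_ltc || want_term || want_efs, label = id)
  }
  # adding events is monotone: granting everyone an LTC episode
  ab2 <- ab
  extra <- dplyr::bind_rows(lapply(members$admin_person_id, function(id)
    ltc_row(person_id = id, start_date = "2014-06-01")))
  ab2$ltc <- dplyr::bind_rows(ab2$ltc, extra)
  calls2 <- apply_admin_definition(ab2, coh, 2014, cfg)
  expect_true(all(calls2$frail >= calls$frail))
})
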