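window_2009_2014 <- c(as.Date("2009-01-01"), as.Date("2014-12-31"))

test_that("atoms match dot-insensitive prefixes, ATC prefixes and whole tokens", {
  dem <- list(kind = "icd9_prefix", values = "290")
  ev <- list(claims = claim_row(icd9_code = "290.0", service_date = "2011-05-02"))
  expect_true(evaluate_atom(dem, ev, window_2009_2014)$hit)
  # dot-insensitive both ways
  ev2 <- list(claims = claim_row(icd9_code = "2901", service_date = "2011-05-02"))
  expect_true(evaluate_atom(dem, ev2, window_2009_2014)$hit)
  # no events: false with empty evidence
  none <- evaluate_atom(dem, list(), window_2009_2014)
  expect_false(none$hit)
  expect_equal(nrow(none$evidence), 0)
  # keyword is whole-token and case-insensitive
  kw <- list(kind = "text_keyword", values = "obstruction")
  hit <- evaluate_atom(kw, list(claims = claim_row(
    free_text = "bowel OBSTRUCTION f/u")), window_2009_2014)
  expect_true(hit$hit)
  miss <- evaluate_atom(kw, list(claims = claim_row(
    free_text = "obstructive sleep apnea")), window_2009_2014)
  expect_false(miss$hit)
  # ATC prefix
  fur <- list(kind = "atc_prefix", values = "C03CA01")
  expect_true(evaluate_atom(fur, list(prescriptions = rx_row(
    atc_code = "C03CA01")), window_2009_2014)$hit)
  expect_false(evaluate_atom(fur, list(prescriptions = rx_row(
    atc_code = "C03DA01")), window_2009_2014)$hit)
  expect_error(evaluate_atom(list(kind = "bogus", values = "x"), list(),
                             window_2009_2014), "unknown atom kind")
})

test_that("events outside the lookback window never count nor appear as evidence", {
  dem <- list(kind = "icd9_prefix", values = "290")
  ev <- list(claims = claim_row(icd9_code = "290.0", service_date = "2008-12-31"))
  res <- evaluate_atom(dem, ev, window_2009_2014)
  expect_false(res$hit)
  expect_equal(nrow(res$evidence), 0)
})

make_def_cohort <- function(persons, claims = NULL, rx = NULL) {
  b <- bundle("emr", persons = persons, claims = claims, prescriptions = rx)
  cohort <- tibble::tibble(
    scrambled_id = persons$person_id, emr_person_id = persons$person_id,
    admin_person_id = persons$person_id, age_on_jan1 = 70L,
    coverage_fraction = 1, included = TRUE,
    exclusion_reason = factor("none", frailscan:::EXCLUSION_LEVELS))
  list(bundle = b, cohort = cohort)
}

test_that("the default definition combines its ingredients as documented", {
  persons <- dplyr::bind_rows(
    person_row("P1", "900000001"), person_row("P2", "900000002"),
    person_row("P3", "900000003"), person_row("P4", "900000004"))
  rx <- dplyr::bind_rows(
    rx_row("P1", atc_code = "A11GA01"),                      # vitamins only
    rx_row("P3", atc_code = "A11GA01"),
    rx_row("P3", atc_code = "C03CA01"))                      # vitamins + furosemide
  claims <- claim_row("P2", icd9_code = "290.0")             # dementia only
  w <- make_def_cohort(persons, claims, rx)
  calls <- apply_emr_definition(default_emr_definition(), w$bundle, w$cohort,
                                2014)
  frail <- setNames(calls$frail, calls$scrambled_id)
  expect_false(frail[["P1"]]) # vitamins alone insufficient
  expect_true(frail[["P2"]])  # dementia coding alone suffices
  expect_true(frail[["P3"]])  # the conjunction fires
  expect_false(frail[["P4"]])
  # frail implies non-empty evidence
  for (i in seq_len(nrow(calls))) {
    if (calls$frail[i]) expect_gt(nrow(calls$evidence[[i]]), 0)
  }
})

test_that("the rule engine equals brute-force evaluation over all assignments", {
  set.seed(42)
  for (k in c(3, 6, 10)) {
    atoms <- paste0("a", seq_len(k))
    for (rep in 1:5) {
      expr <- random_expr(atoms, depth = 3)
      n_cases <- 2^min(k, 10)
      grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
      colnames(grid) <- atoms
      got <- frailscan:::eval_rule_expr(expr, grid)
      want <- vapply(seq_len(nrow(grid)), function(i)
        eval_expr_oracle(expr, grid[i, ]), logical(1))
      expect_identical(got, want,
                       label = sprintf("k=%d rep=%d", k, rep))
    }
  }
})

test_that("adding events never unflags a person under a negation-free rule", {
  persons <- dplyr::bind_rows(person_row("P1", "900000001"),
                              person_row("P2", "900000002"))
  rx <- rx_row("P1", atc_code = "C03CA01")
  w <- make_def_cohort(persons, rx = rx)
  def <- default_emr_definition()
  before <- apply_emr_definition(def, w$bundle, w$cohort, 2014)$frail
  extra <- dplyr::bind_rows(rx, rx_row("P1", atc_code = "A11GA01"),
                            rx_row("P2", atc_code = "A11GA01"))
  w2 <- make_def_cohort(persons, rx = extra)
  after <- apply_emr_definition(def, w2$bundle, w2$cohort, 2014)$frail
  expect_true(all(after >= before))
})

test_that("rule files round-trip through JSON", {
  def <- default_emr_definition()
  path <- withr::local_tempfile(fileext = ".json")
  write_case_definition(def, path)
  def2 <- read_case_definition(path)
  expect_equal(def2$lookback_years, def$lookback_years)
  expect_equal(names(def2$atoms), names(def$atoms))
  expect_equal(frailscan:::deparse_rule_expr(def2$expression),
               frailscan:::deparse_rule_expr(def$expression))
  expect_error(case_definition(list(a = list(kind = "icd9_prefix",
                                             values = "290")),
                               expression = "b"),
               "undeclared")
})
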