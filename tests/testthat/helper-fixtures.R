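# Fixture builders and independent oracles used across the suite.

person_row <- function(person_id = "P1", phn = "900000001",
                       birth_date = "1940-06-15", sex = "female",
                       death_date = NA, income_quintile = 3,
                       postal_code = "V6T2B5",
                       coverage = "2009-01-01..2015-12-31") {
  tibble::tibble(person_id = person_id, phn = phn,
                 birth_date = as.Date(birth_date), sex = sex,
                 death_date = as.Date(death_date),
                 income_quintile = income_quintile,
                 postal_code = postal_code, coverage = coverage)
}

claim_row <- function(person_id = "P1", service_date = "2014-03-01",
                      icd9_code = "", free_text = "", provider_type = "gp",
                      fee = 30) {
  tibble::tibble(person_id = person_id,
                 service_date = as.Date(service_date), icd9_code = icd9_code,
                 free_text = free_text, provider_type = provider_type,
                 fee = fee)
}

rx_row <- function(person_id = "P1", dispense_date = "2014-03-01",
                   atc_code = "C03CA01", source = "emr", cost = 12) {
  tibble::tibble(person_id = person_id,
                 dispense_date = as.Date(dispense_date), atc_code = atc_code,
                 source = source, cost = cost)
}

hospital_row <- function(person_id = "P1", admit_date = "2014-05-01",
                         discharge_date = "2014-05-08",
                         icd10_codes = "I10", cost = 5000) {
  tibble::tibble(person_id = person_id, admit_date = as.Date(admit_date),
                 discharge_date = as.Date(discharge_date),
                 icd10_codes = icd10_codes, cost = cost)
}

ltc_row <- function(person_id = "P1", start_date = "2014-02-01",
                    end_date = NA, setting = "long_term_care") {
  tibble::tibble(person_id = person_id, start_date = as.Date(start_date),
                 end_date = as.Date(end_date), setting = setting)
}

obs_row <- function(person_id = "P1", obs_date = "2014-01-15",
                    kind = "systolic_bp", value = 130) {
  tibble::tibble(person_id = person_id, obs_date = as.Date(obs_date),
                 kind = kind, value = value)
}

# A small random but always-valid bundle for round-trip property tests.
random_bundle <- function(n = 10, seed = 1, source = "emr") {
  set.seed(seed)
  ids <- sprintf("P%03d", seq_len(n))
  persons <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    person_row(
      person_id = ids[i], phn = sprintf("9%08d", i),
      birth_date = as.Date("1935-01-01") + sample.int(7000, 1),
      sex = sample(c("female", "male"), 1),
      death_date = if (runif(1) < 0.2) as.Date("2015-01-01") + sample.int(300, 1) else NA,
      income_quintile = sample.int(5, 1),
      postal_code = paste0(sample(LETTERS[1:18], 1), sample(0:9, 1), "T",
                           sample(0:9, 1), "B", sample(0:9, 1)),
      coverage = if (runif(1) < 0.3)
        "2009-01-01..2012-06-30;2013-01-01..2015-12-31" else
        "2009-01-01..2015-12-31"
    )
  }))
  claims <- dplyr::bind_rows(lapply(seq_len(3 * n), function(i) {
    claim_row(person_id = sample(ids, 1),
              service_date = as.Date("2013-01-01") + sample.int(700, 1),
              icd9_code = sample(c("", "401.1", "290.0", "V66.7", "E88.8"), 1),
              free_text = sample(c("", "follow up", "bowel obstruction"), 1),
              provider_type = sample(c("gp", "specialist"), 1),
              fee = round(runif(1, 10, 90), 2))
  }))
  rx <- dplyr::bind_rows(lapply(seq_len(2 * n), function(i) {
    rx_row(person_id = sample(ids, 1),
           dispense_date = as.Date("2014-01-01") + sample.int(300, 1),
           atc_code = sample(c("A11GA01", "C03CA01", "N06AB04", "A02BC01"), 1),
           source = source, cost = round(runif(1, 5, 60), 2))
  }))
  hosp <- dplyr::bind_rows(lapply(seq_len(max(1, n %/% 3)), function(i) {
    d <- as.Date("2014-01-01") + sample.int(600, 1)
    hospital_row(person_id = sample(ids, 1), admit_date = d,
                 discharge_date = d + sample.int(20, 1),
                 icd10_codes = sample(c("I10", "F03;I10", "Z51.5"), 1),
                 cost = round(runif(1, 1000, 20000), 2))
  }))
  obs <- dplyr::bind_rows(lapply(seq_len(2 * n), function(i) {
    k <- sample(c("systolic_bp", "diastolic_bp", "bmi"), 1)
    obs_row(person_id = sample(ids, 1),
            obs_date = as.Date("2013-06-01") + sample.int(500, 1), kind = k,
            value = switch(k, systolic_bp = round(runif(1, 95, 180), 1),
                           diastolic_bp = round(runif(1, 55, 100), 1),
                           bmi = round(runif(1, 17, 40), 1)))
  }))
  bundle(source, persons = persons, claims = claims, prescriptions = rx,
         hospitals = hosp, observations = obs)
}

# ---- independent oracles ---------------------------------------------------

# Nested rule expression -> base-R logical expression, evaluated per
# assignment (independent path from the package's rule engine).
expr_to_string <- function(expr) {
  if (is.character(expr)) return(expr)
  op <- expr[[1]]
  args <- vapply(expr[-1], expr_to_string, "")
  if (op == "not") paste0("(!", args, ")")
  else paste0("(", paste(args, collapse = if (op == "and") " & " else " | "), ")")
}

eval_expr_oracle <- function(expr, assignment) {
  eval(parse(text = expr_to_string(expr)), envir = as.list(assignment))
}

random_expr <- function(atoms, depth = 3) {
  if (depth == 0 || runif(1) < 0.3) return(sample(atoms, 1))
  op <- sample(c("and", "or", "not"), 1)
  if (op == "not") return(list("not", random_expr(atoms, depth - 1)))
  k <- sample(2:3, 1)
  c(list(op), lapply(seq_len(k), function(i) random_expr(atoms, depth - 1)))
}

# O(n^2) all-pairs comorbidity oracle.
comorbidity_oracle <- function(claim_dates, window_days, any_hospital) {
  if (any_hospital) return(TRUE)
  n <- length(claim_dates)
  if (n < 2) return(FALSE)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(as.integer(claim_dates[j]) - as.integer(claim_dates[i])) <=
          window_days) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Brute-force day-overlap oracle for LTC episodes.
ltc_overlap_oracle <- function(start, end, index_year) {
  days <- seq(frailscan:::year_start(index_year),
              frailscan:::year_end(index_year), by = "day")
  end <- if (is.na(end)) as.Date("9999-12-31") else end
  any(days >= start & days <= end)
}
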