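#' Rolling-window chronic-condition classification
#'
#' Eight chronic conditions (hypertension, diabetes, COPD, osteoarthritis,
#' dementia, depression, epilepsy, parkinsonism) are classified per person
#' and per data source: one hospital diagnosis (ICD-10-CA prefix match)
#' suffices, or two physician claims (ICD-9 prefix match) whose service
#' dates differ by at most the condition's rolling window (730 days by
#' default; 365 for depression). Depression additionally requires
#' treatment evidence in the index year (any antidepressant dispensation,
#' depression claim, or depression hospitalization) when the person first
#' qualified before the index year — the condition can wax and wane.
#' Two same-day claims count as two diagnoses.
#'
#' @name comorbidity
NULL

#' Load condition definitions
#'
#' @param path YAML file; defaults to the shipped definitions.
#' @return Named list of condition definitions (class `condition_defs`).
#' @export
condition_defs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "condition_defs.yaml", package = "frailscan")
    if (path == "") abort("shipped condition definition file not found")
  }
  x <- yaml::read_yaml(path)$conditions
  for (nm in names(x)) {
    cd <- x[[nm]]
    if (length(cd$icd9) == 0 || length(cd$icd10) == 0) {
      abort(sprintf("condition '%s': empty code set", nm))
    }
    if ((cd$window_days %||% 730) <= 0) {
      abort(sprintf("condition '%s': window_days must be positive", nm))
    }
    x[[nm]]$name <- nm
    x[[nm]]$window_days <- as.integer(cd$window_days %||% 730)
  }
  structure(x, class = "condition_defs")
}

# Earliest date at which the two-claim-within-window criterion is met on a
# sorted date vector; NA when never. Any qualifying pair implies an
# adjacent qualifying pair, so a single pass over sorted adjacent gaps
# suffices.
first_pair_within <- function(dates, window_days) {
  if (length(dates) < 2) return(as.Date(NA))
  d <- sort(dates)
  gaps <- as.integer(diff(d))
  ok <- which(gaps <= window_days)
  if (length(ok) == 0) return(as.Date(NA))
  d[ok[1] + 1]
}

#' Classify one condition for one person
#'
#' @param cond_def One condition definition (element of [condition_defs()]).
#' @param claims Physician claims for one person (ICD-9 coded).
#' @param hospitals Hospital abstracts for one person (ICD-10-CA coded).
#' @param study_window Length-2 Date vector delimiting usable data.
#' @return List with `classified` (logical) and `first_qualifying_date`
#'   (`NA` when not classified).
#' @export
classify_condition <- function(cond_def, claims, hospitals, study_window) {
  cl <- claims[claims$service_date >= study_window[1] &
                 claims$service_date <= study_window[2] &
                 claims$icd9_code != "", , drop = FALSE]
  cl <- cl[match_prefix(cl$icd9_code, cond_def$icd9), , drop = FALSE]
  hx <- explode_hospital_codes(hospitals)
  hx <- hx[hx$date >= study_window[1] & hx$date <= study_window[2], ,
           drop = FALSE]
  hx <- hx[match_prefix(hx$code, cond_def$icd10), , drop = FALSE]
  hosp_date <- if (nrow(hx) > 0) min(hx$date) else as.Date(NA)
  pair_date <- first_pair_within(cl$service_date, cond_def$window_days)
  first <- suppressWarnings(min(c(hosp_date, pair_date), na.rm = TRUE))
  if (is.infinite(first)) {
    return(list(classified = FALSE, first_qualifying_date = as.Date(NA)))
  }
  list(classified = TRUE, first_qualifying_date = as.Date(first, origin = "1970-01-01"))
}

#' Classify depression with the persistence requirement
#'
#' @param cond_def The depression condition definition.
#' @param claims,hospitals,prescriptions Event tibbles for one person.
#' @param index_year Index calendar year.
#' @param study_window Length-2 Date vector delimiting usable data.
#' @return Logical.
#' @export
classify_depression <- function(cond_def, claims, hospitals, prescriptions,
                                index_year, study_window) {
  base <- classify_condition(cond_def, claims, hospitals, study_window)
  if (!base$classified) return(FALSE)
  if (base$first_qualifying_date >= year_start(index_year)) return(TRUE)
  ys <- year_start(index_year); ye <- year_end(index_year)
  rx <- prescriptions[prescriptions$dispense_date >= ys &
                        prescriptions$dispense_date <= ye, , drop = FALSE]
  has_rx <- any(match_prefix(rx$atc_code, cond_def$treatment_atc %||% "N06A"))
  cl <- claims[claims$service_date >= ys & claims$service_date <= ye &
                 claims$icd9_code != "", , drop = FALSE]
  has_claim <- any(match_prefix(cl$icd9_code, cond_def$icd9))
  hx <- explode_hospital_codes(hospitals)
  hx <- hx[hx$date >= ys & hx$date <= ye, , drop = FALSE]
  has_hosp <- any(match_prefix(hx$code, cond_def$icd10))
  has_rx || has_claim || has_hosp
}

#' Classify all conditions for every cohort member from one source
#'
#' @param bundle A `frail_bundle` (the claims/hospitals/prescriptions of
#'   one source).
#' @param cohort Output of [build_cohort()] (included rows classified).
#' @param index_year Index calendar year.
#' @param defs [condition_defs()] (default: shipped).
#' @param lookback_years Years of data ending with the index year that the
#'   rolling windows may use (default 6).
#' @return Tibble: `scrambled_id`, one logical column per condition,
#'   `n_conditions`, `band` (`"0-1"`, `"2"`, `"3+"`).
#' @export
classify_conditions <- function(bundle, cohort, index_year,
                                defs = condition_defs(), lookback_years = 6) {
  members <- cohort[cohort$included, ]
  id_col <- if (bundle$source == "emr") "emr_person_id" else "admin_person_id"
  ids <- members[[id_col]]
  window <- c(year_start(index_year - lookback_years + 1), year_end(index_year))
  ys <- year_start(index_year); ye <- year_end(index_year)

  cl <- bundle$claims
  cl <- cl[cl$service_date >= window[1] & cl$service_date <= window[2] &
             cl$icd9_code != "" & cl$person_id %in% ids, , drop = FALSE]
  hx <- explode_hospital_codes(bundle$hospitals)
  hx <- hx[hx$date >= window[1] & hx$date <= window[2] &
             hx$person_id %in% ids, , drop = FALSE]
  rx <- bundle$prescriptions
  rx_iy <- rx[rx$dispense_date >= ys & rx$dispense_date <= ye &
                rx$person_id %in% ids, , drop = FALSE]

  out <- tibble::tibble(scrambled_id = members$scrambled_id)
  flags <- matrix(FALSE, length(ids), length(defs),
                  dimnames = list(NULL, names(defs)))
  for (nm in names(defs)) {
    cd <- defs[[nm]]
    ccl <- cl[match_prefix(cl$icd9_code, cd$icd9), , drop = FALSE]
    chx <- hx[match_prefix(hx$code, cd$icd10), , drop = FALSE]
    pair <- if (nrow(ccl) == 0) NULL else
      ccl |>
        dplyr::group_by(.data$person_id) |>
        dplyr::summarise(
          qdate = first_pair_within(.data$service_date, cd$window_days),
          .groups = "drop") |>
        dplyr::filter(!is.na(.data$qdate))
    hosp <- if (nrow(chx) == 0) NULL else
      chx |>
        dplyr::group_by(.data$person_id) |>
        dplyr::summarise(qdate = min(.data$date), .groups = "drop")
    qual <- dplyr::bind_rows(pair, hosp)
    if (nrow(qual) > 0) {
      qual <- qual |>
        dplyr::group_by(.data$person_id) |>
        dplyr::summarise(qdate = min(.data$qdate), .groups = "drop")
    } else {
      qual <- tibble::tibble(person_id = character(),
                             qdate = as.Date(character()))
    }
    hit <- ids %in% qual$person_id
    if (isTRUE(cd$persistence) && any(hit)) {
      # waxing/waning condition: pre-index qualifiers must show treatment
      # evidence in the index year to stay classified
      atc <- cd$treatment_atc %||% "N06A"
      treated <- unique(c(
        rx_iy$person_id[match_prefix(rx_iy$atc_code, atc)],
        ccl$person_id[ccl$service_date >= ys & ccl$service_date <= ye],
        chx$person_id[chx$date >= ys & chx$date <= ye]
      ))
      early <- qual$person_id[qual$qdate < ys]
      drop <- ids %in% setdiff(early, treated)
      hit <- hit & !drop
    }
    flags[, nm] <- hit
  }
  for (nm in names(defs)) out[[nm]] <- flags[, nm]
  cc <- count_conditions(flags)
  out$n_conditions <- cc$count
  out$band <- cc$band
  out
}

#' Count conditions and band them
#'
#' @param flags Logical matrix or data frame of per-condition indicators
#'   (columns = conditions).
#' @return List with `count` (integer vector) and `band` (factor with
#'   levels `"0-1"`, `"2"`, `"3+"`).
#' @export
count_conditions <- function(flags) {
  flags <- as.matrix(flags)
  count <- as.integer(rowSums(flags))
  band <- cut(count, breaks = c(-Inf, 1, 2, Inf), labels = c("0-1", "2", "3+"))
  list(count = count, band = band)
}
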