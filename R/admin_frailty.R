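#' Administrative frailty case definition
#'
#' A person aged 65+ is considered frail in the administrative data for an
#' index year when at least one of three identification rules fires:
#' 1. resident in a long-term-care or assisted-living facility (any episode
#'    overlapping the index year by at least one day);
#' 2. terminally ill (any palliative/terminal-illness code on a claim or
#'    hospital diagnosis dated in the index year); or
#' 3. at least `efs_min_indices` (default 2) *distinct* domains of the
#'    modified Edmonton Frail Scale with a qualifying event in the index
#'    year — repeated events within one domain count once. The
#'    polypharmacy domain fires on `>= polypharmacy_min_distinct` distinct
#'    full ATC codes dispensed in the year.
#'
#' Code sets ship as an editable YAML file (see
#' `system.file("extdata", "admin_frailty_rules.yaml", package = "frailscan")`)
#' with conservative, documented stand-in defaults.
#'
#' @name admin_frailty
NULL

#' Load an administrative rule configuration
#'
#' @param path YAML file; defaults to the shipped rule set.
#' @return An object of class `admin_rule_config`.
#' @export
admin_rule_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "admin_frailty_rules.yaml",
                        package = "frailscan")
    if (path == "") abort("shipped admin rule file not found")
  }
  x <- yaml::read_yaml(path)
  if (is.null(x$efs_domains) || length(x$efs_domains) == 0) {
    abort("admin rule config must define efs_domains")
  }
  if ((x$efs_min_indices %||% 2) < 1) abort("efs_min_indices must be >= 1")
  if (anyDuplicated(names(x$efs_domains))) {
    abort("EFS domain names must be unique")
  }
  structure(list(
    terminal_icd9 = unlist(x$terminal_illness$icd9),
    terminal_icd10 = unlist(x$terminal_illness$icd10),
    efs_min_indices = as.integer(x$efs_min_indices %||% 2),
    polypharmacy_min_distinct = as.integer(x$polypharmacy_min_distinct %||% 6),
    efs_domains = x$efs_domains
  ), class = "admin_rule_config")
}

# Split hospital rows into one row per diagnosis code.
explode_hospital_codes <- function(hospitals) {
  if (nrow(hospitals) == 0) {
    return(tibble::tibble(person_id = character(), date = as.Date(character()),
                          code = character()))
  }
  codes <- strsplit(hospitals$icd10_codes, ";", fixed = TRUE)
  idx <- rep(seq_len(nrow(hospitals)), lengths(codes))
  tibble::tibble(person_id = hospitals$person_id[idx],
                 date = hospitals$admit_date[idx],
                 code = trimws(unlist(codes)))
}

#' Rule 1: long-term-care or assisted-living residence
#'
#' @param ltc_episodes Tibble of LTC episodes for one or more persons.
#' @param index_year Index calendar year.
#' @return Character vector of person_ids with an episode overlapping the
#'   index year by at least one day (open-ended episodes extend forever).
#' @export
rule_ltc <- function(ltc_episodes, index_year) {
  if (nrow(ltc_episodes) == 0) return(character(0))
  ys <- year_start(index_year); ye <- year_end(index_year)
  ends <- dplyr::coalesce(ltc_episodes$end_date, as.Date("9999-12-31"))
  hit <- ltc_episodes$start_date <= ye & ends >= ys
  unique(ltc_episodes$person_id[hit])
}

#' Rule 2: terminal illness coding in the index year
#'
#' @param claims,hospitals Event tibbles.
#' @param index_year Index calendar year.
#' @param config An [admin_rule_config()].
#' @return Character vector of person_ids with a matching claim or
#'   hospital diagnosis dated in the index year.
#' @export
rule_terminal <- function(claims, hospitals, index_year, config) {
  if (length(config$terminal_icd9) == 0 && length(config$terminal_icd10) == 0) {
    warn("terminal-illness code set is empty; rule 2 never fires")
    return(character(0))
  }
  ys <- year_start(index_year); ye <- year_end(index_year)
  hits <- character(0)
  cl <- claims[claims$service_date >= ys & claims$service_date <= ye &
                 claims$icd9_code != "", ]
  if (nrow(cl) > 0 && length(config$terminal_icd9) > 0) {
    hits <- c(hits, cl$person_id[match_prefix(cl$icd9_code, config$terminal_icd9)])
  }
  hx <- explode_hospital_codes(hospitals)
  hx <- hx[hx$date >= ys & hx$date <= ye, ]
  if (nrow(hx) > 0 && length(config$terminal_icd10) > 0) {
    hits <- c(hits, hx$person_id[match_prefix(hx$code, config$terminal_icd10)])
  }
  unique(hits)
}

#' Rule 3: distinct modified-Edmonton-Frail-Scale domain count
#'
#' @param claims,hospitals,prescriptions Event tibbles.
#' @param index_year Index calendar year.
#' @param config An [admin_rule_config()].
#' @return Tibble `person_id`, `efs_count`, `efs_domains` (comma-separated),
#'   `hit` (`efs_count >= efs_min_indices`); persons with zero qualifying
#'   domains are absent.
#' @export
rule_efs_indices <- function(claims, hospitals, prescriptions, index_year,
                             config) {
  ys <- year_start(index_year); ye <- year_end(index_year)
  cl <- claims[claims$service_date >= ys & claims$service_date <= ye &
                 claims$icd9_code != "", ]
  hx <- explode_hospital_codes(hospitals)
  hx <- hx[hx$date >= ys & hx$date <= ye, ]
  rx <- prescriptions[prescriptions$dispense_date >= ys &
                        prescriptions$dispense_date <= ye, ]
  domain_hits <- lapply(names(config$efs_domains), function(dn) {
    dom <- config$efs_domains[[dn]]
    ids <- if (identical(dom, "distinct_atc")) {
      if (nrow(rx) == 0) character(0) else {
        counts <- tapply(rx$atc_code, rx$person_id,
                         function(a) length(unique(a)))
        names(counts)[counts >= config$polypharmacy_min_distinct]
      }
    } else {
      c(
        if (length(dom$icd9) > 0 && nrow(cl) > 0)
          cl$person_id[match_prefix(cl$icd9_code, unlist(dom$icd9))],
        if (length(dom$icd10) > 0 && nrow(hx) > 0)
          hx$person_id[match_prefix(hx$code, unlist(dom$icd10))]
      )
    }
    ids <- unique(ids)
    if (length(ids) == 0) return(NULL)
    tibble::tibble(person_id = ids, domain = dn)
  })
  all_hits <- dplyr::bind_rows(domain_hits)
  if (is.null(all_hits) || nrow(all_hits) == 0) {
    return(tibble::tibble(person_id = character(), efs_count = integer(),
                          efs_domains = character(), hit = logical()))
  }
  all_hits |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(efs_count = dplyr::n_distinct(.data$domain),
                     efs_domains = paste(sort(unique(.data$domain)),
                                         collapse = ","),
                     .groups = "drop") |>
    dplyr::mutate(hit = .data$efs_count >= config$efs_min_indices)
}

#' Apply the administrative frailty definition to a cohort
#'
#' Frail if and only if at least one of the three rules fires in the index
#' year; the evidence columns record which.
#'
#' @param admin_bundle Administrative bundle (pre-scrambling ids).
#' @param cohort Output of [build_cohort()]; included rows only.
#' @param index_year Index calendar year.
#' @param config An [admin_rule_config()] (default: shipped rules).
#' @return A tibble: `scrambled_id`, `source = "admin"`, `frail`,
#'   `rule_ltc`, `rule_terminal`, `rule_efs`, `efs_count`, `efs_domains`.
#' @export
apply_admin_definition <- function(admin_bundle, cohort, index_year,
                                   config = admin_rule_config()) {
  stopifnot(inherits(config, "admin_rule_config"))
  members <- cohort[cohort$included, ]
  ltc_ids <- rule_ltc(admin_bundle$ltc, index_year)
  term_ids <- rule_terminal(admin_bundle$claims, admin_bundle$hospitals,
                            index_year, config)
  efs <- rule_efs_indices(admin_bundle$claims, admin_bundle$hospitals,
                          admin_bundle$prescriptions, index_year, config)
  efs_ids <- efs$person_id[efs$hit]
  m <- match(members$admin_person_id, efs$person_id)
  out <- tibble::tibble(
    scrambled_id = members$scrambled_id,
    source = "admin",
    rule_ltc = members$admin_person_id %in% ltc_ids,
    rule_terminal = members$admin_person_id %in% term_ids,
    rule_efs = members$admin_person_id %in% efs_ids,
    efs_count = ifelse(is.na(m), 0L, efs$efs_count[m]),
    efs_domains = ifelse(is.na(m), "", efs$efs_domains[m])
  )
  out$frail <- out$rule_ltc | out$rule_terminal | out$rule_efs
  out[, c("scrambled_id", "source", "frail", "rule_ltc", "rule_terminal",
          "rule_efs", "efs_count", "efs_domains")]
}
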