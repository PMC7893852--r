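#' Cohort inclusion criteria
#'
#' A person enters the analysis cohort for an index year when they are
#' linked across the two sources, aged 65 or older on January 1 of the
#' index year, had at least one primary-care (GP) encounter in the EMR in
#' the two calendar years ending with the index year, and were registered
#' for provincial health coverage for at least 75% of the days they were
#' alive in the index year. Exclusions are labelled with the first failing
#' rule in that order.
#'
#' @name cohort_builder
NULL

EXCLUSION_LEVELS <- c("none", "not_linked", "under_65", "no_recent_visit",
                      "low_coverage")

#' Fraction of days alive in the index year covered by the registry
#'
#' Counts calendar days (closed intervals, actual day counts across leap
#' years): the numerator is days of the index year both covered by a
#' registry episode and on or before the death date; the denominator is
#' days alive in the index year. A person dead before January 1 has no
#' alive days; the fraction is defined as 0 and flagged via the
#' `dead_before_year` attribute.
#'
#' @param coverage Coverage episode string (`"start..end;..."`) or a
#'   data frame with `start`/`end` Date columns.
#' @param death_date Death date or `NA`.
#' @param index_year Index calendar year.
#' @return Fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(coverage, death_date, index_year) {
  ys <- year_start(index_year)
  ye <- year_end(index_year)
  if (!is.na(death_date) && death_date < ys) {
    return(structure(0, dead_before_year = TRUE))
  }
  alive_end <- if (is.na(death_date)) ye else min(ye, death_date)
  alive_days <- days_inclusive(ys, alive_end)
  eps <- if (is.data.frame(coverage)) normalize_episodes(coverage) else
    parse_coverage(coverage)
  if (nrow(eps) == 0) return(0)
  ov_start <- pmax(eps$start, ys)
  ov_end <- pmin(eps$end, alive_end)
  covered <- sum(pmax(0L, as.integer(ov_end) - as.integer(ov_start) + 1L))
  covered / alive_days
}

#' Build the inclusion cohort
#'
#' @param emr_bundle Validated EMR bundle (pre-scrambling identifiers).
#' @param admin_bundle Validated administrative bundle.
#' @param crosswalk A [link_deterministic()] crosswalk.
#' @param index_year Index calendar year.
#' @param min_age Minimum age in completed years on January 1 (default 65).
#' @param min_coverage Minimum coverage fraction (default 0.75; persons
#'   with coverage strictly below this are excluded).
#' @param visit_window_years Length in calendar years of the
#'   primary-care-contact window ending December 31 of the index year
#'   (default 2).
#' @return A tibble with one row per EMR person: `scrambled_id`,
#'   `emr_person_id`, `admin_person_id` (`NA` if unlinked), `age_on_jan1`,
#'   `included`, `exclusion_reason`.
#' @export
build_cohort <- function(emr_bundle, admin_bundle, crosswalk, index_year,
                         min_age = 65, min_coverage = 0.75,
                         visit_window_years = 2) {
  p <- emr_bundle$persons
  links <- crosswalk$links
  missing_emr <- setdiff(links$emr_person_id, p$person_id)
  if (length(missing_emr) > 0) {
    abort(sprintf("crosswalk references EMR person(s) absent from bundle: %s",
                  paste(head(missing_emr, 5), collapse = ", ")))
  }
  missing_admin <- setdiff(links$admin_person_id, admin_bundle$persons$person_id)
  if (length(missing_admin) > 0) {
    abort(sprintf("crosswalk references admin person(s) absent from bundle: %s",
                  paste(head(missing_admin, 5), collapse = ", ")))
  }
  jan1 <- year_start(index_year)
  idx <- match(p$person_id, links$emr_person_id)
  linked <- !is.na(idx)
  age <- age_at(p$birth_date, jan1)

  win_lo <- year_start(index_year - visit_window_years + 1)
  win_hi <- year_end(index_year)
  gp <- emr_bundle$claims[emr_bundle$claims$provider_type == "gp" &
                            emr_bundle$claims$service_date >= win_lo &
                            emr_bundle$claims$service_date <= win_hi, ]
  has_visit <- p$person_id %in% gp$person_id

  covfrac <- vapply(seq_len(nrow(p)), function(i) {
    as.numeric(coverage_fraction(p$coverage[i], p$death_date[i], index_year))
  }, numeric(1))

  reason <- rep("none", nrow(p))
  reason[covfrac < min_coverage] <- "low_coverage"
  reason[!has_visit] <- "no_recent_visit"
  reason[age < min_age] <- "under_65"
  reason[!linked] <- "not_linked"

  tibble::tibble(
    scrambled_id = ifelse(linked, links$scrambled_id[idx], p$person_id),
    emr_person_id = p$person_id,
    admin_person_id = ifelse(linked, links$admin_person_id[idx], NA_character_),
    age_on_jan1 = age,
    coverage_fraction = covfrac,
    included = reason == "none",
    exclusion_reason = factor(reason, levels = EXCLUSION_LEVELS)
  )
}
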