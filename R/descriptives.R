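#' Mutually exclusive frailty groups and descriptive tables
#'
#' Cohort members are partitioned into four mutually exclusive groups by
#' their two frailty calls: frail in the EMR definition only
#' (`emr_only`), in the administrative definition only (`admin_only`), in
#' both (`both`), or in neither (`neither`). Characteristics (demographics,
#' blood pressure, BMI, comorbidity bands per source) are summarized on
#' index-year data; utilization, costs, polypharmacy and death on
#' data from the following year, excluding persons who died during the
#' index year from the utilization denominators. Percentages and
#' means/SDs are reported to one decimal, rounded half away from zero.
#'
#' @name descriptives
NULL

GROUP_LEVELS <- c("emr_only", "admin_only", "both", "neither")

#' Assign mutually exclusive frailty groups
#'
#' @param emr_calls,admin_calls Frailty-call tibbles from
#'   [apply_emr_definition()] and [apply_admin_definition()]; both must
#'   cover exactly the same persons.
#' @return Tibble `scrambled_id`, `group` (factor with levels `emr_only`,
#'   `admin_only`, `both`, `neither`).
#' @export
assign_groups <- function(emr_calls, admin_calls) {
  if (!setequal(emr_calls$scrambled_id, admin_calls$scrambled_id)) {
    only <- c(setdiff(emr_calls$scrambled_id, admin_calls$scrambled_id),
              setdiff(admin_calls$scrambled_id, emr_calls$scrambled_id))
    abort(sprintf("person(s) present in one call list only: %s",
                  paste(head(only, 5), collapse = ", ")))
  }
  m <- match(emr_calls$scrambled_id, admin_calls$scrambled_id)
  e <- emr_calls$frail
  a <- admin_calls$frail[m]
  group <- dplyr::case_when(
    e & a ~ "both",
    e & !a ~ "emr_only",
    !e & a ~ "admin_only",
    .default = "neither"
  )
  tibble::tibble(scrambled_id = emr_calls$scrambled_id,
                 group = factor(group, levels = GROUP_LEVELS))
}

#' Rural/urban residence from the forward sortation area
#'
#' Residence is rural when the second character of the forward sortation
#' area (the first three characters of the postal code) is `"0"`.
#'
#' @param postal_code Character vector of 6-character Canadian postal codes.
#' @return Factor with levels `rural`, `urban`.
#' @export
rural_flag <- function(postal_code) {
  # only the FSA's second character matters; require the 6-character shape
  # and a classifiable second character (full postal validation happens at
  # bundle construction)
  bad <- which(!grepl("^[A-Za-z][0-9].{4}$", postal_code))
  if (length(bad) > 0) {
    abort(sprintf("malformed postal code at position(s) %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  factor(ifelse(substr(postal_code, 2, 2) == "0", "rural", "urban"),
         levels = c("rural", "urban"))
}

#' Mean of the three most recent readings
#'
#' Readings are stably sorted by date (then input order); the mean of the
#' last up to three is returned.
#'
#' @param observations Observation tibble (one person, or filtered).
#' @param kind One of `"systolic_bp"`, `"diastolic_bp"`, `"bmi"`.
#' @param window Optional length-2 Date vector restricting reading dates.
#' @return List with `mean` (`NA` when no readings) and `n_used`.
#' @export
mean_recent_bp <- function(observations, kind, window = NULL) {
  x <- observations[observations$kind == kind, , drop = FALSE]
  if (!is.null(window)) {
    x <- x[x$obs_date >= window[1] & x$obs_date <= window[2], , drop = FALSE]
  }
  if (nrow(x) == 0) return(list(mean = NA_real_, n_used = 0L))
  ord <- order(x$obs_date)  # stable: ties keep input order
  vals <- x$value[ord]
  take <- utils::tail(vals, 3)
  list(mean = mean(take), n_used = length(take))
}

#' Polypharmacy: more than five distinct medications in a year
#'
#' @param prescriptions Prescription tibble for one or more persons.
#' @param year Target calendar year.
#' @param min_distinct Count of distinct full ATC codes at or above which
#'   the flag is true (default 6, i.e. strictly more than 5).
#' @return Tibble `person_id`, `n_distinct_atc`, `polypharmacy`.
#' @export
polypharmacy_flag <- function(prescriptions, year, min_distinct = 6) {
  rx <- prescriptions[prescriptions$dispense_date >= year_start(year) &
                        prescriptions$dispense_date <= year_end(year), ,
                      drop = FALSE]
  if (nrow(rx) == 0) {
    return(tibble::tibble(person_id = character(), n_distinct_atc = integer(),
                          polypharmacy = logical()))
  }
  rx |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(n_distinct_atc = dplyr::n_distinct(.data$atc_code),
                     .groups = "drop") |>
    dplyr::mutate(polypharmacy = .data$n_distinct_atc >= min_distinct)
}

mean_sd_row <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(c(mean = NA_real_, sd = NA_real_))
  c(mean = round_half_away(mean(x), 1),
    sd = if (length(x) > 1) round_half_away(sd(x), 1) else NA_real_)
}

#' Summarize the cohort by frailty group
#'
#' Produces the descriptive table contents: per-group counts and
#' percentages for age bands (65-74, 75-84, 85+), sex, income (high =
#' quintiles 3-5, low = 1-2), rural/urban residence, comorbidity bands per
#' source; mean (SD) systolic/diastolic blood pressure (three most recent
#' readings per person, index year and the year before) and BMI; and
#' next-year utilization (GP contacts, costs by category, acute
#' hospitalizations per 100, hospital days, polypharmacy, deaths).
#'
#' @param groups Output of [assign_groups()].
#' @param cohort Output of [build_cohort()].
#' @param emr_bundle,admin_bundle Source bundles (pre-scrambling ids).
#' @param comorbid_emr,comorbid_admin Outputs of [classify_conditions()]
#'   per source.
#' @param index_year Index calendar year.
#' @return A list of class `frail_summary`: `characteristics` and
#'   `utilization`, both long tibbles with one row per group x statistic.
#' @export
summarize_cohort <- function(groups, cohort, emr_bundle, admin_bundle,
                             comorbid_emr, comorbid_admin, index_year) {
  members <- cohort[cohort$included, ]
  members <- dplyr::left_join(members, groups, by = "scrambled_id")
  ep <- emr_bundle$persons
  pm <- match(members$emr_person_id, ep$person_id)
  members$sex <- ep$sex[pm]
  members$income_quintile <- ep$income_quintile[pm]
  members$postal_code <- ep$postal_code[pm]
  members$death_date <- ep$death_date[pm]
  members$age_band <- cut(members$age_on_jan1, c(-Inf, 74, 84, Inf),
                          labels = c("65-74", "75-84", "85+"))
  members$income_band <- factor(
    ifelse(members$income_quintile >= 3, "high", "low"),
    levels = c("high", "low"))
  members$residence <- rural_flag(members$postal_code)
  members$comorb_band_emr <-
    comorbid_emr$band[match(members$scrambled_id, comorbid_emr$scrambled_id)]
  members$comorb_band_admin <-
    comorbid_admin$band[match(members$scrambled_id, comorbid_admin$scrambled_id)]

  bp_window <- c(year_start(index_year - 1), year_end(index_year))
  obs_by <- split(emr_bundle$observations, emr_bundle$observations$person_id)
  empty_obs <- empty_bundle_table("observations")
  for (kind in c("systolic_bp", "diastolic_bp", "bmi")) {
    members[[kind]] <- vapply(members$emr_person_id, function(id) {
      mean_recent_bp(obs_by[[id]] %||% empty_obs, kind, bp_window)$mean
    }, numeric(1))
  }

  cat_block <- function(var) {
    members |>
      dplyr::count(.data$group, level = .data[[var]], .drop = FALSE) |>
      dplyr::group_by(.data$group) |>
      dplyr::mutate(pct = table_pct(.data$n, sum(.data$n))) |>
      dplyr::ungroup() |>
      dplyr::mutate(block = var, level = as.character(.data$level))
  }
  cont_block <- function(var) {
    members |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(
        mean = mean_sd_row(.data[[var]])[["mean"]],
        sd = mean_sd_row(.data[[var]])[["sd"]],
        n = sum(!is.na(.data[[var]])), .groups = "drop") |>
      dplyr::mutate(block = var, level = "mean_sd")
  }
  characteristics <- dplyr::bind_rows(
    members |> dplyr::count(.data$group, .drop = FALSE) |>
      dplyr::mutate(block = "n", level = "n"),
    cat_block("age_band"), cat_block("sex"), cat_block("income_band"),
    cat_block("residence"), cat_block("comorb_band_admin"),
    cat_block("comorb_band_emr"),
    cont_block("systolic_bp"), cont_block("diastolic_bp"), cont_block("bmi")
  )

  ## ---- next-year utilization --------------------------------------------
  uy <- index_year + 1
  ys <- year_start(uy); ye <- year_end(uy)
  # persons who died during the index year drop out of the denominators
  ut <- members[is.na(members$death_date) | members$death_date > year_end(index_year), ]

  count_in_year <- function(tbl, date_col, value = NULL, ids) {
    t2 <- tbl[tbl[[date_col]] >= ys & tbl[[date_col]] <= ye &
                tbl$person_id %in% ids, , drop = FALSE]
    agg <- if (is.null(value)) {
      stats::aggregate(list(x = rep(1, nrow(t2))),
                       by = list(person_id = t2$person_id), FUN = sum)
    } else {
      stats::aggregate(list(x = t2[[value]]),
                       by = list(person_id = t2$person_id), FUN = sum)
    }
    out <- setNames(rep(0, length(ids)), ids)
    if (nrow(t2) > 0) out[agg$person_id] <- agg$x
    unname(out)
  }
  emr_ids <- ut$emr_person_id
  adm_ids <- ut$admin_person_id
  gp_emr <- emr_bundle$claims[emr_bundle$claims$provider_type == "gp", ]
  ut$gp_contacts <- count_in_year(gp_emr, "service_date", NULL, emr_ids)
  adm_gp <- admin_bundle$claims[admin_bundle$claims$provider_type == "gp", ]
  adm_sp <- admin_bundle$claims[admin_bundle$claims$provider_type == "specialist", ]
  ut$cost_gp <- count_in_year(adm_gp, "service_date", "fee", adm_ids)
  ut$cost_specialist <- count_in_year(adm_sp, "service_date", "fee", adm_ids)
  ut$cost_physician <- ut$cost_gp + ut$cost_specialist
  ut$cost_hospital <- count_in_year(admin_bundle$hospitals, "admit_date",
                                    "cost", adm_ids)
  ut$n_hospitalizations <- count_in_year(admin_bundle$hospitals, "admit_date",
                                         NULL, adm_ids)
  hosp_uy <- admin_bundle$hospitals[admin_bundle$hospitals$admit_date <= ye &
                                      admin_bundle$hospitals$discharge_date >= ys, ]
  if (nrow(hosp_uy) > 0) {
    hosp_uy$days <- as.integer(pmin(hosp_uy$discharge_date, ye) -
                                 pmax(hosp_uy$admit_date, ys)) + 1L
  }
  ut$hospital_days <- count_in_year(
    if (nrow(hosp_uy) > 0) hosp_uy else cbind(hosp_uy, days = numeric(0)),
    "admit_date", "days", adm_ids)
  ut$cost_rx <- count_in_year(admin_bundle$prescriptions, "dispense_date",
                              "cost", adm_ids)
  poly <- polypharmacy_flag(admin_bundle$prescriptions, uy)
  ut$polypharmacy <- ut$admin_person_id %in% poly$person_id[poly$polypharmacy]
  ut$died <- !is.na(ut$death_date) & ut$death_date >= ys & ut$death_date <= ye

  util_cont <- function(var) {
    ut |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(mean = mean_sd_row(.data[[var]])[["mean"]],
                       sd = mean_sd_row(.data[[var]])[["sd"]],
                       n = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(block = var, level = "mean_sd")
  }
  util_flag <- function(var) {
    ut |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(n = sum(.data[[var]]),
                       pct = table_pct(sum(.data[[var]]), dplyr::n()),
                       .groups = "drop") |>
      dplyr::mutate(block = var, level = "n_pct")
  }
  per100 <- ut |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean = round_half_away(100 * mean(.data$n_hospitalizations), 1),
                     sd = round_half_away(100 * sd(.data$n_hospitalizations), 1),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(block = "hospitalizations_per_100", level = "mean_sd")
  utilization <- dplyr::bind_rows(
    ut |> dplyr::count(.data$group, .drop = FALSE) |>
      dplyr::mutate(block = "n", level = "n"),
    util_cont("gp_contacts"), util_cont("cost_gp"),
    util_cont("cost_specialist"), util_cont("cost_physician"),
    util_cont("cost_hospital"), per100, util_cont("cost_rx"),
    util_flag("polypharmacy"), util_cont("hospital_days"), util_flag("died")
  )
  structure(list(characteristics = characteristics, utilization = utilization,
                 index_year = index_year),
            class = "frail_summary")
}

#' @export
print.frail_summary <- function(x, ...) {
  cat(sprintf("<frail_summary> index year %d\n", x$index_year))
  cat("characteristics:\n"); print(x$characteristics, n = 20)
  cat("utilization (following year):\n"); print(x$utilization, n = 20)
  invisible(x)
}

#' Pearson chi-square statistic without continuity correction
#'
#' @param tab A contingency table or matrix of counts.
#' @return List with `statistic`, `df`, `p`, and `small_sample` (`TRUE`
#'   when any expected cell is below 1). A table with no variation has
#'   statistic 0 and p 1.
#' @export
chisq_nocorrect <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  keep_r <- rowSums(tab) > 0; keep_c <- colSums(tab) > 0
  tab2 <- tab[keep_r, keep_c, drop = FALSE]
  if (any(dim(tab2) < 2)) {
    return(list(statistic = 0, df = 0, p = 1, small_sample = FALSE))
  }
  exp2 <- outer(rowSums(tab2), colSums(tab2)) / sum(tab2)
  stat <- sum((tab2 - exp2)^2 / exp2)
  df <- (nrow(tab2) - 1) * (ncol(tab2) - 1)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE),
       small_sample = any(exp2 < 1))
}

welch_p <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2 ||
      (sd(x) == 0 && sd(y) == 0)) {
    if (length(x) > 0 && length(y) > 0 && isTRUE(sd(c(x, y)) == 0)) {
      warn("degenerate t-test: zero variance in both samples; p set to 1")
    }
    return(list(statistic = NA_real_, p = 1))
  }
  tt <- t.test(x, y, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p = tt$p.value)
}

#' Compare two frailty groups
#'
#' Pearson chi-square tests (no continuity correction) for the categorical
#' blocks and Welch two-sample t-tests for the continuous ones, comparing
#' two named groups (by convention the EMR-only and admin-only frail
#' groups). P-values are flagged at 0.05, 0.01 and 0.0001.
#'
#' @param groups Output of [assign_groups()].
#' @param members_data Tibble keyed by `scrambled_id` holding the variables
#'   to compare.
#' @param categorical,continuous Character vectors of column names.
#' @param group_a,group_b The two group labels to compare.
#' @return Tibble `variable`, `type`, `statistic`, `p`, `flag`,
#'   `small_sample`.
#' @export
compare_groups <- function(groups, members_data, categorical = character(),
                           continuous = character(),
                           group_a = "emr_only", group_b = "admin_only") {
  dat <- dplyr::left_join(members_data, groups, by = "scrambled_id")
  dat <- dat[dat$group %in% c(group_a, group_b), , drop = FALSE]
  dat$group <- droplevels(factor(dat$group, levels = c(group_a, group_b)))
  rows <- list()
  for (v in categorical) {
    tab <- table(dat$group, dat[[v]])
    cs <- chisq_nocorrect(tab)
    if (cs$small_sample) warn(sprintf("'%s': expected cell below 1", v))
    rows[[v]] <- tibble::tibble(variable = v, type = "categorical",
                                statistic = cs$statistic, p = cs$p,
                                small_sample = cs$small_sample)
  }
  for (v in continuous) {
    wt <- welch_p(dat[[v]][dat$group == group_a], dat[[v]][dat$group == group_b])
    rows[[v]] <- tibble::tibble(variable = v, type = "continuous",
                                statistic = wt$statistic, p = wt$p,
                                small_sample = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  out$flag <- dplyr::case_when(
    out$p < 0.0001 ~ "p<0.0001",
    out$p < 0.01 ~ "p<0.01",
    out$p < 0.05 ~ "p<0.05",
    .default = ""
  )
  out
}
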