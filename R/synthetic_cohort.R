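#' Synthetic linked-cohort generator
#'
#' Generates paired EMR and administrative [source bundles][source_bundle]
#' from a latent frailty model so the full pipeline (linkage, cohort,
#' case definitions, comorbidity, descriptives, CHAID learning) can be run
#' and validated without access to real health data.
#'
#' Each simulated person carries a latent frailty score on the 1-9 clinical
#' frailty continuum (1 = very fit, 9 = terminally ill), drawn from an
#' ordinal logistic model with age and sex effects whose intercept is
#' calibrated so that the fraction with score >= 5 (the clinical threshold
#' for frailty) matches `frail_fraction_target`. The latent class drives:
#' per-atom code emission (dementia coding, furosemide and vitamin
#' dispensations, "obstruction" free text, long-term-care entry,
#' terminal-illness coding, each modified-Edmonton-Frail-Scale domain, and
#' the eight tracked chronic conditions), negative-binomial GP contact
#' volumes (defaults 20 vs 10 contacts per year for frail vs non-frail),
#' hospitalizations, costs (gamma-distributed), and death in the year after
#' the index year via a logistic model increasing in the latent score.
#'
#' @name synthetic_cohort
NULL

# Emission atom vocabulary: P(atom fires | frail), P(atom fires | non-frail).
DEFAULT_EMISSIONS <- list(
  dementia_dx        = c(0.20, 0.03),
  furosemide_rx      = c(0.35, 0.08),
  vitamins_rx        = c(0.40, 0.20),
  obstruction_text   = c(0.06, 0.01),
  ltc_entry          = c(0.30, 0.01),
  terminal_dx        = c(0.10, 0.005),
  efs_cognition      = c(0.30, 0.04),
  efs_mood           = c(0.25, 0.08),
  efs_incontinence   = c(0.20, 0.04),
  efs_falls          = c(0.30, 0.05),
  efs_nutrition      = c(0.15, 0.02),
  efs_polypharmacy   = c(0.55, 0.20),
  efs_function       = c(0.25, 0.03),
  efs_social         = c(0.10, 0.02),
  cond_hypertension  = c(0.65, 0.50),
  cond_diabetes      = c(0.35, 0.22),
  cond_copd          = c(0.30, 0.12),
  cond_osteoarthritis = c(0.40, 0.25),
  cond_dementia      = c(0.35, 0.05),
  cond_depression    = c(0.25, 0.12),
  cond_epilepsy      = c(0.05, 0.02),
  cond_parkinsonism  = c(0.12, 0.02)
)

COND_NAMES <- c("hypertension", "diabetes", "copd", "osteoarthritis",
                "dementia", "depression", "epilepsy", "parkinsonism")

# ICD-9 claim codes / ICD-10-CA hospital codes emitted per condition.
COND_ICD9_EMIT <- list(
  hypertension = c("401.1", "401.9", "402.9"), diabetes = c("250.0", "250.2"),
  copd = c("491.2", "492.8", "496"), osteoarthritis = c("715.9", "715.3"),
  # 294/331 only: ICD-9 290 is reserved for the dementia-coding frailty atom
  # so that planted-rule emission probabilities stay exact
  dementia = c("294.1", "331.0"), depression = c("296.2", "311"),
  epilepsy = c("345.1", "345.9"), parkinsonism = c("332.0")
)
COND_ICD10_EMIT <- list(
  hypertension = c("I10", "I11.9"), diabetes = c("E11.9", "E11.5"),
  copd = c("J44.1", "J43.9"), osteoarthritis = c("M17.1", "M19.9"),
  dementia = c("F03", "G30.9"), depression = c("F32.9", "F33.1"),
  epilepsy = c("G40.9"), parkinsonism = c("G20")
)

EFS_ICD9_EMIT <- list(
  efs_cognition = c("290.0", "294.9", "331.0"),
  efs_mood = c("296.3", "300.0", "311"),
  efs_incontinence = c("788.3", "625.6"),
  efs_falls = c("E88.8", "E88.5", "719.7"),
  efs_nutrition = c("783.2", "783.7"),
  efs_function = c("V46.0", "V49.8"),
  efs_social = c("V60.4", "V60.9")
)

# ATC pool for ordinary (non-atom) medications; excludes A11* (vitamins)
# and C03CA01 (furosemide), which are emitted by their own atoms.
ATC_POOL <- c(
  "A02BC01", "A02BC02", "A10BA02", "A10BB01", "B01AA03", "B01AC06",
  "C01DA14", "C07AB02", "C07AB07", "C08CA01", "C09AA02", "C09AA05",
  "C10AA01", "C10AA05", "H03AA01", "J01CA04", "L04AX03", "M01AE01",
  "N02AA05", "N02BE01", "N03AX16", "N05BA06", "N05CF01", "R03AC02",
  "R03BB04", "S01EE01", "A06AD11", "A12AX", "C03DA01", "M04AA01"
)

#' Simulation configuration
#'
#' @param n_persons Number of EMR-source persons (>= 1).
#' @param index_year Index calendar year (default 2014); the study window
#'   runs from `index_year - 5` (EMR lookback) to `index_year + 1`
#'   (outcome year).
#' @param seed Integer seed; identical configurations generate identical
#'   bundles.
#' @param frail_fraction_target Target fraction with latent score >= 5
#'   (default 0.15).
#' @param unlinked_fraction Fraction of EMR persons absent from the
#'   administrative source (default 0.03, emulating a 97% deterministic
#'   linkage rate); an equal number of admin-only persons is added.
#' @param mean_gp_contacts_frail,mean_gp_contacts_nonfrail Mean annual GP
#'   contacts by latent class (defaults 20 and 10).
#' @param gp_dispersion Negative-binomial size parameter for contact counts.
#' @param mortality_logit_params Named vector `c(intercept=, slope=)` for
#'   P(death in `index_year + 1`) on the logit scale, linear in
#'   `latent_cfs - 5`.
#' @param emission_probabilities Named list of `c(p_frail, p_nonfrail)`
#'   per emission atom; defaults in `frailscan:::DEFAULT_EMISSIONS`.
#' @param coverage_gap_fraction Fraction of persons given a partial-year
#'   registry coverage episode (exercises the coverage exclusion).
#' @return A `sim_config` object (a validated list).
#' @export
sim_config <- function(n_persons,
                       index_year = 2014,
                       seed = 1L,
                       frail_fraction_target = 0.15,
                       unlinked_fraction = 0.03,
                       mean_gp_contacts_frail = 20,
                       mean_gp_contacts_nonfrail = 10,
                       gp_dispersion = 4,
                       mortality_logit_params = c(intercept = -3.0, slope = 0.6),
                       emission_probabilities = DEFAULT_EMISSIONS,
                       coverage_gap_fraction = 0.03) {
  if (n_persons < 1) abort("n_persons must be >= 1")
  if (frail_fraction_target <= 0 || frail_fraction_target >= 1) {
    abort("frail_fraction_target must be in (0, 1)")
  }
  if (unlinked_fraction < 0 || unlinked_fraction >= 1) {
    abort("unlinked_fraction must be in [0, 1)")
  }
  if (mean_gp_contacts_frail <= 0 || mean_gp_contacts_nonfrail <= 0) {
    abort("mean GP contact rates must be positive")
  }
  ep <- modifyList(DEFAULT_EMISSIONS, emission_probabilities)
  unknown <- setdiff(names(ep), names(DEFAULT_EMISSIONS))
  if (length(unknown) > 0) {
    abort(sprintf("unknown emission atom(s): %s", paste(unknown, collapse = ", ")))
  }
  for (nm in names(ep)) {
    if (any(ep[[nm]] < 0 | ep[[nm]] > 1)) {
      abort(sprintf("emission probabilities for '%s' must be in [0, 1]", nm))
    }
  }
  structure(list(
    n_persons = as.integer(n_persons), index_year = as.integer(index_year),
    seed = as.integer(seed), frail_fraction_target = frail_fraction_target,
    unlinked_fraction = unlinked_fraction,
    mean_gp_contacts_frail = mean_gp_contacts_frail,
    mean_gp_contacts_nonfrail = mean_gp_contacts_nonfrail,
    gp_dispersion = gp_dispersion,
    mortality_logit_params = mortality_logit_params,
    emission_probabilities = ep,
    coverage_gap_fraction = coverage_gap_fraction
  ), class = "sim_config")
}

#' Plant a recoverable rule into a simulation configuration
#'
#' Overrides the emission of the named atoms so that truly frail persons
#' satisfy the conjunction of `atoms` with probability `p_frail` and
#' non-frail persons with probability `p_nonfrail`, *exactly*. When the
#' conjunction does not fire, one randomly chosen atom is suppressed and
#' the rest still fire: each atom's marginal stays moderate-to-high in
#' both classes, so no single atom separates the classes on its own and a
#' learner must find the full conjunction (for a single atom the override
#' reduces to plain Bernoulli emission at the stated rates). Used to
#' verify that the CHAID learner recovers a known generating rule at the
#' planted depth.
#'
#' @param config A [sim_config()].
#' @param atoms Character vector of emission atom names (a conjunction);
#'   empty leaves the configuration unchanged.
#' @param p_frail,p_nonfrail Target satisfaction probabilities by class.
#' @return A modified `sim_config`.
#' @export
plant_rule <- function(config, atoms, p_frail = 0.9, p_nonfrail = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  if (length(atoms) == 0) return(config)
  unknown <- setdiff(atoms, names(config$emission_probabilities))
  if (length(unknown) > 0) {
    abort(sprintf("atom(s) not in emission vocabulary: %s",
                  paste(unknown, collapse = ", ")))
  }
  config$planted_rule <- list(atoms = atoms, p_frail = p_frail,
                              p_nonfrail = p_nonfrail)
  config
}

rdate_between <- function(n, from, to) {
  from <- as.Date(from); to <- as.Date(to)
  from + floor(runif(n) * (as.integer(to) - as.integer(from) + 1))
}

# Ordinal thresholds between adjacent frailty levels 1..9 on the latent
# logistic scale; frailty (score >= 5) corresponds to crossing CFS_CUTS[4].
CFS_CUTS <- c(-2.2, -1.2, -0.4, 0.4, 1.2, 2.0, 2.8, 3.6)

calibrate_cfs_intercept <- function(eta, target) {
  f <- function(delta) mean(plogis(eta + delta - CFS_CUTS[4])) - target
  sol <- tryCatch(uniroot(f, c(-30, 30), tol = 1e-10), error = function(e) NULL)
  if (is.null(sol)) {
    abort(sprintf("calibration error: frail fraction target %.3f unreachable",
                  target))
  }
  sol$root
}

#' Generate paired EMR and administrative bundles with ground truth
#'
#' @param config A [sim_config()].
#' @return A list with elements `emr` (a `frail_bundle`), `admin` (a
#'   `frail_bundle`) and `truth` (a tibble with `person_id`, `phn`,
#'   `latent_cfs`, `truly_frail`, one `cond_*` flag per tracked condition,
#'   `died_index_year`, `died_next_year`, and each emission atom's fired
#'   flag).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  iy <- config$index_year
  jan1 <- year_start(iy)
  n_emr <- config$n_persons
  n_unl <- round(config$unlinked_fraction * n_emr)
  n_tot <- n_emr + n_unl

  ## --- persons -----------------------------------------------------------
  person_id <- sprintf("P%06d", seq_len(n_tot))
  phn <- sprintf("9%08d", sample.int(89999999, n_tot))
  age <- pmin(65L + stats::rgeom(n_tot, 0.11), 102L)
  birth_date <- year_start(iy - age) - sample.int(365, n_tot, replace = TRUE) + 1L
  sex <- ifelse(runif(n_tot) < 0.55, "female", "male")
  rural <- runif(n_tot) < 0.30
  postal_code <- paste0(
    sample(LETTERS[1:18], n_tot, replace = TRUE),
    ifelse(rural, "0", as.character(sample.int(9, n_tot, replace = TRUE))),
    sample(LETTERS, n_tot, replace = TRUE),
    sample(0:9, n_tot, replace = TRUE),
    sample(LETTERS, n_tot, replace = TRUE),
    sample(0:9, n_tot, replace = TRUE)
  )
  income_quintile <- sample.int(5, n_tot, replace = TRUE)

  ## --- latent frailty ----------------------------------------------------
  eta <- 0.8 * (age - 75) / 10 + 0.15 * (sex == "female")
  delta <- calibrate_cfs_intercept(eta, config$frail_fraction_target)
  z <- eta + delta + stats::rlogis(n_tot)
  latent_cfs <- as.integer(findInterval(z, CFS_CUTS) + 1L)
  frail <- latent_cfs >= 5L

  ## --- atom and condition emission ---------------------------------------
  ep <- config$emission_probabilities
  fired <- lapply(ep, function(p) {
    runif(n_tot) < ifelse(frail, p[1], p[2])
  })
  names(fired) <- names(ep)
  pr <- config$planted_rule
  if (!is.null(pr)) {
    k <- length(pr$atoms)
    conj <- runif(n_tot) < ifelse(frail, pr$p_frail, pr$p_nonfrail)
    suppress <- sample.int(k, n_tot, replace = TRUE)
    for (j in seq_len(k)) {
      fired[[pr$atoms[j]]] <- conj | (suppress != j)
    }
  }
  cond_flags <- fired[paste0("cond_", COND_NAMES)]

  ## --- deaths ------------------------------------------------------------
  mp <- config$mortality_logit_params
  p_death <- plogis(mp[["intercept"]] + mp[["slope"]] * (latent_cfs - 5))
  died_index <- runif(n_tot) < 0.5 * p_death
  died_next <- !died_index & (runif(n_tot) < p_death)
  death_date <- as.Date(rep(NA, n_tot))
  death_date[died_index] <- rdate_between(sum(died_index), jan1, year_end(iy))
  death_date[died_next] <- rdate_between(sum(died_next), year_start(iy + 1),
                                         year_end(iy + 1))

  ## --- registry coverage -------------------------------------------------
  cov_start <- rep(year_start(iy - 5), n_tot)
  cov_end <- rep(year_end(iy + 1), n_tot)
  gap <- runif(n_tot) < config$coverage_gap_fraction
  cov_start[gap] <- rdate_between(sum(gap), jan1, year_end(iy))
  cov_end <- pmin(cov_end, dplyr::coalesce(death_date, cov_end))
  cov_start <- pmin(cov_start, cov_end)
  coverage <- sprintf("%s..%s", format(cov_start), format(cov_end))

  persons <- tibble::tibble(
    person_id = person_id, phn = phn, birth_date = birth_date, sex = sex,
    death_date = death_date, income_quintile = income_quintile,
    postal_code = postal_code, coverage = coverage
  )

  ## --- event emission ----------------------------------------------------
  gp_mu <- ifelse(frail, config$mean_gp_contacts_frail,
                  config$mean_gp_contacts_nonfrail)
  emit_visits <- function(year) {
    cnt <- rnbinom(n_tot, size = config$gp_dispersion, mu = gp_mu)
    idx <- rep(seq_len(n_tot), cnt)
    tibble::tibble(
      person_id = person_id[idx],
      service_date = rdate_between(length(idx), year_start(year), year_end(year)),
      icd9_code = "", free_text = "",
      provider_type = "gp", fee = round(rgamma(length(idx), 2, scale = 25), 2)
    )
  }
  gp_visits <- dplyr::bind_rows(lapply((iy - 1):(iy + 1), emit_visits))

  emit_atom_claims <- function(atom, codes, text = "") {
    idx <- which(fired[[atom]])
    if (length(idx) == 0) return(NULL)
    tibble::tibble(
      person_id = person_id[idx],
      service_date = rdate_between(length(idx), year_start(iy - 2), year_end(iy)),
      icd9_code = if (is.null(codes)) "" else
        sample(codes, length(idx), replace = TRUE),
      free_text = text, provider_type = "gp",
      fee = round(rgamma(length(idx), 2, scale = 25), 2)
    )
  }
  emr_atom_claims <- dplyr::bind_rows(
    emit_atom_claims("dementia_dx", c("290.0", "290.4")),
    emit_atom_claims("obstruction_text", NULL, "bowel obstruction noted")
  )
  # decoy text that must NOT fire whole-token keyword matching
  decoy_idx <- which(runif(n_tot) < 0.02)
  decoys <- tibble::tibble(
    person_id = person_id[decoy_idx],
    service_date = rdate_between(length(decoy_idx), year_start(iy - 1), year_end(iy)),
    icd9_code = "", free_text = "obstructive sleep apnea",
    provider_type = "gp", fee = round(rgamma(length(decoy_idx), 2, scale = 25), 2)
  )

  # chronic-condition claim pairs (detected per source independently)
  emit_cond_claims <- function(cond, p_detect, depression_gap = 200) {
    flag <- cond_flags[[paste0("cond_", cond)]]
    idx <- which(flag & runif(n_tot) < p_detect)
    if (length(idx) == 0) return(NULL)
    gapmax <- if (cond == "depression") depression_gap else 600
    d1 <- rdate_between(length(idx), year_start(iy - 5), year_end(iy) - gapmax - 1)
    gap_days <- floor(runif(length(idx)) * gapmax)
    codes <- COND_ICD9_EMIT[[cond]]
    tibble::tibble(
      person_id = rep(person_id[idx], 2),
      service_date = c(d1, d1 + gap_days),
      icd9_code = sample(codes, 2 * length(idx), replace = TRUE),
      free_text = "", provider_type = "gp",
      fee = round(rgamma(2 * length(idx), 2, scale = 25), 2)
    )
  }
  emr_cond_claims <- dplyr::bind_rows(
    lapply(COND_NAMES, emit_cond_claims, p_detect = 0.80))
  admin_cond_claims <- dplyr::bind_rows(
    lapply(COND_NAMES, emit_cond_claims, p_detect = 0.85))

  # modified-EFS domain claims and terminal-illness coding (admin billing)
  efs_claims <- dplyr::bind_rows(lapply(names(EFS_ICD9_EMIT), function(atom) {
    emit_atom_claims(atom, EFS_ICD9_EMIT[[atom]])
  }))
  if (nrow(efs_claims) > 0) {
    # EFS indices are assessed in the index year only
    efs_claims$service_date <- rdate_between(nrow(efs_claims), jan1, year_end(iy))
  }
  terminal_claims <- emit_atom_claims("terminal_dx", c("V66.7"))
  if (!is.null(terminal_claims) && nrow(terminal_claims) > 0) {
    terminal_claims$service_date <-
      rdate_between(nrow(terminal_claims), jan1, year_end(iy))
  }

  emit_specialist <- function(year) {
    cnt <- rnbinom(n_tot, size = 2, mu = ifelse(frail, 4, 2))
    idx <- rep(seq_len(n_tot), cnt)
    tibble::tibble(
      person_id = person_id[idx],
      service_date = rdate_between(length(idx), year_start(year), year_end(year)),
      icd9_code = "", free_text = "",
      provider_type = "specialist", fee = round(rgamma(length(idx), 2, scale = 60), 2)
    )
  }
  admin_visits <- dplyr::bind_rows(lapply((iy - 1):(iy + 1), emit_visits))
  specialist_claims <- dplyr::bind_rows(lapply(iy:(iy + 1), emit_specialist))

  ## --- hospitals (admin only) --------------------------------------------
  emit_hospital <- function(year) {
    cnt <- rpois(n_tot, ifelse(frail, 0.5, 0.15))
    idx <- rep(seq_len(n_tot), cnt)
    if (length(idx) == 0) return(NULL)
    admit <- rdate_between(length(idx), year_start(year), year_end(year))
    los <- 1 + rpois(length(idx), ifelse(frail[idx], 7, 3))
    codes <- vapply(idx, function(i) {
      has <- COND_NAMES[vapply(COND_NAMES, function(cn)
        cond_flags[[paste0("cond_", cn)]][i], logical(1))]
      if (length(has) == 0) return("R54")
      sample(COND_ICD10_EMIT[[sample(has, 1)]], 1)
    }, character(1))
    tibble::tibble(
      person_id = person_id[idx], admit_date = admit,
      discharge_date = admit + los, icd10_codes = codes,
      cost = round(rgamma(length(idx), 1.5,
                          scale = ifelse(frail[idx], 6000, 4000)), 2)
    )
  }
  hospitals <- dplyr::bind_rows(lapply(iy:(iy + 1), emit_hospital))
  term_hosp_idx <- which(fired$terminal_dx & runif(n_tot) < 0.5)
  if (length(term_hosp_idx) > 0) {
    admit <- rdate_between(length(term_hosp_idx), jan1, year_end(iy))
    hospitals <- dplyr::bind_rows(hospitals, tibble::tibble(
      person_id = person_id[term_hosp_idx], admit_date = admit,
      discharge_date = admit + 1 + rpois(length(term_hosp_idx), 10),
      icd10_codes = "Z51.5",
      cost = round(rgamma(length(term_hosp_idx), 1.5, scale = 8000), 2)
    ))
  }

  ## --- prescriptions -----------------------------------------------------
  n_drugs <- ifelse(fired$efs_polypharmacy,
                    sample(6:10, n_tot, replace = TRUE),
                    sample(0:5, n_tot, replace = TRUE))
  drug_rows <- rep(seq_len(n_tot), n_drugs)
  drug_atc <- unlist(lapply(seq_len(n_tot), function(i) {
    if (n_drugs[i] == 0) return(character(0))
    sample(ATC_POOL, n_drugs[i])
  }))
  emit_rx <- function(idx, atc, years, src) {
    per_year <- lapply(years, function(yr) {
      tibble::tibble(
        person_id = person_id[idx],
        dispense_date = rdate_between(length(idx), year_start(yr), year_end(yr)),
        atc_code = atc, source = src,
        cost = round(rgamma(length(idx), 2, scale = 20), 2)
      )
    })
    dplyr::bind_rows(per_year)
  }
  admin_rx <- emit_rx(drug_rows, drug_atc, iy:(iy + 1), "admin")
  emr_keep <- runif(length(drug_rows)) < 0.7
  emr_rx <- emit_rx(drug_rows[emr_keep], drug_atc[emr_keep], iy, "emr")
  vit_idx <- which(fired$vitamins_rx)
  fur_idx <- which(fired$furosemide_rx)
  atom_rx <- dplyr::bind_rows(
    emit_rx(vit_idx, sample(c("A11GA01", "A11CC05", "A11DA01"),
                            length(vit_idx), replace = TRUE), iy, "emr"),
    emit_rx(fur_idx, rep("C03CA01", length(fur_idx)), iy, "emr")
  )
  atom_rx_admin <- atom_rx
  if (nrow(atom_rx_admin) > 0) atom_rx_admin$source <- "admin"
  # antidepressant treatment evidence for persisting depression
  dep_idx <- which(cond_flags$cond_depression & runif(n_tot) < 0.75)
  dep_rx <- emit_rx(dep_idx, sample(c("N06AB04", "N06AB06", "N06AX11"),
                                    length(dep_idx), replace = TRUE), iy, "emr")
  dep_rx_admin <- dep_rx
  if (nrow(dep_rx_admin) > 0) dep_rx_admin$source <- "admin"
  # atom_rx / dep_rx are merged below, after death-date clamping

  ## --- LTC episodes (admin only) -----------------------------------------
  ltc_idx <- which(fired$ltc_entry)
  ltc <- tibble::tibble(
    person_id = person_id[ltc_idx],
    start_date = rdate_between(length(ltc_idx), year_start(iy - 1), year_end(iy)),
    end_date = as.Date(rep(NA, length(ltc_idx))),
    setting = sample(c("long_term_care", "assisted_living"), length(ltc_idx),
                     replace = TRUE, prob = c(0.8, 0.2))
  )
  closed <- runif(length(ltc_idx)) < 0.3
  ltc$end_date[closed] <- ltc$start_date[closed] + rpois(sum(closed), 200)

  ## --- observations (EMR only) -------------------------------------------
  n_bp <- sample(0:5, n_tot, replace = TRUE,
                 prob = c(0.05, 0.05, 0.1, 0.3, 0.3, 0.2))
  bp_rows <- rep(seq_len(n_tot), n_bp)
  sys_mu <- ifelse(frail[bp_rows], 125, 132)
  obs <- tibble::tibble(
    person_id = rep(person_id[bp_rows], 2),
    obs_date = rep(rdate_between(length(bp_rows), year_start(iy - 1),
                                 year_end(iy)), 2),
    kind = rep(c("systolic_bp", "diastolic_bp"), each = length(bp_rows)),
    value = round(c(pmin(pmax(stats::rnorm(length(bp_rows), sys_mu, 16), 60), 280),
                    pmin(pmax(stats::rnorm(length(bp_rows), 71, 8), 30), 190)), 1)
  )
  bmi_idx <- which(runif(n_tot) < 0.8)
  obs <- dplyr::bind_rows(obs, tibble::tibble(
    person_id = person_id[bmi_idx],
    obs_date = rdate_between(length(bmi_idx), year_start(iy - 1), year_end(iy)),
    kind = "bmi",
    value = round(pmin(pmax(stats::rnorm(length(bmi_idx), 27.5, 4.5), 12), 60), 1)
  ))

  ## --- source membership and post-death filtering -------------------------
  is_extra <- seq_len(n_tot) > n_emr
  unlinked_emr <- rep(FALSE, n_tot)
  if (n_unl > 0) unlinked_emr[sample(n_emr, n_unl)] <- TRUE
  emr_ids <- person_id[!is_extra]
  admin_ids <- person_id[(!is_extra & !unlinked_emr) | is_extra]

  death_lookup <- setNames(death_date, person_id)
  drop_after_death <- function(x, date_col) {
    if (is.null(x) || nrow(x) == 0) return(x)
    dd <- death_lookup[x$person_id]
    x[is.na(dd) | x[[date_col]] <= dd, ]
  }
  # atom emissions are guarantees ("the code appears in the record"), so
  # their dates clamp to the death date instead of being censored
  clamp_at_death <- function(x, date_col) {
    if (is.null(x) || nrow(x) == 0) return(x)
    dd <- death_lookup[x$person_id]
    x[[date_col]] <- as.Date(pmin(as.integer(x[[date_col]]),
                                  as.integer(dplyr::coalesce(dd, as.Date("9999-12-31")))),
                             origin = "1970-01-01")
    x
  }
  emr_atom_claims <- clamp_at_death(emr_atom_claims, "service_date")
  efs_claims <- clamp_at_death(efs_claims, "service_date")
  terminal_claims <- clamp_at_death(terminal_claims, "service_date")
  atom_rx <- clamp_at_death(atom_rx, "dispense_date")
  atom_rx_admin <- clamp_at_death(atom_rx_admin, "dispense_date")
  ltc <- clamp_at_death(ltc, "start_date")
  emr_rx <- dplyr::bind_rows(emr_rx, atom_rx,
                             clamp_at_death(dep_rx, "dispense_date"))
  admin_rx <- dplyr::bind_rows(admin_rx, atom_rx_admin,
                               clamp_at_death(dep_rx_admin, "dispense_date"))
  restrict <- function(x, ids, date_col) {
    if (is.null(x)) x <- tibble::tibble()
    if (nrow(x) == 0) return(x)
    drop_after_death(x[x$person_id %in% ids, ], date_col)
  }

  emr_claims <- dplyr::bind_rows(gp_visits, emr_atom_claims, decoys,
                                 emr_cond_claims)
  admin_claims <- dplyr::bind_rows(admin_visits, specialist_claims,
                                   admin_cond_claims, efs_claims,
                                   terminal_claims)

  emr_persons <- persons[!is_extra, ]
  admin_persons <- persons[persons$person_id %in% admin_ids, ]

  emr <- bundle("emr",
    persons = emr_persons,
    claims = restrict(emr_claims, emr_ids, "service_date"),
    prescriptions = restrict(emr_rx, emr_ids, "dispense_date"),
    observations = restrict(obs, emr_ids, "obs_date")
  )
  admin <- bundle("admin",
    persons = admin_persons,
    claims = restrict(admin_claims, admin_ids, "service_date"),
    hospitals = restrict(hospitals, admin_ids, "admit_date"),
    prescriptions = restrict(admin_rx, admin_ids, "dispense_date"),
    ltc = restrict(ltc, admin_ids, "start_date")
  )

  truth <- tibble::tibble(
    person_id = person_id, phn = phn, latent_cfs = latent_cfs,
    truly_frail = frail, in_emr = !is_extra, in_admin = person_id %in% admin_ids,
    died_index_year = died_index, died_next_year = died_next
  )
  for (cn in COND_NAMES) truth[[paste0("cond_", cn)]] <- cond_flags[[paste0("cond_", cn)]]
  for (a in setdiff(names(fired), paste0("cond_", COND_NAMES))) {
    truth[[paste0("atom_", a)]] <- fired[[a]]
  }

  list(emr = emr, admin = admin, truth = truth)
}
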