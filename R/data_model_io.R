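#' Source bundles: the flat-file data model
#'
#' A *source bundle* holds the six tables extracted from one data source
#' (primary-care EMR or provincial administrative holdings): persons,
#' physician billing claims, hospital discharge abstracts, prescription
#' dispensations, long-term-care/assisted-living episodes, and
#' blood-pressure/BMI observations. All downstream modules (linkage, cohort
#' construction, frailty classification, comorbidity, descriptives) consume
#' bundles.
#'
#' Tables are tibbles with fixed schemas:
#' * `persons`: `person_id`, `phn`, `birth_date`, `sex` (`female`/`male`),
#'   `death_date` (optional), `income_quintile` (1-5), `postal_code`
#'   (6-character Canadian), `coverage` (registry coverage episodes encoded
#'   `"start..end;start..end"`, closed date intervals)
#' * `claims`: `person_id`, `service_date`, `icd9_code` (possibly empty),
#'   `free_text` (possibly empty), `provider_type` (`gp`/`specialist`), `fee`
#' * `hospitals`: `person_id`, `admit_date`, `discharge_date`, `icd10_codes`
#'   (`;`-separated ICD-10-CA list, at least one), `cost`
#' * `prescriptions`: `person_id`, `dispense_date`, `atc_code`,
#'   `source` (`emr`/`admin`), `cost`
#' * `ltc`: `person_id`, `start_date`, `end_date` (empty = ongoing),
#'   `setting` (`long_term_care`/`assisted_living`)
#' * `observations`: `person_id`, `obs_date`, `kind`
#'   (`systolic_bp`/`diastolic_bp`/`bmi`), `value`
#'
#' @name source_bundle
NULL

BUNDLE_TABLES <- c("persons", "claims", "hospitals", "prescriptions", "ltc",
                   "observations")

BUNDLE_SCHEMAS <- list(
  persons = c(person_id = "c", phn = "c", birth_date = "D", sex = "c",
              death_date = "D", income_quintile = "i", postal_code = "c",
              coverage = "c"),
  claims = c(person_id = "c", service_date = "D", icd9_code = "c",
             free_text = "c", provider_type = "c", fee = "d"),
  hospitals = c(person_id = "c", admit_date = "D", discharge_date = "D",
                icd10_codes = "c", cost = "d"),
  prescriptions = c(person_id = "c", dispense_date = "D", atc_code = "c",
                    source = "c", cost = "d"),
  ltc = c(person_id = "c", start_date = "D", end_date = "D", setting = "c"),
  observations = c(person_id = "c", obs_date = "D", kind = "c", value = "d")
)

ICD9_REGEX <- "^[EV0-9][0-9]{2}(\\.[0-9]{1,2})?$"
ATC_REGEX <- "^[A-V]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$"
POSTAL_REGEX <- "^[A-Za-z][0-9][A-Za-z][0-9][A-Za-z][0-9]$"

empty_bundle_table <- function(table) {
  schema <- BUNDLE_SCHEMAS[[table]]
  cols <- lapply(schema, function(tp) {
    switch(tp, c = character(), D = as.Date(character()), i = integer(),
           d = numeric())
  })
  tibble::as_tibble(cols)
}

#' Construct and validate a source bundle
#'
#' Missing tables default to empty; all type invariants are enforced and
#' tables are canonically sorted (every column, left to right) so that two
#' bundles with the same rows compare equal and serialize identically.
#'
#' @param source `"emr"` or `"admin"`.
#' @param persons,claims,hospitals,prescriptions,ltc,observations Data frames
#'   following the schemas in [source_bundle].
#' @return An object of class `frail_bundle`.
#' @export
bundle <- function(source, persons = NULL, claims = NULL, hospitals = NULL,
                   prescriptions = NULL, ltc = NULL, observations = NULL) {
  source <- match.arg(source, c("emr", "admin"))
  tables <- list(persons = persons, claims = claims, hospitals = hospitals,
                 prescriptions = prescriptions, ltc = ltc,
                 observations = observations)
  tables <- lapply(BUNDLE_TABLES, function(tb) {
    x <- tables[[tb]]
    if (is.null(x) || (is.data.frame(x) && ncol(x) == 0)) {
      return(empty_bundle_table(tb))
    }
    coerce_bundle_table(x, tb)
  })
  names(tables) <- BUNDLE_TABLES
  b <- structure(c(list(source = source), tables), class = "frail_bundle")
  validate_bundle(b)
}

coerce_bundle_table <- function(x, table) {
  schema <- BUNDLE_SCHEMAS[[table]]
  missing <- setdiff(names(schema), names(x))
  if (length(missing) > 0) {
    abort(sprintf("table '%s': missing column(s) %s", table,
                  paste(missing, collapse = ", ")))
  }
  x <- tibble::as_tibble(x)[names(schema)]
  for (col in names(schema)) {
    x[[col]] <- switch(
      schema[[col]],
      c = { v <- as.character(x[[col]]); v[is.na(v)] <- ""; v },
      D = as_date_safe(x[[col]], col, table),
      i = as.integer(x[[col]]),
      d = as.numeric(x[[col]])
    )
  }
  dplyr::arrange(x, dplyr::across(dplyr::everything()))
}

fail_rows <- function(table, field, bad, msg) {
  if (length(bad) == 0) return(invisible(NULL))
  abort(sprintf("table '%s': %s in field '%s' at row(s) %s", table, msg, field,
                paste(head(bad, 5), collapse = ", ")))
}

validate_bundle <- function(b) {
  p <- b$persons
  fail_rows("persons", "person_id", which(duplicated(p$person_id)),
            "duplicate person_id")
  fail_rows("persons", "sex", which(!p$sex %in% c("female", "male")),
            "invalid sex")
  fail_rows("persons", "income_quintile",
            which(!p$income_quintile %in% 1:5), "income quintile not in 1..5")
  fail_rows("persons", "postal_code", which(!grepl(POSTAL_REGEX, p$postal_code)),
            "malformed postal code")
  fail_rows("persons", "death_date",
            which(!is.na(p$death_date) & p$death_date <= p$birth_date),
            "death_date not after birth_date")
  # coverage episode strings parse and each interval is well-formed
  # (vectorized; overlap needs no check — normalization merges at parse time)
  nonempty <- which(p$coverage != "")
  if (length(nonempty) > 0) {
    sp <- strsplit(p$coverage[nonempty], ";", fixed = TRUE)
    row_of <- rep(nonempty, lengths(sp))
    pieces <- strsplit(unlist(sp), "..", fixed = TRUE)
    fail_rows("persons", "coverage",
              unique(row_of[lengths(pieces) != 2]),
              "malformed coverage episode")
    starts <- as_date_safe(vapply(pieces, `[`, "", 1), "coverage", "persons")
    ends <- as_date_safe(vapply(pieces, `[`, "", 2), "coverage", "persons")
    fail_rows("persons", "coverage",
              unique(row_of[is.na(starts) | is.na(ends) | starts > ends]),
              "coverage episode with start after end")
  }

  cl <- b$claims
  bad_icd9 <- which(cl$icd9_code != "" & !grepl(ICD9_REGEX, cl$icd9_code))
  fail_rows("claims", "icd9_code", bad_icd9, "invalid ICD-9 code")
  fail_rows("claims", "provider_type",
            which(!cl$provider_type %in% c("gp", "specialist")),
            "invalid provider_type")
  fail_rows("claims", "fee", which(cl$fee < 0), "negative fee")

  h <- b$hospitals
  fail_rows("hospitals", "discharge_date",
            which(h$admit_date > h$discharge_date),
            "admit_date after discharge_date")
  fail_rows("hospitals", "icd10_codes",
            which(trimws(h$icd10_codes) == ""), "at least one diagnosis required")
  fail_rows("hospitals", "cost", which(h$cost < 0), "negative cost")

  rx <- b$prescriptions
  fail_rows("prescriptions", "atc_code", which(!grepl(ATC_REGEX, rx$atc_code)),
            "invalid ATC code")
  fail_rows("prescriptions", "source", which(!rx$source %in% c("emr", "admin")),
            "invalid source")
  fail_rows("prescriptions", "cost", which(rx$cost < 0), "negative cost")

  lt <- b$ltc
  fail_rows("ltc", "end_date",
            which(!is.na(lt$end_date) & lt$start_date > lt$end_date),
            "start_date after end_date")
  fail_rows("ltc", "setting",
            which(!lt$setting %in% c("long_term_care", "assisted_living")),
            "invalid setting")

  ob <- b$observations
  fail_rows("observations", "kind",
            which(!ob$kind %in% c("systolic_bp", "diastolic_bp", "bmi")),
            "invalid kind")
  lo <- c(systolic_bp = 50, diastolic_bp = 20, bmi = 8)
  hi <- c(systolic_bp = 300, diastolic_bp = 200, bmi = 100)
  in_range <- ob$value >= lo[ob$kind] & ob$value <= hi[ob$kind]
  fail_rows("observations", "value", which(!in_range), "value out of range")

  ids <- p$person_id
  for (tb in setdiff(BUNDLE_TABLES, "persons")) {
    orphan <- which(!b[[tb]]$person_id %in% ids)
    fail_rows(tb, "person_id", orphan, "person_id not present in persons")
  }
  b
}

#' @export
print.frail_bundle <- function(x, ...) {
  cat(sprintf("<frail_bundle> source: %s\n", x$source))
  for (tb in BUNDLE_TABLES) {
    cat(sprintf("  %-13s %6d rows\n", tb, nrow(x[[tb]])))
  }
  invisible(x)
}

episode_frame <- function(start, end) {
  structure(list(start = start, end = end), class = "data.frame",
            row.names = c(NA_integer_, -length(start)))
}

# Parse "start..end;start..end" coverage episodes into normalized
# (merged, sorted) closed intervals. Plain data.frame: this sits on the
# per-person hot path.
parse_coverage <- function(string, row = NA) {
  if (is.na(string) || string == "") {
    return(episode_frame(as.Date(character()), as.Date(character())))
  }
  parts <- strsplit(string, ";", fixed = TRUE)[[1]]
  pieces <- strsplit(parts, "..", fixed = TRUE)
  if (any(lengths(pieces) != 2)) {
    abort(sprintf("persons: malformed coverage episode string at row %s", row))
  }
  start <- as_date_safe(vapply(pieces, `[`, "", 1), "coverage", "persons")
  end <- as_date_safe(vapply(pieces, `[`, "", 2), "coverage", "persons")
  if (any(start > end)) {
    abort(sprintf("persons: coverage episode with start after end at row %s", row))
  }
  normalize_episodes(episode_frame(start, end))
}

# Merge overlapping or day-adjacent closed intervals.
normalize_episodes <- function(eps) {
  if (nrow(eps) <= 1) return(episode_frame(eps$start, eps$end))
  ord <- order(eps$start, eps$end)
  s <- as.integer(eps$start)[ord]
  e <- as.integer(eps$end)[ord]
  out_s <- s[1]; out_e <- e[1]; k <- 1L
  for (i in seq_along(s)[-1]) {
    if (s[i] <= out_e[k] + 1L) {
      out_e[k] <- max(out_e[k], e[i])
    } else {
      k <- k + 1L
      out_s[k] <- s[i]
      out_e[k] <- e[i]
    }
  }
  episode_frame(as.Date(out_s, origin = "1970-01-01"),
                as.Date(out_e, origin = "1970-01-01"))
}

format_coverage <- function(eps) {
  if (nrow(eps) == 0) return("")
  paste(sprintf("%s..%s", format(eps$start), format(eps$end)), collapse = ";")
}

#' Read a source bundle from a directory of CSV files
#'
#' Expects `persons.csv`, `claims.csv`, `hospitals.csv`, `prescriptions.csv`,
#' `ltc.csv` and `observations.csv` with the documented headers. Dates are
#' ISO-8601; empty strings mark absent optional values. All invariants are
#' enforced; a violation is an error naming the table, field and row.
#'
#' @param dir Directory containing the six CSV files.
#' @param source `"emr"` or `"admin"`.
#' @return A validated `frail_bundle`.
#' @export
read_bundle <- function(dir, source) {
  files <- file.path(dir, paste0(BUNDLE_TABLES, ".csv"))
  missing <- BUNDLE_TABLES[!file.exists(files)]
  if (length(missing) > 0) {
    abort(sprintf("missing table file(s) in '%s': %s", dir,
                  paste0(missing, ".csv", collapse = ", ")))
  }
  tables <- lapply(BUNDLE_TABLES, function(tb) {
    schema <- BUNDLE_SCHEMAS[[tb]]
    types <- paste(vapply(schema, function(tp) if (tp == "D") "c" else tp, ""),
                   collapse = "")
    readr::read_csv(file.path(dir, paste0(tb, ".csv")), col_types = types,
                    na = character(), progress = FALSE)
  })
  names(tables) <- BUNDLE_TABLES
  do.call(bundle, c(list(source = source), tables))
}

#' Write a source bundle to a directory of CSV files
#'
#' One CSV per table, deterministic column order and canonical row sort,
#' ISO-8601 dates, UTF-8, LF line endings. `read_bundle(write_bundle(b))`
#' round-trips byte-identically.
#'
#' @param b A `frail_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_bundle <- function(b, dir) {
  stopifnot(inherits(b, "frail_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("cannot create output directory '%s'", dir))
  files <- character(0)
  for (tb in BUNDLE_TABLES) {
    x <- b[[tb]]
    for (col in names(x)) {
      if (inherits(x[[col]], "Date")) x[[col]] <- format(x[[col]], "%Y-%m-%d")
    }
    path <- file.path(dir, paste0(tb, ".csv"))
    readr::write_csv(x, path, na = "", eol = "\n", progress = FALSE)
    files <- c(files, path)
  }
  invisible(files)
}

#' Test two bundles for equality of contents
#' @param a,b Bundles to compare.
#' @return `TRUE` if same source and identical tables after canonical sort.
#' @export
bundles_equal <- function(a, b) {
  if (!identical(a$source, b$source)) return(FALSE)
  all(vapply(BUNDLE_TABLES, function(tb) {
    isTRUE(all.equal(as.data.frame(a[[tb]]), as.data.frame(b[[tb]]),
                     check.attributes = FALSE))
  }, logical(1)))
}
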