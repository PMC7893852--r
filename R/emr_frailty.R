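#' EMR frailty case definition
#'
#' The EMR case definition is a configurable boolean rule over named
#' *atoms*, each one of:
#' * `icd9_prefix`: any billing claim whose ICD-9 code starts with one of
#'   the listed prefixes (dot-insensitive, so `"290"` matches `"290.0"`),
#' * `atc_prefix`: any dispensation whose ATC code starts with one of the
#'   listed prefixes,
#' * `text_keyword`: any claim whose free text contains one of the listed
#'   words as a whole token, case-insensitively (`"obstruction"` matches
#'   `"bowel OBSTRUCTION f/u"` but not `"obstructive"`).
#'
#' Only events inside the lookback window (`lookback_years` calendar years
#' ending December 31 of the index year, default 6) count. The shipped
#' default definition — dementia coding (ICD-9 290) OR (vitamin AND
#' furosemide prescriptions) OR the "obstruction" keyword — is a documented
#' reconstruction of a validated screening definition whose exact boolean
#' structure is unpublished; every atom and the expression are overridable
#' via a JSON rule file.
#'
#' @name emr_frailty
NULL

ATOM_KINDS <- c("icd9_prefix", "atc_prefix", "text_keyword")

#' Define a frailty case definition
#'
#' @param atoms Named list; each element `list(kind = , values = )` with
#'   `kind` one of `"icd9_prefix"`, `"atc_prefix"`, `"text_keyword"`.
#' @param expression Nested boolean expression over atom names:
#'   an atom name, or `list("and"/"or"/"not", ...)`.
#' @param lookback_years Positive integer lookback (default 6).
#' @return An object of class `case_definition`.
#' @export
case_definition <- function(atoms, expression, lookback_years = 6) {
  if (lookback_years < 1) abort("lookback_years must be >= 1")
  if (is.null(names(atoms)) || any(names(atoms) == "")) {
    abort("atoms must be a named list")
  }
  for (nm in names(atoms)) {
    a <- atoms[[nm]]
    if (is.null(a$kind) || !a$kind %in% ATOM_KINDS) {
      abort(sprintf("atom '%s': unknown kind '%s'", nm, a$kind %||% "<missing>"))
    }
    if (length(a$values) == 0) abort(sprintf("atom '%s': empty value set", nm))
  }
  used <- collect_atom_refs(expression)
  undeclared <- setdiff(used, names(atoms))
  if (length(undeclared) > 0) {
    abort(sprintf("expression references undeclared atom(s): %s",
                  paste(undeclared, collapse = ", ")))
  }
  structure(list(atoms = atoms, expression = expression,
                 lookback_years = as.integer(lookback_years)),
            class = "case_definition")
}

collect_atom_refs <- function(expr) {
  if (is.character(expr) && length(expr) == 1) return(expr)
  if (is.list(expr) && length(expr) >= 2 &&
      expr[[1]] %in% c("and", "or", "not")) {
    return(unique(unlist(lapply(expr[-1], collect_atom_refs))))
  }
  abort("malformed rule expression: expected atom name or [and|or|not, ...]")
}

# Evaluate a boolean expression over a named logical matrix (rows = persons).
eval_rule_expr <- function(expr, hits) {
  if (is.character(expr) && length(expr) == 1) return(hits[, expr])
  op <- expr[[1]]
  args <- lapply(expr[-1], eval_rule_expr, hits = hits)
  switch(op,
    "not" = {
      if (length(args) != 1) abort("'not' takes exactly one argument")
      !args[[1]]
    },
    "and" = Reduce(`&`, args),
    "or" = Reduce(`|`, args)
  )
}

strip_dots <- function(x) gsub(".", "", x, fixed = TRUE)

match_prefix <- function(codes, prefixes) {
  codes <- strip_dots(toupper(codes))
  prefixes <- strip_dots(toupper(prefixes))
  hit <- rep(FALSE, length(codes))
  for (p in prefixes) hit <- hit | startsWith(codes, p)
  hit
}

match_keyword <- function(texts, keywords) {
  keywords <- tolower(keywords)
  tokens <- strsplit(tolower(texts), "[^a-z0-9]+")
  vapply(tokens, function(tk) any(tk %in% keywords), logical(1))
}

# All events matching one atom inside a window; returns tibble
# (person_id, date, snippet).
atom_event_hits <- function(atom, claims, prescriptions, window) {
  empty <- tibble::tibble(person_id = character(), date = as.Date(character()),
                          snippet = character())
  switch(atom$kind,
    icd9_prefix = {
      cl <- claims[claims$service_date >= window[1] &
                     claims$service_date <= window[2] & claims$icd9_code != "", ]
      cl <- cl[match_prefix(cl$icd9_code, atom$values), ]
      if (nrow(cl) == 0) empty else
        tibble::tibble(person_id = cl$person_id, date = cl$service_date,
                       snippet = cl$icd9_code)
    },
    atc_prefix = {
      rx <- prescriptions[prescriptions$dispense_date >= window[1] &
                            prescriptions$dispense_date <= window[2], ]
      rx <- rx[match_prefix(rx$atc_code, atom$values), ]
      if (nrow(rx) == 0) empty else
        tibble::tibble(person_id = rx$person_id, date = rx$dispense_date,
                       snippet = rx$atc_code)
    },
    text_keyword = {
      cl <- claims[claims$service_date >= window[1] &
                     claims$service_date <= window[2] & claims$free_text != "", ]
      cl <- cl[match_keyword(cl$free_text, atom$values), ]
      if (nrow(cl) == 0) empty else
        tibble::tibble(person_id = cl$person_id, date = cl$service_date,
                       snippet = cl$free_text)
    },
    abort(sprintf("unknown atom kind '%s'", atom$kind))
  )
}

#' Evaluate a single atom for one person
#'
#' @param atom An atom specification (`list(kind =, values =)`).
#' @param person_events List with `claims` and/or `prescriptions` tibbles
#'   for one person.
#' @param window Length-2 Date vector, inclusive.
#' @return List with `hit` (logical) and `evidence` (tibble of matching
#'   events; empty when `hit` is `FALSE`).
#' @export
evaluate_atom <- function(atom, person_events, window) {
  claims <- person_events$claims %||% empty_bundle_table("claims")
  rx <- person_events$prescriptions %||% empty_bundle_table("prescriptions")
  hits <- atom_event_hits(atom, claims, rx, window)
  list(hit = nrow(hits) > 0, evidence = hits)
}

#' Apply an EMR case definition to a cohort
#'
#' Evaluates every atom over the lookback window ending December 31 of the
#' index year, combines them with the definition's boolean expression, and
#' returns one frailty call per included cohort member.
#'
#' @param case_def A [case_definition()].
#' @param emr_bundle EMR bundle (pre-scrambling person ids).
#' @param cohort Output of [build_cohort()]; only `included` rows are
#'   classified.
#' @param index_year Index calendar year.
#' @return A tibble (`frailty_calls`): `scrambled_id`, `source`, `frail`,
#'   one logical column per atom, and `evidence` (list-column of tibbles
#'   `(atom, date, snippet)`, earliest hit per firing atom; non-empty
#'   whenever `frail`).
#' @export
apply_emr_definition <- function(case_def, emr_bundle, cohort, index_year) {
  stopifnot(inherits(case_def, "case_definition"))
  window <- c(year_start(index_year - case_def$lookback_years + 1),
              year_end(index_year))
  members <- cohort[cohort$included, ]
  atom_names <- names(case_def$atoms)
  hit_mat <- matrix(FALSE, nrow(members), length(atom_names),
                    dimnames = list(NULL, atom_names))
  first_hits <- list()
  for (nm in atom_names) {
    h <- atom_event_hits(case_def$atoms[[nm]], emr_bundle$claims,
                         emr_bundle$prescriptions, window)
    h <- h[h$person_id %in% members$emr_person_id, ]
    hit_mat[, nm] <- members$emr_person_id %in% h$person_id
    if (nrow(h) > 0) {
      h <- h[order(h$person_id, h$date), ]
      h <- h[!duplicated(h$person_id), ]
      h$atom <- nm
      first_hits[[nm]] <- h
    }
  }
  frail <- if (nrow(members) == 0) logical(0) else
    eval_rule_expr(case_def$expression, hit_mat)
  all_hits <- dplyr::bind_rows(first_hits)
  evidence <- lapply(seq_len(nrow(members)), function(i) {
    if (is.null(all_hits) || nrow(all_hits) == 0) {
      return(tibble::tibble(atom = character(), date = as.Date(character()),
                            snippet = character()))
    }
    h <- all_hits[all_hits$person_id == members$emr_person_id[i], ]
    tibble::tibble(atom = h$atom, date = h$date, snippet = h$snippet)
  })
  out <- tibble::tibble(
    scrambled_id = members$scrambled_id,
    source = "emr",
    frail = frail
  )
  for (nm in atom_names) out[[paste0("atom_", nm)]] <- hit_mat[, nm]
  out$evidence <- evidence
  out
}

#' The shipped default EMR frailty definition
#'
#' Dementia coding (ICD-9 prefix 290) OR (vitamin prescriptions, ATC
#' prefix A11, AND furosemide, ATC C03CA01) OR the free-text keyword
#' "obstruction", over a 6-year lookback. A reconstruction with
#' overridable code sets; see [emr_frailty].
#'
#' @return A [case_definition()].
#' @export
default_emr_definition <- function() {
  path <- system.file("extdata", "emr_frailty_rules.json", package = "frailscan")
  if (path == "") {
    abort("shipped rule file not found; is the package installed?")
  }
  read_case_definition(path)
}

#' Read / write case definitions as JSON rule files
#'
#' The JSON layout is `{"atoms": {name: {"kind": ..., "values": [...]}},
#' "expression": ["or", ...], "lookback_years": n}`.
#'
#' @param path File path.
#' @return `read_case_definition()` returns a [case_definition()].
#' @export
read_case_definition <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  atoms <- lapply(x$atoms, function(a) {
    list(kind = a$kind, values = unlist(a$values))
  })
  case_definition(atoms, x$expression, x$lookback_years %||% 6)
}

#' @param case_def A [case_definition()] to serialize.
#' @rdname read_case_definition
#' @export
write_case_definition <- function(case_def, path) {
  x <- list(atoms = lapply(case_def$atoms, function(a)
    list(kind = a$kind, values = as.list(a$values))),
    expression = case_def$expression,
    lookback_years = case_def$lookback_years)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.case_definition <- function(x, ...) {
  cat(sprintf("<case_definition> %d atoms, lookback %d years\n",
              length(x$atoms), x$lookback_years))
  cat("  expression:", deparse_rule_expr(x$expression), "\n")
  invisible(x)
}

deparse_rule_expr <- function(expr) {
  if (is.character(expr)) return(expr)
  op <- expr[[1]]
  args <- vapply(expr[-1], deparse_rule_expr, "")
  if (op == "not") paste0("not(", args, ")")
  else paste0("(", paste(args, collapse = paste0(" ", op, " ")), ")")
}
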