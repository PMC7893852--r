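#' Deterministic person-level linkage and identifier scrambling
#'
#' Emulates the trusted-third-party workflow used for linked health data:
#' the two sources are linked deterministically by exact match on the
#' personal health number (PHN), then released with the PHN removed and
#' person identifiers replaced by keyed one-way scrambled identifiers.
#'
#' @name linkage
NULL

scrambled_id_for <- function(phn, salt) {
  paste0("X", fnv_hash(paste0(salt, ":", phn)))
}

#' Replace person identifiers with scrambled identifiers
#'
#' Applies a keyed one-way transformation of the PHN: the same PHN and salt
#' always map to the same scrambled identifier, and the PHN column is
#' removed from the released bundle.
#'
#' @param b A `frail_bundle` whose persons table retains `phn`.
#' @param salt Fixed salt string keying the transformation.
#' @return A list with `bundle` (person_ids replaced, `phn` blanked) and
#'   `keymap` (tibble `person_id`, `phn`, `scrambled_id`).
#' @export
scramble_ids <- function(b, salt) {
  stopifnot(inherits(b, "frail_bundle"), is.character(salt), length(salt) == 1)
  keymap <- tibble::tibble(
    person_id = b$persons$person_id,
    phn = b$persons$phn,
    scrambled_id = scrambled_id_for(b$persons$phn, salt)
  )
  lut <- setNames(keymap$scrambled_id, keymap$person_id)
  out <- b
  out$persons$person_id <- unname(lut[out$persons$person_id])
  out$persons$phn <- ""
  for (tb in setdiff(BUNDLE_TABLES, "persons")) {
    if (nrow(out[[tb]]) > 0) {
      out[[tb]]$person_id <- unname(lut[out[[tb]]$person_id])
    }
  }
  out <- do.call(bundle, c(list(source = out$source), out[BUNDLE_TABLES]))
  list(bundle = out, keymap = keymap)
}

#' Deterministic linkage by exact PHN match
#'
#' Links persons across the EMR and administrative bundles by exact match
#' on PHN; no fuzzy matching. Duplicate PHNs within a source make
#' deterministic linkage undefined and are an error.
#'
#' @param emr_bundle,admin_bundle Bundles retaining PHN (linkage precedes
#'   scrambling of the released files).
#' @param salt Salt used to mint the project-specific scrambled identifier
#'   for each linked pair.
#' @param denominator Which source's person count divides the linkage rate;
#'   `"emr"` (default; the study cohort is drawn from EMR patients) or
#'   `"admin"`.
#' @return An object of class `frail_crosswalk`: list with `links` (tibble
#'   `emr_person_id`, `admin_person_id`, `phn`, `scrambled_id`),
#'   `linkage_rate`, `unlinked_emr`, `unlinked_admin`.
#' @export
link_deterministic <- function(emr_bundle, admin_bundle, salt = "frailscan",
                               denominator = c("emr", "admin")) {
  denominator <- match.arg(denominator)
  ep <- emr_bundle$persons
  ap <- admin_bundle$persons
  for (src in list(list(n = "EMR", p = ep), list(n = "administrative", p = ap))) {
    dup <- unique(src$p$phn[duplicated(src$p$phn)])
    if (length(dup) > 0) {
      abort(sprintf(
        "duplicate PHN(s) within %s source: %s (deterministic linkage undefined)",
        src$n, paste(head(dup, 5), collapse = ", ")))
    }
  }
  shared <- intersect(ep$phn, ap$phn)
  links <- tibble::tibble(
    phn = shared,
    emr_person_id = ep$person_id[match(shared, ep$phn)],
    admin_person_id = ap$person_id[match(shared, ap$phn)],
    scrambled_id = scrambled_id_for(shared, salt)
  )[, c("emr_person_id", "admin_person_id", "phn", "scrambled_id")]
  denom <- if (denominator == "emr") nrow(ep) else nrow(ap)
  structure(list(
    links = links,
    linkage_rate = if (denom > 0) nrow(links) / denom else 0,
    unlinked_emr = setdiff(ep$person_id, links$emr_person_id),
    unlinked_admin = setdiff(ap$person_id, links$admin_person_id)
  ), class = "frail_crosswalk")
}

#' @export
print.frail_crosswalk <- function(x, ...) {
  cat(sprintf("<frail_crosswalk> %d links, linkage rate %.3f\n",
              nrow(x$links), x$linkage_rate))
  cat(sprintf("  unlinked: %d EMR, %d administrative\n",
              length(x$unlinked_emr), length(x$unlinked_admin)))
  invisible(x)
}
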