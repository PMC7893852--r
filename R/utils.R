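#' @importFrom rlang abort warn .data
#' @importFrom stats rbinom rgamma rnbinom rpois runif plogis qbeta chisq.test
#'   pchisq t.test sd setNames uniroot
#' @importFrom utils head modifyList
NULL

# Round half away from zero (table-style rounding; base round() is banker's).
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count over a denominator, table-rounded
#'
#' Computes `100 * count / denom` rounded half-away-from-zero to one decimal,
#' the convention used throughout the descriptive tables.
#'
#' @param count Numerator count(s).
#' @param denom Denominator(s); a zero denominator yields `NA`.
#' @param digits Decimal places (default 1).
#' @return Numeric vector of percentages.
#' @examples
#' table_pct(45, 70) # 64.3
#' @export
table_pct <- function(count, denom, digits = 1) {
  out <- round_half_away(100 * count / denom, digits)
  out[rep_len(!(denom > 0), length(out))] <- NA_real_
  as.numeric(out)
}

as_date_safe <- function(x, field, table) {
  if (inherits(x, "Date")) return(x)
  suppressWarnings(out <- as.Date(as.character(x), format = "%Y-%m-%d"))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad) > 0) {
    abort(sprintf("table '%s': field '%s' has unparseable ISO-8601 date at row(s) %s",
                  table, field, paste(head(bad, 5), collapse = ", ")))
  }
  out
}

days_inclusive <- function(start, end) as.integer(end) - as.integer(start) + 1L

year_start <- function(year) as.Date(sprintf("%d-01-01", year))
year_end <- function(year) as.Date(sprintf("%d-12-31", year))

# Completed years of age at a reference date.
age_at <- function(birth_date, at_date) {
  by <- as.integer(format(birth_date, "%Y"))
  ay <- as.integer(format(at_date, "%Y"))
  age <- ay - by
  had_birthday <- format(at_date, "%m%d") >= format(birth_date, "%m%d")
  age - as.integer(!had_birthday)
}

# 64-bit keyed FNV-1a-style string hash, returned as 16 hex characters.
# Implemented as two independent 32-bit FNV lanes (different offset bases);
# 32-bit modular multiplication is done in split 16-bit halves so all
# intermediates stay exact in doubles.
fnv_hash <- function(strings) {
  prime <- 16777619
  lane <- function(offset) {
    h <- rep(offset, length(strings))
    codes <- lapply(strings, utf8ToInt)
    maxlen <- max(c(0L, lengths(codes)))
    if (maxlen == 0) return(h)
    mat <- vapply(codes, function(cc) c(cc, rep(-1L, maxlen - length(cc))), integer(maxlen))
    mat <- matrix(mat, nrow = maxlen)
    for (i in seq_len(maxlen)) {
      b <- mat[i, ]
      active <- b >= 0
      hx <- floor(h / 65536); hl <- h %% 65536
      xb <- ifelse(active, bitwXor(hl %% 256, b), hl %% 256)
      hl2 <- floor(hl / 256) * 256 + xb
      hnew <- ((hx * prime) %% 65536) * 65536 + hl2 * prime
      hnew <- hnew %% 4294967296
      h <- ifelse(active, hnew, h)
    }
    h
  }
  hex32 <- function(h) {
    sprintf("%04x%04x", as.integer(floor(h / 65536)), as.integer(h %% 65536))
  }
  paste0(hex32(lane(2166136261)), hex32(lane(40389)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
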