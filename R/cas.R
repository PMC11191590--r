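#' CAS registry number validation and canonicalization
#'
#' A CAS registry number has the form `NNNNNNN-NN-N` (two to seven leading
#' digits, two middle digits, one check digit). The check digit is the
#' weighted sum of all other digits taken right to left with weights
#' 1, 2, 3, ..., modulo 10. `normalize_cas()` strips leading zeros from the
#' first segment so that registry keys compare canonically, and validates
#' the check digit; `cas_is_valid()` is the vectorized predicate.
#'
#' @param x Character vector of putative CAS numbers.
#' @param strict If `TRUE` (default) `normalize_cas()` errors on the first
#'   malformed or checksum-failing value; if `FALSE` such values are
#'   returned as `NA` so callers can quarantine them.
#'
#' @return `normalize_cas()`: a character vector of canonical hyphenated CAS
#'   numbers (or `NA` where invalid when `strict = FALSE`).
#'   `cas_is_valid()`: a logical vector.
#'
#' @examples
#' normalize_cas("0050-00-0")   # formaldehyde -> "50-00-0"
#' cas_is_valid(c("900-95-8", "50-00-1"))
#' @export
normalize_cas <- function(x, strict = TRUE) {
  if (length(x) == 0) return(character())
  if (!is.character(x)) abort("`x` must be a character vector of CAS numbers")
  raw <- stringr::str_trim(x)
  pat <- "^0*([0-9]{2,7})-([0-9]{2})-([0-9])$"
  ok_pat <- stringr::str_detect(raw, pat) & !is.na(raw)
  canon <- rep(NA_character_, length(raw))
  if (any(ok_pat)) {
    m <- stringr::str_match(raw[ok_pat], pat)
    cand <- paste0(m[, 2], "-", m[, 3], "-", m[, 4])
    ok_sum <- vapply(cand, cas_checksum_ok, logical(1), USE.NAMES = FALSE)
    canon[ok_pat] <- ifelse(ok_sum, cand, NA_character_)
    if (strict && any(!ok_sum)) {
      abort(sprintf("CAS check-digit failure: %s",
                    paste(unique(raw[ok_pat][!ok_sum]), collapse = ", ")),
            class = "plastitox_cas_checksum")
    }
  }
  if (strict && any(!ok_pat)) {
    abort(sprintf("malformed CAS number(s): %s",
                  paste(unique(raw[!ok_pat]), collapse = ", ")),
          class = "plastitox_cas_format")
  }
  canon
}

#' @rdname normalize_cas
#' @export
cas_is_valid <- function(x) {
  !is.na(suppressWarnings(normalize_cas(as.character(x), strict = FALSE)))
}

cas_checksum_ok <- function(cas) {
  digits <- as.integer(strsplit(gsub("-", "", cas), "")[[1]])
  check <- digits[length(digits)]
  body <- rev(digits[-length(digits)])
  sum(body * seq_along(body)) %% 10 == check
}

# append a valid check digit to a digit-string body, e.g. "90095" -> "900-95-8"
cas_from_body <- function(body) {
  vapply(body, function(b) {
    d <- rev(as.integer(strsplit(b, "")[[1]]))
    chk <- sum(d * seq_along(d)) %% 10
    n <- nchar(b)
    paste0(substr(b, 1, n - 2), "-", substr(b, n - 1, n), "-", chk)
  }, character(1), USE.NAMES = FALSE)
}
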