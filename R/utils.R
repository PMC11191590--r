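# internal helpers shared across modules

# round-half-up at `digits` decimals (base round() is half-to-even; printed
# registry percentages are conventionally rounded half-up)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# split pipe-delimited multi-valued CSV cells into trimmed character vectors
split_multi <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(character())
    out <- stringr::str_trim(strsplit(s, "|", fixed = TRUE)[[1]])
    out[nzchar(out)]
  })
}

collapse_multi <- function(x) {
  vapply(x, function(v) paste(v, collapse = "|"), character(1))
}

squash_ws <- function(x) stringr::str_squish(tolower(x))

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
}
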