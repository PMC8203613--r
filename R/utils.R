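# Internal helpers shared across modules.

# Canonical form used for every name lookup in the package: trim, collapse
# internal whitespace, casefold. FAERS free-text fields are inconsistently
# cased and padded.
norm_term <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# round() in base R rounds half to even; presentation tables in this field
# round half up (e.g. 41.465 -> 41.47 at 2 decimals).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

# Deterministic, locale-independent ordering (C collation).
order_radix <- function(...) order(..., method = "radix")

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

# Integer YYYYMMDD -> Date; invalid encodings become NA.
ymd_to_date <- function(x) {
  as.Date(sprintf("%08d", as.integer(x)), format = "%Y%m%d")
}

date_to_ymd <- function(d) {
  as.integer(format(d, "%Y%m%d"))
}
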