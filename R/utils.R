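# Internal helpers shared across stages.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Round half away from zero, the convention used for reported percentages.
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Percentage with an undefined (NA) result on an empty denominator, never 0.
pct_of <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)

as_date_strict <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  out
}

# Calendar year of a Date without timezone surprises.
date_year <- function(x) as.integer(format(x, "%Y"))

# min() as integer, NA on empty input (quiet under data.table's empty-group
# prototype evaluation)
min_day <- function(x) {
  x <- x[!is.na(x)]
  if (length(x)) as.integer(min(x)) else NA_integer_
}

stop_input <- function(...) stop(..., call. = FALSE)
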