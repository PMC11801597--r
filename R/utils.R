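#' Round half away from zero
#'
#' Fixed-precision rounding in which a trailing 5 always rounds away from
#' zero, the convention used when formatting report tables. Base
#' [round()] rounds half to even, which disagrees with printed
#' percentage tables on exact .xx5 values.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(0.125, 2)   # 0.13
#' round(0.125, 2)           # 0.12 (banker's rounding)
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Parse FAERS-style compact dates
#'
#' FAERS date fields carry 8-digit (YYYYMMDD), 6-digit (YYYYMM) or 4-digit
#' (YYYY) values. Partial dates are resolved to the first day of the stated
#' period; anything unparseable becomes `NA` rather than dropping the row.
#'
#' @param x Character (or numeric) vector of compact date strings.
#' @return A `Date` vector.
#' @export
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x) | !grepl("^[0-9]{4}([0-9]{2}([0-9]{2})?)?$", x)] <- NA_character_
  full <- ifelse(is.na(x), NA_character_,
          ifelse(nchar(x) == 4L, paste0(x, "0101"),
          ifelse(nchar(x) == 6L, paste0(x, "01"), x)))
  as.Date(full, format = "%Y%m%d")
}

# FAERS age unit -> years multiplier. Ages outside [0, 120] years are
# implausible artifacts of unit coding errors and are set to missing.
age_to_years <- function(value, unit) {
  mult <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52,
            DY = 1 / 365.25, HR = 1 / 8766)
  v <- suppressWarnings(as.numeric(value))
  u <- toupper(trimws(as.character(unit)))
  y <- v * unname(mult[match(u, names(mult))])
  y[!is.na(y) & (y < 0 | y > 120)] <- NA_real_
  y
}

# Date -> FAERS 8-digit form ("" for missing); used by the writer and the
# synthetic generator.
format_faers_date <- function(x) {
  out <- format(x, "%Y%m%d")
  out[is.na(out)] <- ""
  out
}
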