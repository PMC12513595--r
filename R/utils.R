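# Shared helpers: text folding, date parsing, rounding.

#' Fold free text for dictionary lookup
#'
#' Lower-cases, trims, collapses internal whitespace and strips punctuation
#' so that lookups are case- and punctuation-insensitive.
#'
#' @param x character vector.
#' @return folded character vector, same length.
#' @keywords internal
fold_text <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[[:punct:]]+", " ", x)
  gsub("[[:space:]]+", " ", trimws(x))
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; reported percentages use the
#' conventional half-up rule (49.845 -> 49.85).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Parse spontaneous-report dates
#'
#' Accepts `YYYYMMDD`, `YYYY-MM-DD`, `YYYY/MM/DD` (day precision),
#' `YYYYMM` (month precision) and `YYYY` (year precision). Partial dates
#' are anchored to the first day of their period and flagged so that
#' day-level arithmetic (time to onset) can treat them as absent.
#'
#' @param x character vector of raw date fields.
#' @return tibble with columns `date` (Date, `NA` when unparseable) and
#'   `precision` (`"day"`, `"month"`, `"year"` or `NA`).
#' @export
parse_pv_date <- function(x) {
  x <- gsub("[-/]", "", trimws(as.character(x)))
  x[is.na(x) | x == "" | grepl("[^0-9]", x)] <- NA_character_
  n <- nchar(x)
  precision <- dplyr::case_when(
    is.na(x) ~ NA_character_,
    n == 8 ~ "day",
    n == 6 ~ "month",
    n == 4 ~ "year",
    TRUE ~ NA_character_
  )
  full <- dplyr::case_when(
    is.na(precision) ~ NA_character_,
    precision == "day" ~ x,
    precision == "month" ~ paste0(x, "01"),
    precision == "year" ~ paste0(x, "0101")
  )
  date <- as.Date(full, format = "%Y%m%d")
  precision[is.na(date)] <- NA_character_
  tibble::tibble(date = date, precision = precision)
}

# format a Date as YYYYMMDD ("" for NA)
format_pv_date <- function(d) {
  out <- format(d, "%Y%m%d")
  out[is.na(out)] <- ""
  out
}

#' Assign an age group from age in years
#'
#' Groups are `<18`, `18-65` (inclusive on both ends), `>65` and
#' `unknown` for missing ages.
#'
#' @param age_years numeric vector (years; may contain `NA`).
#' @return character vector of group labels.
#' @export
age_group_of <- function(age_years) {
  dplyr::case_when(
    is.na(age_years) ~ "unknown",
    age_years < 18 ~ "<18",
    age_years <= 65 ~ "18-65",
    TRUE ~ ">65"
  )
}

# stop unless all names are present in a data frame
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
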