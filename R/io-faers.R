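# FAERS-dialect quarterly ASCII tables: "$"-delimited DEMO / DRUG / REAC /
# INDI / THER / OUTC, one header row each, joined on PRIMARYID.

faers_sex_out <- c(male = "M", female = "F", unknown = "UNK")
faers_sex_in <- c(M = "male", F = "female", UNK = "unknown")
faers_role_out <- c(
  primary_suspect = "PS", secondary_suspect = "SS",
  concomitant = "C", interacting = "I", unknown = "UNK"
)
faers_role_in <- c(
  PS = "primary_suspect", SS = "secondary_suspect",
  C = "concomitant", I = "interacting", UNK = "unknown"
)
faers_occp_out <- c(
  health_professional = "MD", non_health_professional = "CN", unknown = ""
)

format_by_precision <- function(date, precision) {
  dplyr::case_when(
    is.na(date) ~ "",
    precision == "month" ~ format(date, "%Y%m"),
    precision == "year" ~ format(date, "%Y"),
    TRUE ~ format(date, "%Y%m%d")
  )
}

#' Write reports as FAERS-dialect quarterly tables
#'
#' Emits `DEMO.txt`, `DRUG.txt`, `REAC.txt`, `INDI.txt`, `THER.txt` and
#' `OUTC.txt` ("$"-delimited, one header row) into `directory`. A
#' write-then-[read_faers_quarter()] round trip reproduces the reports
#' exactly.
#'
#' @param reports normalized-report tibble (see [generate_reports()]).
#' @param directory output directory (created if absent).
#' @return `directory`, invisibly.
#' @export
write_faers_tables <- function(reports, directory) {
  if (nrow(reports) == 0) rlang::abort("no reports to write")
  if (!dir.exists(directory) &&
    !dir.create(directory, recursive = TRUE, showWarnings = FALSE)) {
    rlang::abort(sprintf("cannot create directory '%s'", directory))
  }
  demo <- tibble::tibble(
    PRIMARYID = reports$report_id,
    CASEID = reports$case_id,
    CASEVERSION = reports$case_version,
    FDA_DT = format_by_precision(reports$receipt_date, reports$receipt_precision),
    EVENT_DT = format_pv_date(reports$event_onset_date),
    SEX = faers_sex_out[reports$sex],
    AGE = ifelse(is.na(reports$age_years), "", as.character(reports$age_years)),
    AGE_COD = ifelse(is.na(reports$age_years), "", "YR"),
    OCCR_COUNTRY = reports$country,
    OCCP_COD = faers_occp_out[reports$reporter_type]
  )
  unn <- function(col, value_name) {
    out <- tidyr::unnest(
      tibble::tibble(PRIMARYID = reports$report_id, value = reports[[col]]),
      "value"
    )
    names(out)[2] <- value_name
    out
  }
  drug <- tidyr::unnest(
    tibble::tibble(PRIMARYID = reports$report_id, d = reports$drugs), "d"
  ) |>
    dplyr::group_by(.data$PRIMARYID) |>
    dplyr::mutate(DRUG_SEQ = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      .data$PRIMARYID, .data$DRUG_SEQ,
      ROLE_COD = faers_role_out[.data$role],
      DRUGNAME = .data$name_raw
    )
  reac <- unn("events", "PT")
  indi <- unn("indications", "INDI_PT") |>
    dplyr::group_by(.data$PRIMARYID) |>
    dplyr::mutate(INDI_DRUG_SEQ = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("PRIMARYID", "INDI_DRUG_SEQ", "INDI_PT")
  outc <- unn("outcomes", "OUTC_COD")
  ther <- tibble::tibble(
    PRIMARYID = reports$report_id, DSG_DRUG_SEQ = 1L,
    START_DT = format_pv_date(reports$therapy_start_date)
  )
  tabs <- list(
    DEMO = demo, DRUG = drug, REAC = reac,
    INDI = indi, THER = ther, OUTC = outc
  )
  for (nm in names(tabs)) {
    readr::write_delim(tabs[[nm]], file.path(directory, paste0(nm, ".txt")),
      delim = "$", na = ""
    )
  }
  invisible(directory)
}

read_faers_file <- function(directory, name, required = FALSE) {
  path <- file.path(directory, paste0(name, ".txt"))
  if (!file.exists(path)) {
    if (required) {
      rlang::abort(sprintf("mandatory FAERS table '%s.txt' not found in '%s'", name, directory))
    }
    return(NULL)
  }
  tab <- suppressWarnings(readr::read_delim(
    path,
    delim = "$", na = character(),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  ))
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    bad <- unique(probs$row)
    rlang::inform(sprintf(
      "%s.txt: %d malformed line(s) skipped", name, length(bad)
    ))
    tab <- tab[-bad, , drop = FALSE]
  }
  tab
}

# align child-table rows to report ids, preserving file order; reports
# without rows get a zero-length entry
collect_list <- function(ids, keys, values) {
  out <- split(values, factor(keys, levels = ids))
  names(out) <- NULL
  lapply(out, function(v) as.character(v))
}

drop_orphans <- function(tab, ids, what) {
  if (is.null(tab) || nrow(tab) == 0) {
    return(tab)
  }
  orphan <- !(tab$PRIMARYID %in% ids)
  if (any(orphan)) {
    rlang::inform(sprintf(
      "%s: %d row(s) with no matching DEMO record skipped", what, sum(orphan)
    ))
    tab <- tab[!orphan, , drop = FALSE]
  }
  tab
}

#' Read a FAERS-dialect quarter into normalized reports
#'
#' Joins DEMO, DRUG, REAC, INDI, THER and OUTC on `PRIMARYID` into one
#' normalized report per DEMO row. Unparseable dates become absent
#' (never fail a row); child rows whose `PRIMARYID` has no DEMO row are
#' skipped and counted; DEMO rows with no reactions are dropped (a report
#' must carry at least one event). Ages are harmonized to years using
#' `AGE_COD` (`YR`, `DEC`, `MON`, `WK`, `DY`, `HR`).
#'
#' @param directory directory holding the "$"-delimited tables.
#' @param lexicon drug lexicon used to canonicalize `DRUGNAME`.
#' @return normalized-report tibble, one row per DEMO row.
#' @export
read_faers_quarter <- function(directory, lexicon = read_drug_lexicon()) {
  demo <- read_faers_file(directory, "DEMO", required = TRUE)
  reac <- read_faers_file(directory, "REAC", required = TRUE)
  drug <- read_faers_file(directory, "DRUG")
  indi <- read_faers_file(directory, "INDI")
  ther <- read_faers_file(directory, "THER")
  outc <- read_faers_file(directory, "OUTC")

  ids <- demo$PRIMARYID
  reac <- drop_orphans(reac, ids, "REAC")
  drug <- drop_orphans(drug, ids, "DRUG")
  indi <- drop_orphans(indi, ids, "INDI")
  ther <- drop_orphans(ther, ids, "THER")
  outc <- drop_orphans(outc, ids, "OUTC")

  receipt <- parse_pv_date(demo$FDA_DT)
  onset <- parse_pv_date(demo$EVENT_DT)
  onset$date[is.na(onset$precision) | onset$precision != "day"] <- NA

  age_factor <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365.25, DY = 1 / 365.25, HR = 1 / 8766)
  age_years <- suppressWarnings(as.numeric(demo$AGE)) *
    unname(age_factor[toupper(demo$AGE_COD)])

  events <- collect_list(ids, reac$PRIMARYID, reac$PT)
  indications <- if (!is.null(indi) && nrow(indi) > 0) {
    collect_list(ids, indi$PRIMARYID, indi$INDI_PT)
  } else {
    rep(list(character(0)), length(ids))
  }
  outcomes <- if (!is.null(outc) && nrow(outc) > 0) {
    collect_list(ids, outc$PRIMARYID, outc$OUTC_COD)
  } else {
    rep(list(character(0)), length(ids))
  }

  # report-level therapy start: earliest day-precision START_DT
  start_date <- rep(as.Date(NA), length(ids))
  if (!is.null(ther) && nrow(ther) > 0) {
    st <- parse_pv_date(ther$START_DT)
    keep <- !is.na(st$precision) & st$precision == "day"
    if (any(keep)) {
      agg <- tibble::tibble(id = ther$PRIMARYID[keep], date = st$date[keep]) |>
        dplyr::group_by(.data$id) |>
        dplyr::summarise(date = min(.data$date), .groups = "drop")
      start_date[match(agg$id, ids)] <- agg$date
    }
  }

  drugs <- rep(list(tibble::tibble(
    name_raw = character(0), name_canonical = character(0), role = character(0)
  )), length(ids))
  if (!is.null(drug) && nrow(drug) > 0) {
    norm <- normalize_drug_name(drug$DRUGNAME, lexicon)
    dd <- tibble::tibble(
      id = drug$PRIMARYID,
      name_raw = drug$DRUGNAME,
      name_canonical = norm$canonical,
      role = unname(faers_role_in[toupper(drug$ROLE_COD)])
    )
    dd$role[is.na(dd$role)] <- "unknown"
    split_dd <- split(dd[, -1], factor(dd$id, levels = ids))
    drugs <- lapply(split_dd, tibble::as_tibble)
    names(drugs) <- NULL
  }

  reports <- tibble::tibble(
    report_id = ids,
    case_id = demo$CASEID,
    case_version = dplyr::coalesce(suppressWarnings(as.integer(demo$CASEVERSION)), 1L),
    source = "FAERS",
    receipt_date = receipt$date,
    receipt_precision = receipt$precision,
    sex = dplyr::coalesce(unname(faers_sex_in[toupper(demo$SEX)]), "unknown"),
    age_years = age_years,
    age_group = age_group_of(age_years),
    country = demo$OCCR_COUNTRY,
    reporter_type = dplyr::case_when(
      toupper(demo$OCCP_COD) %in% c("MD", "PH", "OT", "RN", "HP") ~ "health_professional",
      toupper(demo$OCCP_COD) %in% c("CN", "LW") ~ "non_health_professional",
      TRUE ~ "unknown"
    ),
    outcomes = outcomes, drugs = drugs, events = events,
    indications = indications,
    therapy_start_date = start_date,
    event_onset_date = onset$date
  )
  no_event <- lengths(reports$events) == 0
  if (any(no_event)) {
    rlang::inform(sprintf(
      "%d DEMO row(s) with no reaction rows dropped", sum(no_event)
    ))
    reports <- reports[!no_event, , drop = FALSE]
  }
  reports
}
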