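# JADER-dialect tables: comma-delimited demo / drug / reac files keyed by
# case id + sequence. Ages are decade bands, involvement codes replace
# drug roles, and the reporting country is Japan by construction.

jader_sex_out <- c(male = "男性", female = "女性", unknown = "")
jader_role_out <- c(
  primary_suspect = "被疑薬",
  secondary_suspect = "被疑薬",
  concomitant = "併用薬",
  interacting = "相互作用",
  unknown = ""
)
jader_reporter_out <- c(
  health_professional = "医療関係者",
  non_health_professional = "消費者等",
  unknown = ""
)

jader_age_band <- function(age_years) {
  ifelse(is.na(age_years), "",
    paste0(floor(age_years / 10) * 10, "代")
  )
}

# decade band -> midpoint years ("60代" -> 65); unknown/blank -> NA
jader_band_midpoint <- function(band) {
  band <- trimws(as.character(band))
  dec <- suppressWarnings(as.numeric(sub("代$", "", band)))
  dec[!grepl("代$", band)] <- NA
  mid <- dec + 5
  mid[band == "10歳未満"] <- 5
  mid
}

#' Write reports as JADER-dialect tables
#'
#' Emits comma-delimited `demo.csv`, `drug.csv` and `reac.csv` keyed by
#' case id + sequence. The dialect stores age as a decade band and has no
#' country field, so a write-then-[read_jader()] round trip reproduces
#' the [jader_projection()] of the input (band-midpoint age, Japan,
#' suspect roles collapsed to the dialect's involvement codes) rather
#' than the input bit-for-bit.
#'
#' @inheritParams write_faers_tables
#' @return `directory`, invisibly.
#' @export
write_jader_tables <- function(reports, directory) {
  if (nrow(reports) == 0) rlang::abort("no reports to write")
  if (!dir.exists(directory) &&
    !dir.create(directory, recursive = TRUE, showWarnings = FALSE)) {
    rlang::abort(sprintf("cannot create directory '%s'", directory))
  }
  demo <- tibble::tibble(
    case_id = reports$case_id,
    case_version = reports$case_version,
    receipt_date = format_by_precision(reports$receipt_date, reports$receipt_precision),
    sex = jader_sex_out[reports$sex],
    age_band = jader_age_band(reports$age_years),
    outcome = vapply(reports$outcomes, paste, character(1), collapse = ";"),
    reporter = jader_reporter_out[reports$reporter_type]
  )
  # indications ride on drug rows (one per row, dialect convention);
  # child tables carry the case version so duplicate case versions keep
  # their own drug/reaction rows
  drug <- purrr::pmap_dfr(
    list(
      reports$case_id, reports$case_version, reports$drugs,
      reports$indications, format_pv_date(reports$therapy_start_date)
    ),
    function(cid, ver, d, ind, st) {
      nd <- nrow(d)
      tibble::tibble(
        case_id = cid, case_version = ver, drug_seq = seq_len(nd),
        involvement = unname(jader_role_out[d$role]),
        drug_name = d$name_raw,
        indication = c(ind, rep("", max(0, nd - length(ind))))[seq_len(nd)],
        therapy_start_date = c(st, rep("", nd - 1))
      )
    }
  )
  reac <- purrr::pmap_dfr(
    list(
      reports$case_id, reports$case_version, reports$events,
      format_pv_date(reports$event_onset_date)
    ),
    function(cid, ver, ev, onset) {
      tibble::tibble(
        case_id = cid, case_version = ver, reac_seq = seq_along(ev), pt = ev,
        event_onset_date = c(onset, rep("", length(ev) - 1))
      )
    }
  )
  readr::write_csv(demo, file.path(directory, "demo.csv"), na = "")
  readr::write_csv(drug, file.path(directory, "drug.csv"), na = "")
  readr::write_csv(reac, file.path(directory, "reac.csv"), na = "")
  invisible(directory)
}

read_jader_file <- function(directory, name, required = FALSE) {
  path <- file.path(directory, paste0(name, ".csv"))
  if (!file.exists(path)) {
    if (required) {
      rlang::abort(sprintf("mandatory JADER table '%s.csv' not found in '%s'", name, directory))
    }
    return(NULL)
  }
  suppressWarnings(readr::read_csv(
    path,
    na = character(),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  ))
}

#' Read JADER-dialect tables into normalized reports
#'
#' Involvement codes map to drug roles (the dialect does not distinguish
#' primary from secondary suspects), decade age bands map to their
#' midpoint in years, the country is fixed to Japan and the source is
#' set to `"JADER"`. Reports lacking sex are retained with
#' `sex = "unknown"`.
#'
#' @inheritParams read_faers_quarter
#' @return normalized-report tibble, one row per demo row.
#' @export
read_jader <- function(directory, lexicon = read_drug_lexicon()) {
  demo <- read_jader_file(directory, "demo", required = TRUE)
  reac <- read_jader_file(directory, "reac", required = TRUE)
  drug <- read_jader_file(directory, "drug")

  version <- dplyr::coalesce(suppressWarnings(as.integer(demo$case_version)), 1L)
  ids <- paste0(demo$case_id, "-", version)
  key_of <- function(tab) {
    if ("case_version" %in% names(tab)) {
      v <- dplyr::coalesce(suppressWarnings(as.integer(tab$case_version)), 1L)
    } else {
      v <- version[match(tab$case_id, demo$case_id)]
    }
    paste0(tab$case_id, "-", v)
  }
  reac$.key <- key_of(reac)
  orphan <- !(reac$.key %in% ids)
  if (any(orphan)) {
    rlang::inform(sprintf("reac.csv: %d orphan row(s) skipped", sum(orphan)))
    reac <- reac[!orphan, , drop = FALSE]
  }

  receipt <- parse_pv_date(demo$receipt_date)
  age_years <- jader_band_midpoint(demo$age_band)
  sex_in <- c("男性" = "male", "女性" = "female")
  events <- collect_list(ids, reac$.key, reac$pt)
  onset_raw <- vapply(
    split(reac$event_onset_date, factor(reac$.key, levels = ids)),
    function(v) {
      v <- v[nzchar(v)]
      if (length(v) > 0) v[[1]] else ""
    }, character(1)
  )
  onset <- parse_pv_date(unname(onset_raw))
  onset$date[is.na(onset$precision) | onset$precision != "day"] <- NA

  outcomes <- lapply(strsplit(demo$outcome, ";", fixed = TRUE), function(v) {
    v <- v[!is.na(v) & nzchar(v)]
    as.character(v)
  })

  drugs <- rep(list(tibble::tibble(
    name_raw = character(0), name_canonical = character(0), role = character(0)
  )), length(ids))
  indications <- rep(list(character(0)), length(ids))
  start_date <- rep(as.Date(NA), length(ids))
  if (!is.null(drug) && nrow(drug) > 0) {
    drug$.key <- key_of(drug)
    orphan <- !(drug$.key %in% ids)
    if (any(orphan)) {
      rlang::inform(sprintf("drug.csv: %d orphan row(s) skipped", sum(orphan)))
      drug <- drug[!orphan, , drop = FALSE]
    }
    norm <- normalize_drug_name(drug$drug_name, lexicon)
    role <- dplyr::case_when(
      drug$involvement == "被疑薬" ~ "primary_suspect",
      drug$involvement == "併用薬" ~ "concomitant",
      drug$involvement == "相互作用" ~ "interacting",
      TRUE ~ "unknown"
    )
    dd <- tibble::tibble(
      key = drug$.key, name_raw = drug$drug_name,
      name_canonical = norm$canonical, role = role
    )
    split_dd <- split(dd[, -1], factor(dd$key, levels = ids))
    drugs <- lapply(split_dd, tibble::as_tibble)
    names(drugs) <- NULL
    indications <- lapply(
      split(drug$indication, factor(drug$.key, levels = ids)),
      function(v) as.character(v[nzchar(v)])
    )
    names(indications) <- NULL
    st <- parse_pv_date(drug$therapy_start_date)
    keep <- !is.na(st$precision) & st$precision == "day"
    if (any(keep)) {
      agg <- tibble::tibble(key = drug$.key[keep], date = st$date[keep]) |>
        dplyr::group_by(.data$key) |>
        dplyr::summarise(date = min(.data$date), .groups = "drop")
      start_date[match(agg$key, ids)] <- agg$date
    }
  }

  reports <- tibble::tibble(
    report_id = ids,
    case_id = demo$case_id,
    case_version = version,
    source = "JADER",
    receipt_date = receipt$date,
    receipt_precision = receipt$precision,
    sex = dplyr::coalesce(unname(sex_in[demo$sex]), "unknown"),
    age_years = age_years,
    age_group = age_group_of(age_years),
    country = "Japan",
    reporter_type = dplyr::case_when(
      demo$reporter == "医療関係者" ~ "health_professional",
      demo$reporter == "消費者等" ~ "non_health_professional",
      TRUE ~ "unknown"
    ),
    outcomes = outcomes, drugs = drugs, events = events,
    indications = indications,
    therapy_start_date = start_date,
    event_onset_date = onset$date
  )
  no_event <- lengths(reports$events) == 0
  if (any(no_event)) {
    rlang::inform(sprintf("%d demo row(s) with no reaction rows dropped", sum(no_event)))
    reports <- reports[!no_event, , drop = FALSE]
  }
  reports
}

#' Project reports onto what the JADER dialect can represent
#'
#' The JADER dialect stores age as a decade band, has no country field,
#' does not distinguish primary from secondary suspect drugs, and keys
#' records by case id + version. This helper applies exactly those
#' transformations, so that for any report set `x`,
#' `read_jader(write_jader_tables(x, d))` equals `jader_projection(x)`.
#'
#' @param reports normalized-report tibble.
#' @return projected tibble of the same shape.
#' @export
jader_projection <- function(reports) {
  mid <- jader_band_midpoint(jader_age_band(reports$age_years))
  dplyr::mutate(reports,
    report_id = paste0(.data$case_id, "-", .data$case_version),
    source = "JADER",
    country = "Japan",
    age_years = mid,
    age_group = age_group_of(mid),
    drugs = lapply(.data$drugs, function(d) {
      d$role[d$role == "secondary_suspect"] <- "primary_suspect"
      d
    })
  )
}
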