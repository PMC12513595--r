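# Descriptive surfaces: demographics, annual distribution, SOC
# distribution, time to onset, and indication strata.

count_category <- function(values, source, denominators, variable) {
  tab <- tibble::tibble(source = source, category = values) |>
    dplyr::count(.data$source, .data$category) |>
    tidyr::pivot_wider(names_from = "source", values_from = "n", values_fill = 0L)
  srcs <- names(denominators)
  for (s in srcs) if (!s %in% names(tab)) tab[[s]] <- 0L
  tab$total_n <- rowSums(as.matrix(tab[, srcs, drop = FALSE]))
  for (s in srcs) {
    tab[[paste0(s, "_pct")]] <- round_half_up(100 * tab[[s]] / denominators[[s]], 2)
  }
  tab$total_pct <- round_half_up(100 * tab$total_n / sum(denominators), 2)
  tab$variable <- variable
  dplyr::relocate(tab, "variable", "category") |>
    dplyr::rename_with(\(x) paste0(x, "_n"), dplyr::all_of(srcs)) |>
    dplyr::arrange(dplyr::desc(.data$total_n))
}

#' Demographic summary of a report corpus
#'
#' Per-category counts and percentages for sex, age group, indication
#' (top 20, remainder pooled as `"Other"`), country, outcome and
#' reporter type, split by source with a pooled column. Percentages are
#' count over the source's report count, rounded half-up to 2 decimals;
#' multi-valued variables (indication, outcome) count mentions, so their
#' percentages may exceed 100 in total. The male-to-female ratio is
#' reported to 2 decimals (`NA` when no female reports).
#'
#' @param reports deduplicated normalized-report tibble (sources may be
#'   mixed; the summary splits on the `source` column).
#' @param top_indications number of indication categories kept.
#' @return object of class `pv_demographics`: list with `table` (tidy
#'   per-category tibble), `sex_ratio`, and `n_reports` per source.
#' @export
demographic_summary <- function(reports, top_indications = 20) {
  srcs <- sort(unique(reports$source))
  denominators <- vapply(srcs, function(s) sum(reports$source == s), integer(1))
  one <- function(col, variable) {
    count_category(reports[[col]], reports$source, denominators, variable)
  }
  long_counts <- function(col, variable) {
    n_per <- lengths(reports[[col]])
    vals <- unlist(reports[[col]], use.names = FALSE)
    vals <- if (is.null(vals)) character(0) else vals
    src <- rep(reports$source, n_per)
    none <- n_per == 0
    vals <- c(vals, rep("Unknown", sum(none)))
    src <- c(src, reports$source[none])
    count_category(vals, src, denominators, variable)
  }
  ind <- long_counts("indications", "indication")
  if (nrow(ind) > top_indications) {
    keep <- ind[seq_len(top_indications), ]
    rest <- ind[-seq_len(top_indications), ]
    pooled <- rest |>
      dplyr::summarise(dplyr::across(dplyr::ends_with("_n"), sum)) |>
      dplyr::mutate(variable = "indication", category = "Other")
    for (s in srcs) {
      pooled[[paste0(s, "_pct")]] <-
        round_half_up(100 * pooled[[paste0(s, "_n")]] / denominators[[s]], 2)
    }
    pooled$total_pct <- round_half_up(100 * pooled$total_n / sum(denominators), 2)
    ind <- dplyr::bind_rows(keep, pooled)
  }
  table <- dplyr::bind_rows(
    one("sex", "sex"),
    one("age_group", "age_group"),
    ind,
    one("country", "country"),
    long_counts("outcomes", "outcome"),
    one("reporter_type", "reporter_type")
  )
  n_male <- sum(reports$sex == "male")
  n_female <- sum(reports$sex == "female")
  sex_ratio <- if (n_female > 0 && n_male > 0) {
    round_half_up(n_male / n_female, 2)
  } else {
    NA_real_
  }
  structure(
    list(table = table, sex_ratio = sex_ratio, n_reports = denominators),
    class = "pv_demographics"
  )
}

#' @export
print.pv_demographics <- function(x, ...) {
  cat(sprintf(
    "<pv_demographics> %s reports; male:female ratio %s\n",
    paste(sprintf("%s=%d", names(x$n_reports), x$n_reports), collapse = ", "),
    ifelse(is.na(x$sex_ratio), "not defined", sprintf("%.2f:1", x$sex_ratio))
  ))
  print(x$table, n = 20)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pv_demographics <- function(x, ...) x$table

#' Annual distribution of reports
#'
#' Counts reports by calendar year of the receipt date (year precision
#' suffices); reports without a receipt date are tallied under
#' `year = NA`.
#'
#' @param reports normalized-report tibble.
#' @return tibble with columns `source`, `year`, `n`.
#' @export
annual_distribution <- function(reports) {
  tibble::tibble(
    source = reports$source,
    year = as.integer(format(reports$receipt_date, "%Y"))
  ) |>
    dplyr::count(.data$source, .data$year) |>
    dplyr::arrange(.data$source, .data$year)
}

#' System-organ-class distribution of reported events
#'
#' Report-level SOC counts: a report counts once per SOC it mentions,
#' regardless of how many of its PTs fall in that SOC. Proportions are
#' over total SOC mentions. PTs absent from the dictionary accumulate
#' under `"Unmapped"`.
#'
#' @param reports normalized-report tibble.
#' @param dict PT/SOC dictionary.
#' @return tibble with columns `soc`, `n`, `prop`, sorted descending.
#' @export
soc_distribution <- function(reports, dict = read_pt_soc_dictionary()) {
  pairs <- tibble::tibble(
    report = rep(seq_len(nrow(reports)), lengths(reports$events)),
    soc = map_pt_to_soc(unlist(reports$events, use.names = FALSE), dict)
  ) |>
    dplyr::distinct()
  pairs |>
    dplyr::count(.data$soc) |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::arrange(dplyr::desc(.data$n))
}

#' Time from therapy start to event onset
#'
#' Evaluable reports carry both a day-precision therapy-start and event
#' date with onset on or after start; all others (missing, partial or
#' negative intervals) are excluded and counted. Days are binned on
#' `breaks` (default 0-7, 8-30, 31-60, 61-90, 91-180, >180).
#'
#' @param reports normalized-report tibble.
#' @param breaks upper bin edges in days (the last bin is open-ended).
#' @return object of class `pv_onset`: `n_evaluable`, `n_excluded`,
#'   `median_days`, `days` and the `bins` tibble with cumulative
#'   proportions.
#' @export
time_to_onset <- function(reports, breaks = c(7, 30, 60, 90, 180)) {
  start <- reports$therapy_start_date
  onset <- reports$event_onset_date
  days <- as.integer(onset - start)
  evaluable <- !is.na(days) & days >= 0
  days <- days[evaluable]
  labels <- c(
    paste0(c(0, utils::head(breaks, -1) + 1), "-", breaks),
    paste0(">", breaks[length(breaks)])
  )
  bin <- cut(days, c(-1, breaks, Inf), labels = labels)
  bins <- tibble::tibble(bin = factor(labels, levels = labels)) |>
    dplyr::left_join(
      tibble::tibble(bin = bin) |> dplyr::count(.data$bin),
      by = "bin"
    ) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      prop = if (length(days) > 0) .data$n / length(days) else NA_real_,
      cum_prop = cumsum(.data$prop)
    )
  structure(
    list(
      n_evaluable = length(days),
      n_excluded = nrow(reports) - length(days),
      median_days = if (length(days) > 0) median(days) else NA_real_,
      days = days,
      bins = bins
    ),
    class = "pv_onset"
  )
}

#' @export
print.pv_onset <- function(x, ...) {
  cat(sprintf(
    "<pv_onset> %d evaluable reports (%d excluded); median onset %s days\n",
    x$n_evaluable, x$n_excluded, format(x$median_days)
  ))
  print(x$bins)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pv_onset <- function(x, ...) x$bins

#' @exportS3Method generics::glance
glance.pv_onset <- function(x, ...) {
  tibble::tibble(
    n_evaluable = x$n_evaluable, n_excluded = x$n_excluded,
    median_days = x$median_days
  )
}

#' Classify indication text into tumor / non-tumor strata
#'
#' Case-folded keyword containment against an [indication_lexicon()];
#' texts matching neither list (including empty or missing text) are
#' `"unknown"`. The keyword lists are disjoint by construction; a text
#' containing keywords of both kinds classifies as tumor (malignancy
#' dominates the treatment context).
#'
#' @param text character vector of indication texts.
#' @param lexicon an [indication_lexicon()].
#' @return character vector in `{"tumor", "non_tumor", "unknown"}`.
#' @export
classify_indication <- function(text, lexicon = indication_lexicon()) {
  folded <- fold_text(text)
  match_any <- function(x, keywords) {
    hit <- rep(FALSE, length(x))
    for (kw in keywords) hit <- hit | grepl(kw, x, fixed = TRUE)
    hit
  }
  out <- rep("unknown", length(folded))
  out[match_any(folded, lexicon$non_tumor)] <- "non_tumor"
  out[match_any(folded, lexicon$tumor)] <- "tumor"
  out[is.na(text) | !nzchar(trimws(text))] <- "unknown"
  out
}

#' Report-level stratum from all indications of a report
#'
#' @param reports normalized-report tibble.
#' @param lexicon an [indication_lexicon()].
#' @return character vector, one stratum per report.
#' @export
report_stratum <- function(reports, lexicon = indication_lexicon()) {
  vapply(reports$indications, function(ind) {
    if (length(ind) == 0) {
      return("unknown")
    }
    cls <- classify_indication(ind, lexicon)
    if (any(cls == "tumor")) {
      "tumor"
    } else if (any(cls == "non_tumor")) {
      "non_tumor"
    } else {
      "unknown"
    }
  }, character(1))
}

#' Signal table for one indication stratum
#'
#' Restricts the focal-drug cohort to reports whose indications classify
#' to `stratum`; by default the comparator cells keep the full non-focal
#' corpus (set `restrict_background = TRUE` to restrict it too). Focal
#' reports of other strata are excluded entirely.
#'
#' @param reports deduplicated normalized-report tibble.
#' @param focal_drug canonical focal drug name.
#' @param stratum `"tumor"`, `"non_tumor"` or `"unknown"`.
#' @param lexicon an [indication_lexicon()].
#' @param restrict_background restrict the comparator to the stratum too.
#' @param roles drug roles that make a report focal.
#' @param ... passed on to [add_signal_stats()] (e.g. `fit`, `criteria`).
#' @return signal tibble (see [add_signal_stats()]) with a `stratum`
#'   column; empty with a warning when the stratum has no focal reports.
#' @export
stratified_signals <- function(reports, focal_drug,
                               stratum = c("tumor", "non_tumor", "unknown"),
                               lexicon = indication_lexicon(),
                               restrict_background = FALSE,
                               roles = "primary_suspect", ...) {
  stratum <- match.arg(stratum)
  focal <- report_is_focal(reports, focal_drug, roles)
  strata <- report_stratum(reports, lexicon)
  keep <- (focal & strata == stratum) |
    (!focal & (!restrict_background | strata == stratum))
  n_focal <- sum(focal & strata == stratum)
  if (n_focal == 0) {
    rlang::warn(sprintf("stratum '%s' has no focal reports", stratum))
    return(dplyr::mutate(
      build_tables(reports[!focal, , drop = FALSE][0, ], focal_drug) |>
        suppressWarnings(),
      stratum = character(0)
    ))
  }
  if (n_focal < 10) {
    rlang::warn(sprintf(
      "stratum '%s' has only %d focal report(s); estimates will be unstable",
      stratum, n_focal
    ))
  }
  tables <- build_tables(reports[keep, , drop = FALSE], focal_drug, roles = roles)
  out <- add_signal_stats(tables, ...)
  dplyr::mutate(out, stratum = stratum, .after = "drug")
}
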