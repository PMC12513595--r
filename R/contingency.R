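# Drug-event 2x2 contingency tables.
#
# The counting unit is the deduplicated report: a report contributes at
# most once to a given event, even if it lists the same PT twice (or, at
# SOC level, several PTs of the same SOC). Margins are pair-based by
# default: a+b is the number of distinct (focal report, event) pairs and
# n the corpus-wide total of such pairs, so a+b+c+d is conserved across
# events. Report-based margins (a+b = number of focal reports) are
# available as a switch.

report_is_focal <- function(reports, focal_drug, roles) {
  purrr::map_lgl(reports$drugs, function(d) {
    any(d$name_canonical == focal_drug & d$role %in% roles)
  })
}

#' Build 2x2 tables for every observed event
#'
#' For each event observed at least once in the corpus: `a` counts focal
#' reports mentioning the event, `b` the remaining focal margin, and
#' `c`, `d` the same cells over non-focal reports.
#'
#' @param reports deduplicated normalized-report tibble (the whole
#'   corpus, focal and comparator reports together).
#' @param focal_drug canonical name of the focal drug.
#' @param level `"pt"` (events are preferred terms) or `"soc"` (events
#'   are system organ classes via `dict`).
#' @param dict PT/SOC dictionary, required when `level = "soc"`.
#' @param margins `"pairs"` (default: margins are distinct report-event
#'   pairs) or `"reports"` (margins are report counts).
#' @param roles drug roles that make a report focal.
#' @return tibble with columns `drug`, `event`, `level`, `a`, `b`, `c`,
#'   `d`, `n`, sorted by decreasing `a`.
#' @export
build_tables <- function(reports, focal_drug,
                         level = c("pt", "soc"), dict = NULL,
                         margins = c("pairs", "reports"),
                         roles = "primary_suspect") {
  level <- match.arg(level)
  margins <- match.arg(margins)
  focal <- report_is_focal(reports, focal_drug, roles)
  if (!any(focal)) {
    rlang::warn(sprintf("no focal reports for drug '%s'", focal_drug))
    return(tibble::tibble(
      drug = character(0), event = character(0), level = character(0),
      a = integer(0), b = integer(0), c = integer(0), d = integer(0),
      n = integer(0)
    ))
  }
  pairs <- tibble::tibble(
    report = rep(seq_len(nrow(reports)), lengths(reports$events)),
    event = unlist(reports$events, use.names = FALSE)
  )
  if (level == "soc") {
    if (is.null(dict)) rlang::abort("level = 'soc' needs a PT/SOC dictionary")
    pairs$event <- map_pt_to_soc(pairs$event, dict)
  }
  pairs <- dplyr::distinct(pairs)
  pairs$focal <- focal[pairs$report]

  counts <- pairs |>
    dplyr::count(.data$event, .data$focal) |>
    tidyr::pivot_wider(
      names_from = "focal", values_from = "n",
      values_fill = 0L, names_prefix = "f"
    )
  if (!"fTRUE" %in% names(counts)) counts$fTRUE <- 0L
  if (!"fFALSE" %in% names(counts)) counts$fFALSE <- 0L

  if (margins == "pairs") {
    m_focal <- sum(pairs$focal)
    m_other <- sum(!pairs$focal)
  } else {
    m_focal <- sum(focal)
    m_other <- sum(!focal)
  }
  counts |>
    dplyr::transmute(
      drug = focal_drug,
      event = .data$event,
      level = level,
      a = as.integer(.data$fTRUE),
      b = as.integer(m_focal - .data$fTRUE),
      c = as.integer(.data$fFALSE),
      d = as.integer(m_other - .data$fFALSE),
      n = .data$a + .data$b + .data$c + .data$d
    ) |>
    dplyr::arrange(dplyr::desc(.data$a), .data$event)
}

#' Aggregate to system-organ-class tables
#'
#' SOC-level cells are report-level unions — a report with several PTs of
#' one SOC counts once toward that SOC — so they are recomputed from the
#' reports rather than summed over PT-level tables (which would
#' double-count such reports).
#'
#' @inheritParams build_tables
#' @return SOC-level contingency tibble (see [build_tables()]).
#' @export
aggregate_to_soc <- function(reports, dict, focal_drug,
                             margins = c("pairs", "reports"),
                             roles = "primary_suspect") {
  build_tables(reports, focal_drug,
    level = "soc", dict = dict,
    margins = margins, roles = roles
  )
}
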