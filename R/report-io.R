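# Case deduplication and suspect-drug selection on normalized reports.

#' Deduplication policy
#'
#' Duplicates are records sharing a case id. The keep rule is a total
#' order: highest case version, then latest receipt date, then
#' lexicographically largest report id — the standard
#' keep-the-latest-version rule for spontaneous-report databases.
#'
#' @param key grouping key (only `"case_id"` is supported).
#' @param keep character vector giving the tie-break order; a permutation
#'   of `c("case_version", "receipt_date", "report_id")`.
#' @return a `dedup_policy` list.
#' @export
dedup_policy <- function(key = "case_id",
                         keep = c("case_version", "receipt_date", "report_id")) {
  if (!identical(key, "case_id")) rlang::abort("only key = 'case_id' is supported")
  if (!setequal(keep, c("case_version", "receipt_date", "report_id"))) {
    rlang::abort("keep must order case_version, receipt_date and report_id")
  }
  structure(list(key = key, keep = keep), class = "dedup_policy")
}

#' Deduplicate reports to one record per case
#'
#' Keeps exactly one report per case id, chosen by the policy's total
#' order (descending on each key in turn; missing receipt dates sort
#' last). Idempotent; the input is not modified.
#'
#' @param reports normalized-report tibble.
#' @param policy a [dedup_policy()].
#' @return tibble with one row per distinct case id, in first-occurrence
#'   order of the input.
#' @export
deduplicate <- function(reports, policy = dedup_policy()) {
  stopifnot(inherits(policy, "dedup_policy"))
  if (nrow(reports) == 0) {
    return(reports)
  }
  reports |>
    dplyr::mutate(.orig_row = dplyr::row_number()) |>
    dplyr::arrange(dplyr::across(
      dplyr::all_of(policy$keep),
      \(x) dplyr::desc(x)
    )) |>
    dplyr::distinct(.data$case_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$.orig_row) |>
    dplyr::select(-".orig_row")
}

#' Select reports naming a drug as suspect
#'
#' Keeps reports in which `canonical_drug` appears with one of the given
#' roles. The default counts only the primary suspect; widen `roles` to
#' include `"secondary_suspect"` for the broader reading.
#'
#' @param reports normalized-report tibble (drug names canonicalized).
#' @param canonical_drug canonical drug name to select on.
#' @param roles drug roles that qualify.
#' @return the qualifying subset of `reports`.
#' @export
filter_suspect <- function(reports, canonical_drug,
                           roles = "primary_suspect") {
  hit <- purrr::map_lgl(reports$drugs, function(d) {
    any(d$name_canonical == canonical_drug & d$role %in% roles)
  })
  seen <- purrr::map_lgl(reports$drugs, function(d) {
    any(d$name_canonical == canonical_drug)
  })
  if (!any(seen)) {
    rlang::warn(sprintf(
      "drug '%s' does not appear in any report; empty result", canonical_drug
    ))
  }
  reports[hit, , drop = FALSE]
}
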