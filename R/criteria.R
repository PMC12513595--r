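# Conjunctive positive-signal criteria and the ranked signal surface.

#' Positive-signal criteria
#'
#' The default conjunction: count `a >= 3`, ROR 95% CI lower bound `> 1`,
#' `PRR > 2`, `IC > 0`, `IC - 2SD > 0` and `EBGM05 > 2`. A statistic that
#' is not evaluable (zero cells without continuity correction) vetoes the
#' flag rather than being imputed.
#'
#' @param min_count minimum focal count `a`.
#' @param ror_ci_low,prr,ic,ic025,ebgm05 thresholds (each exceeded
#'   strictly).
#' @return a `signal_criteria` list.
#' @export
signal_criteria <- function(min_count = 3, ror_ci_low = 1, prr = 2,
                            ic = 0, ic025 = 0, ebgm05 = 2) {
  vals <- c(min_count, ror_ci_low, prr, ic, ic025, ebgm05)
  if (any(!is.finite(vals))) rlang::abort("criteria thresholds must be finite")
  structure(
    list(
      min_count = min_count, ror_ci_low = ror_ci_low, prr = prr,
      ic = ic, ic025 = ic025, ebgm05 = ebgm05
    ),
    class = "signal_criteria"
  )
}

#' Evaluate the signal criteria on computed records
#'
#' @param records data frame with columns `a`, `ror_ci_low`, `prr`, `ic`,
#'   `ic025`, `ebgm05` (as produced by [add_signal_stats()]).
#' @param criteria a [signal_criteria()].
#' @return logical vector, `FALSE` wherever any statistic is missing.
#' @export
evaluate_criteria <- function(records, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  check_columns(
    records, c("a", "ror_ci_low", "prr", "ic", "ic025", "ebgm05"),
    "signal records"
  )
  ok <- records$a >= criteria$min_count &
    records$ror_ci_low > criteria$ror_ci_low &
    records$prr > criteria$prr &
    records$ic > criteria$ic &
    records$ic025 > criteria$ic025 &
    records$ebgm05 > criteria$ebgm05
  ok & !is.na(ok)
}

#' Compute all four disproportionality statistics on contingency tables
#'
#' Adds ROR with its Wald interval, PRR with chi-squared, the BCPNN
#' information component with its `IC - 2SD` bound, the expected count
#' `E = (a+b)(a+c)/n`, EBGM/EBGM05 under the (supplied or freshly
#' fitted) gamma-mixture prior, and the conjunctive `flagged` column.
#'
#' @param tables contingency tibble from [build_tables()].
#' @param fit optional `mgps_fit`; when `NULL` the hyperparameters are
#'   fitted on the pairs of `tables` via [mgps_pairs()] and [fit_mgps()].
#' @param priors BCPNN prior pseudo-counts.
#' @param criteria positive-signal thresholds.
#' @param correction Haldane-Anscombe continuity correction for the ROR
#'   on zero-cell tables.
#' @param yates Yates-corrected chi-squared.
#' @param include_comparator when fitting internally, also use the
#'   comparator cells (see [mgps_pairs()]).
#' @return `tables` with the statistic columns and `flagged` appended;
#'   the fitted `mgps_fit` is attached as attribute `"mgps_fit"`.
#' @export
add_signal_stats <- function(tables, fit = NULL,
                             priors = bcpnn_priors(),
                             criteria = signal_criteria(),
                             correction = FALSE, yates = TRUE,
                             include_comparator = TRUE) {
  check_columns(tables, c("a", "b", "c", "d", "n"), "contingency tables")
  if (nrow(tables) == 0) {
    return(dplyr::mutate(tables, flagged = logical(0)))
  }
  if (is.null(fit)) {
    fit <- fit_mgps(mgps_pairs(tables, include_comparator = include_comparator))
  }
  if (!isTRUE(fit$converged)) {
    rlang::warn("MGPS fit did not converge; EBGM columns set to NA")
  }
  out <- dplyr::bind_cols(
    tables,
    ror_stats(tables$a, tables$b, tables$c, tables$d, correction = correction),
    prr_stats(tables$a, tables$b, tables$c, tables$d, yates = yates),
    ic_stats(tables$a, tables$b, tables$c, tables$d, priors = priors)
  )
  out$expected <- (as.numeric(tables$a) + tables$b) *
    (as.numeric(tables$a) + tables$c) / as.numeric(tables$n)
  if (isTRUE(fit$converged)) {
    eb <- ebgm_stats(tables$a, out$expected, fit)
    out$ebgm <- eb$ebgm
    out$ebgm05 <- eb$ebgm05
  } else {
    out$ebgm <- NA_real_
    out$ebgm05 <- NA_real_
  }
  out$flagged <- evaluate_criteria(out, criteria)
  attr(out, "mgps_fit") <- fit
  out
}

#' Rank signal records for reporting
#'
#' Reproduces the top-N surface: drops records with fewer than
#' `min_count` focal reports, drops events matching the treated
#' indications or disease-progression terms, sorts descending by the
#' chosen key (the other key breaking ties) and truncates to `top_n`.
#'
#' @param records signal tibble from [add_signal_stats()].
#' @param by primary sort key: `"ror"` or `"count"`.
#' @param top_n number of rows returned.
#' @param exclude_events event names to drop (typically the treated
#'   indications, which trivially co-report with the drug).
#' @param progression_terms disease-progression event names to drop.
#' @param min_count minimum focal count retained.
#' @param flagged_only keep only records passing the signal criteria.
#' @return ranked tibble of at most `top_n` rows.
#' @export
rank_signals <- function(records, by = c("ror", "count"), top_n = 30,
                         exclude_events = character(0),
                         progression_terms = c(
                           "Disease progression",
                           "Malignant neoplasm progression",
                           "Neoplasm progression"
                         ),
                         min_count = 3, flagged_only = FALSE) {
  by <- match.arg(by)
  drop <- fold_text(c(exclude_events, progression_terms))
  out <- records |>
    dplyr::filter(
      .data$a >= min_count,
      !(fold_text(.data$event) %in% drop)
    )
  if (flagged_only && "flagged" %in% names(out)) {
    out <- dplyr::filter(out, .data$flagged)
  }
  if (by == "ror") {
    out <- dplyr::arrange(out, dplyr::desc(.data$ror), dplyr::desc(.data$a))
  } else {
    out <- dplyr::arrange(out, dplyr::desc(.data$a), dplyr::desc(.data$ror))
  }
  utils::head(out, top_n)
}
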