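# End-to-end orchestration: ingest -> dedup -> contingency -> statistics
# -> criteria -> ranking -> profiling, with a run manifest.

#' Configure a pipeline run
#'
#' Paths are validated here (before any compute); thresholds and ranking
#' options are carried to the relevant stages.
#'
#' @param input_dir directory with the report tables.
#' @param source input dialect, `"FAERS"` or `"JADER"`.
#' @param focal_drug canonical focal drug name.
#' @param out_dir output directory (created on run).
#' @param lexicon_path,dict_path optional paths overriding the shipped
#'   drug lexicon and PT/SOC dictionary.
#' @param criteria a [signal_criteria()].
#' @param priors a [bcpnn_priors()].
#' @param top_n,by ranking options (see [rank_signals()]).
#' @param exclude_indications event names excluded from rankings;
#'   `NULL` derives the list from the focal cohort's recorded indications.
#' @param correction,yates statistic switches (see [add_signal_stats()]).
#' @param stratify also compute tumor / non-tumor stratified signal
#'   tables.
#' @param roles drug roles that make a report focal.
#' @param seed integer seed echoed into the manifest (the pipeline
#'   itself is deterministic).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, source = c("FAERS", "JADER"),
                            focal_drug = "obinutuzumab",
                            out_dir = tempfile("pvrun"),
                            lexicon_path = NULL, dict_path = NULL,
                            criteria = signal_criteria(),
                            priors = bcpnn_priors(),
                            top_n = 30, by = c("ror", "count"),
                            exclude_indications = NULL,
                            correction = FALSE, yates = TRUE,
                            stratify = FALSE,
                            roles = "primary_suspect",
                            seed = 1L) {
  source <- match.arg(source)
  by <- match.arg(by)
  if (!dir.exists(input_dir)) {
    rlang::abort(sprintf("input directory '%s' does not exist", input_dir))
  }
  for (p in c(lexicon_path, dict_path)) {
    if (!is.null(p) && !file.exists(p)) {
      rlang::abort(sprintf("configured path '%s' does not exist", p))
    }
  }
  stopifnot(inherits(criteria, "signal_criteria"), inherits(priors, "bcpnn_priors"))
  structure(
    list(
      input_dir = input_dir, source = source, focal_drug = focal_drug,
      out_dir = out_dir, lexicon_path = lexicon_path, dict_path = dict_path,
      criteria = criteria, priors = priors, top_n = top_n, by = by,
      exclude_indications = exclude_indications,
      correction = correction, yates = yates, stratify = stratify,
      roles = roles, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

write_stage_csv <- function(x, dir, name) {
  readr::write_csv(x, file.path(dir, paste0(name, ".csv")), na = "")
}

#' Run the signal-mining pipeline end to end
#'
#' Executes ingest, deduplication, suspect selection, contingency
#' building (PT and SOC level), the four disproportionality statistics
#' with the conjunctive criteria, ranked surfaces, and profiling
#' (demographics, annual distribution, SOC distribution, time to onset,
#' optional indication strata). All outputs plus a run manifest (config
#' echo, package version, seed, per-stage row counts) are written under
#' `config$out_dir`. Identical config and inputs give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return list with the in-memory results (`reports`, `signals_pt`,
#'   `signals_soc`, `ranked`, `profile`, `manifest`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  lexicon <- read_drug_lexicon(config$lexicon_path)
  dict <- read_pt_soc_dictionary(config$dict_path)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  counts <- list()

  raw <- stage("ingest", if (config$source == "FAERS") {
    read_faers_quarter(config$input_dir, lexicon)
  } else {
    read_jader(config$input_dir, lexicon)
  })
  counts$reports_read <- nrow(raw)

  reports <- stage("deduplicate", deduplicate(raw))
  counts$reports_deduplicated <- nrow(reports)

  focal <- stage(
    "filter_suspect",
    filter_suspect(reports, config$focal_drug, config$roles)
  )
  counts$focal_reports <- nrow(focal)

  tables_pt <- stage(
    "contingency_pt",
    build_tables(reports, config$focal_drug, level = "pt", roles = config$roles)
  )
  tables_soc <- stage(
    "contingency_soc",
    aggregate_to_soc(reports, dict, config$focal_drug, roles = config$roles)
  )
  counts$pt_pairs <- nrow(tables_pt)
  counts$soc_pairs <- nrow(tables_soc)

  fit <- stage("mgps_fit", fit_mgps(mgps_pairs(tables_pt)))
  signals_pt <- stage("signal_stats_pt", add_signal_stats(
    tables_pt,
    fit = fit, priors = config$priors, criteria = config$criteria,
    correction = config$correction, yates = config$yates
  ))
  signals_soc <- stage("signal_stats_soc", add_signal_stats(
    tables_soc,
    fit = fit, priors = config$priors, criteria = config$criteria,
    correction = config$correction, yates = config$yates
  ))
  counts$flagged_pt <- sum(signals_pt$flagged)
  counts$flagged_soc <- sum(signals_soc$flagged)

  exclusions <- config$exclude_indications %||%
    unique(unlist(focal$indications, use.names = FALSE))
  ranked <- list(
    by_ror = rank_signals(signals_pt,
      by = "ror", top_n = config$top_n,
      exclude_events = exclusions, flagged_only = TRUE
    ),
    by_count = rank_signals(signals_pt,
      by = "count", top_n = config$top_n,
      exclude_events = exclusions, flagged_only = TRUE
    )
  )

  profile <- stage("profiling", list(
    demographics = demographic_summary(reports),
    annual = annual_distribution(reports),
    soc = soc_distribution(focal, dict),
    onset = time_to_onset(focal)
  ))
  if (config$stratify) {
    profile$stratified <- dplyr::bind_rows(
      stratified_signals(reports, config$focal_drug,
        stratum = "tumor",
        fit = fit, priors = config$priors, criteria = config$criteria
      ),
      stratified_signals(reports, config$focal_drug,
        stratum = "non_tumor",
        fit = fit, priors = config$priors, criteria = config$criteria
      )
    )
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("pvsignals")),
    seed = config$seed,
    source = config$source,
    focal_drug = config$focal_drug,
    dictionary_version = attr(dict, "version"),
    criteria = unclass(config$criteria),
    stage_counts = counts
  )

  write_stage_csv(signals_pt, config$out_dir, "signals_pt")
  write_stage_csv(signals_soc, config$out_dir, "signals_soc")
  write_stage_csv(ranked$by_ror, config$out_dir, "top_by_ror")
  write_stage_csv(ranked$by_count, config$out_dir, "top_by_count")
  write_stage_csv(profile$demographics$table, config$out_dir, "demographics")
  write_stage_csv(profile$annual, config$out_dir, "annual_distribution")
  write_stage_csv(profile$soc, config$out_dir, "soc_distribution")
  write_stage_csv(profile$onset$bins, config$out_dir, "onset_bins")
  if (!is.null(profile$stratified)) {
    write_stage_csv(profile$stratified, config$out_dir, "signals_stratified")
  }
  jsonlite::write_json(
    manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  jsonlite::write_json(
    signals_pt, file.path(config$out_dir, "signals_pt.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  invisible(list(
    reports = reports, signals_pt = signals_pt, signals_soc = signals_soc,
    ranked = ranked, profile = profile, manifest = manifest, mgps_fit = fit
  ))
}
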