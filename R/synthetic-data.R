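# Synthetic spontaneous-report generator.
#
# Builds a reporting universe with known ground truth: a background
# population of reports over a PT catalogue with baseline reporting
# weights, a focal-drug cohort in which chosen PTs are injected at a
# known relative reporting rate, duplicate case versions, partially
# missing dates, configurable demographic mixes and a Weibull
# time-to-onset. Every downstream stage of the pipeline is testable
# against the returned ground truth without any external data.

#' Specify one injected signal
#'
#' @param pt_name PT to inject; must exist in the catalogue.
#' @param relative_rate multiplier (> 0) applied to the PT's baseline
#'   reporting weight within the focal-drug cohort, before the weight
#'   vector is renormalized.
#' @param stratum optional indication stratum restriction: `"tumor"` or
#'   `"non_tumor"` injects only into focal reports whose indication
#'   classifies to that stratum; `NA` (default) injects into all focal
#'   reports.
#' @return a `signal_spec` list.
#' @export
signal_spec <- function(pt_name, relative_rate, stratum = NA_character_) {
  stopifnot(is.character(pt_name), length(pt_name) == 1)
  if (!is.numeric(relative_rate) || relative_rate <= 0) {
    rlang::abort("relative_rate must be a positive number")
  }
  if (!is.na(stratum) && !stratum %in% c("tumor", "non_tumor")) {
    rlang::abort("stratum must be NA, 'tumor' or 'non_tumor'")
  }
  structure(
    list(pt_name = pt_name, relative_rate = relative_rate, stratum = stratum),
    class = "signal_spec"
  )
}

#' Default PT catalogue
#'
#' Derived from the shipped PT/SOC dictionary with Zipf-decaying baseline
#' reporting weights, normalised to sum to one.
#'
#' @param dict dictionary tibble from [read_pt_soc_dictionary()].
#' @return tibble with columns `pt_name`, `soc_name`, `baseline_probability`.
#' @export
default_pt_catalog <- function(dict = read_pt_soc_dictionary()) {
  w <- 1 / seq_len(nrow(dict))
  tibble::tibble(
    pt_name = dict$pt,
    soc_name = dict$soc,
    baseline_probability = w / sum(w)
  )
}

check_mix <- function(mix, what) {
  if (is.null(names(mix)) || any(names(mix) == "")) {
    rlang::abort(sprintf("%s must be a named probability vector", what))
  }
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
    rlang::abort(sprintf("%s must be non-negative and sum to 1 (got %.12f)", what, sum(mix)))
  }
  mix
}

#' Configure a synthetic reporting universe
#'
#' Defaults emulate a mid-sized FAERS-like corpus for an anti-CD20
#' antibody: demographic and indication mixes follow the published
#' report-level shares for such a cohort, receipt dates are uniform over
#' `year_range`, and onset follows a Weibull with median 14 days.
#'
#' @param n_background_reports,n_drug_reports report counts for the
#'   comparator universe and the focal-drug cohort.
#' @param pt_catalog tibble `(pt_name, soc_name, baseline_probability)`;
#'   baseline probabilities must lie in (0,1).
#' @param signals list of [signal_spec()] objects (ground-truth injections).
#' @param mean_pts_per_report mean of the Poisson number of distinct PTs
#'   per report (floored at 1).
#' @param duplicate_fraction fraction (in `[0,1)`) of unique cases
#'   re-emitted as a later case version.
#' @param missing_date_fraction fraction of reports losing either the
#'   therapy-start or the event-onset date.
#' @param sex_mix,age_mix,country_mix,reporter_mix,outcome_mix named
#'   probability vectors (each summing to 1). The outcome category
#'   `"none"` yields a report with no outcome codes.
#' @param indication_mix named probability vector over indication texts.
#' @param tto_shape,tto_scale Weibull time-to-onset parameters (days).
#' @param focal_drug canonical name of the focal drug.
#' @param background_drugs suspect-drug names used by background reports.
#' @param year_range two calendar years bounding receipt dates.
#' @param source dialect tag stored on the reports (`"FAERS"` or `"JADER"`).
#' @param seed integer seed; identical configs give identical universes.
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(
    n_background_reports = 20000,
    n_drug_reports = 2000,
    pt_catalog = default_pt_catalog(),
    signals = list(
      signal_spec("Infusion related reaction", 25),
      signal_spec("Myelosuppression", 20),
      signal_spec("Tumour lysis syndrome", 15),
      signal_spec("Cytomegalovirus infection", 8)
    ),
    mean_pts_per_report = 2.5,
    duplicate_fraction = 0.05,
    missing_date_fraction = 0.30,
    sex_mix = c(male = 0.50, female = 0.36, unknown = 0.14),
    age_mix = c("<18" = 0.005, "18-65" = 0.345, ">65" = 0.40, unknown = 0.25),
    country_mix = c(
      "United States" = 0.30, Japan = 0.29, China = 0.08,
      France = 0.05, Germany = 0.05, Other = 0.23
    ),
    reporter_mix = c(
      health_professional = 0.94, non_health_professional = 0.055,
      unknown = 0.005
    ),
    outcome_mix = c(HO = 0.30, DE = 0.10, LT = 0.04, DS = 0.01, OT = 0.29, none = 0.26),
    indication_mix = c(
      "Follicular lymphoma" = 0.32,
      "Chronic lymphocytic leukaemia" = 0.29,
      "B-cell lymphoma" = 0.08,
      "Diffuse large B-cell lymphoma" = 0.05,
      "Mantle cell lymphoma" = 0.02,
      "Waldenstrom's macroglobulinaemia" = 0.01,
      "Lupus nephritis" = 0.03,
      "Glomerulonephritis membranous" = 0.02,
      "Nephrotic syndrome" = 0.01,
      "Systemic lupus erythematosus" = 0.01,
      "Unknown" = 0.16
    ),
    tto_shape = 0.8,
    tto_scale = 22.2,
    focal_drug = "obinutuzumab",
    background_drugs = c(
      "rituximab", "ibrutinib", "venetoclax", "bendamustine", "methotrexate"
    ),
    year_range = c(2016, 2025),
    source = c("FAERS", "JADER"),
    seed = 1L) {
  source <- match.arg(source)
  if (nrow(pt_catalog) == 0) rlang::abort("PT catalogue is empty")
  check_columns(pt_catalog, c("pt_name", "soc_name", "baseline_probability"), "pt_catalog")
  if (any(pt_catalog$baseline_probability <= 0) ||
    any(pt_catalog$baseline_probability >= 1)) {
    rlang::abort("baseline probabilities must lie in (0, 1)")
  }
  stopifnot(
    n_background_reports >= 0, n_drug_reports >= 0,
    mean_pts_per_report > 0, tto_shape > 0, tto_scale > 0
  )
  if (duplicate_fraction < 0 || duplicate_fraction >= 1) {
    rlang::abort("duplicate_fraction must be in [0, 1)")
  }
  if (missing_date_fraction < 0 || missing_date_fraction > 1) {
    rlang::abort("missing_date_fraction must be in [0, 1]")
  }
  for (nm in c("sex_mix", "age_mix", "country_mix", "reporter_mix", "outcome_mix", "indication_mix")) {
    check_mix(get(nm), nm)
  }
  signals <- lapply(signals, function(s) {
    if (!inherits(s, "signal_spec")) rlang::abort("signals must be signal_spec objects")
    if (!s$pt_name %in% pt_catalog$pt_name) {
      rlang::abort(sprintf("signal PT '%s' is not in the catalogue", s$pt_name))
    }
    base <- pt_catalog$baseline_probability[pt_catalog$pt_name == s$pt_name]
    if (base * s$relative_rate > 1) {
      rlang::abort(sprintf(
        "relative_rate %.3g pushes PT '%s' above probability 1 before renormalization",
        s$relative_rate, s$pt_name
      ))
    }
    s
  })
  structure(
    list(
      n_background_reports = as.integer(n_background_reports),
      n_drug_reports = as.integer(n_drug_reports),
      pt_catalog = pt_catalog, signals = signals,
      mean_pts_per_report = mean_pts_per_report,
      duplicate_fraction = duplicate_fraction,
      missing_date_fraction = missing_date_fraction,
      sex_mix = sex_mix, age_mix = age_mix, country_mix = country_mix,
      reporter_mix = reporter_mix, outcome_mix = outcome_mix,
      indication_mix = indication_mix,
      tto_shape = tto_shape, tto_scale = tto_scale,
      focal_drug = focal_drug, background_drugs = background_drugs,
      year_range = as.integer(year_range), source = source,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# focal-cohort PT weight vector for one stratum: multiply injected PTs'
# baselines by their relative rate, then renormalize the whole vector so
# the per-report PT-count distribution stays fixed
injected_weights <- function(config, stratum) {
  w <- config$pt_catalog$baseline_probability
  names(w) <- config$pt_catalog$pt_name
  for (s in config$signals) {
    applies <- is.na(s$stratum) || identical(s$stratum, stratum)
    if (applies) w[s$pt_name] <- w[s$pt_name] * s$relative_rate
  }
  w / sum(w)
}

# Weighted sampling without replacement for many reports at once via the
# exponential-race construction: item j's key is Exp(1)/w_j and the k
# smallest keys are the sample, which reproduces successive sampling
# proportional to the weights. Processed in row chunks to bound memory.
sample_pts_race <- function(weights, k, chunk_rows = 20000L) {
  n <- length(k)
  p <- length(weights)
  out <- vector("list", ceiling(n / chunk_rows))
  for (ci in seq_along(out)) {
    rows <- ((ci - 1L) * chunk_rows + 1L):min(ci * chunk_rows, n)
    m <- length(rows)
    kc <- k[rows]
    keys <- matrix(rexp(m * p) / rep(weights, each = m), m, p)
    sel <- matrix(NA_integer_, m, max(kc))
    for (j in seq_len(max(kc))) {
      act <- which(kc >= j)
      if (length(act) == 0) break
      mc <- max.col(-keys, ties.method = "first")
      sel[cbind(act, j)] <- mc[act]
      keys[cbind(act, mc[act])] <- Inf
    }
    tsel <- t(sel)
    out[[ci]] <- tsel[!is.na(tsel)]
  }
  unlist(out, use.names = FALSE)
}

# chop a vector or data frame into a list aligned to per-report sizes
chop_by_size <- function(x, sizes) {
  idx <- split(seq_len(sum(sizes)), rep(seq_along(sizes), sizes))
  names(idx) <- NULL
  vctrs::vec_chop(x, indices = idx)
}

sample_ages <- function(groups) {
  n <- length(groups)
  out <- rep(NA_real_, n)
  i <- groups == "<18"
  out[i] <- sample(1:17, sum(i), replace = TRUE)
  i <- groups == "18-65"
  out[i] <- sample(18:65, sum(i), replace = TRUE)
  i <- groups == ">65"
  out[i] <- sample(66:90, sum(i), replace = TRUE)
  out
}

#' Generate a synthetic reporting universe
#'
#' Draws `n_background_reports + n_drug_reports` unique cases, injects
#' the configured signals into the focal cohort, then re-emits a
#' `duplicate_fraction` of cases as a later case version (same case id,
#' version + 1, later receipt date) so that the keep-latest-version
#' deduplication rule is the unique correct behaviour. Identical configs
#' (including seed) produce identical output.
#'
#' @param config a [generator_config()].
#' @return list of class `pv_universe` with elements
#'   * `reports`: normalized-report tibble (one row per emitted record,
#'     duplicates included),
#'   * `ground_truth`: list with `injected_pts`, per-PT `expected` counts
#'     under a binomial approximation, the stratum shares, and bookkeeping
#'     counts (`n_unique_cases`, `n_duplicates`).
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  nb <- config$n_background_reports
  nd <- config$n_drug_reports
  n <- nb + nd
  if (n == 0) rlang::abort("config generates zero reports")
  cat_pts <- config$pt_catalog$pt_name
  lexicon <- read_drug_lexicon()

  is_focal <- c(rep(FALSE, nb), rep(TRUE, nd))
  case_id <- sprintf("%08d", 10000000L + seq_len(n))
  report_id <- paste0(case_id, "01")

  sex <- sample(names(config$sex_mix), n, TRUE, config$sex_mix)
  age_grp_drawn <- sample(names(config$age_mix), n, TRUE, config$age_mix)
  age_years <- sample_ages(age_grp_drawn)
  country <- sample(names(config$country_mix), n, TRUE, config$country_mix)
  reporter <- sample(names(config$reporter_mix), n, TRUE, config$reporter_mix)
  outcome_draw <- sample(names(config$outcome_mix), n, TRUE, config$outcome_mix)
  outcomes <- lapply(outcome_draw, function(o) if (o == "none") character(0) else o)
  indication <- sample(names(config$indication_mix), n, TRUE, config$indication_mix)

  # stratum-specific focal weight vectors (background keeps baselines)
  ind_lex <- indication_lexicon()
  stratum <- classify_indication(indication, ind_lex)
  w_bg <- config$pt_catalog$baseline_probability / sum(config$pt_catalog$baseline_probability)
  w_focal <- list(
    tumor = injected_weights(config, "tumor"),
    non_tumor = injected_weights(config, "non_tumor"),
    unknown = injected_weights(config, "unknown")
  )

  k <- pmin(pmax(1L, rpois(n, config$mean_pts_per_report)), length(cat_pts))
  # one weight class per report: background, or focal by stratum
  class_of <- ifelse(is_focal, paste0("focal_", stratum), "background")
  weight_of <- c(
    list(background = w_bg),
    setNames(w_focal, paste0("focal_", names(w_focal)))
  )
  events <- vector("list", n)
  for (cls in unique(class_of)) {
    rows <- which(class_of == cls)
    idx_long <- sample_pts_race(weight_of[[cls]], k[rows])
    events[rows] <- chop_by_size(cat_pts[idx_long], k[rows])
  }

  # dates: receipt uniform over the year range; onset precedes the report
  # by a short filing delay; therapy start = onset - Weibull time-to-onset
  d0 <- as.Date(sprintf("%d-01-01", config$year_range[1]))
  d1 <- as.Date(sprintf("%d-12-31", config$year_range[2]))
  receipt <- d0 + sample.int(as.integer(d1 - d0) + 1L, n, replace = TRUE) - 1L
  onset <- receipt - sample(0:30, n, replace = TRUE)
  tto_days <- round(rweibull(n, config$tto_shape, config$tto_scale))
  start <- onset - tto_days
  lose <- runif(n) < config$missing_date_fraction
  lose_start <- lose & runif(n) < 0.5
  lose_onset <- lose & !lose_start
  start[lose_start] <- NA
  onset[lose_onset] <- NA

  # drugs: one primary suspect; ~30% of reports add a concomitant
  suspect_raw <- ifelse(is_focal, config$focal_drug,
    sample(config$background_drugs, n, replace = TRUE)
  )
  conco_raw <- sample(config$background_drugs, n, replace = TRUE)
  has_conco <- runif(n) < 0.30 & conco_raw != suspect_raw
  sizes <- 1L + has_conco
  rep_idx <- c(seq_len(n), which(has_conco))
  rank_in_report <- c(rep(1L, n), rep(2L, sum(has_conco)))
  ord <- order(rep_idx, rank_in_report)
  raw_long <- c(suspect_raw, conco_raw[has_conco])[ord]
  role_long <- c(rep("primary_suspect", n), rep("concomitant", sum(has_conco)))[ord]
  drug_long <- tibble::tibble(
    name_raw = raw_long,
    name_canonical = normalize_drug_name(raw_long, lexicon)$canonical,
    role = role_long
  )
  drugs <- chop_by_size(drug_long, sizes)

  reports <- tibble::tibble(
    report_id = report_id, case_id = case_id, case_version = 1L,
    source = config$source,
    receipt_date = receipt, receipt_precision = "day",
    sex = sex, age_years = age_years, age_group = age_group_of(age_years),
    country = if (config$source == "JADER") "Japan" else country,
    reporter_type = reporter,
    outcomes = outcomes, drugs = drugs, events = events,
    indications = as.list(indication),
    therapy_start_date = start, event_onset_date = onset
  )

  # duplicate injection: exact copies, version + 1, later receipt date
  n_dup <- round(config$duplicate_fraction * n)
  if (n_dup > 0) {
    idx <- sample.int(n, n_dup, replace = FALSE)
    dup <- reports[idx, ]
    dup$case_version <- 2L
    dup$report_id <- paste0(dup$case_id, "02")
    dup$receipt_date <- dup$receipt_date + sample(1:90, n_dup, replace = TRUE)
    reports <- dplyr::bind_rows(reports, dup)
  }

  # binomial ground truth: E[count of PT in cohort] ~ n_reports * m_eff * p
  # where m_eff = E[max(1, Poisson(mean))] = mean + exp(-mean)
  lambda <- config$mean_pts_per_report
  m_eff <- lambda + exp(-lambda)
  strat_share <- vapply(
    c("tumor", "non_tumor", "unknown"),
    function(s) {
      sum(config$indication_mix[classify_indication(names(config$indication_mix), ind_lex) == s])
    },
    numeric(1)
  )
  p_focal_marginal <- Reduce(`+`, Map(
    function(s, sh) w_focal[[s]] * sh,
    names(strat_share), strat_share
  ))
  expected <- tibble::tibble(
    pt_name = cat_pts,
    soc_name = config$pt_catalog$soc_name,
    p_background = as.numeric(w_bg),
    p_focal = as.numeric(p_focal_marginal),
    expected_a = nd * m_eff * as.numeric(p_focal_marginal),
    expected_c = nb * m_eff * as.numeric(w_bg)
  )
  ground_truth <- list(
    injected_pts = unique(vapply(config$signals, `[[`, character(1), "pt_name")),
    expected = expected,
    stratum_share = strat_share,
    mean_pts_effective = m_eff,
    expected_focal_pairs = nd * m_eff,
    n_unique_cases = n,
    n_duplicates = n_dup
  )
  structure(list(reports = reports, ground_truth = ground_truth),
    class = "pv_universe"
  )
}

#' @export
print.pv_universe <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf(
    "<pv_universe> %d records (%d unique cases, %d duplicates), %d injected PT signal(s)\n",
    nrow(x$reports), gt$n_unique_cases, gt$n_duplicates, length(gt$injected_pts)
  ))
  invisible(x)
}

#' Write ground truth as a JSON sidecar
#'
#' @param ground_truth the `ground_truth` element of a [generate_reports()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
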