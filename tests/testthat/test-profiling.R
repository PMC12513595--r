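test_that("demographic shares and the sex ratio reproduce their arithmetic", {
  dem <- demographic_summary(demography_fixture())
  expect_equal(dem$sex_ratio, 1.35)
  tab <- dem$table
  pick <- function(var, cat) tab$total_pct[tab$variable == var & tab$category == cat]
  expect_equal(pick("sex", "male"), 49.85)
  expect_equal(pick("sex", "female"), 36.85)
  expect_equal(pick("age_group", ">65"), 39.82)
  # single-valued variables: per-source counts sum to the source totals
  sex_rows <- tab[tab$variable == "sex", ]
  expect_equal(sum(sex_rows$FAERS_n), 7868)
  expect_equal(sum(sex_rows$JADER_n), 9452 - 7868)
  # every percentage equals its count over its denominator at 2 decimals
  expect_equal(
    tab$total_pct,
    round_half_up(100 * tab$total_n / 9452, 2)
  )
})

test_that("an all-unknown-sex corpus has no defined ratio", {
  r <- dplyr::bind_rows(
    make_report(report_id = "U1", sex = "unknown"),
    make_report(report_id = "U2", sex = "unknown")
  )
  expect_true(is.na(demographic_summary(r)$sex_ratio))
})

test_that("annual distribution counts years and conserves totals", {
  r <- dplyr::bind_rows(
    make_report(report_id = "Y1", receipt_date = as.Date("2019-05-01")),
    make_report(report_id = "Y2", receipt_date = as.Date("2019-08-01")),
    make_report(report_id = "Y3", receipt_date = as.Date("2019-12-31")),
    make_report(report_id = "Y4", receipt_date = as.Date("2020-01-01")),
    make_report(report_id = "Y5", receipt_date = as.Date(NA), receipt_precision = NA)
  )
  ann <- annual_distribution(r)
  expect_equal(ann$n[match(2019, ann$year)], 3L)
  expect_equal(ann$n[match(2020, ann$year)], 1L)
  expect_equal(sum(ann$n[!is.na(ann$year)]), nrow(r) - 1)
  expect_equal(sum(ann$n), nrow(r))
})

test_that("receipt years are uniform under the generator's date model", {
  u <- generate_reports(generator_config(
    n_background_reports = 0, n_drug_reports = 4000,
    duplicate_fraction = 0, year_range = c(2016, 2025), seed = 31
  ))
  ann <- annual_distribution(u$reports)
  days <- as.numeric(diff(as.Date(c("2016-01-01", "2026-01-01"))))
  per_year <- as.numeric(diff(as.Date(sprintf("%d-01-01", 2016:2026))))
  gof <- stats::chisq.test(ann$n, p = per_year / days)
  expect_gt(gof$p.value, 0.001)
})

test_that("SOC distribution counts reports once per organ class", {
  dict <- tibble::tibble(pt = c("X", "Y"), soc = c("S", "S"))
  r <- dplyr::bind_rows(
    make_report(report_id = "S1", events = c("X", "Y")),
    make_report(report_id = "S2", events = "X")
  )
  soc <- soc_distribution(r, dict)
  expect_equal(soc$soc, "S")
  expect_equal(soc$n, 2L)
  expect_equal(soc$prop, 1)

  u <- small_universe(seed = 32, n_background = 300, n_drug = 60)
  dist <- soc_distribution(u$reports, read_pt_soc_dictionary())
  expect_equal(sum(dist$prop), 1, tolerance = 1e-9)
  # brute-force recount of the top SOC
  top <- dist$soc[1]
  manual <- sum(vapply(u$reports$events, function(e) {
    top %in% suppressWarnings(map_pt_to_soc(e, read_pt_soc_dictionary()))
  }, logical(1)))
  expect_equal(dist$n[1], manual)
})

test_that("onset days use calendar arithmetic and exclusion rules", {
  r <- dplyr::bind_rows(
    make_report(
      report_id = "T1",
      therapy_start_date = as.Date("2020-01-01"),
      event_onset_date = as.Date("2020-01-15")
    ),
    make_report( # event precedes start: excluded
      report_id = "T2",
      therapy_start_date = as.Date("2020-03-01"),
      event_onset_date = as.Date("2020-02-01")
    ),
    make_report(report_id = "T3") # no dates: excluded
  )
  tto <- time_to_onset(r)
  expect_equal(tto$n_evaluable, 1L)
  expect_equal(tto$n_excluded, 2L)
  expect_equal(tto$median_days, 14)
  expect_equal(sum(tto$bins$n), tto$n_evaluable)
  expect_equal(tto$bins$n[tto$bins$bin == "8-30"], 1L)
  expect_equal(tto$n_evaluable + tto$n_excluded, nrow(r))
})

test_that("generated onsets recover the Weibull median", {
  shape <- 1.2
  scale <- 20
  u <- generate_reports(generator_config(
    n_background_reports = 0, n_drug_reports = 2000,
    missing_date_fraction = 0, duplicate_fraction = 0,
    tto_shape = shape, tto_scale = scale, seed = 33
  ))
  tto <- time_to_onset(u$reports)
  expect_equal(tto$n_evaluable, 2000L)
  med_true <- scale * log(2)^(1 / shape)
  dens <- stats::dweibull(med_true, shape, scale)
  se_med <- 1 / (2 * dens * sqrt(2000))
  # 0.5 allows for rounding to whole days
  expect_lt(abs(tto$median_days - med_true), 3 * se_med + 0.5)
})

test_that("indications classify into tumor and non-tumor strata", {
  expect_equal(classify_indication("Follicular lymphoma"), "tumor")
  expect_equal(classify_indication("Chronic lymphocytic leukaemia"), "tumor")
  expect_equal(classify_indication("Lupus nephritis"), "non_tumor")
  expect_equal(classify_indication("Glomerulonephritis membranous"), "non_tumor")
  expect_equal(classify_indication(""), "unknown")
  expect_equal(classify_indication(NA_character_), "unknown")
})

test_that("stratified a-cells partition the overall a-cell", {
  u <- small_universe(seed = 34, n_background = 1500, n_drug = 400)
  reports <- deduplicate(u$reports)
  fit <- mgps_hyperparams(1, 1, p_mix = 1)
  overall <- build_tables(reports, "obinutuzumab")
  strat <- suppressWarnings(dplyr::bind_rows(
    stratified_signals(reports, "obinutuzumab", "tumor", fit = fit),
    stratified_signals(reports, "obinutuzumab", "non_tumor", fit = fit),
    stratified_signals(reports, "obinutuzumab", "unknown", fit = fit)
  ))
  sums <- dplyr::summarise(
    dplyr::group_by(strat, .data$event),
    a = sum(.data$a), .groups = "drop"
  )
  joined <- dplyr::left_join(overall, sums, by = "event", suffix = c("_all", "_strat"))
  joined$a_strat[is.na(joined$a_strat)] <- 0L
  expect_equal(joined$a_all, joined$a_strat)
})

test_that("a stratum-restricted injection is flagged only in its stratum", {
  cfg <- generator_config(
    n_background_reports = 20000, n_drug_reports = 3000,
    signals = list(signal_spec("Hypotension", 30, stratum = "tumor")),
    duplicate_fraction = 0, seed = 35
  )
  u <- generate_reports(cfg)
  reports <- deduplicate(u$reports)
  tumor <- stratified_signals(reports, "obinutuzumab", "tumor")
  non_tumor <- stratified_signals(reports, "obinutuzumab", "non_tumor")
  expect_true(tumor$flagged[tumor$event == "Hypotension"])
  nt <- non_tumor$flagged[non_tumor$event == "Hypotension"]
  expect_true(length(nt) == 0 || !nt)
})

test_that("an empty stratum warns and returns an empty table", {
  u <- generate_reports(generator_config(
    n_background_reports = 50, n_drug_reports = 20,
    indication_mix = c("Follicular lymphoma" = 1),
    duplicate_fraction = 0, seed = 36
  ))
  expect_warning(
    empty <- stratified_signals(u$reports, "obinutuzumab", "non_tumor"),
    "no focal reports"
  )
  expect_equal(nrow(empty), 0)
})
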