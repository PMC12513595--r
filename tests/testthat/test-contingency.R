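test_that("tiny corpora enumerate exactly", {
  corpus <- dplyr::bind_rows(
    make_report(report_id = "F1", events = "X"),
    make_report(report_id = "F2", events = "X"),
    make_report(report_id = "B1", drug = "rituximab", events = "Y"),
    make_report(report_id = "B2", drug = "rituximab", events = "Y")
  )
  tabs <- build_tables(corpus, "obinutuzumab")
  x <- tabs[tabs$event == "X", ]
  expect_equal(unlist(x[, c("a", "b", "c", "d")]),
    c(a = 2, b = 0, c = 0, d = 2),
    ignore_attr = TRUE
  )
})

test_that("a report listing the same PT twice counts once", {
  corpus <- dplyr::bind_rows(
    make_report(report_id = "F1", events = c("X", "X")),
    make_report(report_id = "B1", drug = "rituximab", events = "X")
  )
  tabs <- build_tables(corpus, "obinutuzumab")
  expect_equal(tabs$a[tabs$event == "X"], 1L)
})

test_that("every table matches a brute-force recount on synthetic data", {
  u <- small_universe(seed = 12, n_background = 400, n_drug = 80)
  reports <- deduplicate(u$reports)
  tabs <- build_tables(reports, "obinutuzumab")
  for (ev in sample(tabs$event, 15)) {
    oracle <- oracle_table(reports, "obinutuzumab", ev)
    got <- tabs[tabs$event == ev, ]
    expect_equal(
      unlist(got[, c("a", "b", "c", "d")]),
      unlist(oracle),
      ignore_attr = TRUE
    )
  }
})

test_that("cells conserve the corpus-wide pair total", {
  u <- small_universe(seed = 13, n_background = 300, n_drug = 60)
  reports <- deduplicate(u$reports)
  tabs <- build_tables(reports, "obinutuzumab")
  total_pairs <- sum(vapply(reports$events, function(e) length(unique(e)), integer(1)))
  expect_true(all(tabs$n == total_pairs))
  expect_equal(sum(tabs$a + tabs$c), total_pairs)
})

test_that("swapping the focal drug swaps (a,b) with (c,d)", {
  u <- generate_reports(generator_config(
    n_background_reports = 300, n_drug_reports = 80,
    background_drugs = "rituximab", seed = 14
  ))
  reports <- deduplicate(u$reports)
  t1 <- build_tables(reports, "obinutuzumab")
  t2 <- build_tables(reports, "rituximab")
  joined <- dplyr::inner_join(t1, t2, by = "event", suffix = c("_f", "_r"))
  expect_equal(joined$a_f, joined$c_r)
  expect_equal(joined$b_f, joined$d_r)
  expect_equal(joined$c_f, joined$a_r)
  expect_equal(joined$d_f, joined$b_r)
})

test_that("SOC aggregation counts a report once per organ class", {
  dict <- tibble::tibble(pt = c("X", "Y", "Z"), soc = c("S", "S", "T"))
  corpus <- dplyr::bind_rows(
    make_report(report_id = "F1", events = c("X", "Y")), # both in SOC S
    make_report(report_id = "B1", drug = "rituximab", events = "Z")
  )
  tabs <- aggregate_to_soc(corpus, dict, "obinutuzumab")
  expect_equal(tabs$a[tabs$event == "S"], 1L)

  # SOC count is at least the largest member-PT count
  u <- small_universe(seed = 15, n_background = 300, n_drug = 80)
  reports <- deduplicate(u$reports)
  full_dict <- read_pt_soc_dictionary()
  tabs_pt <- build_tables(reports, "obinutuzumab")
  tabs_soc <- aggregate_to_soc(reports, full_dict, "obinutuzumab")
  pt_with_soc <- dplyr::mutate(tabs_pt,
    soc = suppressWarnings(map_pt_to_soc(event, full_dict))
  )
  max_pt <- dplyr::summarise(
    dplyr::group_by(pt_with_soc, soc),
    max_a = max(a), .groups = "drop"
  )
  joined <- dplyr::inner_join(tabs_soc, max_pt, by = c(event = "soc"))
  expect_true(all(joined$a >= joined$max_a))

  # brute-force recount at SOC level
  for (ev in sample(tabs_soc$event, 5)) {
    oracle <- oracle_table(reports, "obinutuzumab", ev, level = "soc", dict = full_dict)
    got <- tabs_soc[tabs_soc$event == ev, ]
    expect_equal(
      unlist(got[, c("a", "b", "c", "d")]),
      unlist(oracle),
      ignore_attr = TRUE
    )
  }
})

test_that("report-based margins are available as a switch", {
  u <- small_universe(seed = 16, n_background = 200, n_drug = 50)
  reports <- deduplicate(u$reports)
  tabs <- build_tables(reports, "obinutuzumab", margins = "reports")
  expect_true(all(tabs$a + tabs$b == 50))
})

test_that("a corpus without focal reports warns and returns empty", {
  corpus <- make_report(report_id = "B1", drug = "rituximab")
  expect_warning(tabs <- build_tables(corpus, "obinutuzumab"), "no focal")
  expect_equal(nrow(tabs), 0)
})
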