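test_that("worked examples reproduce the closed-form values", {
  expect_equal(ror_stats(5, 5, 5, 5)$ror, 1.0)
  expect_equal(ror_stats(10, 90, 100, 9900)$ror, 11.0)
  expect_equal(
    ror_stats(5, 5, 5, 5)$ror_ci_low,
    exp(-1.96 * sqrt(0.8))
  )

  expect_equal(prr_stats(10, 90, 100, 9900)$prr, 10.0)
  expect_equal(
    prr_stats(10, 90, 100, 9900)$chi2,
    oracle_prr_chi2(10, 90, 100, 9900)$chi2
  )
  expect_equal(prr_stats(10, 90, 100, 9900)$chi2, 66.33, tolerance = 1e-4)
  expect_equal(prr_stats(5, 5, 5, 5)$prr, 1.0)

  ic <- ic_stats(1, 9, 9, 81)
  expect_equal(ic$ic, -0.113, tolerance = 1e-3)
  expect_equal(ic$ic025, ic$ic - 2 * ic$ic_sd)
})

test_that("the chi-squared is minimal at independence for fixed margins", {
  # margins fixed at (10, 10, 10, 10): slide mass along the diagonal
  chi_indep <- prr_stats(5, 5, 5, 5)$chi2
  others <- vapply(c(1:4, 6:9), function(a) {
    prr_stats(a, 10 - a, 10 - a, a)$chi2
  }, numeric(1))
  expect_true(all(others >= chi_indep))
})

test_that("IC vanishes at exact independence in large samples", {
  ic <- ic_stats(100, 9900, 9900, 980100)$ic
  expect_lt(abs(ic), 0.05)
})

test_that("ROR, PRR, chi2 and IC match independent oracles on random tables", {
  set.seed(42)
  n_tab <- 1000
  a <- sample(1:10000, n_tab, replace = TRUE)
  b <- sample(1:10000, n_tab, replace = TRUE)
  c <- sample(1:10000, n_tab, replace = TRUE)
  d <- sample(1:10000, n_tab, replace = TRUE)

  got_ror <- ror_stats(a, b, c, d)
  got_prr <- prr_stats(a, b, c, d)
  got_ic <- ic_stats(a, b, c, d)
  exp_ror <- oracle_ror(a, b, c, d)
  exp_prr <- oracle_prr_chi2(a, b, c, d)
  exp_ic <- oracle_ic(a, b, c, d)

  rel <- function(x, y) max(abs(x - y) / pmax(abs(y), 1e-300))
  expect_lt(rel(got_ror$ror, exp_ror$ror), 1e-9)
  expect_lt(rel(got_ror$ror_ci_low, exp_ror$lo), 1e-9)
  expect_lt(rel(got_ror$ror_ci_high, exp_ror$hi), 1e-9)
  expect_lt(rel(got_prr$prr, exp_prr$prr), 1e-9)
  expect_lt(rel(got_prr$chi2, exp_prr$chi2), 1e-9)
  expect_lt(rel(got_ic$ic, exp_ic$ic), 1e-9)
  expect_lt(rel(got_ic$ic025, exp_ic$ic - 2 * exp_ic$sd), 1e-9)

  # credibility bound never exceeds the point estimate
  expect_true(all(got_ic$ic025 <= got_ic$ic))
})

test_that("zero cells mark frequentist statistics not evaluable", {
  expect_true(all(is.na(ror_stats(3, 0, 5, 100))))
  expect_true(all(is.na(prr_stats(3, 10, 0, 100))))
  # continuity correction recovers an estimate for zero-cell tables only
  corrected <- ror_stats(3, 0, 5, 100, correction = TRUE)
  expect_equal(corrected$ror, oracle_ror(3.5, 0.5, 5.5, 100.5)$ror)
  untouched <- ror_stats(3, 7, 5, 100, correction = TRUE)
  expect_equal(untouched$ror, ror_stats(3, 7, 5, 100)$ror)
  # IC is defined everywhere through the pseudo-counts
  expect_true(is.finite(ic_stats(0, 10, 0, 100)$ic))
})

test_that("the conjunctive criteria veto on any failed or missing condition", {
  base <- tibble::tibble(
    a = 10, ror_ci_low = 1.5, prr = 3, ic = 1, ic025 = 0.5, ebgm05 = 2.5
  )
  expect_true(evaluate_criteria(base))
  expect_false(evaluate_criteria(dplyr::mutate(base, a = 2)))
  expect_false(evaluate_criteria(dplyr::mutate(base, ebgm05 = 1.99)))
  expect_false(evaluate_criteria(dplyr::mutate(base, ror_ci_low = NA_real_)))
  expect_false(evaluate_criteria(dplyr::mutate(base, prr = 2)))
})

test_that("ranking sorts, tie-breaks, excludes and truncates", {
  records <- tibble::tibble(
    drug = "obinutuzumab",
    event = c("Follicular lymphoma", "Disease progression", "E1", "E2", "E3", "E4"),
    a = c(50L, 40L, 10L, 3L, 2L, 8L),
    ror = c(9, 8, 5, 5, 7, 2)
  )
  ranked <- rank_signals(records,
    by = "ror",
    exclude_events = "Follicular lymphoma", top_n = 30
  )
  # indication and progression terms dropped, a < 3 dropped
  expect_false(any(ranked$event %in% c("Follicular lymphoma", "Disease progression", "E3")))
  # equal ROR: larger count first
  expect_equal(ranked$event[1:2], c("E1", "E2"))
  expect_equal(
    rank_signals(records, exclude_events = "Follicular lymphoma", top_n = 2)$event,
    c("E1", "E2")
  )
  byc <- rank_signals(records, by = "count", exclude_events = "Follicular lymphoma")
  expect_equal(byc$event[1], "E1")
})

test_that("add_signal_stats assembles all statistics and the flag", {
  u <- small_universe(seed = 21, n_background = 2000, n_drug = 300)
  tabs <- build_tables(deduplicate(u$reports), "obinutuzumab")
  sig <- add_signal_stats(tabs)
  expect_true(all(c(
    "ror", "ror_ci_low", "ror_ci_high", "prr", "chi2", "ic", "ic025",
    "expected", "ebgm", "ebgm05", "flagged"
  ) %in% names(sig)))
  expect_s3_class(attr(sig, "mgps_fit"), "mgps_fit")
  # flag agrees with re-evaluating the criteria
  expect_equal(sig$flagged, evaluate_criteria(sig))
  # injected PTs dominate the flagged set
  flagged <- sig$event[sig$flagged]
  expect_true(all(u$ground_truth$injected_pts %in% flagged))
})
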