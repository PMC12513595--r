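test_that("FAERS write/read round trip is an identity", {
  u <- small_universe(
    seed = 5, n_background = 300, n_drug = 60,
    duplicate_fraction = 0.1, missing_date_fraction = 0.3
  )
  dir <- withr::local_tempdir()
  write_faers_tables(u$reports, dir)
  back <- read_faers_quarter(dir)
  expect_equal(back, u$reports)
})

test_that("decade-coded ages convert to years", {
  dir <- withr::local_tempdir()
  u <- generate_reports(generator_config(
    n_background_reports = 0, n_drug_reports = 3,
    duplicate_fraction = 0, missing_date_fraction = 0, seed = 2
  ))
  write_faers_tables(u$reports, dir)
  demo <- readr::read_delim(file.path(dir, "DEMO.txt"),
    delim = "$",
    col_types = readr::cols(.default = readr::col_character())
  )
  demo$AGE <- c("6", "420", "65")
  demo$AGE_COD <- c("DEC", "MON", "YR")
  readr::write_delim(demo, file.path(dir, "DEMO.txt"), delim = "$", na = "")
  back <- read_faers_quarter(dir)
  expect_equal(back$age_years, c(60, 35, 65))
  expect_equal(back$age_group, c("18-65", "18-65", "18-65"))
})

test_that("orphan child rows are skipped with a message", {
  u <- small_universe(seed = 6, n_background = 20, n_drug = 5)
  dir <- withr::local_tempdir()
  write_faers_tables(u$reports, dir)
  reac_path <- file.path(dir, "REAC.txt")
  writeLines(c(readLines(reac_path), "9999999999$Pyrexia"), reac_path)
  expect_message(back <- read_faers_quarter(dir), "no matching DEMO")
  expect_equal(nrow(back), nrow(u$reports))
})

test_that("missing mandatory tables raise an ingestion error naming the file", {
  dir <- withr::local_tempdir()
  expect_error(read_faers_quarter(dir), "DEMO")
  u <- small_universe(seed = 6, n_background = 10, n_drug = 2)
  write_faers_tables(u$reports, dir)
  file.remove(file.path(dir, "REAC.txt"))
  expect_error(read_faers_quarter(dir), "REAC")
})

test_that("JADER round trip equals the dialect projection, then stabilises", {
  u <- generate_reports(generator_config(
    n_background_reports = 200, n_drug_reports = 50,
    duplicate_fraction = 0.1, missing_date_fraction = 0.2,
    source = "JADER", seed = 9
  ))
  dir <- withr::local_tempdir()
  write_jader_tables(u$reports, dir)
  back <- read_jader(dir)
  expect_equal(back, jader_projection(u$reports))

  # a second write/read cycle is an exact identity
  dir2 <- withr::local_tempdir()
  write_jader_tables(back, dir2)
  expect_equal(read_jader(dir2), back)

  # suspect involvement survives the round trip
  roles <- unlist(lapply(back$drugs, function(d) d$role))
  expect_true("primary_suspect" %in% roles)
  expect_false("unknown" %in% roles)
})

test_that("JADER specifics: empty outcomes, decade bands, missing sex", {
  dir <- withr::local_tempdir()
  r <- dplyr::bind_rows(
    make_report(
      report_id = "C001-1", case_id = "C001", source = "JADER",
      outcomes = character(0), age_years = 67, country = "Japan"
    ),
    make_report(
      report_id = "C002-1", case_id = "C002", source = "JADER",
      sex = "unknown", age_years = NA, country = "Japan"
    )
  )
  write_jader_tables(r, dir)
  demo <- readr::read_csv(file.path(dir, "demo.csv"),
    na = character(),
    col_types = readr::cols(.default = readr::col_character())
  )
  # no outcomes -> empty field, row still present
  expect_equal(nrow(demo), 2)
  expect_equal(demo$outcome[1], "")
  expect_equal(demo$age_band[1], "60代")

  back <- read_jader(dir)
  expect_equal(back$sex, c("male", "unknown"))
  expect_equal(back$age_years, c(65, NA))
  expect_equal(back$outcomes[[1]], character(0))
})

test_that("deduplication keeps one report per case by the policy order", {
  versions <- dplyr::bind_rows(
    make_report(report_id = "1000000101", case_id = "10000001", case_version = 1),
    make_report(report_id = "1000000102", case_id = "10000001", case_version = 2),
    make_report(report_id = "1000000103", case_id = "10000001", case_version = 3)
  )
  kept <- deduplicate(versions)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$case_version, 3L)

  # ties on version fall back to receipt date, then report id
  ties <- dplyr::bind_rows(
    make_report(report_id = "A", case_id = "X", receipt_date = as.Date("2020-01-01")),
    make_report(report_id = "B", case_id = "X", receipt_date = as.Date("2020-06-01")),
    make_report(report_id = "C", case_id = "X", receipt_date = as.Date("2020-06-01"))
  )
  expect_equal(deduplicate(ties)$report_id, "C")

  # idempotence
  expect_equal(deduplicate(kept), kept)
})

test_that("dedup output size equals the number of distinct cases", {
  u <- small_universe(seed = 4, n_background = 150, n_drug = 30,
    duplicate_fraction = 0.15
  )
  dd <- deduplicate(u$reports)
  expect_equal(nrow(dd), dplyr::n_distinct(u$reports$case_id))
  expect_equal(nrow(dd), u$ground_truth$n_unique_cases)
  # input untouched
  expect_equal(nrow(u$reports), u$ground_truth$n_unique_cases +
    u$ground_truth$n_duplicates)
})

test_that("suspect filtering respects roles and widens monotonically", {
  conco_only <- make_report(
    report_id = "Z1", drug = "obinutuzumab", role = "concomitant"
  )
  secondary <- make_report(
    report_id = "Z2", drug = "obinutuzumab", role = "secondary_suspect"
  )
  primary <- make_report(report_id = "Z3")
  corpus <- dplyr::bind_rows(conco_only, secondary, primary)

  default <- filter_suspect(corpus, "obinutuzumab")
  expect_equal(default$report_id, "Z3")

  widened <- filter_suspect(corpus, "obinutuzumab",
    roles = c("primary_suspect", "secondary_suspect")
  )
  expect_true(all(default$report_id %in% widened$report_id))
  expect_setequal(widened$report_id, c("Z2", "Z3"))

  expect_warning(
    none <- filter_suspect(corpus, "neverdrug"),
    "does not appear"
  )
  expect_equal(nrow(none), 0)
})

test_that("the generator focal cohort is recovered exactly after dedup", {
  u <- small_universe(seed = 8, n_background = 500, n_drug = 120,
    duplicate_fraction = 0.08
  )
  focal <- filter_suspect(deduplicate(u$reports), "obinutuzumab")
  expect_equal(nrow(focal), 120)
})
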