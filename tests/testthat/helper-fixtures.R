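# Fixture builders: crafted single reports and small synthetic universes.

make_report <- function(report_id = "1000000101",
                        case_id = substr(report_id, 1, 8),
                        case_version = 1L,
                        source = "FAERS",
                        receipt_date = as.Date("2020-06-15"),
                        receipt_precision = "day",
                        sex = "male",
                        age_years = 60,
                        country = "United States",
                        reporter_type = "health_professional",
                        outcomes = character(0),
                        drug = "obinutuzumab",
                        role = "primary_suspect",
                        events = "Pyrexia",
                        indications = character(0),
                        therapy_start_date = as.Date(NA),
                        event_onset_date = as.Date(NA)) {
  tibble::tibble(
    report_id = report_id, case_id = case_id,
    case_version = as.integer(case_version), source = source,
    receipt_date = receipt_date, receipt_precision = receipt_precision,
    sex = sex, age_years = age_years,
    age_group = age_group_of(age_years), country = country,
    reporter_type = reporter_type,
    outcomes = list(outcomes),
    drugs = list(tibble::tibble(
      name_raw = drug,
      name_canonical = normalize_drug_name(drug)$canonical,
      role = role
    )),
    events = list(events),
    indications = list(indications),
    therapy_start_date = therapy_start_date,
    event_onset_date = event_onset_date
  )
}

# uniform catalogue of n_pt synthetic preferred terms
uniform_catalog <- function(n_pt = 100, baseline = 0.01) {
  tibble::tibble(
    pt_name = sprintf("PT%03d", seq_len(n_pt)),
    soc_name = rep(sprintf("SOC%02d", seq_len(max(1, n_pt %/% 10))),
      length.out = n_pt
    ),
    baseline_probability = baseline
  )
}

# modest universe over the shipped catalogue for IO / profiling tests
small_universe <- function(seed = 1, n_background = 2000, n_drug = 400, ...) {
  generate_reports(generator_config(
    n_background_reports = n_background, n_drug_reports = n_drug,
    seed = seed, ...
  ))
}

# direct-formula transcriptions used as independent oracles
oracle_ror <- function(a, b, c, d) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  c <- as.numeric(c)
  d <- as.numeric(d)
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(
    ror = ror,
    lo = exp(log(ror) - 1.96 * se),
    hi = exp(log(ror) + 1.96 * se)
  )
}

oracle_prr_chi2 <- function(a, b, c, d) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  c <- as.numeric(c)
  d <- as.numeric(d)
  n <- a + b + c + d
  list(
    prr = (a / (a + b)) / (c / (c + d)),
    chi2 = n * (abs(a * d - b * c) - n / 2)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
  )
}

oracle_ic <- function(a, b, c, d, alpha = 2, beta = 2, alpha1 = 1,
                      beta1 = 1, g11 = 1) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  c <- as.numeric(c)
  d <- as.numeric(d)
  n <- a + b + c + d
  gam <- g11 * (n + alpha) * (n + beta) / ((a + b + alpha1) * (a + c + beta1))
  ic <- log2((a + g11) * (n + alpha) * (n + beta) /
    ((n + gam) * (a + b + alpha1) * (a + c + beta1)))
  v <- (1 / log(2)^2) * (
    (n - a + gam - g11) / ((a + g11) * (1 + n + gam)) +
      (n - (a + b) + alpha - alpha1) / ((a + b + alpha1) * (1 + n + alpha)) +
      (n - (a + c) + beta - beta1) / ((a + c + beta1) * (1 + n + beta))
  )
  list(ic = ic, sd = sqrt(v))
}

# brute-force O(reports x events) recount of one 2x2 table
oracle_table <- function(reports, focal_drug, event, level = "pt", dict = NULL) {
  focal <- vapply(reports$drugs, function(d) {
    any(d$name_canonical == focal_drug & d$role == "primary_suspect")
  }, logical(1))
  evs <- lapply(reports$events, function(e) {
    if (level == "soc") unique(suppressWarnings(map_pt_to_soc(e, dict))) else unique(e)
  })
  has <- vapply(evs, function(e) event %in% e, logical(1))
  pairs_per_report <- lengths(evs)
  a <- sum(focal & has)
  c <- sum(!focal & has)
  list(
    a = a, b = sum(pairs_per_report[focal]) - a,
    c = c, d = sum(pairs_per_report[!focal]) - c
  )
}

# corpus with prescribed category counts (source split FAERS/JADER)
demography_fixture <- function() {
  n_total <- 9452
  n_faers <- 7868
  sex <- rep(
    c("male", "female", "unknown"),
    times = c(4712, 3483, 9452 - 4712 - 3483)
  )
  age <- rep(
    c("<18", "18-65", ">65", "unknown"),
    times = c(30, 3315, 3764, 9452 - 30 - 3315 - 3764)
  )
  tibble::tibble(
    report_id = sprintf("R%05d", seq_len(n_total)),
    case_id = sprintf("C%05d", seq_len(n_total)),
    case_version = 1L,
    source = rep(c("FAERS", "JADER"), times = c(n_faers, n_total - n_faers)),
    receipt_date = as.Date("2022-06-01"),
    receipt_precision = "day",
    sex = sex,
    age_years = NA_real_,
    age_group = age,
    country = "United States",
    reporter_type = "health_professional",
    outcomes = rep(list(character(0)), n_total),
    drugs = rep(list(tibble::tibble(
      name_raw = "obinutuzumab", name_canonical = "obinutuzumab",
      role = "primary_suspect"
    )), n_total),
    events = rep(list("Pyrexia"), n_total),
    indications = rep(list(character(0)), n_total),
    therapy_start_date = as.Date(NA),
    event_onset_date = as.Date(NA)
  )
}
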