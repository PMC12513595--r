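# Frequentist disproportionality statistics (ROR, PRR, chi-squared) and
# the BCPNN information component with its closed-form posterior moments.

#' Reporting odds ratio with Wald 95% interval
#'
#' `ROR = (a d)/(b c)`, with the interval computed on the log scale:
#' `exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. Tables containing
#' a zero cell are not evaluable (all three results `NA`) unless the
#' Haldane-Anscombe continuity correction is switched on, which then adds
#' 0.5 to every cell of exactly those tables.
#'
#' @param a,b,c,d vectors of 2x2 cell counts (recycled to a common length).
#' @param correction apply the +0.5 continuity correction to zero-cell
#'   tables instead of marking them not evaluable.
#' @return tibble with columns `ror`, `ror_ci_low`, `ror_ci_high`.
#' @export
ror_stats <- function(a, b, c, d, correction = FALSE) {
  z <- cbind(a = a, b = b, c = c, d = d)
  zero <- rowSums(z == 0) > 0
  if (correction) {
    z[zero, ] <- z[zero, , drop = FALSE] + 0.5
    zero[] <- FALSE
  }
  log_ror <- unname(log(z[, "a"]) + log(z[, "d"]) - log(z[, "b"]) - log(z[, "c"]))
  se <- unname(sqrt(rowSums(1 / z)))
  out <- tibble::tibble(
    ror = exp(log_ror),
    ror_ci_low = exp(log_ror - 1.96 * se),
    ror_ci_high = exp(log_ror + 1.96 * se)
  )
  out[zero, ] <- NA_real_
  out
}

#' Proportional reporting ratio and chi-squared
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the chi-squared statistic uses the
#' Yates continuity correction
#' `n (|ad - bc| - n/2)^2 / [(a+b)(c+d)(a+c)(b+d)]` by default, or the
#' uncorrected `n (ad - bc)^2 / [...]` with `yates = FALSE`. Tables with
#' an empty drug margin, empty comparator margin or `c = 0` are not
#' evaluable (`NA`).
#'
#' @inheritParams ror_stats
#' @param yates use the Yates-corrected chi-squared.
#' @return tibble with columns `prr`, `chi2`.
#' @export
prr_stats <- function(a, b, c, d, yates = TRUE) {
  # double precision: cell products overflow integer range on large corpora
  a <- as.numeric(a)
  b <- as.numeric(b)
  c <- as.numeric(c)
  d <- as.numeric(d)
  n <- a + b + c + d
  bad <- (a + b) == 0 | (c + d) == 0 | c == 0
  prr <- (a / (a + b)) / (c / (c + d))
  dev <- if (yates) (abs(a * d - b * c) - n / 2)^2 else (a * d - b * c)^2
  chi2 <- n * dev / ((a + b) * (c + d) * (a + c) * (b + d))
  out <- tibble::tibble(prr = prr, chi2 = chi2)
  out[bad, ] <- NA_real_
  out
}

#' BCPNN prior pseudo-counts
#'
#' The Bate-style parameterization of the information-component prior:
#' `alpha`, `beta` on the margins, `alpha1`, `beta1` on the drug and
#' event marginals, and `gamma11` on the joint cell. The defaults give
#' the standard vague prior centred on independence (IC = 0).
#'
#' @param alpha,beta,alpha1,beta1,gamma11 positive prior pseudo-counts.
#' @return a `bcpnn_priors` list.
#' @export
bcpnn_priors <- function(alpha = 2, beta = 2, alpha1 = 1, beta1 = 1, gamma11 = 1) {
  vals <- c(alpha, beta, alpha1, beta1, gamma11)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    rlang::abort("all BCPNN prior pseudo-counts must be positive and finite")
  }
  structure(
    list(
      alpha = alpha, beta = beta, alpha1 = alpha1, beta1 = beta1,
      gamma11 = gamma11
    ),
    class = "bcpnn_priors"
  )
}

#' BCPNN information component with closed-form credibility bound
#'
#' Posterior expectation and variance of
#' `IC = log2 p(drug, event) / (p(drug) p(event))` under Beta/Dirichlet
#' pseudo-count priors, evaluated in closed form (no posterior sampling):
#'
#' `E(IC) = log2 [ (a + g11)(n + alpha)(n + beta) /
#'                ((n + gamma)(a + b + alpha1)(a + c + beta1)) ]`
#'
#' with `gamma = g11 (n + alpha)(n + beta) /
#' ((a + b + alpha1)(a + c + beta1))`, and the matching variance on the
#' log2 scale. The lower credibility bound is `ic - 2 sd`, the quantity
#' thresholded by the positive-signal criteria. Defined for zero cells
#' thanks to the pseudo-counts.
#'
#' @inheritParams ror_stats
#' @param priors a [bcpnn_priors()] object.
#' @return tibble with columns `ic`, `ic_sd`, `ic025` (= `ic - 2 ic_sd`).
#' @export
ic_stats <- function(a, b, c, d, priors = bcpnn_priors()) {
  stopifnot(inherits(priors, "bcpnn_priors"))
  al <- priors$alpha
  be <- priors$beta
  a1 <- priors$alpha1
  b1 <- priors$beta1
  g11 <- priors$gamma11
  a <- as.numeric(a)
  n <- a + as.numeric(b) + as.numeric(c) + as.numeric(d)
  b <- as.numeric(b)
  c <- as.numeric(c)
  gam <- g11 * (n + al) * (n + be) / ((a + b + a1) * (a + c + b1))
  ic <- log2(
    (a + g11) * (n + al) * (n + be) /
      ((n + gam) * (a + b + a1) * (a + c + b1))
  )
  vic <- (1 / log(2)^2) * (
    (n - a + gam - g11) / ((a + g11) * (1 + n + gam)) +
      (n - (a + b) + al - a1) / ((a + b + a1) * (1 + n + al)) +
      (n - (a + c) + be - b1) / ((a + c + b1) * (1 + n + be))
  )
  ic_sd <- sqrt(vic)
  tibble::tibble(ic = ic, ic_sd = ic_sd, ic025 = ic - 2 * ic_sd)
}
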