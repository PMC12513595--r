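# Empirical-Bayes gamma-Poisson shrinker (DuMouchel's MGPS).
#
# Observed counts a ~ Poisson(lambda E) with E the expected count under
# row/column independence; the relative reporting rate lambda has a
# two-component gamma mixture prior. The marginal likelihood of each
# count is a two-component negative-binomial mixture, maximised over the
# five hyperparameters; the posterior for each pair is again a gamma
# mixture, giving EBGM (posterior geometric mean of lambda) and EBGM05
# (posterior 5th percentile) in closed form up to one root find.

#' Build (count, expected) pairs for hyperparameter fitting
#'
#' Uses every PT-level table: the focal cell `a` with
#' `E = (a+b)(a+c)/n`, and (by default) the comparator cell `c` with
#' `E = (c+d)(a+c)/n`, so the prior is informed by the whole corpus, not
#' only the focal drug.
#'
#' @param tables contingency tibble from [build_tables()].
#' @param include_comparator also use the comparator cells.
#' @return tibble with columns `count`, `expected`.
#' @export
mgps_pairs <- function(tables, include_comparator = TRUE) {
  check_columns(tables, c("a", "b", "c", "d", "n"), "contingency tables")
  a <- as.numeric(tables$a)
  b <- as.numeric(tables$b)
  c <- as.numeric(tables$c)
  d <- as.numeric(tables$d)
  n <- as.numeric(tables$n)
  out <- tibble::tibble(count = tables$a, expected = (a + b) * (a + c) / n)
  if (include_comparator) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      count = tables$c, expected = (c + d) * (a + c) / n
    ))
  }
  out
}

# log marginal likelihood of counts under the NB mixture; theta is the
# unconstrained parameterization (log shapes/rates, logit mixing weight)
mgps_loglik <- function(count, expected, alpha1, beta1, alpha2, beta2, p_mix) {
  l1 <- dnbinom(count, size = alpha1, prob = beta1 / (beta1 + expected), log = TRUE) +
    log(p_mix)
  l2 <- dnbinom(count, size = alpha2, prob = beta2 / (beta2 + expected), log = TRUE) +
    log1p(-p_mix)
  m <- pmax(l1, l2)
  sum(m + log1p(exp(pmin(l1, l2) - m)))
}

theta_to_par <- function(theta) {
  list(
    alpha1 = exp(theta[1]), beta1 = exp(theta[2]),
    alpha2 = exp(theta[3]), beta2 = exp(theta[4]),
    p_mix = stats::plogis(theta[5])
  )
}

#' Fit the gamma-mixture hyperparameters
#'
#' Maximises the summed log marginal (negative-binomial mixture)
#' likelihood over the five hyperparameters, with positivity enforced by
#' log-reparameterization and the mixing weight by logit. Zero-count
#' pairs are excluded from the likelihood. Optimisation runs Nelder-Mead
#' from `start` and is polished with BFGS.
#'
#' @param pairs tibble with columns `count` and `expected` (one row per
#'   drug-event pair), e.g. from [mgps_pairs()].
#' @param start numeric start `(alpha1, beta1, alpha2, beta2, p_mix)`.
#' @return object of class `mgps_fit`: hyperparameters, `loglik`,
#'   `converged`, `n_pairs`, and the prior mixture mean/geometric mean.
#' @export
fit_mgps <- function(pairs, start = c(0.2, 0.1, 2.0, 4.0, 1 / 3)) {
  check_columns(pairs, c("count", "expected"), "MGPS pairs")
  use <- pairs$count > 0 & pairs$expected > 0
  count <- pairs$count[use]
  expected <- pairs$expected[use]
  if (length(count) < 50) {
    rlang::warn(sprintf(
      "only %d usable pairs; MGPS hyperparameter estimates may be unstable",
      length(count)
    ))
  }
  negll <- function(theta) {
    p <- theta_to_par(theta)
    ll <- mgps_loglik(count, expected, p$alpha1, p$beta1, p$alpha2, p$beta2, p$p_mix)
    if (!is.finite(ll)) {
      return(1e12)
    }
    -ll
  }
  theta0 <- c(log(start[1:4]), stats::qlogis(start[5]))
  nm <- optim(theta0, negll, method = "Nelder-Mead", control = list(maxit = 4000))
  bf <- tryCatch(
    optim(nm$par, negll, method = "BFGS", control = list(maxit = 500)),
    error = function(e) nm
  )
  best <- if (bf$value <= nm$value) bf else nm
  par <- theta_to_par(best$par)
  # identifiability cleanup: when one component carries (essentially) no
  # posterior responsibility the likelihood is flat in its parameters and
  # the optimizer can leave it anywhere, corrupting prior summaries.
  # Collapsing it onto the dominant component never decreases the
  # likelihood and makes the reported prior well-defined.
  l1 <- dnbinom(count, size = par$alpha1, prob = par$beta1 / (par$beta1 + expected), log = TRUE) +
    log(par$p_mix)
  l2 <- dnbinom(count, size = par$alpha2, prob = par$beta2 / (par$beta2 + expected), log = TRUE) +
    log1p(-par$p_mix)
  resp1 <- sum(1 / (1 + exp(l2 - l1)))
  if (resp1 < 1e-3) {
    par$alpha1 <- par$alpha2
    par$beta1 <- par$beta2
  } else if (length(count) - resp1 < 1e-3) {
    par$alpha2 <- par$alpha1
    par$beta2 <- par$beta1
  }
  ll_final <- mgps_loglik(
    count, expected,
    par$alpha1, par$beta1, par$alpha2, par$beta2, par$p_mix
  )
  structure(
    c(par, list(
      loglik = ll_final,
      converged = best$convergence == 0,
      n_pairs = length(count),
      prior_mean = par$p_mix * par$alpha1 / par$beta1 +
        (1 - par$p_mix) * par$alpha2 / par$beta2,
      prior_geometric_mean = exp(
        par$p_mix * (digamma(par$alpha1) - log(par$beta1)) +
          (1 - par$p_mix) * (digamma(par$alpha2) - log(par$beta2))
      )
    )),
    class = "mgps_fit"
  )
}

#' Construct an MGPS fit from known hyperparameters
#'
#' Useful for degenerate or externally supplied priors (e.g. a pinned
#' single-component prior).
#'
#' @param alpha1,beta1,alpha2,beta2 positive gamma shapes and rates.
#' @param p_mix mixing weight in `(0, 1]`; `1` pins the first component.
#' @return an `mgps_fit` object (loglik `NA`, converged `TRUE`).
#' @export
mgps_hyperparams <- function(alpha1, beta1, alpha2 = alpha1, beta2 = beta1,
                             p_mix = 1) {
  stopifnot(
    alpha1 > 0, beta1 > 0, alpha2 > 0, beta2 > 0,
    p_mix > 0, p_mix <= 1
  )
  structure(
    list(
      alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2, beta2 = beta2,
      p_mix = p_mix, loglik = NA_real_, converged = TRUE, n_pairs = 0L,
      prior_mean = p_mix * alpha1 / beta1 + (1 - p_mix) * alpha2 / beta2,
      prior_geometric_mean = exp(
        p_mix * (digamma(alpha1) - log(beta1)) +
          (1 - p_mix) * (digamma(alpha2) - log(beta2))
      )
    ),
    class = "mgps_fit"
  )
}

#' @export
print.mgps_fit <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<mgps_fit> p = %.3f * Gamma(%.3g, %.3g) + %.3f * Gamma(%.3g, %.3g)\n",
      "  loglik %.3f over %d pairs (converged: %s); prior mean %.3f\n"
    ),
    x$p_mix, x$alpha1, x$beta1, 1 - x$p_mix, x$alpha2, x$beta2,
    x$loglik, x$n_pairs, x$converged, x$prior_mean
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mgps_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha1", "beta1", "alpha2", "beta2", "p_mix"),
    estimate = c(x$alpha1, x$beta1, x$alpha2, x$beta2, x$p_mix)
  )
}

#' @exportS3Method generics::glance
glance.mgps_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik, converged = x$converged, n_pairs = x$n_pairs,
    prior_mean = x$prior_mean,
    prior_geometric_mean = x$prior_geometric_mean
  )
}

#' EBGM and EBGM05 for observed counts
#'
#' The posterior of the relative reporting rate for a pair with count
#' `a` and expected `E` is the gamma mixture
#' `Q Gamma(alpha1 + a, beta1 + E) + (1 - Q) Gamma(alpha2 + a, beta2 + E)`
#' with `Q` the posterior component weight from the negative-binomial
#' marginals. `EBGM = exp(E[ln lambda])` (the posterior geometric mean)
#' and `EBGM05` solves the mixture CDF = 0.05 by bracketed root finding.
#'
#' @param count,expected vectors of observed and expected counts.
#' @param fit an `mgps_fit` (from [fit_mgps()] or [mgps_hyperparams()]).
#' @param quantile_tol absolute tolerance on the EBGM05 root.
#' @return tibble with columns `ebgm`, `ebgm05`.
#' @export
ebgm_stats <- function(count, expected, fit, quantile_tol = 1e-8) {
  stopifnot(inherits(fit, "mgps_fit"))
  if (any(expected <= 0)) rlang::abort("expected counts must be positive")
  a1 <- fit$alpha1
  b1 <- fit$beta1
  a2 <- fit$alpha2
  b2 <- fit$beta2
  p <- fit$p_mix
  if (p >= 1) {
    q_post <- rep(1, length(count))
  } else {
    l1 <- dnbinom(count, size = a1, prob = b1 / (b1 + expected), log = TRUE) + log(p)
    l2 <- dnbinom(count, size = a2, prob = b2 / (b2 + expected), log = TRUE) + log1p(-p)
    q_post <- 1 / (1 + exp(l2 - l1))
  }
  s1 <- a1 + count
  r1 <- b1 + expected
  s2 <- a2 + count
  r2 <- b2 + expected
  ebgm <- exp(
    q_post * (digamma(s1) - log(r1)) + (1 - q_post) * (digamma(s2) - log(r2))
  )
  ebgm05 <- vapply(seq_along(count), function(i) {
    if (q_post[i] >= 1 - 1e-12) {
      return(qgamma(0.05, shape = s1[i], rate = r1[i]))
    }
    if (q_post[i] <= 1e-12) {
      return(qgamma(0.05, shape = s2[i], rate = r2[i]))
    }
    q1 <- qgamma(0.05, shape = s1[i], rate = r1[i])
    q2 <- qgamma(0.05, shape = s2[i], rate = r2[i])
    lo <- min(q1, q2)
    hi <- max(q1, q2)
    f <- function(l) {
      q_post[i] * pgamma(l, shape = s1[i], rate = r1[i]) +
        (1 - q_post[i]) * pgamma(l, shape = s2[i], rate = r2[i]) - 0.05
    }
    if (abs(hi - lo) < quantile_tol) {
      return((lo + hi) / 2)
    }
    root <- tryCatch(
      uniroot(f, c(lo, hi), tol = quantile_tol, extendInt = "upX"),
      error = function(e) {
        rlang::abort(sprintf(
          "EBGM05 root bracketing failed for count=%g, expected=%g", count[i], expected[i]
        ))
      }
    )
    root$root
  }, numeric(1))
  tibble::tibble(ebgm = ebgm, ebgm05 = ebgm05)
}
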