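# Exact count inference for reversal rates and event proportions.
#
# Reversals are rare relative to the number of trajectory points, so counts
# are treated as Poisson with the number of trajectory points as exposure.
# Repolarization-event proportions are compared against 0.5 with exact
# binomial tests. All routines delegate to the corresponding exact methods
# in stats and are cross-checked against brute-force enumeration in the
# test suite.

#' Exact (Garwood) Poisson confidence interval for a reversal rate
#'
#' Rate estimate `n_r / n_t` with an exact gamma-quantile confidence
#' interval, where `n_r` is the number of reversal events and `n_t` the
#' number of trajectory points observed (the exposure).
#'
#' @param n_r event count.
#' @param n_t exposure (trajectory points); must be > 0.
#' @param conf confidence level.
#' @return list of class `rate_estimate`: `n_r`, `n_t`, `rate`, `ci_low`,
#'   `ci_high`, `conf_level` (rates in events per trajectory point).
#' @export
poisson_rate_ci <- function(n_r, n_t, conf = 0.95) {
  check_finite(n_r = n_r, n_t = n_t, conf = conf)
  if (n_t <= 0) stop("exposure n_t must be > 0")
  if (n_r < 0 || n_r != round(n_r)) stop("n_r must be a non-negative integer")
  ci <- stats::poisson.test(n_r, T = n_t, conf.level = conf)$conf.int
  structure(list(n_r = n_r, n_t = n_t, rate = n_r / n_t,
                 ci_low = ci[1], ci_high = ci[2], conf_level = conf),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rate %.3g per point (n_r = %d, n_t = %g), %d%% CI [%.3g, %.3g]\n",
              x$rate, x$n_r, x$n_t, round(100 * x$conf_level),
              x$ci_low, x$ci_high))
  invisible(x)
}

#' Exact two-sample Poisson rate comparison
#'
#' Conditional exact test of equal rates for two Poisson counts with
#' exposures: given `N = n1 + n2`, `n1` is binomial(`N`, `T1/(T1+T2)`) under
#' the null, and the p-value is an exact binomial tail (or, two-sided, the
#' minimum-likelihood) sum.
#'
#' @param n1,n2 event counts.
#' @param T1,T2 exposures (> 0).
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (rate 1 vs rate 2).
#' @return the p-value.
#' @export
exact_poisson_two_sample <- function(n1, T1, n2, T2,
                                     alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  check_finite(n1 = n1, T1 = T1, n2 = n2, T2 = T2)
  if (T1 <= 0 || T2 <= 0) stop("exposures must be > 0")
  if (n1 + n2 <= 0) stop("need at least one event")
  stats::poisson.test(c(n1, n2), T = c(T1, T2),
                      alternative = alternative)$p.value
}

#' Exact binomial test
#'
#' Exact test of `k` successes in `n` trials against success probability
#' `p0`. The two-sided p-value follows the minimum-likelihood convention:
#' the sum of probabilities of all outcomes no more likely than the one
#' observed.
#'
#' @param k successes; `0 <= k <= n`.
#' @param n trials.
#' @param p0 null success probability.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return the p-value.
#' @export
exact_binomial_test <- function(k, n, p0 = 0.5,
                                alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  check_finite(k = k, n = n, p0 = p0)
  if (k < 0 || k > n) stop("need 0 <= k <= n")
  stats::binom.test(k, n, p = p0, alternative = alternative)$p.value
}

#' Wilson score interval for a proportion
#'
#' @param k successes.
#' @param n trials (> 0).
#' @param conf confidence level.
#' @return numeric length-2 vector `c(low, high)`, bounded in \[0, 1\].
#' @export
proportion_ci <- function(k, n, conf = 0.95) {
  check_finite(k = k, n = n, conf = conf)
  if (n <= 0) stop("n must be > 0")
  if (k < 0 || k > n) stop("need 0 <= k <= n")
  # prop.test without continuity correction returns the Wilson score interval
  ci <- suppressWarnings(
    stats::prop.test(k, n, conf.level = conf, correct = FALSE)$conf.int)
  as.numeric(ci)
}

#' Per-interval reversal-rate report
#'
#' Formats the output of [reversal_rate_series()] together with exact
#' Poisson confidence intervals, as plain text and as a data frame.
#'
#' @param rates data frame from [reversal_rate_series()].
#' @param conf confidence level for the per-interval intervals.
#' @return the input with columns `ci_low`, `ci_high` appended, invisibly
#'   printed as text.
#' @export
rate_report <- function(rates, conf = 0.95) {
  stopifnot(all(c("interval", "n_r", "n_t", "rate") %in% names(rates)))
  lo <- hi <- rep(NA_real_, nrow(rates))
  for (i in seq_len(nrow(rates))) {
    if (rates$n_t[i] > 0) {
      est <- poisson_rate_ci(rates$n_r[i], rates$n_t[i], conf)
      lo[i] <- est$ci_low; hi[i] <- est$ci_high
    }
  }
  rates$ci_low <- lo
  rates$ci_high <- hi
  rates
}
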