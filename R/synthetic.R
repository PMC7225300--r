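#' Simulate a Kaplan-Meier curve from known Weibull parameters
#'
#' Draws `n` event times by inverse-CDF sampling,
#' \eqn{t = (-\log U / \lambda)^{1/\gamma}} (cycle units), applies
#' independent uniform censoring on `(0, t_max)` with `t_max` calibrated by
#' bisection so that the expected censored fraction equals
#' `censor_fraction`, and computes the product-limit (Kaplan-Meier)
#' estimate via [survival::survfit()].  Used for parameter-recovery testing
#' of the curve-fitting stage; deterministic given `seed`.
#'
#' @param true_params A [weibull_params()] ground truth.
#' @param n Number of subjects (>= 10).
#' @param censor_fraction Expected fraction censored, in `[0, 1)`.
#' @param seed Integer seed (required).
#'
#' @return A list with elements `curve` (KM tibble at event times, see
#'   [km_curve()]), `cohort` (tibble with per-subject `time` and `status`,
#'   1 = event), `true_params`, `censor_fraction` and `seed`.
#' @examples
#' sim <- simulate_km(weibull_params(0.07396, 1.02298), n = 200, seed = 1)
#' fit_weibull_km(sim$curve)
#' @export
simulate_km <- function(true_params, n, censor_fraction = 0, seed) {
  stopifnot(inherits(true_params, "weibull_params"),
            is.numeric(n), n >= 10, missing(seed) == FALSE)
  if (!is.numeric(censor_fraction) || censor_fraction < 0 ||
      censor_fraction >= 1) {
    rlang::abort("`censor_fraction` must lie in [0, 1).",
                 class = "renalcea_error_config")
  }
  lambda <- true_params$scale
  gamma <- true_params$shape
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  event_times <- (-log(stats::runif(n)) / lambda)^(1 / gamma)
  if (censor_fraction > 0) {
    t_max <- calibrate_censoring(lambda, gamma, censor_fraction)
    censor_times <- stats::runif(n, 0, t_max)
    status <- as.integer(event_times <= censor_times)
    obs <- pmin(event_times, censor_times)
  } else {
    status <- rep(1L, n)
    obs <- event_times
  }
  cohort <- tibble::tibble(time = obs, status = status)
  fit <- survival::survfit(survival::Surv(time, status) ~ 1, data = cohort)
  keep <- fit$n.event > 0
  curve <- km_curve(fit$time[keep], fit$surv[keep])
  list(curve = curve, cohort = cohort, true_params = true_params,
       censor_fraction = censor_fraction, seed = seed)
}

# Expected censored fraction under C ~ U(0, t_max) is
# (1/t_max) * integral_0^t_max S(t) dt, which decreases from 1 to 0 in
# t_max; solve for the requested fraction by bisection.
calibrate_censoring <- function(lambda, gamma, target) {
  expected <- function(t_max) {
    stats::integrate(function(t) exp(-lambda * t^gamma), 0, t_max,
                     rel.tol = 1e-9)$value / t_max
  }
  lo <- 1e-6
  hi <- 1
  while (expected(hi) > target) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (expected(mid) > target) lo <- mid else hi <- mid
    if (hi - lo < 1e-8 * hi) break
  }
  (lo + hi) / 2
}

#' Synthetic all-cause-mortality life table
#'
#' A deterministic Gompertz-style schedule,
#' \eqn{q(\mathrm{age}) = \min(1,\; 0.0005\,e^{0.09(\mathrm{age}-30)})},
#' tabulated for ages 40-110 with the final age forced to 1 so old age is
#' absorbing.  This is a synthetic stand-in for a national period life
#' table, shaped to give plausible background mortality around the
#' cohort's starting age (q(61) is about 0.008); a real table can be
#' supplied instead as a two-column CSV via [read_life_table()].
#'
#' @return A tibble with columns `age` and `annual_death_prob`.
#' @export
fixture_life_table <- function() {
  age <- 40:110
  q <- pmin(1, 0.0005 * exp(0.09 * (age - 30)))
  q[length(q)] <- 1
  tibble::tibble(age = age, annual_death_prob = q)
}
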