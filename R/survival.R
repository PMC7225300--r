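#' Weibull survival parameters
#'
#' Container for the two-parameter survival form \eqn{S(t) = \exp(-\lambda
#' t^\gamma)} used to extrapolate progression-free survival (PFS) and overall
#' survival (OS) beyond trial follow-up.  `scale` (\eqn{\lambda}) is a
#' cumulative-hazard coefficient in units of cycle\eqn{^{-shape}}; `shape`
#' (\eqn{\gamma}) is dimensionless, with values above 1 implying an
#' increasing hazard.
#'
#' @param scale Positive scale parameter \eqn{\lambda}.
#' @param shape Positive shape parameter \eqn{\gamma}.
#' @param fit_r_squared Optional goodness-of-fit statistic in `[0, 1]`
#'   carried along when the parameters come from [fit_weibull_km()].
#'
#' @return An object of class `weibull_params`.
#' @examples
#' wp <- weibull_params(scale = 0.05483, shape = 0.97914)
#' survival_at(wp, 0:10)
#' @export
weibull_params <- function(scale, shape, fit_r_squared = NULL) {
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale),
            is.numeric(shape), length(shape) == 1L, is.finite(shape))
  if (scale <= 0 || shape <= 0) {
    rlang::abort("`scale` and `shape` must both be positive.",
                 class = "renalcea_error_domain")
  }
  if (!is.null(fit_r_squared)) {
    stopifnot(is.numeric(fit_r_squared), length(fit_r_squared) == 1L)
  }
  structure(
    list(scale = scale, shape = shape, fit_r_squared = fit_r_squared),
    class = "weibull_params"
  )
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("<weibull_params> scale = %g, shape = %g", x$scale, x$shape))
  if (!is.null(x$fit_r_squared)) cat(sprintf(", r^2 = %.4f", x$fit_r_squared))
  cat("\n")
  invisible(x)
}

#' Evaluate the Weibull survival function
#'
#' Returns \eqn{S(t) = \exp(-\lambda t^\gamma)}, the modelled proportion of
#' the cohort still event-free at time `t` (in model cycles).
#'
#' @param params A [weibull_params()] object.
#' @param t Non-negative time(s) in cycles; vectorised.
#'
#' @return Numeric vector of survival proportions in `[0, 1]`.
#' @export
survival_at <- function(params, t) {
  stopifnot(inherits(params, "weibull_params"), is.numeric(t))
  if (any(t < 0)) {
    rlang::abort("`t` must be non-negative.", class = "renalcea_error_domain")
  }
  exp(-params$scale * t^params$shape)
}

#' Per-cycle transition probability from a Weibull survival model
#'
#' The discrete hazard of [survival_at()] over cycle `t`: the conditional
#' probability that a subject event-free at the start of cycle `t`
#' experiences the event during that cycle,
#' \eqn{1 - \exp[\lambda (t-1)^\gamma - \lambda t^\gamma]}.  The product of
#' `1 - transition_prob()` over cycles `1..T` recovers `survival_at(T)`.
#'
#' @param params A [weibull_params()] object.
#' @param t Cycle index being entered, integer-valued and at least 1;
#'   vectorised.
#'
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
transition_prob <- function(params, t) {
  stopifnot(inherits(params, "weibull_params"), is.numeric(t))
  if (any(t < 1)) {
    rlang::abort("Cycle index `t` must be >= 1.",
                 class = "renalcea_error_domain")
  }
  1 - exp(params$scale * (t - 1)^params$shape - params$scale * t^params$shape)
}

#' Construct and validate a Kaplan-Meier curve table
#'
#' A KM curve is a tibble with columns `time` (cycles, strictly increasing,
#' non-negative) and `survival` (non-increasing, in `[0, 1]`).  Curve-fitting
#' functions accept any data frame with these columns; `km_curve()` just
#' validates and standardises one.
#'
#' @param time Non-negative times in model cycles, strictly increasing.
#' @param survival Survival proportions in `[0, 1]`, non-increasing.
#'
#' @return A tibble with columns `time` and `survival`.
#' @export
km_curve <- function(time, survival) {
  stopifnot(is.numeric(time), is.numeric(survival),
            length(time) == length(survival))
  if (any(time < 0)) {
    rlang::abort("KM times must be non-negative.",
                 class = "renalcea_error_domain")
  }
  if (any(diff(time) <= 0)) {
    rlang::abort("KM times must be strictly increasing.",
                 class = "renalcea_error_domain")
  }
  if (any(survival < 0 | survival > 1) || any(diff(survival) > 1e-12)) {
    rlang::abort("KM survival must be non-increasing and within [0, 1].",
                 class = "renalcea_error_domain")
  }
  tibble::tibble(time = as.numeric(time), survival = as.numeric(survival))
}

# Points usable for linearised fitting: t > 0 and S strictly inside (0, 1).
usable_km_points <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("time", "survival") %in% names(curve)))
  dplyr::filter(tibble::as_tibble(curve),
                .data$time > 0, .data$survival > 0, .data$survival < 1)
}

#' Fit a Weibull survival model to Kaplan-Meier points
#'
#' Ordinary least squares on the complementary-log-log linearisation
#' \eqn{\log(-\log S) = \log\lambda + \gamma \log t}.  The fit is
#' deterministic and exact on noiseless curves generated from the same
#' Weibull form.  Points with `S` equal to 0 or 1 (or `t = 0`) carry no
#' information on this scale and are dropped before regression.
#'
#' @param curve Data frame with columns `time` and `survival`
#'   (see [km_curve()]).
#'
#' @return A [weibull_params()] object with `fit_r_squared` set to the
#'   R-squared of the linearised regression.
#' @examples
#' wp <- weibull_params(0.05, 1)
#' crv <- km_curve(1:50, survival_at(wp, 1:50))
#' fit_weibull_km(crv)
#' @export
fit_weibull_km <- function(curve) {
  pts <- usable_km_points(curve)
  if (nrow(pts) < 3L) {
    rlang::abort(
      sprintf("Weibull fitting needs at least 3 usable points; got %d.",
              nrow(pts)),
      class = "renalcea_error_fit"
    )
  }
  fit <- stats::lm(log(-log(survival)) ~ log(time), data = pts)
  co <- stats::coef(fit)
  scale <- exp(unname(co[1L]))
  shape <- unname(co[2L])
  if (!is.finite(scale) || !is.finite(shape) || shape <= 0) {
    rlang::abort("Weibull fit did not yield positive parameters.",
                 class = "renalcea_error_fit")
  }
  # R^2 on the linearised scale, computed directly (summary.lm warns on
  # numerically perfect fits)
  y <- log(-log(pts$survival))
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  weibull_params(scale, shape, fit_r_squared = r2)
}

# Survival functions for the four candidate parametric families.
# Parameterisations:
#   weibull      S = exp(-scale * t^shape)
#   log-logistic S = 1 / (1 + (scale * t)^shape)
#   log-normal   S = 1 - pnorm((log t - meanlog) / sdlog)
#   logistic     S = 1 / (1 + exp((t - location) / scale))
family_survival <- function(family, params, t) {
  switch(family,
    "weibull" = exp(-params[["scale"]] * t^params[["shape"]]),
    "log-logistic" = 1 / (1 + (params[["scale"]] * t)^params[["shape"]]),
    "log-normal" = 1 - stats::pnorm((log(t) - params[["meanlog"]]) /
                                      params[["sdlog"]]),
    "logistic" = 1 / (1 + exp((t - params[["location"]]) /
                                params[["scale"]])),
    rlang::abort(sprintf("Unknown survival family '%s'.", family))
  )
}

# Deterministic linearised fit of one family; returns NULL when the
# linearisation produces inadmissible parameters for that family.
fit_one_family <- function(family, pts) {
  t <- pts$time
  s <- pts$survival
  params <- switch(family,
    "weibull" = {
      co <- stats::coef(stats::lm(log(-log(s)) ~ log(t)))
      c(scale = exp(unname(co[1])), shape = unname(co[2]))
    },
    "log-logistic" = {
      # log(1/S - 1) = shape*log(scale) + shape*log(t)
      co <- stats::coef(stats::lm(log(1 / s - 1) ~ log(t)))
      shape <- unname(co[2])
      c(scale = exp(unname(co[1]) / shape), shape = shape)
    },
    "log-normal" = {
      # qnorm(1 - S) = (log t - meanlog) / sdlog
      co <- stats::coef(stats::lm(stats::qnorm(1 - s) ~ log(t)))
      sdlog <- 1 / unname(co[2])
      c(meanlog = -unname(co[1]) * sdlog, sdlog = sdlog)
    },
    "logistic" = {
      # log(1/S - 1) = (t - location) / scale
      co <- stats::coef(stats::lm(log(1 / s - 1) ~ t))
      scl <- 1 / unname(co[2])
      c(location = -unname(co[1]) * scl, scale = scl)
    }
  )
  admissible <- switch(family,
    "weibull" = ,
    "log-logistic" = params[["scale"]] > 0 && params[["shape"]] > 0,
    "log-normal" = params[["sdlog"]] > 0,
    "logistic" = params[["scale"]] > 0
  )
  if (!all(is.finite(params)) || !isTRUE(admissible)) return(NULL)
  params
}

#' Fit all four candidate parametric survival families
#'
#' Fits Weibull, log-logistic, log-normal and logistic survival models to
#' the same Kaplan-Meier point set by deterministic linearised least
#' squares, and ranks them by R-squared computed on the survival scale
#' (observed vs fitted `S`), so that the statistic is comparable across
#' families.  The family with the highest R-squared is flagged `best`.
#'
#' @inheritParams fit_weibull_km
#'
#' @return A tibble with one row per family and columns `family`,
#'   `params` (named-numeric list column), `r_squared` and `best`.
#' @export
fit_all_families <- function(curve) {
  pts <- usable_km_points(curve)
  if (nrow(pts) < 3L) {
    rlang::abort(
      sprintf("Parametric fitting needs at least 3 usable points; got %d.",
              nrow(pts)),
      class = "renalcea_error_fit"
    )
  }
  families <- c("weibull", "log-logistic", "log-normal", "logistic")
  ss_tot <- sum((pts$survival - mean(pts$survival))^2)
  rows <- purrr::map(families, function(fam) {
    params <- fit_one_family(fam, pts)
    if (is.null(params)) {
      return(tibble::tibble(family = fam, params = list(NULL),
                            r_squared = -Inf))
    }
    fitted <- family_survival(fam, params, pts$time)
    r2 <- 1 - sum((pts$survival - fitted)^2) / ss_tot
    tibble::tibble(family = fam, params = list(params), r_squared = r2)
  })
  out <- dplyr::bind_rows(rows)
  out$best <- seq_len(nrow(out)) == which.max(out$r_squared)
  dplyr::arrange(out, dplyr::desc(.data$r_squared))
}

#' Per-cycle background mortality from a life table
#'
#' Converts the annual all-cause death probability at the (floored) current
#' age to the model's cycle length via
#' \eqn{1 - (1 - q)^{\mathrm{cycle\_days}/365.25}}.
#'
#' @param table Life table: data frame with columns `age` (integer years)
#'   and `annual_death_prob` in `[0, 1]`.  See [fixture_life_table()].
#' @param age Current age in years (real); looked up at `floor(age)`.
#' @param cycle_days Cycle length in days.
#'
#' @return Per-cycle death probability.
#' @export
background_death_prob <- function(table, age, cycle_days) {
  stopifnot(is.data.frame(table),
            all(c("age", "annual_death_prob") %in% names(table)),
            is.numeric(age), length(age) == 1L,
            is.numeric(cycle_days), cycle_days > 0)
  idx <- match(floor(age), table$age)
  if (is.na(idx)) {
    rlang::abort(
      sprintf("Life table does not cover age %d.", floor(age)),
      class = "renalcea_error_lookup"
    )
  }
  q <- table$annual_death_prob[idx]
  1 - (1 - q)^(cycle_days / 365.25)
}

#' Read or write the two-column interchange formats
#'
#' Life tables are CSVs with header `age,annual_death_prob`; KM curves are
#' CSVs with header `time_cycles,survival`.
#'
#' @param path File path.
#' @param table,curve Object to write.
#' @return The tibble read, or (for writers) `path` invisibly.
#' @name interchange
NULL

#' @rdname interchange
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("age", "annual_death_prob") %in% names(df))) {
    rlang::abort("Life-table CSV must have columns 'age' and 'annual_death_prob'.",
                 class = "renalcea_error_io")
  }
  if (any(df$annual_death_prob < 0 | df$annual_death_prob > 1)) {
    rlang::abort("Life-table probabilities must lie in [0, 1].",
                 class = "renalcea_error_io")
  }
  tibble::as_tibble(df[c("age", "annual_death_prob")])
}

#' @rdname interchange
#' @export
write_life_table <- function(table, path) {
  stopifnot(all(c("age", "annual_death_prob") %in% names(table)))
  utils::write.csv(table[c("age", "annual_death_prob")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname interchange
#' @export
read_km_curve <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_cycles", "survival") %in% names(df))) {
    rlang::abort("KM CSV must have columns 'time_cycles' and 'survival'.",
                 class = "renalcea_error_io")
  }
  km_curve(df$time_cycles, df$survival)
}

#' @rdname interchange
#' @export
write_km_curve <- function(curve, path) {
  stopifnot(all(c("time", "survival") %in% names(curve)))
  out <- data.frame(time_cycles = curve$time, survival = curve$survival)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
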