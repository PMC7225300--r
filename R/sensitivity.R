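#' Parameter range for sensitivity analysis
#'
#' One sensitivity-analysis parameter with its base-case value, low/high
#' range and sampling distribution (gamma for costs and prices, beta for
#' utilities and probabilities).  Where no published range exists the
#' convention is plus/minus 20% of the base case.
#'
#' @param name Parameter label understood by the configuration mapper
#'   (see [model_parameters()] for the naming scheme).
#' @param base,low,high Base-case value and range, `low <= base <= high`.
#' @param distribution `"gamma"` or `"beta"`.
#'
#' @return A one-row tibble.
#' @export
param_range <- function(name, base, low, high,
                        distribution = c("gamma", "beta")) {
  distribution <- match.arg(distribution)
  if (!(is.numeric(base) && is.numeric(low) && is.numeric(high)) ||
      low > base || base > high) {
    rlang::abort(
      sprintf("Parameter '%s' violates low <= base <= high.", name),
      class = "renalcea_error_config"
    )
  }
  if (distribution == "beta" && (low < 0 || high > 1)) {
    rlang::abort(
      sprintf("Beta-distributed parameter '%s' must lie in [0, 1].", name),
      class = "renalcea_error_config"
    )
  }
  tibble::tibble(name = name, base = base, low = low, high = high,
                 distribution = distribution)
}

pm20 <- function(base, cap = Inf) {
  c(low = 0.8 * base, high = min(cap, 1.2 * base))
}

#' Sensitivity-analysis parameter table for a configuration
#'
#' Enumerates the parameters entering the one-way and probabilistic
#' sensitivity analyses, mirroring the input table's distribution
#' assignments: unit prices and costs (gamma) with their published ranges
#' (plus/minus 20% where none is published), health-state utilities and
#' adverse-event probabilities (beta, plus/minus 20%, capped at 1).  The
#' progressed-disease utility is identical in both arms and is treated as
#' a single shared parameter.  Survival (Weibull) parameters are not
#' sampled, matching the input table, which assigns them no distribution;
#' this is a documented limitation.
#'
#' Naming scheme: `price_<drug>`, `cost_administration`,
#' `cost_supportive_care`, `cost_ae_<event>`, `utility_pfs_<arm>`,
#' `utility_pd`, `prob_<event>_<arm>`.
#'
#' @param config A configuration list (see [rcc_base_config()]).
#' @return A tibble of [param_range()] rows.
#' @export
model_parameters <- function(config) {
  rows <- list()
  for (d in names(config$drugs)) {
    dd <- config$drugs[[d]]
    rng <- if (is.null(dd$range)) pm20(dd$unit_price) else dd$range
    rows <- c(rows, list(param_range(paste0("price_", d), dd$unit_price,
                                     rng[[1]], rng[[2]], "gamma")))
  }
  adm <- config$costs$administration_per_unit
  rows <- c(rows, list(param_range("cost_administration", adm$value,
                                   adm$range[[1]], adm$range[[2]],
                                   "gamma")))
  sup <- config$costs$supportive_care_per_cycle
  rows <- c(rows, list(param_range("cost_supportive_care", sup$value,
                                   sup$range[[1]], sup$range[[2]],
                                   "gamma")))
  for (e in names(config$adverse_event_costs)) {
    ec <- config$adverse_event_costs[[e]]
    rng <- if (is.null(ec$range)) pm20(ec$value) else ec$range
    rows <- c(rows, list(param_range(paste0("cost_ae_", e), ec$value,
                                     rng[[1]], rng[[2]], "gamma")))
  }
  for (a in names(config$arms)) {
    u <- config$utilities[[paste0("pfs_", a)]]
    rng <- pm20(u, cap = 1)
    rows <- c(rows, list(param_range(paste0("utility_pfs_", a), u,
                                     rng[[1]], rng[[2]], "beta")))
  }
  updr <- pm20(config$utilities$pd, cap = 1)
  rows <- c(rows, list(param_range("utility_pd", config$utilities$pd,
                                   updr[[1]], updr[[2]], "beta")))
  for (a in names(config$arms)) {
    for (ev in config$arms[[a]]$adverse_events) {
      rng <- pm20(ev$probability, cap = 1)
      rows <- c(rows, list(param_range(
        paste0("prob_", ev$name, "_", a), ev$probability,
        rng[[1]], rng[[2]], "beta"
      )))
    }
  }
  dplyr::bind_rows(rows)
}

# Write one named parameter value back into the configuration.
set_config_param <- function(config, name, value) {
  if (grepl("^price_", name)) {
    drug <- sub("^price_", "", name)
    stopifnot(drug %in% names(config$drugs))
    config$drugs[[drug]]$unit_price <- value
  } else if (name == "cost_administration") {
    config$costs$administration_per_unit$value <- value
  } else if (name == "cost_supportive_care") {
    config$costs$supportive_care_per_cycle$value <- value
  } else if (grepl("^cost_ae_", name)) {
    ev <- sub("^cost_ae_", "", name)
    stopifnot(ev %in% names(config$adverse_event_costs))
    config$adverse_event_costs[[ev]]$value <- value
  } else if (grepl("^utility_pfs_", name)) {
    arm <- sub("^utility_pfs_", "", name)
    stopifnot(paste0("pfs_", arm) %in% names(config$utilities))
    config$utilities[[paste0("pfs_", arm)]] <- value
  } else if (name == "utility_pd") {
    config$utilities$pd <- value
  } else if (grepl("^prob_", name)) {
    bits <- sub("^prob_", "", name)
    arm <- NULL
    for (a in names(config$arms)) {
      if (grepl(paste0("_", a, "$"), bits)) {
        arm <- a
        ev <- sub(paste0("_", a, "$"), "", bits)
      }
    }
    if (is.null(arm)) {
      rlang::abort(sprintf("Cannot map parameter '%s' to an arm.", name),
                   class = "renalcea_error_config")
    }
    idx <- which(purrr::map_chr(config$arms[[arm]]$adverse_events,
                                "name") == ev)
    stopifnot(length(idx) == 1L)
    config$arms[[arm]]$adverse_events[[idx]]$probability <- value
  } else {
    rlang::abort(sprintf("Unknown sensitivity parameter '%s'.", name),
                 class = "renalcea_error_config")
  }
  config
}

apply_param_vector <- function(config, values) {
  for (nm in names(values)) {
    config <- set_config_param(config, nm, values[[nm]])
  }
  config
}

#' One-way (tornado) deterministic sensitivity analysis
#'
#' Re-runs the full two-arm comparison with each parameter set to its low
#' and then its high value, all others held at base, and reports the ICER
#' at both ends together with the absolute spread, sorted by descending
#' spread (the tornado ordering).
#'
#' @param config A configuration list.
#' @param parameters Parameter table from [model_parameters()] (or built
#'   with [param_range()]).
#' @param life_table Life table for background mortality.
#'
#' @return A tibble with columns `name`, `base`, `low`, `high`,
#'   `icer_at_low`, `icer_at_high`, `spread`, sorted by `spread`.
#' @export
one_way_dsa <- function(config, parameters = model_parameters(config),
                        life_table = fixture_life_table()) {
  stopifnot(is.data.frame(parameters),
            all(c("name", "base", "low", "high", "distribution") %in%
                  names(parameters)))
  bad <- parameters$low > parameters$base |
    parameters$base > parameters$high |
    (parameters$distribution == "beta" &
       (parameters$low < 0 | parameters$high > 1))
  if (any(bad)) {
    rlang::abort(
      paste0("Invalid range for parameter(s): ",
             paste(parameters$name[bad], collapse = ", ")),
      class = "renalcea_error_config"
    )
  }
  icer_at <- function(name, value) {
    res <- run_base_case(set_config_param(config, name, value),
                         life_table)
    res$icer
  }
  out <- purrr::pmap(
    parameters[c("name", "low", "high")],
    function(name, low, high) {
      tibble::tibble(
        name = name,
        icer_at_low = icer_at(name, low),
        icer_at_high = icer_at(name, high)
      )
    }
  )
  out <- dplyr::bind_rows(out)
  out <- dplyr::left_join(parameters[c("name", "base", "low", "high")],
                          out, by = "name")
  out$spread <- abs(out$icer_at_high - out$icer_at_low)
  dplyr::arrange(out, dplyr::desc(.data$spread))
}

#' Draw one probabilistic-sensitivity-analysis parameter vector
#'
#' Costs and prices are drawn from gamma distributions moment-matched to
#' `mean = base` and `sd = (high - low) / (2 * 1.96)` (ranges read as
#' approximate 95% intervals); utilities and probabilities from beta
#' distributions moment-matched to `mean = base` and `sd = 0.2 * base`,
#' with the sd shrunk (with a warning) if the beta moments are infeasible.
#' Degenerate ranges (`low == high`) return the base value exactly.
#'
#' @param parameters Parameter table from [model_parameters()].
#' @param seed Integer seed (required); the draw is deterministic given it.
#'
#' @return A named numeric vector of sampled values.
#' @export
sample_params <- function(parameters, seed) {
  stopifnot(!missing(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  draws <- purrr::pmap_dbl(
    parameters[c("name", "base", "low", "high", "distribution")],
    function(name, base, low, high, distribution) {
      if (low == high) return(base)
      if (distribution == "gamma") {
        sd <- (high - low) / (2 * 1.96)
        if (sd == 0 || base == 0) return(base)
        shape <- base^2 / sd^2
        stats::rgamma(1L, shape = shape, rate = shape / base)
      } else {
        m <- base
        if (m <= 0 || m >= 1) return(base)
        sd <- 0.2 * m
        sd_max <- sqrt(m * (1 - m))
        if (sd >= sd_max) {
          rlang::warn(sprintf(
            "Beta moments infeasible for '%s'; shrinking sd from %.4f to %.4f.",
            name, sd, 0.95 * sd_max))
          sd <- 0.95 * sd_max
        }
        nu <- m * (1 - m) / sd^2 - 1
        stats::rbeta(1L, shape1 = m * nu, shape2 = (1 - m) * nu)
      }
    }
  )
  stats::setNames(draws, parameters$name)
}

#' Probabilistic sensitivity analysis
#'
#' Runs `n` Monte-Carlo draws.  A master seed spawns one substream seed
#' per draw (so increasing `n` leaves earlier draws unchanged); each draw
#' samples the full parameter vector with [sample_params()], rebuilds both
#' arms and records incremental cost, incremental QALYs and net monetary
#' benefit at the configured willingness-to-pay.
#'
#' @param config A configuration list.
#' @param n Number of draws (>= 1); the reference analysis uses 1,000.
#' @param seed Master integer seed (required).
#' @param parameters Parameter table from [model_parameters()].
#' @param life_table Life table for background mortality.
#'
#' @return An object of class `cea_psa` with elements `draws` (tibble:
#'   one row per draw with the sampled parameters and results), `wtp`,
#'   `n`, `seed` and `reference`/`comparator` labels.
#' @export
run_psa <- function(config, n, seed,
                    parameters = model_parameters(config),
                    life_table = fixture_life_table()) {
  stopifnot(is.numeric(n), n >= 1, !missing(seed))
  validate_config(config)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  substreams <- sample.int(.Machine$integer.max, n, replace = TRUE)
  wtp <- config$model$wtp
  rows <- purrr::map(seq_len(n), function(i) {
    values <- sample_params(parameters, substreams[i])
    res <- run_base_case(apply_param_vector(config, values), life_table)
    g <- glance(res)
    dplyr::bind_cols(
      tibble::tibble(draw = i, substream_seed = substreams[i]),
      tibble::as_tibble(as.list(values)),
      tibble::tibble(
        cost_reference = g$cost_reference,
        qalys_reference = g$qalys_reference,
        cost_comparator = g$cost_comparator,
        qalys_comparator = g$qalys_comparator,
        delta_cost = g$delta_cost,
        delta_qaly = g$delta_qaly,
        nmb = wtp * g$delta_qaly - g$delta_cost
      )
    )
  })
  structure(
    list(draws = dplyr::bind_rows(rows), wtp = wtp, n = n, seed = seed,
         reference = config$model$reference_arm,
         comparator = config$model$comparator_arm),
    class = "cea_psa"
  )
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("<cea_psa> %d draws (seed %s), %s vs %s\n", x$n,
              format(x$seed), x$comparator, x$reference))
  cat(sprintf("  P(cost-effective at $%s/QALY) = %.3f\n",
              format(x$wtp, big.mark = ","), prob_cost_effective(x)))
  invisible(x)
}

#' Probability the comparator is cost-effective at a threshold
#'
#' Fraction of PSA draws with strictly positive net monetary benefit at
#' willingness-to-pay `wtp`; a tie at exactly zero counts as not
#' cost-effective.
#'
#' @param psa A `cea_psa` object.
#' @param wtp Willingness-to-pay; defaults to the analysis threshold.
#' @return A proportion in `[0, 1]`.
#' @export
prob_cost_effective <- function(psa, wtp = psa$wtp) {
  stopifnot(inherits(psa, "cea_psa"))
  mean(wtp * psa$draws$delta_qaly - psa$draws$delta_cost > 0)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value in `wtp_grid`, the probability that
#' each strategy is cost-effective: for the comparator, the fraction of
#' draws with positive net monetary benefit; for the reference, the
#' complement (ties favour the reference), so the two curves sum to 1.
#'
#' @param psa A `cea_psa` object.
#' @param wtp_grid Increasing vector of willingness-to-pay values.
#' @return A tibble with columns `wtp`, `strategy`, `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 400000, by = 10000)) {
  stopifnot(inherits(psa, "cea_psa"), is.numeric(wtp_grid),
            length(wtp_grid) >= 1)
  if (nrow(psa$draws) == 0L) {
    rlang::abort("PSA contains no draws.",
                 class = "renalcea_error_contract")
  }
  p <- purrr::map_dbl(wtp_grid, ~ prob_cost_effective(psa, wtp = .x))
  dplyr::bind_rows(
    tibble::tibble(wtp = wtp_grid, strategy = psa$comparator,
                   probability = p),
    tibble::tibble(wtp = wtp_grid, strategy = psa$reference,
                   probability = 1 - p)
  )
}

#' Tidiers for a probabilistic sensitivity analysis
#'
#' `tidy()` returns the per-draw results table; `glance()` a one-row
#' summary with the probability of cost-effectiveness at the analysis
#' threshold.
#'
#' @param x A `cea_psa`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cea_psa
#' @export
tidy.cea_psa <- function(x, ...) {
  x$draws
}

#' @rdname tidy.cea_psa
#' @method glance cea_psa
#' @export
glance.cea_psa <- function(x, ...) {
  tibble::tibble(
    n = x$n, seed = x$seed, wtp = x$wtp,
    mean_delta_cost = mean(x$draws$delta_cost),
    mean_delta_qaly = mean(x$draws$delta_qaly),
    prob_cost_effective = prob_cost_effective(x)
  )
}
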