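#' Base-case model configuration for first-line advanced RCC
#'
#' Returns the full two-arm configuration of the base-case analysis as a
#' nested list (serialisable to YAML with [write_config()]): Weibull PFS/OS
#' parameters per arm, dosing schedules (avelumab 10 mg/kg IV every 2
#' weeks at an assumed 70 kg body weight, axitinib 5 mg orally twice
#' daily, sunitinib 50 mg/day for 4 of every 6 weeks), 2019-USD unit
#' prices with published ranges, grade >= 3 adverse-event probabilities
#' and per-event costs, state utilities, the subsequent-therapy mix after
#' progression, and the global model settings (6-week cycles, 10-year
#' horizon, 3% discounting, start age 61, WTP $150,000/QALY).
#'
#' The subsequent-therapy mix shares (cabozantinib 30.4% after the
#' combination; cabozantinib 10.8%, sunitinib 8.9%, nivolumab 41.4% after
#' sunitinib) are applied as branch probabilities of the progressed state,
#' with the residual receiving supportive care; this is the reading that
#' validates against the published arm totals.  The trial-reported uptake
#' fractions (20.8% / 39.2% of each arm receiving any subsequent therapy)
#' are carried in `subsequent_uptake` and can be activated with
#' [apply_subsequent_uptake()] to run the alternative reading in which the
#' shares apply only within that treated subset.
#'
#' @return A nested configuration list.
#' @examples
#' cfg <- rcc_base_config()
#' validate_config(cfg)
#' @export
rcc_base_config <- function() {
  list(
    model = list(
      cycle_days = 42,
      horizon_cycles = 87L,
      discount_rate_annual = 0.03,
      start_age_years = 61,
      wtp = 150000,
      body_weight_kg = 70,
      reference_arm = "sunitinib",
      comparator_arm = "combination"
    ),
    costs = list(
      administration_per_unit = list(value = 302.27,
                                     range = c(241.82, 362.73)),
      supportive_care_per_cycle = list(value = 1256,
                                       range = c(1022, 1489))
    ),
    drugs = list(
      avelumab = list(unit_price = 81.742, unit_mg = 10, range = NULL),
      axitinib = list(unit_price = 213.154, unit_mg = 5,
                      range = c(170.52, 255.78)),
      sunitinib = list(unit_price = 623.08, unit_mg = 50,
                       range = c(498.46, 747.7)),
      nivolumab = list(unit_price = 27.498, unit_mg = 1,
                       range = c(22, 33)),
      cabozantinib = list(unit_price = 491.299, unit_mg = 60,
                          range = c(393.04, 589.56))
    ),
    adverse_event_costs = list(
      hypertension = list(value = 209.004, range = c(167.20, 250.81)),
      diarrhea = list(value = 5991.38, range = c(4793.104, 7189.656)),
      anemia = list(value = 1947.189, range = c(1557.751, 2336.627)),
      thrombocytopenia = list(value = 4155.245, range = c(3324.20, 4986.29)),
      neutropenia = list(value = 1060.986, range = c(848.79, 1273.18)),
      ppe = list(value = 122.98, range = c(3.43, 1748))
    ),
    utilities = list(
      pfs_combination = 0.82,
      pfs_sunitinib = 0.73,
      pd = 0.66
    ),
    arms = list(
      combination = list(
        label = "avelumab + axitinib",
        pfs = list(scale = 0.05483, shape = 0.97914),
        os = list(scale = 0.00821, shape = 1.16584),
        regimen = list(
          list(drug = "avelumab", mg_per_kg = 10, admins_per_cycle = 3,
               route = "IV"),
          list(drug = "axitinib", mg_per_admin = 5, admins_per_cycle = 84,
               route = "oral")
        ),
        adverse_events = list(
          list(name = "hypertension", probability = 0.256),
          list(name = "diarrhea", probability = 0.067),
          list(name = "ppe", probability = 0.058)
        ),
        subsequent = list(
          fraction_treated = 1,
          mix = list(
            list(drug = "cabozantinib", mg_per_admin = 60,
                 admins_per_cycle = 42, route = "oral", share = 0.304)
          )
        )
      ),
      sunitinib = list(
        label = "sunitinib",
        pfs = list(scale = 0.07396, shape = 1.02298),
        os = list(scale = 0.01117, shape = 1.11967),
        regimen = list(
          list(drug = "sunitinib", mg_per_admin = 50, admins_per_cycle = 28,
               route = "oral")
        ),
        adverse_events = list(
          list(name = "hypertension", probability = 0.117),
          list(name = "anemia", probability = 0.082),
          list(name = "thrombocytopenia", probability = 0.062),
          list(name = "neutropenia", probability = 0.08)
        ),
        subsequent = list(
          fraction_treated = 1,
          mix = list(
            list(drug = "cabozantinib", mg_per_admin = 60,
                 admins_per_cycle = 42, route = "oral", share = 0.108),
            list(drug = "sunitinib", mg_per_admin = 50,
                 admins_per_cycle = 42, route = "oral", share = 0.089),
            list(drug = "nivolumab", mg_per_admin = 240,
                 admins_per_cycle = 3, route = "IV", share = 0.414)
          )
        )
      )
    ),
    subsequent_uptake = list(combination = 0.208, sunitinib = 0.392)
  )
}

#' Switch to the uptake-restricted subsequent-therapy reading
#'
#' Copies each arm's `subsequent_uptake` fraction into its
#' `subsequent$fraction_treated`, so that the mix shares apply only within
#' the subset of progressed patients who received any subsequent therapy
#' and everyone else falls back to supportive care.
#'
#' @param config A configuration list.
#' @return The modified configuration.
#' @export
apply_subsequent_uptake <- function(config) {
  for (arm in names(config$subsequent_uptake)) {
    config$arms[[arm]]$subsequent$fraction_treated <-
      config$subsequent_uptake[[arm]]
  }
  config
}

#' Read, write and validate YAML configurations
#'
#' The configuration round-trips through YAML: `read_config(write_config(x))`
#' reproduces an equivalent structure.  `validate_config()` checks every
#' field the model needs and reports all problems at once, naming the
#' offending fields.
#'
#' @param config A configuration list.
#' @param path File path.
#' @return `read_config()` returns the configuration list;
#'   `write_config()` returns `path` invisibly; `validate_config()`
#'   returns the configuration invisibly or errors.
#' @name config_io
NULL

#' @rdname config_io
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname config_io
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname config_io
#' @export
validate_config <- function(config) {
  problems <- character()
  need <- function(ok, field) {
    if (!isTRUE(ok)) problems <<- c(problems, field)
  }
  num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

  m <- config$model
  need(num(m$cycle_days) && m$cycle_days > 0, "model$cycle_days")
  need(num(m$horizon_cycles) && m$horizon_cycles >= 1,
       "model$horizon_cycles")
  need(num(m$discount_rate_annual) && m$discount_rate_annual >= 0,
       "model$discount_rate_annual")
  need(num(m$start_age_years) && m$start_age_years > 0,
       "model$start_age_years")
  need(num(m$wtp) && m$wtp >= 0, "model$wtp")
  need(num(m$body_weight_kg) && m$body_weight_kg > 0,
       "model$body_weight_kg")
  need(is.character(m$reference_arm) &&
         m$reference_arm %in% names(config$arms), "model$reference_arm")
  need(is.character(m$comparator_arm) &&
         m$comparator_arm %in% names(config$arms), "model$comparator_arm")

  need(num(config$costs$administration_per_unit$value) &&
         config$costs$administration_per_unit$value >= 0,
       "costs$administration_per_unit$value")
  need(num(config$costs$supportive_care_per_cycle$value) &&
         config$costs$supportive_care_per_cycle$value >= 0,
       "costs$supportive_care_per_cycle$value")

  for (d in names(config$drugs)) {
    dd <- config$drugs[[d]]
    need(num(dd$unit_price) && dd$unit_price >= 0,
         sprintf("drugs$%s$unit_price", d))
    need(num(dd$unit_mg) && dd$unit_mg > 0, sprintf("drugs$%s$unit_mg", d))
  }
  for (e in names(config$adverse_event_costs)) {
    need(num(config$adverse_event_costs[[e]]$value) &&
           config$adverse_event_costs[[e]]$value >= 0,
         sprintf("adverse_event_costs$%s$value", e))
  }
  for (a in names(config$arms)) {
    arm <- config$arms[[a]]
    for (p in c("pfs", "os")) {
      need(num(arm[[p]]$scale) && arm[[p]]$scale > 0,
           sprintf("arms$%s$%s$scale", a, p))
      need(num(arm[[p]]$shape) && arm[[p]]$shape > 0,
           sprintf("arms$%s$%s$shape", a, p))
    }
    u <- config$utilities[[paste0("pfs_", a)]]
    need(num(u) && u >= 0 && u <= 1, sprintf("utilities$pfs_%s", a))
    for (comp in arm$regimen) {
      need(is.character(comp$drug) && comp$drug %in% names(config$drugs),
           sprintf("arms$%s$regimen drug '%s'", a, comp$drug %||% "?"))
      need(num(comp$admins_per_cycle) && comp$admins_per_cycle >= 0,
           sprintf("arms$%s$regimen$admins_per_cycle (%s)", a,
                   comp$drug %||% "?"))
      need(!is.null(comp$mg_per_admin) || !is.null(comp$mg_per_kg),
           sprintf("arms$%s$regimen dose fields (%s)", a,
                   comp$drug %||% "?"))
    }
    for (ev in arm$adverse_events) {
      need(is.character(ev$name) &&
             ev$name %in% names(config$adverse_event_costs),
           sprintf("arms$%s$adverse_events name '%s'", a, ev$name %||% "?"))
      need(num(ev$probability) && ev$probability >= 0 &&
             ev$probability <= 1,
           sprintf("arms$%s$adverse_events$probability (%s)", a,
                   ev$name %||% "?"))
    }
    sub <- arm$subsequent
    need(num(sub$fraction_treated) && sub$fraction_treated >= 0 &&
           sub$fraction_treated <= 1,
         sprintf("arms$%s$subsequent$fraction_treated", a))
    shares <- purrr::map_dbl(sub$mix, ~ .x$share %||% NA_real_)
    need(all(is.finite(shares)) && all(shares >= 0) &&
           sum(shares) <= 1 + 1e-9,
         sprintf("arms$%s$subsequent$mix shares", a))
  }
  need(num(config$utilities$pd) && config$utilities$pd >= 0 &&
         config$utilities$pd <= 1, "utilities$pd")

  if (length(problems)) {
    rlang::abort(
      paste0("Invalid configuration field(s): ",
             paste(problems, collapse = ", ")),
      class = "renalcea_error_config"
    )
  }
  invisible(config)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Build a drug_regimen from a list of config regimen components, resolving
# unit prices and priced units from the drug table.
build_regimen <- function(components, config) {
  rows <- purrr::map(components, function(comp) {
    drug <- config$drugs[[comp$drug]]
    if (is.null(drug)) {
      rlang::abort(sprintf("Unknown drug '%s' in regimen.", comp$drug),
                   class = "renalcea_error_config")
    }
    if (!is.null(comp$mg_per_kg)) {
      drug_component(comp$drug, drug$unit_price,
                     admins_per_cycle = comp$admins_per_cycle,
                     route = comp$route,
                     mg_per_kg = comp$mg_per_kg,
                     mg_per_unit = drug$unit_mg)
    } else {
      drug_component(comp$drug, drug$unit_price,
                     admins_per_cycle = comp$admins_per_cycle,
                     route = comp$route,
                     units_per_admin = comp$mg_per_admin / drug$unit_mg)
    }
  })
  drug_regimen(dplyr::bind_rows(rows),
               body_weight_kg = config$model$body_weight_kg)
}

#' Materialise arm specifications from a configuration
#'
#' @param config A validated configuration list.
#' @return A named list of [arm_spec()] objects.
#' @export
config_to_arms <- function(config) {
  validate_config(config)
  admin <- config$costs$administration_per_unit$value
  purrr::imap(config$arms, function(arm, arm_name) {
    aes <- ae_profile(
      name = purrr::map_chr(arm$adverse_events, "name"),
      probability = purrr::map_dbl(arm$adverse_events, "probability"),
      cost = purrr::map_dbl(
        arm$adverse_events,
        ~ config$adverse_event_costs[[.x$name]]$value
      )
    )
    mix_components <- purrr::map(arm$subsequent$mix, function(comp) {
      list(regimen = build_regimen(list(comp), config), share = comp$share)
    })
    arm_spec(
      name = arm$label %||% arm_name,
      pfs_model = weibull_params(arm$pfs$scale, arm$pfs$shape),
      os_model = weibull_params(arm$os$scale, arm$os$shape),
      utility_pfs = config$utilities[[paste0("pfs_", arm_name)]],
      utility_pd = config$utilities$pd,
      regimen = build_regimen(arm$regimen, config),
      ae_profile = aes,
      subsequent = subsequent_mix(
        fraction_treated = arm$subsequent$fraction_treated,
        components = mix_components,
        supportive_care_cost_per_cycle =
          config$costs$supportive_care_per_cycle$value
      ),
      admin_unit_cost = admin
    )
  })
}

config_to_model <- function(config) {
  model_config(
    cycle_days = config$model$cycle_days,
    horizon_cycles = config$model$horizon_cycles,
    discount_rate_annual = config$model$discount_rate_annual,
    start_age_years = config$model$start_age_years,
    wtp = config$model$wtp
  )
}

#' Run the base-case two-arm analysis
#'
#' Builds both arms from the configuration, runs the Markov cohort for
#' each, accumulates discounted costs, QALYs and life-years, and compares
#' the comparator arm against the reference with [icer()].
#'
#' @param config A configuration list (see [rcc_base_config()]).
#' @param life_table Life table for background mortality; defaults to the
#'   synthetic [fixture_life_table()].
#'
#' @return A `cea_comparison` (see [icer()]) with an extra `traces`
#'   element holding each arm's cohort trace.
#' @examples
#' res <- run_base_case(rcc_base_config())
#' tidy(res)
#' @export
run_base_case <- function(config, life_table = fixture_life_table()) {
  arms <- config_to_arms(config)
  cfg <- config_to_model(config)
  ref_name <- config$model$reference_arm
  cmp_name <- config$model$comparator_arm
  traces <- purrr::map(arms, run_cohort, cfg = cfg,
                       life_table = life_table)
  totals <- purrr::map2(traces, arms, accumulate_economics, cfg = cfg)
  res <- icer(totals[[ref_name]], totals[[cmp_name]], wtp = cfg$wtp)
  res$traces <- traces
  res
}

#' Run a drug price-reduction scenario
#'
#' Multiplies the configuration-level unit price of `drug` by `fraction`
#' (affecting every regimen that uses the drug) and reruns the base case.
#'
#' @inheritParams run_base_case
#' @param drug Drug label in `config$drugs`.
#' @param fraction Price multiplier in `(0, 1]`.
#' @return A `cea_comparison`.
#' @export
run_price_scenario <- function(config, drug, fraction,
                               life_table = fixture_life_table()) {
  if (!drug %in% names(config$drugs)) {
    rlang::abort(sprintf("Unknown drug '%s' in configuration.", drug),
                 class = "renalcea_error_config")
  }
  stopifnot(is.numeric(fraction), fraction > 0, fraction <= 1)
  config$drugs[[drug]]$unit_price <-
    config$drugs[[drug]]$unit_price * fraction
  run_base_case(config, life_table)
}

#' Run the hazard-ratio subgroup analysis
#'
#' Applies a proportional-hazards PFS (and optionally OS) hazard ratio to
#' the comparator arm's survival models and reruns the comparison.  The
#' hazard ratio has no default: the PD-L1-positive subgroup value comes
#' from the trial and must be supplied.
#'
#' @inheritParams run_base_case
#' @param pfs_hazard_ratio Positive PFS hazard ratio (required).
#' @param os_hazard_ratio Optional positive OS hazard ratio.
#' @return A `cea_comparison`.
#' @export
run_subgroup <- function(config, pfs_hazard_ratio, os_hazard_ratio = NULL,
                         life_table = fixture_life_table()) {
  if (missing(pfs_hazard_ratio) || is.null(pfs_hazard_ratio)) {
    rlang::abort(
      "A PFS hazard ratio is required for the subgroup analysis; the trial value is not bundled and must be supplied.",
      class = "renalcea_error_config"
    )
  }
  stopifnot(is.numeric(pfs_hazard_ratio), pfs_hazard_ratio > 0)
  cmp <- config$model$comparator_arm
  config$arms[[cmp]]$pfs$scale <-
    config$arms[[cmp]]$pfs$scale * pfs_hazard_ratio
  if (!is.null(os_hazard_ratio)) {
    stopifnot(is.numeric(os_hazard_ratio), os_hazard_ratio > 0)
    config$arms[[cmp]]$os$scale <-
      config$arms[[cmp]]$os$scale * os_hazard_ratio
  }
  run_base_case(config, life_table)
}
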