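#' Drug regimen components
#'
#' A regimen is a set of drug components dosed per administration and per
#' cycle.  Units per administration may be fixed (`units_per_admin`) or
#' weight-based (`mg_per_kg` with `mg_per_unit`), in which case they are
#' computed from the regimen's `body_weight_kg` at costing time.  Only
#' intravenous (`route = "IV"`) components attract an administration fee.
#'
#' @param drug Drug label.
#' @param unit_price Price in USD per priced unit (e.g. per 10 mg vial
#'   fraction for avelumab, per 5 mg tablet for axitinib).
#' @param admins_per_cycle Number of administrations per model cycle.
#' @param route `"oral"` or `"IV"`.
#' @param units_per_admin Priced units per administration, for fixed-dose
#'   components.
#' @param mg_per_kg,mg_per_unit Weight-based dosing: mg per kilogram per
#'   administration and mg per priced unit.
#'
#' @return A one-row tibble describing the component.
#' @export
drug_component <- function(drug, unit_price, admins_per_cycle,
                           route = c("oral", "IV"),
                           units_per_admin = NULL,
                           mg_per_kg = NULL, mg_per_unit = NULL) {
  route <- match.arg(route)
  if (!is.numeric(unit_price) || unit_price < 0) {
    rlang::abort(sprintf("Negative or invalid unit price for '%s'.", drug),
                 class = "renalcea_error_config")
  }
  stopifnot(is.numeric(admins_per_cycle), admins_per_cycle >= 0)
  fixed <- !is.null(units_per_admin)
  weight_based <- !is.null(mg_per_kg)
  if (fixed == weight_based) {
    rlang::abort(
      sprintf("Component '%s' needs exactly one of `units_per_admin` or `mg_per_kg`.",
              drug),
      class = "renalcea_error_config"
    )
  }
  if (weight_based && is.null(mg_per_unit)) {
    rlang::abort("Weight-based components need `mg_per_unit`.",
                 class = "renalcea_error_config")
  }
  tibble::tibble(
    drug = drug,
    unit_price = unit_price,
    admins_per_cycle = admins_per_cycle,
    route = route,
    units_per_admin = if (fixed) units_per_admin else NA_real_,
    mg_per_kg = if (weight_based) mg_per_kg else NA_real_,
    mg_per_unit = if (weight_based) mg_per_unit else NA_real_
  )
}

#' Assemble a drug regimen
#'
#' @param ... [drug_component()] rows (or data frames of them).
#' @param body_weight_kg Body weight used for weight-based components; the
#'   base case assumes 70 kg.
#'
#' @return An object of class `drug_regimen`.
#' @export
drug_regimen <- function(..., body_weight_kg = 70) {
  components <- dplyr::bind_rows(...)
  stopifnot(is.numeric(body_weight_kg), body_weight_kg > 0)
  structure(list(components = components, body_weight_kg = body_weight_kg),
            class = "drug_regimen")
}

resolve_units <- function(regimen) {
  comp <- regimen$components
  if (nrow(comp) == 0L) return(comp)
  dplyr::mutate(
    comp,
    units = dplyr::if_else(
      is.na(.data$units_per_admin),
      regimen$body_weight_kg * .data$mg_per_kg / .data$mg_per_unit,
      .data$units_per_admin
    )
  )
}

#' Drug plus administration cost of a regimen per model cycle
#'
#' Drug acquisition cost is linear in the dispensed amount (no vial
#' wastage): the sum over components of
#' `unit_price * units_per_admin * admins_per_cycle`.  Each intravenous
#' administration additionally incurs `admin_unit_cost`; oral dispensing
#' does not.
#'
#' @param regimen A [drug_regimen()].
#' @param admin_unit_cost Administration fee in USD per IV infusion.
#'
#' @return Cost in USD per cycle.
#' @export
regimen_cycle_cost <- function(regimen, admin_unit_cost) {
  stopifnot(inherits(regimen, "drug_regimen"),
            is.numeric(admin_unit_cost), admin_unit_cost >= 0)
  comp <- resolve_units(regimen)
  if (nrow(comp) == 0L) return(0)
  if (any(comp$unit_price < 0)) {
    rlang::abort("Negative unit price in regimen.",
                 class = "renalcea_error_config")
  }
  drug_cost <- sum(comp$unit_price * comp$units * comp$admins_per_cycle)
  admin_cost <- sum(comp$admins_per_cycle[comp$route == "IV"]) *
    admin_unit_cost
  drug_cost + admin_cost
}

#' Adverse-event profile and its expected one-off cost
#'
#' Grade >= 3 adverse events observed in at least 5% of either trial arm
#' are modelled as a single incidence-weighted lump sum charged to the
#' whole cohort at model entry (cycle 1).  The anaemia cost, priced per
#' month, is charged for one month.
#'
#' @param name Event labels.
#' @param probability Incidence proportions in `[0, 1]`.
#' @param cost One-off management cost in USD per event.
#'
#' @return `ae_profile()`: a tibble with columns `name`, `probability`,
#'   `cost`.  `ae_expected_cost()`: expected USD per patient.
#' @export
ae_profile <- function(name = character(), probability = numeric(),
                       cost = numeric()) {
  stopifnot(length(name) == length(probability),
            length(name) == length(cost))
  if (any(probability < 0 | probability > 1)) {
    rlang::abort("AE probabilities must lie in [0, 1].",
                 class = "renalcea_error_config")
  }
  if (any(cost < 0)) {
    rlang::abort("AE costs must be non-negative.",
                 class = "renalcea_error_config")
  }
  tibble::tibble(name = name, probability = probability, cost = cost)
}

#' @rdname ae_profile
#' @param profile An [ae_profile()] tibble.
#' @export
ae_expected_cost <- function(profile) {
  stopifnot(is.data.frame(profile),
            all(c("probability", "cost") %in% names(profile)))
  if (nrow(profile) == 0L) return(0)
  sum(profile$probability * profile$cost)
}

#' Subsequent-therapy mix for the progressed-disease state
#'
#' After progression a fraction of the cohort receives active subsequent
#' therapy split across named regimens; everyone else (the untreated
#' fraction plus any residual share of the treated fraction) receives
#' supportive care.
#'
#' @param fraction_treated Fraction of progressed patients eligible for
#'   active subsequent therapy, in `[0, 1]`.
#' @param components List of `list(regimen = <drug_regimen>, share = <num>)`
#'   entries; shares must sum to at most 1.
#' @param supportive_care_cost_per_cycle USD per cycle of supportive care.
#'
#' @return An object of class `subsequent_mix`.
#' @export
subsequent_mix <- function(fraction_treated, components = list(),
                           supportive_care_cost_per_cycle) {
  stopifnot(is.numeric(fraction_treated),
            fraction_treated >= 0, fraction_treated <= 1,
            is.numeric(supportive_care_cost_per_cycle),
            supportive_care_cost_per_cycle >= 0)
  shares <- purrr::map_dbl(components, "share")
  if (length(shares) && sum(shares) > 1 + 1e-9) {
    rlang::abort("Subsequent-therapy shares must sum to at most 1.",
                 class = "renalcea_error_config")
  }
  structure(
    list(fraction_treated = fraction_treated,
         components = components,
         supportive_care_cost_per_cycle = supportive_care_cost_per_cycle),
    class = "subsequent_mix"
  )
}

#' Expected per-cycle cost in the progressed-disease state
#'
#' `fraction_treated * sum(share_i * regimen_cost_i)` plus supportive care
#' for the complement `1 - fraction_treated * sum(share_i)` (the untreated
#' fraction and any residual share of treated patients whose drug is not
#' named).
#'
#' @param mix A [subsequent_mix()].
#' @param admin_unit_cost Administration fee per IV infusion, USD.
#'
#' @return Cost in USD per cycle spent in the progressed state.
#' @export
pd_cycle_cost <- function(mix, admin_unit_cost) {
  stopifnot(inherits(mix, "subsequent_mix"))
  shares <- purrr::map_dbl(mix$components, "share")
  costs <- purrr::map_dbl(mix$components,
                          ~ regimen_cycle_cost(.x$regimen, admin_unit_cost))
  treated <- mix$fraction_treated * sum(shares * costs)
  supportive <- (1 - mix$fraction_treated * sum(shares)) *
    mix$supportive_care_cost_per_cycle
  treated + supportive
}

#' Specification of one treatment strategy
#'
#' Bundles everything needed to run and cost one arm: the fitted PFS and
#' OS survival models, state utilities, the first-line regimen, the
#' adverse-event profile, the subsequent-therapy mix and the
#' administration fee.
#'
#' @param name Strategy label.
#' @param pfs_model,os_model [weibull_params()] for PFS and OS.
#' @param utility_pfs,utility_pd State utilities in `[0, 1]`.  The
#'   base-case inputs value progressed disease below progression-free
#'   survival; the ordering is not enforced here so that probabilistic
#'   sensitivity draws may cross.
#' @param regimen First-line [drug_regimen()].
#' @param ae_profile An [ae_profile()] tibble.
#' @param subsequent A [subsequent_mix()].
#' @param admin_unit_cost Administration fee per IV infusion, USD.
#'
#' @return An object of class `arm_spec`.
#' @export
arm_spec <- function(name, pfs_model, os_model, utility_pfs, utility_pd,
                     regimen, ae_profile, subsequent, admin_unit_cost) {
  stopifnot(inherits(pfs_model, "weibull_params"),
            inherits(os_model, "weibull_params"),
            is.numeric(utility_pfs), utility_pfs >= 0, utility_pfs <= 1,
            is.numeric(utility_pd), utility_pd >= 0, utility_pd <= 1,
            inherits(regimen, "drug_regimen"),
            is.data.frame(ae_profile),
            inherits(subsequent, "subsequent_mix"),
            is.numeric(admin_unit_cost), admin_unit_cost >= 0)
  structure(
    list(name = name, pfs_model = pfs_model, os_model = os_model,
         utility_pfs = utility_pfs, utility_pd = utility_pd,
         regimen = regimen, ae_profile = ae_profile,
         subsequent = subsequent, admin_unit_cost = admin_unit_cost),
    class = "arm_spec"
  )
}

#' Accumulate discounted costs, QALYs and life-years over a trace
#'
#' Applies the half-cycle correction to the trace, then for each cycle `k`
#' charges the first-line regimen (drug plus administration) to effective
#' PFS occupancy, the subsequent-therapy/supportive-care cost to effective
#' PD occupancy, and accrues utility-weighted person-time, all discounted
#' at the cycle's index.  The incidence-weighted adverse-event lump sum is
#' charged once at cycle 1.
#'
#' @param trace A trace from [run_cohort()] under the same `cfg`.
#' @param arm The [arm_spec()] that produced the trace.
#' @param cfg The [model_config()] used.
#'
#' @return An object of class `econ_totals` with elements `arm`,
#'   `total_cost`, `total_qalys`, `total_ly` and a per-cycle `breakdown`
#'   tibble.
#' @export
accumulate_economics <- function(trace, arm, cfg) {
  stopifnot(inherits(arm, "arm_spec"), inherits(cfg, "model_config"))
  if (nrow(trace) != cfg$horizon_cycles + 1L) {
    rlang::abort("Trace horizon does not match `cfg$horizon_cycles`.",
                 class = "renalcea_error_contract")
  }
  eff <- half_cycle_correct(trace)
  df <- discount_factor(eff$cycle, cfg)
  cyc_years <- cfg$cycle_days / 365.25

  c_pfs <- regimen_cycle_cost(arm$regimen, arm$admin_unit_cost)
  c_pd <- pd_cycle_cost(arm$subsequent, arm$admin_unit_cost)
  c_ae <- ae_expected_cost(arm$ae_profile)

  cost_cycle <- (eff$pfs * c_pfs + eff$pd * c_pd) * df
  cost_cycle[1L] <- cost_cycle[1L] + c_ae * df[1L]
  qaly_cycle <- (eff$pfs * arm$utility_pfs + eff$pd * arm$utility_pd) *
    cyc_years * df
  ly_cycle <- (eff$pfs + eff$pd) * cyc_years * df

  breakdown <- tibble::tibble(
    cycle = eff$cycle,
    eff_pfs = eff$pfs,
    eff_pd = eff$pd,
    discount_factor = df,
    cost = cost_cycle,
    qalys = qaly_cycle,
    life_years = ly_cycle
  )
  structure(
    list(arm = arm$name,
         total_cost = sum(cost_cycle),
         total_qalys = sum(qaly_cycle),
         total_ly = sum(ly_cycle),
         breakdown = breakdown),
    class = "econ_totals"
  )
}

#' @export
print.econ_totals <- function(x, ...) {
  cat(sprintf("<econ_totals> %s: cost $%s, %.3f QALYs, %.3f LYs\n",
              x$arm, format(round(x$total_cost), big.mark = ","),
              x$total_qalys, x$total_ly))
  invisible(x)
}

#' Tidiers for accumulated economic totals
#'
#' `tidy()` returns the per-cycle breakdown; `glance()` a one-row summary.
#'
#' @param x An `econ_totals` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy econ_totals
#' @export
tidy.econ_totals <- function(x, ...) {
  x$breakdown
}

#' @rdname tidy.econ_totals
#' @method glance econ_totals
#' @export
glance.econ_totals <- function(x, ...) {
  tibble::tibble(arm = x$arm, total_cost = x$total_cost,
                 total_qalys = x$total_qalys, total_ly = x$total_ly)
}
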