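#' Markov model configuration
#'
#' Global settings of the three-state cohort model: a 6-week (42-day) cycle,
#' an 87-cycle (10-year) horizon, 3% annual discounting of both costs and
#' health outcomes, a cohort starting age of 61 years, and a
#' willingness-to-pay threshold of $150,000 per QALY.
#'
#' @param cycle_days Cycle length in days.
#' @param horizon_cycles Number of cycles simulated.
#' @param discount_rate_annual Annual discount rate (>= 0) applied to costs
#'   and health outcomes alike.
#' @param start_age_years Cohort age at model entry, used for life-table
#'   background mortality.
#' @param wtp Willingness-to-pay threshold in USD per QALY.
#'
#' @return An object of class `model_config`.
#' @export
model_config <- function(cycle_days = 42, horizon_cycles = 87,
                         discount_rate_annual = 0.03,
                         start_age_years = 61, wtp = 150000) {
  stopifnot(is.numeric(cycle_days), cycle_days > 0,
            is.numeric(horizon_cycles), horizon_cycles >= 1,
            horizon_cycles == as.integer(horizon_cycles),
            is.numeric(start_age_years), start_age_years > 0,
            is.numeric(wtp), wtp >= 0)
  if (!is.numeric(discount_rate_annual) || discount_rate_annual < 0) {
    rlang::abort("`discount_rate_annual` must be non-negative.",
                 class = "renalcea_error_config")
  }
  structure(
    list(cycle_days = cycle_days,
         horizon_cycles = as.integer(horizon_cycles),
         discount_rate_annual = discount_rate_annual,
         start_age_years = start_age_years,
         wtp = wtp),
    class = "model_config"
  )
}

#' Per-cycle discount factor
#'
#' \eqn{(1 + r)^{-k \cdot \mathrm{cycle\_days} / 365.25}} for cycle index
#' `k`; equals 1 at `k = 0` and is strictly decreasing for a positive rate.
#'
#' @param k Non-negative cycle index (vectorised).
#' @param cfg A [model_config()].
#'
#' @return Numeric vector of discount factors in `(0, 1]`.
#' @export
discount_factor <- function(k, cfg) {
  stopifnot(inherits(cfg, "model_config"), is.numeric(k))
  if (any(k < 0)) {
    rlang::abort("Cycle index `k` must be non-negative.",
                 class = "renalcea_error_domain")
  }
  (1 + cfg$discount_rate_annual)^(-k * cfg$cycle_days / 365.25)
}

#' Run the three-state Markov cohort
#'
#' Simulates occupancy of the progression-free (PFS), progressed-disease
#' (PD) and death states over the model horizon for one treatment arm.
#' The whole cohort starts in PFS.  At each cycle `k >= 1` the per-cycle
#' death probability applied to both alive states is the larger of the
#' OS-model discrete hazard and the life-table background mortality at the
#' cohort's current age; the PFS-to-PD probability is the PFS-model
#' discrete hazard net of death, `max(0, p_exit - p_death)`.  Death is
#' absorbing.  With background mortality switched off the death column
#' reproduces the OS curve exactly.
#'
#' @param arm An [arm_spec()] (only `pfs_model` and `os_model` are used).
#' @param cfg A [model_config()].
#' @param life_table Life table covering all ages reached over the horizon
#'   (columns `age`, `annual_death_prob`); see [fixture_life_table()].
#'
#' @return A tibble (one row per cycle `0..horizon`) with columns `cycle`,
#'   `pfs`, `pd`, `death`, `age` and `discount_factor`.  Rows sum to 1.
#' @export
run_cohort <- function(arm, cfg, life_table) {
  stopifnot(inherits(cfg, "model_config"))
  pfs_model <- arm$pfs_model
  os_model <- arm$os_model
  stopifnot(inherits(pfs_model, "weibull_params"),
            inherits(os_model, "weibull_params"))
  h <- cfg$horizon_cycles
  cyc_years <- cfg$cycle_days / 365.25
  occ <- matrix(0, nrow = h + 1L, ncol = 3L,
                dimnames = list(NULL, c("pfs", "pd", "death")))
  occ[1L, ] <- c(1, 0, 0)
  ages <- cfg$start_age_years + (0:h) * cyc_years
  p_death_os <- transition_prob(os_model, seq_len(h))
  p_exit_pfs <- transition_prob(pfs_model, seq_len(h))
  for (k in seq_len(h)) {
    q_bg <- background_death_prob(life_table, ages[k], cfg$cycle_days)
    p_death <- max(p_death_os[k], q_bg)
    p_pd <- min(max(0, p_exit_pfs[k] - p_death), 1 - p_death)
    s <- occ[k, ]
    occ[k + 1L, "pfs"] <- s[["pfs"]] * (1 - p_death - p_pd)
    occ[k + 1L, "pd"] <- s[["pfs"]] * p_pd + s[["pd"]] * (1 - p_death)
    occ[k + 1L, "death"] <- s[["death"]] +
      (s[["pfs"]] + s[["pd"]]) * p_death
  }
  tibble::tibble(
    cycle = 0:h,
    pfs = occ[, "pfs"],
    pd = occ[, "pd"],
    death = occ[, "death"],
    age = ages,
    discount_factor = discount_factor(0:h, cfg)
  )
}

#' Half-cycle correction of a cohort trace
#'
#' Effective state occupancy for cycle `k` is the trapezoid average of the
#' memberships at the start and end of the cycle, so that transitions are
#' effectively treated as occurring mid-cycle.  Applied identically to
#' costs and health outcomes.
#'
#' @param trace A trace from [run_cohort()].
#'
#' @return A tibble with one row per cycle `1..horizon` and columns
#'   `cycle`, `pfs`, `pd`, `death` holding effective occupancies.
#' @export
half_cycle_correct <- function(trace) {
  stopifnot(is.data.frame(trace),
            all(c("cycle", "pfs", "pd", "death") %in% names(trace)))
  n <- nrow(trace)
  if (n < 2L) {
    rlang::abort("Trace must contain at least one cycle.",
                 class = "renalcea_error_domain")
  }
  tibble::tibble(
    cycle = trace$cycle[-1L],
    pfs = (trace$pfs[-n] + trace$pfs[-1L]) / 2,
    pd = (trace$pd[-n] + trace$pd[-1L]) / 2,
    death = (trace$death[-n] + trace$death[-1L]) / 2
  )
}

#' Export a cohort trace as CSV
#'
#' Writes the columns `cycle`, `pfs`, `pd`, `death`, `discount_factor`.
#'
#' @param trace A trace from [run_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  cols <- c("cycle", "pfs", "pd", "death", "discount_factor")
  stopifnot(all(cols %in% names(trace)))
  utils::write.csv(as.data.frame(trace[cols]), path, row.names = FALSE)
  invisible(path)
}
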