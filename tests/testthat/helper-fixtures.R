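# Shared fixtures, built in code.

# Life table with no background mortality, for oracle comparisons where the
# cohort death column must reproduce the OS closed form exactly.
zero_mortality_table <- function() {
  tibble::tibble(age = 30:130, annual_death_prob = 0)
}

# A minimal arm around given survival parameters and flat costs.
make_arm <- function(pfs = weibull_params(0.05483, 0.97914),
                     os = weibull_params(0.00821, 1.16584),
                     utility_pfs = 0.82, utility_pd = 0.66,
                     drug_price = 100, supportive = 1256,
                     ae = ae_profile(), admin = 302.27,
                     name = "test-arm") {
  reg <- drug_regimen(
    drug_component("drug-a", drug_price, admins_per_cycle = 42,
                   route = "oral", units_per_admin = 1)
  )
  arm_spec(
    name = name, pfs_model = pfs, os_model = os,
    utility_pfs = utility_pfs, utility_pd = utility_pd,
    regimen = reg, ae_profile = ae,
    subsequent = subsequent_mix(0, list(),
                                supportive_care_cost_per_cycle = supportive),
    admin_unit_cost = admin
  )
}

# Fake accumulated totals for pure ICER arithmetic.
fake_totals <- function(cost, qalys, ly = qalys, arm = "x") {
  structure(list(arm = arm, total_cost = cost, total_qalys = qalys,
                 total_ly = ly, breakdown = tibble::tibble()),
            class = "econ_totals")
}
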