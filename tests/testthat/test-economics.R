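admin_fee <- 302.27

test_that("regimen cycle costs match hand-computed dosing arithmetic", {
  expect_equal(regimen_cycle_cost(drug_regimen(), admin_fee), 0)

  combo <- drug_regimen(
    drug_component("avelumab", 81.742, admins_per_cycle = 3, route = "IV",
                   mg_per_kg = 10, mg_per_unit = 10),
    drug_component("axitinib", 213.154, admins_per_cycle = 84,
                   route = "oral", units_per_admin = 1),
    body_weight_kg = 70
  )
  # avelumab: 700 mg/admin = 70 units of 10 mg at $81.742, 3 admins
  avelumab_drug <- 70 * 81.742 * 3
  expect_equal(avelumab_drug, 17165.82)
  # axitinib: 5 mg twice daily for 42 days
  axitinib_drug <- 84 * 213.154
  expect_equal(regimen_cycle_cost(combo, admin_fee),
               avelumab_drug + 3 * admin_fee + axitinib_drug)
  expect_equal(3 * admin_fee, 906.81)

  sunitinib <- drug_regimen(
    drug_component("sunitinib", 623.08, admins_per_cycle = 28,
                   route = "oral", units_per_admin = 1)
  )
  expect_equal(regimen_cycle_cost(sunitinib, admin_fee), 17446.24)

  expect_error(drug_component("x", -1, 1, "oral", units_per_admin = 1),
               class = "renalcea_error_config")
})

test_that("expected adverse-event lump sums match the incidence weighting", {
  expect_equal(ae_expected_cost(ae_profile()), 0)
  combo <- ae_profile(
    name = c("hypertension", "diarrhea", "ppe"),
    probability = c(0.256, 0.067, 0.058),
    cost = c(209.004, 5991.38, 122.98)
  )
  expect_equal(ae_expected_cost(combo), 462.05, tolerance = 1e-4)
  sun <- ae_profile(
    name = c("hypertension", "anemia", "thrombocytopenia", "neutropenia"),
    probability = c(0.117, 0.082, 0.062, 0.08),
    cost = c(209.004, 1947.189, 4155.245, 1060.986)
  )
  expect_equal(ae_expected_cost(sun), 526.63, tolerance = 1e-4)
  expect_error(ae_profile("x", 1.2, 10), class = "renalcea_error_config")
})

test_that("progressed-state costs blend subsequent therapy and supportive care", {
  nivo <- drug_regimen(
    drug_component("nivolumab", 27.498, admins_per_cycle = 3, route = "IV",
                   units_per_admin = 240)
  )
  expect_equal(regimen_cycle_cost(nivo, admin_fee), 19798.56 + 906.81)
  cabo <- drug_regimen(
    drug_component("cabozantinib", 491.299, admins_per_cycle = 42,
                   route = "oral", units_per_admin = 1)
  )
  expect_equal(regimen_cycle_cost(cabo, admin_fee), 20634.56,
               tolerance = 1e-6)

  # no active therapy -> supportive care only
  none <- subsequent_mix(0, list(), supportive_care_cost_per_cycle = 1256)
  expect_equal(pd_cycle_cost(none, admin_fee), 1256)

  mix <- subsequent_mix(
    0.392,
    list(list(regimen = cabo, share = 0.108),
         list(regimen = nivo, share = 0.414)),
    supportive_care_cost_per_cycle = 1256
  )
  expected <- 0.392 * (0.108 * regimen_cycle_cost(cabo, admin_fee) +
                         0.414 * regimen_cycle_cost(nivo, admin_fee)) +
    (1 - 0.392 * (0.108 + 0.414)) * 1256
  expect_equal(pd_cycle_cost(mix, admin_fee), expected)

  expect_error(
    subsequent_mix(1, list(list(regimen = cabo, share = 0.7),
                           list(regimen = nivo, share = 0.6)),
                   supportive_care_cost_per_cycle = 0),
    class = "renalcea_error_config"
  )
})

test_that("accumulation identities hold in limiting cases", {
  cfg <- model_config()
  lt <- fixture_life_table()

  free <- make_arm(drug_price = 0, supportive = 0, admin = 0)
  tr <- run_cohort(free, cfg, lt)
  tot_free <- accumulate_economics(tr, free, cfg)
  expect_equal(tot_free$total_cost, 0)
  expect_gt(tot_free$total_qalys, 0)
  expect_lte(tot_free$total_qalys, tot_free$total_ly)

  # utilities of 1 without discounting make QALYs equal life-years
  cfg0 <- model_config(discount_rate_annual = 0)
  perfect <- make_arm(utility_pfs = 1, utility_pd = 1)
  tr0 <- run_cohort(perfect, cfg0, lt)
  tot0 <- accumulate_economics(tr0, perfect, cfg0)
  expect_equal(tot0$total_qalys, tot0$total_ly)

  # QALYs ignore prices; costs ignore utilities
  cheap <- make_arm(drug_price = 1)
  pricey <- make_arm(drug_price = 999)
  tot_cheap <- accumulate_economics(run_cohort(cheap, cfg, lt), cheap, cfg)
  tot_pricey <- accumulate_economics(run_cohort(pricey, cfg, lt),
                                     pricey, cfg)
  expect_equal(tot_pricey$total_qalys, tot_cheap$total_qalys)
  dim_util <- make_arm(utility_pfs = 0.5, utility_pd = 0.2)
  tot_dim <- accumulate_economics(run_cohort(dim_util, cfg, lt),
                                  dim_util, cfg)
  base_util <- make_arm()
  tot_base <- accumulate_economics(run_cohort(base_util, cfg, lt),
                                   base_util, cfg)
  expect_equal(tot_dim$total_cost, tot_base$total_cost)
  expect_lt(tot_dim$total_qalys, tot_base$total_qalys)

  # doubling the discount rate strictly shrinks both totals
  cfg6 <- model_config(discount_rate_annual = 0.06)
  arm <- make_arm()
  t3 <- accumulate_economics(run_cohort(arm, cfg, lt), arm, cfg)
  t6 <- accumulate_economics(run_cohort(arm, cfg6, lt), arm, cfg6)
  expect_lt(t6$total_cost, t3$total_cost)
  expect_lt(t6$total_qalys, t3$total_qalys)

  # total cost is non-decreasing in the unit price
  expect_gt(tot_pricey$total_cost,
            accumulate_economics(run_cohort(make_arm(drug_price = 1),
                                            cfg, lt),
                                 make_arm(drug_price = 1), cfg)$total_cost)
})

test_that("an immediately absorbing cohort is charged only the AE lump sum", {
  cfg <- model_config()
  lt <- zero_mortality_table()
  doomed <- make_arm(os = weibull_params(50, 1),
                     pfs = weibull_params(50, 1),
                     drug_price = 0, supportive = 0, admin = 0,
                     ae = ae_profile("hypertension", 0.256, 209.004))
  tr <- run_cohort(doomed, cfg, lt)
  expect_lt(tr$pfs[2] + tr$pd[2], 1e-12)
  tot <- accumulate_economics(tr, doomed, cfg)
  expect_equal(tot$total_cost,
               0.256 * 209.004 * discount_factor(1, cfg))
  # QALY residual is the half-cycle of the entry state
  expect_equal(tot$total_qalys,
               0.5 * doomed$utility_pfs * (42 / 365.25) *
                 discount_factor(1, cfg),
               tolerance = 1e-10)
})

test_that("economic tidiers expose per-cycle and total views", {
  cfg <- model_config()
  arm <- make_arm()
  tot <- accumulate_economics(run_cohort(arm, cfg, fixture_life_table()),
                              arm, cfg)
  td <- tidy(tot)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), cfg$horizon_cycles)
  expect_equal(sum(td$cost), tot$total_cost)
  g <- glance(tot)
  expect_equal(g$total_qalys, tot$total_qalys)
  expect_equal(g$arm, "test-arm")
})
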