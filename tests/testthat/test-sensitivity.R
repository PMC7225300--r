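config <- rcc_base_config()

test_that("parameter table mirrors the input table's distribution column", {
  params <- model_parameters(config)
  expect_true(all(c("price_avelumab", "price_axitinib",
                    "cost_supportive_care", "utility_pfs_combination",
                    "utility_pd", "prob_hypertension_sunitinib") %in%
                    params$name))
  # shared PD utility appears once, not per arm
  expect_equal(sum(grepl("^utility_pd", params$name)), 1)
  expect_true(all(params$low <= params$base & params$base <= params$high))
  beta <- params[params$distribution == "beta", ]
  expect_true(all(beta$low >= 0 & beta$high <= 1))
  # published ranges are used where they exist
  ax <- params[params$name == "price_axitinib", ]
  expect_equal(c(ax$low, ax$high), c(170.52, 255.78))
  # Weibull survival parameters are deliberately absent
  expect_false(any(grepl("scale|shape", params$name)))
  expect_error(param_range("bad", 1, 2, 0.5),
               "bad", class = "renalcea_error_config")
})

test_that("sampling is deterministic, respects supports, and hits its moments", {
  params <- model_parameters(config)
  d1 <- sample_params(params, seed = 99)
  d2 <- sample_params(params, seed = 99)
  expect_identical(d1, d2)
  expect_true(all(d1[grepl("^utility|^prob", names(d1))] >= 0))
  expect_true(all(d1[grepl("^utility|^prob", names(d1))] <= 1))
  expect_true(all(d1[grepl("^price|^cost", names(d1))] >= 0))

  # degenerate range returns base exactly
  degen <- param_range("price_avelumab", 81.742, 81.742, 81.742, "gamma")
  expect_identical(sample_params(degen, seed = 1)[["price_avelumab"]],
                   81.742)

  # gamma mean matches the base value (law of large numbers)
  sup <- params[params$name == "cost_supportive_care", ]
  draws <- vapply(1:4000, function(s) sample_params(sup, seed = s)[[1]],
                  numeric(1))
  expect_equal(mean(draws), 1256, tolerance = 0.02)

  # beta utility draws live in [0, 1]
  ut <- params[params$name == "utility_pfs_combination", ]
  udraws <- vapply(1:500, function(s) sample_params(ut, seed = s)[[1]],
                   numeric(1))
  expect_true(all(udraws >= 0 & udraws <= 1))
  expect_equal(mean(udraws), 0.82, tolerance = 0.05)
})

test_that("tornado rows are sorted by spread and inert parameters rank last", {
  params <- dplyr::bind_rows(
    param_range("utility_pfs_combination", 0.82, 0.656, 0.984, "beta"),
    param_range("price_axitinib", 213.154, 170.52, 255.78, "gamma"),
    # degenerate range: the ICER cannot depend on it
    param_range("cost_supportive_care", 1256, 1256, 1256, "gamma")
  )
  tor <- one_way_dsa(config, params)
  expect_equal(nrow(tor), 3)
  expect_true(all(diff(tor$spread) <= 0))
  expect_identical(tor$name[3], "cost_supportive_care")
  expect_equal(tor$spread[3], 0)
  # raising a combination drug price raises the ICER monotonically
  ax <- tor[tor$name == "price_axitinib", ]
  expect_lt(ax$icer_at_low, ax$icer_at_high)

  bad <- param_range("price_axitinib", 213.154, 170.52, 255.78, "gamma")
  bad$low <- 300
  expect_error(one_way_dsa(config, bad), "price_axitinib",
               class = "renalcea_error_config")
})

test_that("PSA is reproducible and earlier draws survive an increase in n", {
  p1 <- run_psa(config, n = 8, seed = 5)
  p2 <- run_psa(config, n = 8, seed = 5)
  expect_identical(p1$draws, p2$draws)
  p3 <- run_psa(config, n = 12, seed = 5)
  expect_identical(p1$draws, p3$draws[1:8, ])
})

test_that("degenerate distributions reproduce the base-case ICER exactly", {
  params <- model_parameters(config)
  params$low <- params$base
  params$high <- params$base
  psa <- run_psa(config, n = 3, seed = 1, parameters = params)
  base <- run_base_case(config)
  expect_equal(unique(psa$draws$delta_cost), base$delta_cost)
  expect_equal(unique(psa$draws$delta_qaly), base$delta_qaly)
  expect_identical(psa$draws$delta_cost / psa$draws$delta_qaly,
                   rep(base$icer, 3))
})

test_that("acceptability curves are complementary and behave at the limits", {
  psa <- run_psa(config, n = 40, seed = 3)
  grid <- c(0, 5e4, 15e4, 5e5, 1e9)
  cv <- ceac(psa, grid)
  expect_true(all(cv$probability >= 0 & cv$probability <= 1))
  wide <- tidyr::pivot_wider(cv, names_from = "strategy",
                             values_from = "probability")
  expect_equal(wide$combination + wide$sunitinib, rep(1, length(grid)))
  # at zero WTP only cost savings count
  expect_equal(wide$combination[wide$wtp == 0],
               mean(psa$draws$delta_cost < 0))
  # in the limit only QALY gains count
  expect_equal(wide$combination[wide$wtp == 1e9],
               mean(psa$draws$delta_qaly > 0))
  # monotone in WTP when every draw gains QALYs
  keep <- psa$draws$delta_qaly > 0
  psa_pos <- psa
  psa_pos$draws <- psa$draws[keep, ]
  cv_pos <- ceac(psa_pos, seq(0, 1e6, by = 5e4))
  probs <- cv_pos$probability[cv_pos$strategy == "combination"]
  expect_true(all(diff(probs) >= 0))
})

test_that("PSA tidiers summarise draws and thresholds", {
  psa <- run_psa(config, n = 10, seed = 2)
  expect_equal(nrow(tidy(psa)), 10)
  g <- glance(psa)
  expect_equal(g$n, 10)
  expect_equal(g$prob_cost_effective, prob_cost_effective(psa))
  expect_true(g$prob_cost_effective >= 0 && g$prob_cost_effective <= 1)
})
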