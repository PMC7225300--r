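test_that("Weibull survival function evaluates the closed form", {
  wp_sun <- weibull_params(0.07396, 1.02298)
  expect_identical(survival_at(wp_sun, 0), 1)
  expect_equal(survival_at(wp_sun, 1), exp(-0.07396))
  expect_equal(survival_at(wp_sun, 1), 0.92871, tolerance = 1e-5)

  wp_os <- weibull_params(0.00821, 1.16584)
  expect_equal(survival_at(wp_os, 87), 0.223, tolerance = 5e-3)

  t <- seq(0, 87, by = 0.5)
  s <- survival_at(wp_os, t)
  expect_true(all(diff(s) <= 0))
  expect_error(survival_at(wp_sun, -1), class = "renalcea_error_domain")
  expect_error(weibull_params(-0.1, 1), class = "renalcea_error_domain")
})

test_that("per-cycle transition probability is the discrete hazard", {
  wp_sun <- weibull_params(0.07396, 1.02298)
  expect_equal(transition_prob(wp_sun, 1), 1 - exp(-0.07396))
  expect_equal(transition_prob(wp_sun, 1), 0.07129, tolerance = 1e-4)
  expect_equal(transition_prob(weibull_params(0.05483, 0.97914), 1),
               0.05335, tolerance = 1e-4)
  # vanishing hazard limit
  expect_equal(transition_prob(weibull_params(1e-12, 1.1), 5), 0,
               tolerance = 1e-10)
  expect_error(transition_prob(wp_sun, 0), class = "renalcea_error_domain")
})

test_that("cumulative product of conditional survival recovers S(T)", {
  grid <- expand.grid(scale = c(0.005, 0.05483, 0.07396, 0.2),
                      shape = c(0.8, 0.97914, 1.11967, 1.5))
  for (i in seq_len(nrow(grid))) {
    wp <- weibull_params(grid$scale[i], grid$shape[i])
    tp <- transition_prob(wp, 1:87)
    expect_true(all(tp >= 0 & tp <= 1))
    # independent oracle: conditional survival ratios of the closed form
    cond <- survival_at(wp, 1:87) / survival_at(wp, 0:86)
    expect_equal(tp, 1 - cond, tolerance = 1e-12)
    expect_equal(cumprod(1 - tp), survival_at(wp, 1:87), tolerance = 1e-10)
  }
})

test_that("cloglog Weibull fit is the identity on noiseless curves", {
  wp <- weibull_params(0.05, 1.0)
  crv <- km_curve(1:50, survival_at(wp, 1:50))
  fit <- fit_weibull_km(crv)
  expect_equal(fit$scale, 0.05, tolerance = 1e-6)
  expect_equal(fit$shape, 1.0, tolerance = 1e-6)
  expect_gte(fit$fit_r_squared, 0.97)

  wp2 <- weibull_params(0.00821, 1.16584)
  fit2 <- fit_weibull_km(km_curve(1:87, survival_at(wp2, 1:87)))
  expect_equal(fit2$scale, wp2$scale, tolerance = 1e-6)
  expect_equal(fit2$shape, wp2$shape, tolerance = 1e-6)
})

test_that("fitting rejects curves with too few usable points", {
  crv <- km_curve(c(1, 2, 3), c(1, 0.5, 0))  # only one point inside (0,1)
  expect_error(fit_weibull_km(crv), "1", class = "renalcea_error_fit")
  expect_error(fit_all_families(crv), class = "renalcea_error_fit")
})

test_that("parameters are recovered from simulated censored KM data", {
  true <- weibull_params(0.07396, 1.02298)
  errs <- vapply(1:20, function(s) {
    sim <- simulate_km(true, n = 2000, censor_fraction = 0.1, seed = s)
    f <- fit_weibull_km(sim$curve)
    c(abs(f$scale - true$scale) / true$scale,
      abs(f$shape - true$shape) / true$shape)
  }, numeric(2))
  expect_lt(median(errs[1, ]), 0.10)
  expect_lt(median(errs[2, ]), 0.05)
})

test_that("cloglog fit agrees with a maximum-likelihood oracle", {
  skip_if_not_installed("flexsurv")
  sim <- simulate_km(weibull_params(0.07396, 1.02298), n = 2000,
                     censor_fraction = 0.1, seed = 11)
  ours <- fit_weibull_km(sim$curve)
  ml <- flexsurv::flexsurvreg(survival::Surv(time, status) ~ 1,
                              data = sim$cohort, dist = "weibull")
  # flexsurv: S(t) = exp(-(t/scale)^shape) -> lambda = scale^-shape
  co <- ml$res[, "est"]
  expect_equal(ours$shape, unname(co["shape"]), tolerance = 0.05)
  expect_equal(ours$scale, unname(co["scale"]^-co["shape"]),
               tolerance = 0.10)
})

test_that("family selection flags the generating family", {
  t <- 1:50
  wb <- fit_all_families(km_curve(t, exp(-0.06 * t^1.1)))
  expect_identical(wb$family[wb$best], "weibull")
  ll <- fit_all_families(km_curve(t, 1 / (1 + (0.08 * t)^1.3)))
  expect_identical(ll$family[ll$best], "log-logistic")
  # all four families are fitted and scored on a common point set
  expect_setequal(wb$family,
                  c("weibull", "log-logistic", "log-normal", "logistic"))
  expect_true(all(is.finite(wb$r_squared)))
})

test_that("Weibull wins on simulated Weibull KM curves in >=90% of replicates", {
  wp <- weibull_params(0.00821, 1.16584)
  wins <- vapply(1:20, function(s) {
    sim <- simulate_km(wp, n = 2000, censor_fraction = 0, seed = s)
    fits <- fit_all_families(sim$curve)
    fits$family[fits$best] == "weibull"
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("background mortality converts annual to per-cycle probability", {
  lt <- tibble::tibble(age = 60:70,
                       annual_death_prob = c(0, 1, 0.012, rep(0.5, 8)))
  expect_equal(background_death_prob(lt, 60.9, 42), 0)
  expect_equal(background_death_prob(lt, 61, 42), 1)
  expect_equal(background_death_prob(lt, 62.4, 42),
               1 - 0.988^(42 / 365.25))
  expect_equal(background_death_prob(lt, 62.4, 42), 0.001387,
               tolerance = 1e-3)
  expect_error(background_death_prob(lt, 59, 42),
               class = "renalcea_error_lookup")
})

test_that("KM curve validation enforces monotone survival", {
  expect_error(km_curve(c(1, 2), c(0.5, 0.8)),
               class = "renalcea_error_domain")
  expect_error(km_curve(c(2, 1), c(0.8, 0.5)),
               class = "renalcea_error_domain")
  expect_silent(km_curve(c(1, 2), c(0.8, 0.5)))
})
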