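test_that("elementary daily processes match hand-computed values", {
  co <- rice_coeff()
  expect_equal(daily_mean_temperature(30, 20), 25)
  expect_equal(daily_mean_temperature(18, 18), 18)
  expect_equal(daily_mean_temperature(25.5, 14.5), 20)
  expect_equal(gdd_increment(25, 12), 13)
  expect_equal(gdd_increment(10, 12), 0)
  expect_equal(gdd_increment(12, 12), 0)
  expect_equal(absorbed_radiation(16, 0, co), 0)
  expect_equal(absorbed_radiation(16, 2, co), 7.2 * (1 - exp(-1.2)), tolerance = 1e-12)
  expect_lt(abs(absorbed_radiation(16, 1e6, co) - 0.45 * 16), 1e-9)
  q <- 7.2 * (1 - exp(-1.2))
  expect_equal(biomass_increment(q, co), 3.49 * q, tolerance = 1e-12)
  expect_equal(biomass_increment(0, co), 0)
  expect_equal(biomass_increment(q, crop_coefficients("soybean")), 1.65 * q,
               tolerance = 1e-12)
  p <- default_initial_params()
  expect_equal(leaf_allocation(0, p), 0.675)
  expect_equal(leaf_allocation(0, calibration_params(0.2, 1.5, 1e-3, 0)), 0)
  expect_equal(leaf_allocation(1e5, calibration_params(0.2, 0.3, 1e-3, 0)), 0)
  dm <- biomass_increment(q, co)
  expect_equal(lai_increment(dm, 0.675, co), dm * 0.675 * 0.016, tolerance = 1e-12)
  expect_equal(lai_increment(dm, 0, co), 0)
  pc <- calibration_params(0.2, 0.325, 1.25e-3, 1.25e-3)
  expect_equal(senescence_decrement(4, 13, 0.5, pc), 0)
  expect_equal(senescence_decrement(4, 13, 0, pc), 1.25e-3 * 13 * 4, tolerance = 1e-12)
  expect_equal(senescence_decrement(4, 13, 0, calibration_params(0.2, 0.3, 1e-3, 0)), 0)
})

test_that("built-in crop coefficients carry the published values", {
  rice <- crop_coefficients("rice")
  soy <- crop_coefficients("soybean")
  expect_equal(unlist(rice[c("epsilon", "k", "s_leaf", "t_base", "beta")]),
               c(epsilon = 3.49, k = 0.60, s_leaf = 0.016, t_base = 12.0, beta = 0.45))
  expect_equal(unlist(soy[c("epsilon", "k", "s_leaf", "t_base", "beta")]),
               c(epsilon = 1.65, k = 0.71, s_leaf = 0.017, t_base = 10.0, beta = 0.45))
  expect_equal(unlist(unclass(default_initial_params())),
               c(l0 = 0.2, a = 0.325, b = 1.25e-3, c = 1.25e-3))
  over <- crop_coefficients("rice", epsilon = 2.0)
  expect_equal(over$epsilon, 2.0)
  expect_equal(over$k, 0.60)
  expect_error(crop_coefficients("rice", epsilon = -1), "positive")
  expect_error(calibration_params(-0.1, 0.3, 1e-3, 0), "nonnegative")
})

test_that("simulate matches the independent day-loop oracle on random draws", {
  for (s in 1:100) {
    w <- random_weather(n_days = sample(60:150, 1), seed = s)
    p <- random_params(seed = 1000 + s)
    traj <- simulate_rscm(w, rice_coeff(), p)
    ref <- oracle_simulate(w, rice_coeff(), p)
    for (col in c("gdd_cum", "lai", "biomass", "q_abs", "p1")) {
      denom <- pmax(abs(ref[[col]]), 1)
      expect_lt(max(abs(traj[[col]] - ref[[col]]) / denom), 1e-12)
    }
  }
})

test_that("constant-forcing simulation obeys the closed-form LAI recurrence", {
  n <- 100
  w <- data.frame(date = as.Date("2021-06-01") + 0:(n - 1),
                  tmax_c = 30, tmin_c = 20, srad_mj_m2 = 16, prcp_mm = 0)
  co <- rice_coeff()
  p <- calibration_params(l0 = 0.2, a = 0, b = 0, c = 0)
  traj <- simulate_rscm(w, co, p)
  L <- numeric(n)
  L[1] <- p$l0
  for (t in 2:n) {
    L[t] <- L[t - 1] + co$epsilon * co$s_leaf * co$beta * 16 * (1 - exp(-co$k * L[t - 1]))
  }
  expect_equal(traj$lai, L, tolerance = 1e-14)
  expect_true(all(traj$p1 == 1))
})

test_that("degenerate regimes: no radiation, immediate clamp, gaps", {
  n <- 60
  w <- data.frame(date = as.Date("2021-06-01") + 0:(n - 1),
                  tmax_c = 28, tmin_c = 18, srad_mj_m2 = 0, prcp_mm = 0)
  traj <- simulate_rscm(w, rice_coeff(), default_initial_params())
  expect_true(all(traj$biomass == traj$biomass[1]))
  expect_true(all(traj$lai == traj$lai[1]))

  clamp <- simulate_rscm(random_weather(80, seed = 5), rice_coeff(),
                         calibration_params(0.3, 1.2, 1e-3, 2e-3))
  expect_true(all(clamp$p1 == 0))
  expect_true(all(diff(clamp$lai) <= 0))
  expect_equal(clamp$lai[1], 0.3)

  w_gap <- random_weather(80, seed = 6)[-c(10, 11), ]
  expect_error(simulate_rscm(w_gap, rice_coeff(), default_initial_params()),
               class = "rscmlai_gap_error")
})

test_that("conservation and monotone-response invariants hold", {
  set.seed(404)
  for (s in 1:10) {
    w <- random_weather(100, seed = 300 + s)
    p <- random_params(seed = 400 + s)
    traj <- simulate_rscm(w, rice_coeff(), p)
    expect_true(all(diff(traj$biomass) >= 0))
    expect_true(all(diff(traj$gdd_cum) >= 0))
    expect_true(all(traj$q_abs >= 0 & traj$q_abs <= 0.45 * w$srad_mj_m2 + 1e-12))
    expect_true(all(traj$lai >= 0))

    hi_eps <- crop_coefficients("rice", epsilon = 3.49 * 1.3)
    expect_gte(simulate_rscm(w, hi_eps, p)$biomass[100], traj$biomass[100])
    hi_k <- crop_coefficients("rice", k = 0.8)
    expect_true(all(simulate_rscm(w, hi_k, p)$q_abs >= traj$q_abs - 1e-12))
  }
})

test_that("a window with missing start weather or bad params is rejected", {
  w <- random_weather(50, seed = 9)
  expect_error(simulate_rscm(w, rice_coeff(), default_initial_params(),
                             start = min(w$date) - 5),
               class = "rscmlai_gap_error")
  expect_error(simulate_rscm(w, rice_coeff(),
                             list(l0 = "x", a = 1, b = 1, c = 1)))
})
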