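test_that("generated weather matches its configured climatology and seed contract", {
  cfg <- synthetic_config("rice")
  w <- generate_weather(cfg, seed = 1)
  expect_equal(w$date, seq(cfg$start, cfg$end, by = "day"))
  t_mean <- (w$tmax_c + w$tmin_c) / 2
  expect_lt(abs(mean(t_mean) - 24), 0.5)
  expect_lt(abs(mean(w$srad_mj_m2) - 16.5), 1)
  expect_equal(w$tmax_c - w$tmin_c, rep(10, nrow(w)), tolerance = 1e-12)
  expect_true(all(w$srad_mj_m2 >= 0 & w$prcp_mm >= 0))
  expect_identical(w, generate_weather(cfg, seed = 1))
  expect_false(identical(w, generate_weather(cfg, seed = 2)))

  quiet <- synthetic_config("rice", temp_noise_sd = 0, srad_noise_sd = 0)
  wq <- generate_weather(quiet, seed = 3)
  frac <- (seq_len(nrow(wq)) - 1) / (nrow(wq) - 1)
  expect_equal((wq$tmax_c + wq$tmin_c) / 2,
               24 + 4 * cos(2 * pi * (frac - 0.5)), tolerance = 1e-12)
  expect_true(all(wq$srad_mj_m2 == 16.5))
  expect_error(synthetic_config("rice", start = "2021-09-01", end = "2021-06-01"))
})

test_that("trajectory generation delegates to the simulator and responds to RUE", {
  cfg <- synthetic_config("rice")
  w <- generate_weather(cfg, seed = 2)
  co <- rice_coeff()
  traj <- generate_trajectory(w, co, cfg$true_params)
  direct <- simulate_rscm(w, co, cfg$true_params)
  expect_identical(traj$lai, direct$lai)
  expect_gt(max(traj$lai), 2)
  expect_lt(max(traj$lai), 8)
  lo <- generate_trajectory(w, co, cfg$true_params, rue_multiplier = 0.6)
  hi <- generate_trajectory(w, co, cfg$true_params, rue_multiplier = 1.2)
  expect_lt(max(lo$lai), max(hi$lai))
})

test_that("the optical forward model interpolates soil to canopy and keeps NDVI monotone", {
  sp <- endmember_spectra()
  bare <- lai_to_reflectance(0, sp, noise_sd = 0)
  expect_equal(unlist(bare), c(r560 = 0.10, r660 = 0.14, r800 = 0.22))
  closed <- lai_to_reflectance(1e6, sp, noise_sd = 0)
  expect_equal(unlist(closed), c(r560 = 0.06, r660 = 0.04, r800 = 0.48))
  grid <- lai_to_reflectance(seq(0, 8, by = 0.25), sp, noise_sd = 0)
  ndvi <- compute_ndvi(r660 = grid$r660, r800 = grid$r800)
  expect_true(all(diff(ndvi) > 0))
  noisy <- lai_to_reflectance(rep(2, 50), sp, noise_sd = 0.1, seed = 4)
  expect_true(all(as.matrix(noisy) >= 0 & as.matrix(noisy) <= 1))
  expect_identical(noisy, lai_to_reflectance(rep(2, 50), sp, noise_sd = 0.1, seed = 4))
  expect_error(endmember_spectra(soil = c(r560 = 0.1, r660 = 0.01, r800 = 0.5)),
               "r800")
})

test_that("generated datasets have the campaign sizes, ranges and determinism", {
  d_rice <- generate_dataset(synthetic_config("rice"), seed = 42)
  expect_equal(nrow(d_rice), 552)
  d_soy <- generate_dataset(synthetic_config("soybean"), seed = 42)
  expect_equal(nrow(d_soy), 556)
  expect_false(anyNA(d_rice))
  expect_true(all(d_rice$lai >= 0))
  expect_true(all(d_rice$ndvi > -0.2 & d_rice$ndvi < 1))
  expect_identical(d_rice, generate_dataset(synthetic_config("rice"), seed = 42))
  expect_equal(attr(d_rice, "crop"), "rice")
})

test_that("observation sampling mirrors the six-date schedule and is unbiased", {
  expect_equal(default_obs_dates(2021),
               as.Date(c("2021-07-13", "2021-07-29", "2021-08-12",
                         "2021-08-26", "2021-09-16", "2021-09-30")))
  expect_equal(as.integer(format(default_obs_dates(2021), "%j")),
               c(194, 210, 224, 238, 259, 273))

  cfg <- synthetic_config("rice")
  w <- generate_weather(cfg, seed = 6)
  traj <- simulate_rscm(w, rice_coeff(), cfg$true_params)
  exact <- generate_observation_series(traj, noise_sd = 0)
  idx <- match(exact$date, traj$date)
  expect_equal(exact$lai, traj$lai[idx])
  expect_true(all(exact$source == "direct"))

  reps <- vapply(1:1000, function(s) {
    generate_observation_series(traj, noise_sd = 0.1, seed = s)$lai
  }, numeric(6))
  expect_lt(max(abs(rowMeans(reps) - traj$lai[idx])), 0.02)

  expect_error(generate_observation_series(traj, dates = max(traj$date) + 3),
               class = "rscmlai_validation_error")
})

test_that("the default noisy dataset is learnable and favors tree ensembles", {
  d <- generate_dataset(synthetic_config("rice"), seed = 42)
  sp <- split_dataset(d, seed = 42)
  et <- evaluate_regressor(fit_regressor(regressor_spec("extra_trees", seed = 42),
                                         sp$train), sp$test)
  ridge <- evaluate_regressor(fit_regressor(regressor_spec("ridge", seed = 42),
                                            sp$train), sp$test)
  expect_gte(et$test_score, 0.80)
  expect_gte(et$test_score, ridge$test_score)

  d0 <- generate_dataset(synthetic_config("rice", reflectance_noise_sd = 0,
                                          lai_noise_sd = 0), seed = 42)
  sp0 <- split_dataset(d0, seed = 42)
  et0 <- evaluate_regressor(fit_regressor(regressor_spec("extra_trees", seed = 42),
                                          sp0$train), sp0$test)
  expect_gte(et0$test_score, 0.99)
})
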