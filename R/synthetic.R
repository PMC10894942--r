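#' Configuration of the synthetic field-campaign generator
#'
#' Bundles everything needed to emulate the statistical structure of a
#' proximal-sensing LAI campaign: a seasonal weather climate, nitrogen-level
#' treatments expressed as radiation-use-efficiency multipliers, the true
#' growth parameters per treatment, an optical forward model from LAI to
#' three-band reflectance, and noise levels for reflectance and LAI
#' measurement.
#'
#' Defaults emulate a temperate paddy/upland season: mean temperature 24
#' degC with 4 degC seasonal amplitude (sinusoid peaking mid-season) and 1.5
#' degC daily noise, 10 degC diurnal range, mean solar radiation 16.5 MJ
#' m^-2 d^-1 with sd 3; treatments 0.6/1.0/1.2 emulating no/full/heavy
#' nitrogen; multiplicative log-normal reflectance noise (sd 0.05);
#' additive LAI measurement noise sd 0.4 m^2 m^-2; 552 samples for rice and
#' 556 for soybean.
#'
#' @param crop `"rice"` or `"soybean"`.
#' @param start,end season window (dates); default 2021-06-01 to 2021-10-15.
#' @param mean_temp,temp_amplitude,temp_noise_sd,diurnal_range climate
#'   controls, degC.
#' @param mean_srad,srad_noise_sd solar radiation controls, MJ m^-2 d^-1.
#' @param treatments numeric RUE multipliers, one per nitrogen level.
#' @param true_params a [calibration_params()] object used as generating
#'   truth (shared across treatments). The default
#'   (l0 = 0.15, a = 0.40, b = 1.5e-3, c = 2.0e-3) gives a realistic rice
#'   season peaking near 3.7 m^2 m^-2 with late-season senescence.
#' @param reflectance_noise_sd sd of the log-normal multiplicative band
#'   noise.
#' @param lai_noise_sd sd of the additive LAI measurement noise, m^2 m^-2.
#' @param n_samples rows in a generated LAI-VI dataset (default 552 rice /
#'   556 soybean).
#' @param spectra an [endmember_spectra()] object.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(crop = c("rice", "soybean"),
                             start = "2021-06-01", end = "2021-10-15",
                             mean_temp = 24, temp_amplitude = 4,
                             temp_noise_sd = 1.5, diurnal_range = 10,
                             mean_srad = 16.5, srad_noise_sd = 3,
                             treatments = c(0.6, 1.0, 1.2),
                             true_params = calibration_params(0.15, 0.40, 1.5e-3, 2.0e-3),
                             reflectance_noise_sd = 0.05,
                             lai_noise_sd = 0.4,
                             n_samples = NULL,
                             spectra = endmember_spectra()) {
  crop <- match.arg(crop)
  if (is.null(n_samples)) n_samples <- if (crop == "rice") 552L else 556L
  start <- as_date_strict(start); end <- as_date_strict(end)
  assert_that(start < end, "season end must be after start")
  assert_that(temp_noise_sd >= 0 && srad_noise_sd >= 0 &&
                reflectance_noise_sd >= 0 && lai_noise_sd >= 0,
              "noise standard deviations must be nonnegative")
  assert_that(length(treatments) >= 1 && all(treatments > 0),
              "at least one positive treatment multiplier is required")
  assert_that(n_samples >= 10, "n_samples must be at least 10")
  structure(list(crop = crop, start = start, end = end,
                 mean_temp = mean_temp, temp_amplitude = temp_amplitude,
                 temp_noise_sd = temp_noise_sd, diurnal_range = diurnal_range,
                 mean_srad = mean_srad, srad_noise_sd = srad_noise_sd,
                 treatments = treatments, true_params = true_params,
                 reflectance_noise_sd = reflectance_noise_sd,
                 lai_noise_sd = lai_noise_sd, n_samples = as.integer(n_samples),
                 spectra = spectra),
            class = "synthetic_config")
}

#' Soil and vegetation endmember spectra
#'
#' The two-endmember optical model: plot reflectance is a fractional-cover
#' mix of a bare-soil and a closed-canopy spectrum, with cover
#' `f = 1 - exp(-k_cover * LAI)`. Defaults are plausible textbook spectra
#' (synthetic, not measurements): soil (0.10, 0.14, 0.22) and vegetation
#' (0.06, 0.04, 0.48) at 560/660/800 nm, `k_cover = 0.5`. Vegetation must be
#' brighter than soil at 800 nm and darker at 660 nm so NDVI increases with
#' cover.
#'
#' @param soil,vegetation numeric length-3 reflectance fractions
#'   (r560, r660, r800).
#' @param k_cover canopy-cover extinction coefficient.
#' @return A list of class `endmember_spectra`.
#' @export
endmember_spectra <- function(soil = c(r560 = 0.10, r660 = 0.14, r800 = 0.22),
                              vegetation = c(r560 = 0.06, r660 = 0.04, r800 = 0.48),
                              k_cover = 0.5) {
  assert_that(all(soil >= 0 & soil <= 1) && all(vegetation >= 0 & vegetation <= 1),
              "endmember reflectances must be fractions in [0, 1]")
  assert_that(vegetation[["r800"]] > soil[["r800"]] &&
                vegetation[["r660"]] < soil[["r660"]],
              "need vegetation r800 > soil r800 and vegetation r660 < soil r660")
  assert_that(k_cover > 0, "k_cover must be positive")
  structure(list(soil = soil, vegetation = vegetation, k_cover = k_cover),
            class = "endmember_spectra")
}

#' Generate a synthetic daily weather series
#'
#' Daily mean temperature follows a sinusoid peaking mid-season around the
#' configured seasonal mean, plus Gaussian noise; Tmax/Tmin are the mean
#' plus/minus half the diurnal range. Solar radiation is the configured mean
#' plus Gaussian noise (floored at 0.1 MJ m^-2 d^-1). Precipitation is
#' generated (wet days, gamma amounts) but unused by the crop dynamics.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return A weather data.frame: `date`, `tmax_c`, `tmin_c`, `srad_mj_m2`,
#'   `prcp_mm`.
#' @export
generate_weather <- function(config, seed = 0L) {
  assert_that(inherits(config, "synthetic_config"), "config must be a synthetic_config")
  dates <- seq(config$start, config$end, by = "day")
  n <- length(dates)
  frac <- (seq_len(n) - 1) / (n - 1)
  with_rng_seed(seed, {
    # full-period cosine: zero seasonal mean, peak at mid-season
    t_mean <- config$mean_temp +
      config$temp_amplitude * cos(2 * pi * (frac - 0.5)) +
      stats::rnorm(n, 0, config$temp_noise_sd)
    srad <- pmax(config$mean_srad + stats::rnorm(n, 0, config$srad_noise_sd), 0.1)
    wet <- stats::rbinom(n, 1, 0.35)
    prcp <- wet * stats::rgamma(n, shape = 0.8, scale = 12)
    data.frame(date = dates,
               tmax_c = t_mean + config$diurnal_range / 2,
               tmin_c = t_mean - config$diurnal_range / 2,
               srad_mj_m2 = srad,
               prcp_mm = prcp)
  })
}

#' Generate a true LAI trajectory for one treatment
#'
#' Thin wrapper over [simulate_rscm()]: applies the treatment's RUE
#' multiplier to the crop coefficients and runs the simulator with the
#' configured true parameters.
#'
#' @param weather weather series (e.g. from [generate_weather()]).
#' @param coeff a [crop_coefficients()] object.
#' @param params a [calibration_params()] object.
#' @param rue_multiplier treatment multiplier applied to epsilon.
#' @return An `rscm_trajectory`.
#' @export
generate_trajectory <- function(weather, coeff, params, rue_multiplier = 1) {
  assert_that(is_number(rue_multiplier) && rue_multiplier > 0,
              "rue_multiplier must be positive")
  coeff$epsilon <- coeff$epsilon * rue_multiplier
  simulate_rscm(weather, coeff, params)
}

#' Map LAI to noisy three-band canopy reflectance
#'
#' Two-endmember mixing with exponential canopy cover: fractional cover
#' `f = 1 - exp(-k_cover * lai)`, each band `f * vegetation + (1 - f) *
#' soil`, multiplied by independent log-normal noise `exp(N(0, sd^2))` and
#' clamped to \[0, 1\].
#'
#' @param lai numeric LAI values (m^2 m^-2), nonnegative.
#' @param spectra an [endmember_spectra()] object.
#' @param noise_sd log-normal band noise sd (0 = deterministic).
#' @param seed integer seed (ignored when `noise_sd = 0`).
#' @return A data.frame with columns `r560`, `r660`, `r800`.
#' @export
lai_to_reflectance <- function(lai, spectra = endmember_spectra(),
                               noise_sd = 0, seed = 0L) {
  assert_that(all(is.finite(lai) & lai >= 0), "lai must be finite and nonnegative")
  f <- 1 - exp(-spectra$k_cover * lai)
  bands <- vapply(c("r560", "r660", "r800"), function(bn) {
    f * spectra$vegetation[[bn]] + (1 - f) * spectra$soil[[bn]]
  }, numeric(length(lai)))
  bands <- matrix(bands, nrow = length(lai),
                  dimnames = list(NULL, c("r560", "r660", "r800")))
  if (noise_sd > 0) {
    noise <- with_rng_seed(seed,
      matrix(exp(stats::rnorm(length(bands), 0, noise_sd)), nrow(bands)))
    bands <- bands * noise
  }
  as.data.frame(pmin(pmax(bands, 0), 1))
}

#' Generate a synthetic LAI-VI dataset
#'
#' Emulates a multi-treatment seasonal sampling campaign: for each nitrogen
#' treatment a true LAI trajectory is simulated, then `n_samples` (treatment,
#' date) pairs are drawn uniformly across treatments and season days; each
#' true LAI is pushed through the optical forward model with multiplicative
#' reflectance noise, transformed to the four vegetation indices
#' (`literature` dialect), and paired with the true LAI plus additive
#' measurement noise (clamped at 0).
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed controlling weather, sampling and all noise.
#' @return A data.frame with columns `date`, `treatment`, `mtvi1`, `ndvi`,
#'   `osavi`, `rdvi`, `lai` and attribute `crop`.
#' @export
generate_dataset <- function(config, seed = 0L) {
  assert_that(inherits(config, "synthetic_config"), "config must be a synthetic_config")
  weather <- generate_weather(config, seed = seed)
  coeff <- crop_coefficients(config$crop)
  trajs <- lapply(config$treatments, function(m) {
    generate_trajectory(weather, coeff, config$true_params, rue_multiplier = m)
  })
  n_days <- nrow(weather)
  with_rng_seed(seed + 1L, {
    ti <- sample.int(length(trajs), config$n_samples, replace = TRUE)
    di <- sample.int(n_days, config$n_samples, replace = TRUE)
    true_lai <- vapply(seq_len(config$n_samples),
                       function(i) trajs[[ti[i]]]$lai[di[i]], numeric(1))
    refl <- lai_to_reflectance(true_lai, config$spectra, noise_sd = 0)
    if (config$reflectance_noise_sd > 0) {
      noise <- matrix(exp(stats::rnorm(3 * config$n_samples, 0,
                                       config$reflectance_noise_sd)),
                      ncol = 3)
      refl <- as.data.frame(pmin(pmax(as.matrix(refl) * noise, 0), 1))
    }
    lai_obs <- pmax(true_lai + stats::rnorm(config$n_samples, 0, config$lai_noise_sd), 0)
    vi <- compute_vi_table(refl, dialect = "literature")
    out <- data.frame(date = weather$date[di],
                      treatment = config$treatments[ti],
                      vi[c("mtvi1", "ndvi", "osavi", "rdvi")],
                      lai = lai_obs)
    structure(out, crop = config$crop,
              provenance = "synthetic two-endmember optical forward model")
  })
}

#' Default observation schedule: the six 2021 sampling days
#'
#' Day-of-year 194, 210, 224, 238, 259 and 273 of the given year — the
#' standard six-date proximal-sensing schedule emulated by the generator.
#'
#' @param year calendar year (default 2021).
#' @return A Date vector of length 6.
#' @export
default_obs_dates <- function(year = 2021) {
  as.Date(paste0(year, "-01-01")) + c(194, 210, 224, 238, 259, 273) - 1
}

#' Sample noisy LAI observations from a trajectory
#'
#' Picks the trajectory's LAI on the given dates and adds Gaussian
#' measurement noise, clamped at 0; the field-measured (`direct`) source
#' label is attached.
#'
#' @param traj an `rscm_trajectory`.
#' @param dates observation dates (default: [default_obs_dates()] for the
#'   trajectory's year, restricted to the trajectory window).
#' @param noise_sd measurement noise sd, m^2 m^-2.
#' @param seed integer seed.
#' @return A data.frame: `date`, `lai`, `source`.
#' @export
generate_observation_series <- function(traj, dates = NULL, noise_sd = 0.1,
                                        seed = 0L) {
  assert_that(inherits(traj, "rscm_trajectory"), "traj must be an rscm_trajectory")
  if (is.null(dates)) {
    yr <- as.integer(format(traj$date[1], "%Y"))
    dates <- default_obs_dates(yr)
    dates <- dates[dates >= min(traj$date) & dates <= max(traj$date)]
  }
  dates <- as_date_strict(dates)
  idx <- match(dates, traj$date)
  if (anyNA(idx)) {
    stop_rscmlai(sprintf("observation date(s) outside the trajectory window: %s",
                         paste(format(dates[is.na(idx)]), collapse = ", ")),
                 "rscmlai_validation_error")
  }
  lai <- traj$lai[idx]
  if (noise_sd > 0) {
    lai <- with_rng_seed(seed, pmax(lai + stats::rnorm(length(lai), 0, noise_sd), 0))
  }
  data.frame(date = dates, lai = lai, source = "direct")
}
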