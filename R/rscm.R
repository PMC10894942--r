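#' Crop-specific coefficients of the daily crop simulator
#'
#' Fixed (non-calibrated) coefficients of the process model: radiation use
#' efficiency \eqn{\epsilon} (g MJ^-1), Beer-Lambert light extinction
#' coefficient \eqn{k}, specific leaf area \eqn{S} (m^2 g^-1), base
#' temperature \eqn{T_b} (degC) and the photosynthetically active fraction of
#' incident solar radiation \eqn{\beta} (default 0.45).
#'
#' Built-in values: rice \eqn{\epsilon}=3.49, k=0.60, S=0.016, T_b=12.0;
#' soybean \eqn{\epsilon}=1.65, k=0.71, S=0.017, T_b=10.0.
#'
#' @param crop `"rice"` or `"soybean"`.
#' @param epsilon,k,s_leaf,t_base,beta optional overrides of individual
#'   coefficients.
#' @return An object of class `crop_coefficients` (a named list).
#' @export
crop_coefficients <- function(crop = c("rice", "soybean"),
                              epsilon = NULL, k = NULL, s_leaf = NULL,
                              t_base = NULL, beta = NULL) {
  crop <- match.arg(crop)
  defaults <- switch(crop,
    rice    = list(epsilon = 3.49, k = 0.60, s_leaf = 0.016, t_base = 12.0, beta = 0.45),
    soybean = list(epsilon = 1.65, k = 0.71, s_leaf = 0.017, t_base = 10.0, beta = 0.45)
  )
  ov <- list(epsilon = epsilon, k = k, s_leaf = s_leaf, t_base = t_base, beta = beta)
  for (nm in names(ov)) if (!is.null(ov[[nm]])) defaults[[nm]] <- ov[[nm]]
  out <- c(defaults, list(crop = crop))
  validate_coefficients(out)
  structure(out, class = "crop_coefficients")
}

validate_coefficients <- function(x) {
  for (nm in c("epsilon", "k", "s_leaf", "t_base", "beta")) {
    assert_that(is_number(x[[nm]]), sprintf("coefficient %s must be a finite number", nm))
  }
  assert_that(x$epsilon > 0 && x$k > 0 && x$s_leaf > 0,
              "epsilon, k and s_leaf must be positive")
  assert_that(x$beta > 0 && x$beta <= 1, "beta must be in (0, 1]")
  invisible(TRUE)
}

#' Tunable growth parameters recalibrated within the season
#'
#' The four parameters adjusted against observed/estimated LAI: initial LAI
#' `l0` (m^2 m^-2), leaf-allocation magnitude `a` and shape `b`
#' ((degC d)^-1), and post-expansion senescence rate `c`
#' ((degC d)^-1). All must be nonnegative.
#'
#' @param l0,a,b,c parameter values.
#' @return An object of class `calibration_params` (a named list).
#' @seealso [default_initial_params()] for the standard starting values.
#' @export
calibration_params <- function(l0, a, b, c) {
  out <- list(l0 = l0, a = a, b = b, c = c)
  for (nm in names(out)) {
    assert_that(is_number(out[[nm]]) && out[[nm]] >= 0,
                sprintf("parameter %s must be a finite nonnegative number", nm))
  }
  structure(out, class = "calibration_params")
}

#' Standard initial values for the calibrated parameters
#'
#' The consistent starting point used before any within-season
#' recalibration: l0 = 0.2, a = 3.25e-1, b = 1.25e-3, c = 1.25e-3.
#'
#' @return A [calibration_params()] object.
#' @export
default_initial_params <- function() {
  calibration_params(l0 = 0.2, a = 3.25e-1, b = 1.25e-3, c = 1.25e-3)
}

#' Elementary daily processes of the crop simulator
#'
#' The individual model equations, exposed for testing and inspection:
#' \describe{
#'   \item{`daily_mean_temperature`}{T = (Tmax + Tmin)/2.}
#'   \item{`gdd_increment`}{\eqn{\Delta D = \max(T - T_b, 0)} (degC d).}
#'   \item{`absorbed_radiation`}{\eqn{Q = \beta R (1 - e^{-k \cdot LAI})}
#'     (MJ m^-2 d^-1).}
#'   \item{`biomass_increment`}{\eqn{\Delta M = \epsilon Q} (g m^-2 d^-1).}
#'   \item{`leaf_allocation`}{\eqn{P_1 = \max(1 - a e^{bD}, 0)}, the fraction
#'     of new dry mass allocated to leaves, declining with cumulative GDD D.}
#'   \item{`lai_increment`}{\eqn{\Delta L = \Delta M \cdot P_1 \cdot S}.}
#'   \item{`senescence_decrement`}{\eqn{\Delta L_{sen} = c \cdot \Delta D
#'     \cdot LAI} once \eqn{P_1 = 0}, else 0; clamped so LAI stays
#'     nonnegative. With c = 0 the model has no senescence term.}
#' }
#'
#' @param tmax,tmin daily maximum/minimum temperature, degC.
#' @param t_mean daily mean temperature, degC.
#' @param srad daily incident solar radiation, MJ m^-2 d^-1.
#' @param lai leaf area index, m^2 m^-2.
#' @param q_abs absorbed radiation, MJ m^-2 d^-1.
#' @param gdd_cum cumulative growing degree days, degC d.
#' @param gdd_inc daily GDD increment, degC d.
#' @param dm daily dry-mass increment, g m^-2 d^-1.
#' @param p1 leaf-allocation fraction in \[0, 1\].
#' @param coeff a [crop_coefficients()] object.
#' @param params a [calibration_params()] object.
#' @name rscm_processes
NULL

#' @rdname rscm_processes
#' @export
daily_mean_temperature <- function(tmax, tmin) {
  assert_that(all(tmax >= tmin), "tmax must be >= tmin")
  (tmax + tmin) / 2
}

#' @rdname rscm_processes
#' @export
gdd_increment <- function(t_mean, t_base) {
  pmax(t_mean - t_base, 0)
}

#' @rdname rscm_processes
#' @export
absorbed_radiation <- function(srad, lai, coeff) {
  assert_that(all(srad >= 0) && all(lai >= 0), "srad and lai must be nonnegative")
  coeff$beta * srad * (1 - exp(-coeff$k * lai))
}

#' @rdname rscm_processes
#' @export
biomass_increment <- function(q_abs, coeff) {
  assert_that(all(q_abs >= 0), "q_abs must be nonnegative")
  coeff$epsilon * q_abs
}

#' @rdname rscm_processes
#' @export
leaf_allocation <- function(gdd_cum, params) {
  assert_that(all(gdd_cum >= 0), "gdd_cum must be nonnegative")
  pmax(1 - params$a * exp(params$b * gdd_cum), 0)
}

#' @rdname rscm_processes
#' @export
lai_increment <- function(dm, p1, coeff) {
  assert_that(all(dm >= 0) && all(p1 >= 0 & p1 <= 1),
              "dm must be nonnegative and p1 in [0, 1]")
  dm * p1 * coeff$s_leaf
}

#' @rdname rscm_processes
#' @export
senescence_decrement <- function(lai, gdd_inc, p1, params) {
  assert_that(all(lai >= 0) && all(gdd_inc >= 0), "lai and gdd_inc must be nonnegative")
  dec <- ifelse(p1 == 0, params$c * gdd_inc * lai, 0)
  pmin(dec, lai)
}

# Fast inner loop shared by simulate_rscm() and the calibration objective:
# returns only the daily LAI vector, assumes pre-validated inputs.
sim_lai_core <- function(t_mean, srad, coeff, l0, a, b, c_eff) {
  n <- length(t_mean)
  lai <- numeric(n)
  lai[1] <- l0
  gdd <- 0
  k <- coeff$k; beta <- coeff$beta; eps_s <- coeff$epsilon * coeff$s_leaf
  t_base <- coeff$t_base
  for (i in 2:n) {
    dD <- t_mean[i] - t_base
    if (dD < 0) dD <- 0
    gdd <- gdd + dD
    p1 <- 1 - a * exp(b * gdd)
    if (p1 < 0) p1 <- 0
    absorbed <- beta * srad[i] * (1 - exp(-k * lai[i - 1]))
    dL <- eps_s * absorbed * p1
    sen <- if (p1 == 0) min(c_eff * dD * lai[i - 1], lai[i - 1]) else 0
    lai[i] <- lai[i - 1] + dL - sen
  }
  lai
}

check_weather <- function(weather, start = NULL, end = NULL) {
  assert_that(is.data.frame(weather) &&
                all(c("date", "tmax_c", "tmin_c", "srad_mj_m2") %in% names(weather)),
              "weather must have columns date, tmax_c, tmin_c, srad_mj_m2")
  weather$date <- as_date_strict(weather$date)
  assert_that(all(is.finite(weather$tmax_c)) && all(is.finite(weather$tmin_c)) &&
                all(is.finite(weather$srad_mj_m2)),
              "weather values must be finite")
  assert_that(all(weather$tmax_c >= weather$tmin_c), "weather: tmax_c < tmin_c found")
  assert_that(all(weather$srad_mj_m2 >= 0), "weather: negative srad_mj_m2 found")
  if (!is.null(start)) {
    start <- as_date_strict(start); end <- as_date_strict(end)
    assert_that(start <= end, "simulation start date is after end date")
    wanted <- seq(start, end, by = "day")
    missing <- wanted[!wanted %in% weather$date]
    if (length(missing)) {
      stop_rscmlai(sprintf("weather series has gaps in the simulation window: %s",
                           paste(format(utils::head(missing, 5)), collapse = ", ")),
                   "rscmlai_gap_error")
    }
    weather <- weather[match(wanted, weather$date), , drop = FALSE]
  } else {
    d <- as.integer(diff(weather$date))
    assert_that(all(d == 1L), "weather dates must be strictly increasing and gap-free",
                class = "rscmlai_gap_error")
  }
  rownames(weather) <- NULL
  weather
}

#' Run the daily crop growth simulation
#'
#' Forward daily integration of the process model. The state on the start
#' date (transplanting/sowing) is `gdd_cum = 0`, `lai = l0`,
#' `biomass = l0 / s_leaf` (leaf mass consistent with the initial LAI and the
#' specific leaf area). Each subsequent day applies, in order: the GDD
#' increment, the leaf-allocation fraction at the updated GDD, light
#' interception using the previous day's LAI, the biomass increment, and the
#' LAI increment minus the senescence decrement.
#'
#' @param weather data.frame with columns `date`, `tmax_c`, `tmin_c`,
#'   `srad_mj_m2` (and optionally `prcp_mm`, carried but unused by the
#'   dynamics), gap-free over the simulation window.
#' @param coeff a [crop_coefficients()] object.
#' @param params a [calibration_params()] object.
#' @param start,end simulation window (default: full weather range).
#' @param senescence logical; set `FALSE` to disable the senescence term
#'   regardless of `params$c`.
#' @return A data.frame of class `rscm_trajectory` with columns `date`,
#'   `gdd_cum`, `lai`, `biomass`, `q_abs`, `p1`, and attributes `coeff` and
#'   `params`.
#' @examples
#' w <- generate_weather(synthetic_config("rice"), seed = 1)
#' traj <- simulate_rscm(w, crop_coefficients("rice"), default_initial_params())
#' max(traj$lai)
#' @export
simulate_rscm <- function(weather, coeff, params,
                          start = NULL, end = NULL, senescence = TRUE) {
  if (is.null(start)) start <- min(as_date_strict(weather$date))
  if (is.null(end)) end <- max(as_date_strict(weather$date))
  weather <- check_weather(weather, start, end)
  validate_coefficients(coeff)
  assert_that(is.list(params) && all(c("l0", "a", "b", "c") %in% names(params)),
              "params must be a calibration_params object")
  params <- calibration_params(params$l0, params$a, params$b, params$c)

  n <- nrow(weather)
  gdd <- lai <- biomass <- q_abs <- p1 <- numeric(n)
  c_eff <- if (senescence) params$c else 0

  gdd[1] <- 0
  lai[1] <- params$l0
  biomass[1] <- params$l0 / coeff$s_leaf
  q_abs[1] <- 0
  p1[1] <- leaf_allocation(0, params)

  t_mean <- (weather$tmax_c + weather$tmin_c) / 2
  if (n > 1) {
    for (i in 2:n) {
      dD <- max(t_mean[i] - coeff$t_base, 0)
      gdd[i] <- gdd[i - 1] + dD
      p1[i] <- max(1 - params$a * exp(params$b * gdd[i]), 0)
      q_abs[i] <- coeff$beta * weather$srad_mj_m2[i] * (1 - exp(-coeff$k * lai[i - 1]))
      dM <- coeff$epsilon * q_abs[i]
      dL <- dM * p1[i] * coeff$s_leaf
      sen <- if (p1[i] == 0) min(c_eff * dD * lai[i - 1], lai[i - 1]) else 0
      lai[i] <- lai[i - 1] + dL - sen
      biomass[i] <- biomass[i - 1] + dM
    }
  }

  out <- data.frame(date = weather$date, gdd_cum = gdd, lai = lai,
                    biomass = biomass, q_abs = q_abs, p1 = p1)
  structure(out, class = c("rscm_trajectory", "data.frame"),
            coeff = coeff, params = params)
}

#' @export
print.rscm_trajectory <- function(x, ...) {
  cf <- attr(x, "coeff")
  cat(sprintf("<rscm_trajectory> %s, %d days (%s to %s)\n",
              if (!is.null(cf$crop)) cf$crop else "custom crop",
              nrow(x), format(min(x$date)), format(max(x$date))))
  cat(sprintf("  peak LAI %.2f m2/m2 on %s; final biomass %.0f g/m2\n",
              max(x$lai), format(x$date[which.max(x$lai)]), x$biomass[nrow(x)]))
  invisible(x)
}
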