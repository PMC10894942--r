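#' Sum-of-squares LAI mismatch objective
#'
#' The calibration objective: the sum over observation dates of the squared
#' difference between simulated and observed LAI, plus, when Gaussian priors
#' are supplied, a quadratic penalty \eqn{\sum ((\theta - \mu)/\sigma)^2}
#' over the parameters that carry a prior.
#'
#' @param params a [calibration_params()] object (or coercible list).
#' @param weather gap-free daily weather covering all observation dates.
#' @param coeff a [crop_coefficients()] object.
#' @param obs observation data.frame with columns `date` and `lai` (see
#'   [generate_observation_series()] and [read_table()] kind `"lai_obs"`).
#' @param priors optional named list; each of `l0`, `a`, `b`, `c` may map to
#'   `list(mean =, sd =)` with `sd > 0`.
#' @param start,end,senescence passed to [simulate_rscm()].
#' @return Nonnegative scalar; 0 iff the simulation reproduces every
#'   observation exactly and no prior exerts pull.
#' @export
lai_objective <- function(params, weather, coeff, obs, priors = NULL,
                          start = NULL, end = NULL, senescence = TRUE) {
  f <- make_lai_objective(weather, coeff, obs, priors, start, end, senescence)
  f(params)
}

# Validates inputs once and returns a fast closure over calibration_params;
# this is what Powell iterates on.
make_lai_objective <- function(weather, coeff, obs, priors = NULL,
                               start = NULL, end = NULL, senescence = TRUE) {
  obs <- check_obs(obs)
  if (is.null(start)) start <- min(as_date_strict(weather$date))
  if (is.null(end)) end <- max(as_date_strict(weather$date))
  weather <- check_weather(weather, start, end)
  validate_coefficients(coeff)
  idx <- match(obs$date, weather$date)
  if (anyNA(idx)) {
    stop_rscmlai(sprintf("observation date(s) outside weather coverage: %s",
                         paste(format(obs$date[is.na(idx)]), collapse = ", ")),
                 "rscmlai_gap_error")
  }
  t_mean <- (weather$tmax_c + weather$tmin_c) / 2
  srad <- weather$srad_mj_m2
  lai_obs <- obs$lai
  function(params) {
    lai <- sim_lai_core(t_mean, srad, coeff, params$l0, params$a, params$b,
                        if (senescence) params$c else 0)
    sum((lai[idx] - lai_obs)^2) + prior_penalty(params, priors)
  }
}

prior_penalty <- function(params, priors) {
  if (is.null(priors)) return(0)
  pen <- 0
  for (nm in intersect(names(priors), c("l0", "a", "b", "c"))) {
    pr <- priors[[nm]]
    if (is.null(pr)) next
    assert_that(is_number(pr$mean) && is_number(pr$sd) && pr$sd > 0,
                sprintf("prior for %s needs finite mean and sd > 0", nm))
    pen <- pen + ((params[[nm]] - pr$mean) / pr$sd)^2
  }
  pen
}

check_obs <- function(obs) {
  assert_that(is.data.frame(obs) && all(c("date", "lai") %in% names(obs)),
              "observations must be a data.frame with columns date, lai")
  assert_that(nrow(obs) >= 1, "at least one LAI observation is required")
  obs$date <- as_date_strict(obs$date)
  assert_that(all(is.finite(obs$lai)) && all(obs$lai >= 0),
              "observed LAI must be finite and nonnegative")
  assert_that(!is.unsorted(obs$date, strictly = TRUE),
              "observation dates must be strictly increasing")
  obs
}

#' Recalibrate the growth parameters against observed LAI
#'
#' Minimizes [lai_objective()] over (l0, a, b, c) with Powell's
#' derivative-free method. Nonnegativity is enforced by optimizing the
#' log-transformed parameters \eqn{\theta = e^{\phi}}, which keeps the
#' search unconstrained; a parameter starting at 0 is floored at 1e-12
#' before the transform.
#'
#' @param initial starting [calibration_params()]; typically
#'   [default_initial_params()] for a fresh season.
#' @inheritParams lai_objective
#' @param control list of options: `tol` (objective tolerance, default
#'   1e-6), `maxit` (maximum Powell sweeps, default 1000).
#' @return An object of class `rscm_calibration`: a list with `params`
#'   (fitted [calibration_params()]), `initial`, `objective`,
#'   `initial_objective`, `n_evaluations`, `converged`, `residuals`
#'   (data.frame date, residual = sim - obs), `obs`, and the `options` used.
#' @examples
#' cfg <- synthetic_config("rice")
#' w <- generate_weather(cfg, seed = 7)
#' truth <- simulate_rscm(w, crop_coefficients("rice"),
#'                        calibration_params(0.15, 0.40, 1.5e-3, 2.0e-3))
#' obs <- generate_observation_series(truth, noise_sd = 0, seed = 1)
#' fit <- calibrate_rscm(default_initial_params(), w, crop_coefficients("rice"), obs)
#' fit$objective
#' @export
calibrate_rscm <- function(initial, weather, coeff, obs, priors = NULL,
                           control = list(), start = NULL, end = NULL,
                           senescence = TRUE) {
  obs <- check_obs(obs)
  tol <- if (!is.null(control$tol)) control$tol else 1e-6
  maxit <- if (!is.null(control$maxit)) control$maxit else 1000

  theta0 <- c(initial$l0, initial$a, initial$b, initial$c)
  phi0 <- log(pmax(theta0, 1e-12))
  obj <- make_lai_objective(weather, coeff, obs, priors,
                            start = start, end = end, senescence = senescence)
  objective_phi <- function(phi) {
    th <- exp(phi)
    obj(list(l0 = th[1], a = th[2], b = th[3], c = th[4]))
  }

  f0 <- objective_phi(phi0)
  res <- powell_minimize(objective_phi, phi0, tol = tol, maxit = maxit)
  th <- exp(res$par)
  fitted <- calibration_params(th[1], th[2], th[3], th[4])

  traj <- simulate_rscm(weather, coeff, fitted, start = start, end = end,
                        senescence = senescence)
  idx <- match(obs$date, traj$date)
  structure(list(
    params = fitted,
    initial = initial,
    objective = res$value,
    initial_objective = f0,
    n_evaluations = res$counts,
    converged = res$converged,
    residuals = data.frame(date = obs$date, residual = traj$lai[idx] - obs$lai),
    obs = obs,
    options = list(tol = tol, maxit = maxit, senescence = senescence,
                   priors = priors)
  ), class = "rscm_calibration")
}

#' @export
print.rscm_calibration <- function(x, ...) {
  p <- x$params
  cat(sprintf("<rscm_calibration> objective %.6g (from %.6g), %d evaluations%s\n",
              x$objective, x$initial_objective, x$n_evaluations,
              if (x$converged) "" else " [not converged]"))
  cat(sprintf("  l0=%.4g a=%.4g b=%.4g c=%.4g; %d observations\n",
              p$l0, p$a, p$b, p$c, nrow(x$obs)))
  invisible(x)
}

#' Within-season calibration update
#'
#' Re-runs [calibrate_rscm()] on all observations accumulated so far,
#' warm-starting from the previous result's parameters — the in-season
#' assimilation step applied each time a new remotely sensed LAI estimate
#' arrives. With an empty increment the previous result is returned
#' unchanged.
#'
#' @param state a previous `rscm_calibration` result, or a
#'   [calibration_params()] object for the first update of the season.
#' @param new_obs data.frame of newly arrived observations (columns `date`,
#'   `lai`); may have zero rows.
#' @inheritParams calibrate_rscm
#' @return An `rscm_calibration` object covering all observations to date.
#' @export
inseason_update <- function(state, weather, coeff, new_obs, priors = NULL,
                            control = list(), start = NULL, end = NULL,
                            senescence = TRUE) {
  if (inherits(state, "rscm_calibration")) {
    if (is.null(new_obs) || nrow(new_obs) == 0) return(state)
    all_obs <- rbind(state$obs[c("date", "lai")],
                     check_obs(new_obs)[c("date", "lai")])
    all_obs <- all_obs[order(all_obs$date), , drop = FALSE]
    warm <- state$params
  } else {
    assert_that(!is.null(new_obs) && nrow(new_obs) >= 1,
                "first in-season update needs at least one observation")
    all_obs <- check_obs(new_obs)
    warm <- state
  }
  calibrate_rscm(warm, weather, coeff, all_obs, priors = priors,
                 control = control, start = start, end = end,
                 senescence = senescence)
}
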