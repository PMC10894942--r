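# Independent reference implementations used as oracles. Deliberately naive
# straight-line code, kept structurally different from the package internals.

# Day-loop crop simulator: full state, scalar arithmetic, no vectorization.
oracle_simulate <- function(weather, coeff, params, senescence = TRUE) {
  n <- nrow(weather)
  lai <- params$l0
  biomass <- params$l0 / coeff$s_leaf
  gdd <- 0
  out <- data.frame(date = weather$date, gdd_cum = NA_real_, lai = NA_real_,
                    biomass = NA_real_, q_abs = NA_real_, p1 = NA_real_)
  out$gdd_cum[1] <- 0
  out$lai[1] <- lai
  out$biomass[1] <- biomass
  out$q_abs[1] <- 0
  out$p1[1] <- max(1 - params$a * exp(params$b * 0), 0)
  for (i in seq_len(n)[-1]) {
    t_mean <- (weather$tmax_c[i] + weather$tmin_c[i]) / 2
    dD <- max(t_mean - coeff$t_base, 0)
    gdd <- gdd + dD
    p1 <- max(1 - params$a * exp(params$b * gdd), 0)
    q <- coeff$beta * weather$srad_mj_m2[i] * (1 - exp(-coeff$k * lai))
    dM <- coeff$epsilon * q
    dL <- dM * p1 * coeff$s_leaf
    sen <- 0
    if (senescence && p1 == 0) sen <- min(params$c * dD * lai, lai)
    lai_new <- lai + dL - sen
    biomass <- biomass + dM
    out$gdd_cum[i] <- gdd
    out$lai[i] <- lai_new
    out$biomass[i] <- biomass
    out$q_abs[i] <- q
    out$p1[i] <- p1
    lai <- lai_new
  }
  out
}

# Loop-based evaluation statistics.
oracle_rmse <- function(s, o) {
  acc <- 0
  for (i in seq_along(s)) acc <- acc + (s[i] - o[i])^2
  sqrt(acc / length(s))
}
oracle_mae <- function(s, o) {
  acc <- 0
  for (i in seq_along(s)) acc <- acc + abs(s[i] - o[i])
  acc / length(s)
}
oracle_nse <- function(s, o) {
  obar <- sum(o) / length(o)
  num <- 0; den <- 0
  for (i in seq_along(s)) {
    num <- num + (s[i] - o[i])^2
    den <- den + (o[i] - obar)^2
  }
  1 - num / den
}

random_weather <- function(n_days = 120, seed = 1, year = 2021) {
  set.seed(seed)
  data.frame(
    date = as.Date(sprintf("%d-06-01", year)) + 0:(n_days - 1),
    tmax_c = runif(n_days, 22, 35),
    tmin_c = runif(n_days, 12, 21),
    srad_mj_m2 = runif(n_days, 5, 28),
    prcp_mm = rexp(n_days, 0.2)
  )
}

random_params <- function(seed = 1) {
  set.seed(seed)
  calibration_params(l0 = runif(1, 0.05, 0.5), a = runif(1, 0.1, 0.9),
                     b = runif(1, 5e-4, 5e-3), c = runif(1, 0, 5e-3))
}

rice_coeff <- function() crop_coefficients("rice")
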