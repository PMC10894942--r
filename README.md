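# rscmlai

Remote-sensing-integrated crop modelling with machine-learned leaf area
index (LAI), for rice and soybean.

Crop researchers and agronomists who measure canopy reflectance with
proximal multispectral sensors can use this package to (1) turn
three-band reflectance (560/660/800 nm) into the four vegetation indices
MTVI1, NDVI, OSAVI and RDVI, (2) train and benchmark a family of
regression models that estimate LAI from those indices, and (3)
assimilate the estimated LAI into a daily process-based crop simulator
by recalibrating its growth parameters within the season.

## The model

The simulator steps five equations forward daily:

* ΔD = max(T − T_b, 0) — thermal time (growing degree days), with
  T = (Tmax + Tmin)/2;
* Q = β·R·(1 − e^(−k·LAI)) — Beer–Lambert interception of solar
  radiation R, with β = 0.45;
* ΔM = ε·Q — dry-mass growth at radiation use efficiency ε;
* P₁ = max(1 − a·e^(b·D), 0) — the fraction of new mass allocated to
  leaves, declining with thermal time;
* ΔL = ΔM·P₁·S — leaf expansion at specific leaf area S;

plus a post-expansion senescence term ΔL_sen = c·ΔD·LAI once P₁ = 0.
Built-in coefficients: rice ε = 3.49 g MJ⁻¹, k = 0.60, S = 0.016 m² g⁻¹,
T_b = 12 °C; soybean ε = 1.65, k = 0.71, S = 0.017, T_b = 10.

Within-season calibration adjusts (L₀, a, b, c) — initial LAI,
allocation magnitude/shape, senescence rate — from the standard start
(0.2, 0.325, 1.25×10⁻³, 1.25×10⁻³) by minimizing the sum of squared
differences between simulated and observed LAI with Powell's
derivative-free conjugate-direction method (implemented in the package,
log-transformed parameters for nonnegativity, optional Gaussian-prior
penalties). Evaluation uses RMSE, MAE and Nash–Sutcliffe efficiency
(NSE), all in the divide-by-n convention.

A synthetic field-campaign generator (seasonal weather, two-endmember
canopy reflectance, multi-treatment LAI–VI datasets of 552/556 rows)
makes the whole pipeline runnable and testable without field data; see
the methods vignette (`vignettes/rscm-lai-assimilation.Rmd`) for every
modelling choice and its rationale.

## Worked example

```r
library(rscmlai)

cfg  <- synthetic_config("rice")
co   <- crop_coefficients("rice")

# train an extremely randomized trees regressor on a synthetic campaign
d    <- generate_dataset(cfg, seed = 42)           # 552 rows of (VIs, LAI)
sp   <- split_dataset(d, ratio = 0.8, seed = 42)   # 441 train / 111 test
art  <- fit_regressor(regressor_spec("extra_trees", seed = 42), sp$train)
evaluate_regressor(art, sp$test)
#>     regressor train_score test_score      rmse       mae       nse
#> 1 extra_trees   0.9976513  0.8789659 0.5550302 0.4348285 0.8789659

# a fresh season: estimate LAI from reflectance, assimilate, recalibrate
w     <- generate_weather(cfg, seed = 7)
truth <- simulate_rscm(w, co, cfg$true_params)
dates <- default_obs_dates(2021)                   # DOY 194 ... 273
refl  <- lai_to_reflectance(truth$lai[match(dates, truth$date)],
                            cfg$spectra, noise_sd = 0.05, seed = 8)
obs   <- data.frame(date = dates,
                    lai  = predict(art, compute_vi_table(refl, "literature")),
                    source = "ml_estimated")
fit   <- calibrate_rscm(default_initial_params(), w, co, obs)
fit
#> <rscm_calibration> objective 0.257958 (from 125.816), 988 evaluations
#>   l0=0.1529 a=0.3785 b=0.001606 c=0.001856; 6 observations

nse(simulate_rscm(w, co, fit$params)$lai, truth$lai)
#> [1] 0.9716413
```

The evaluation row says the tree ensemble explains ~88% of test-set LAI
variance at the default campaign noise; the calibration result shows the
objective falling from 125.8 to 0.26 (m² m⁻²)² over six assimilated
observations, and the recalibrated season tracks the synthetic truth at
NSE 0.97.

A thin command-line wrapper over the same functions is installed at
`inst/cli/rscmlai.R` (subcommands `synth-weather`, `synth-dataset`,
`compute-vi`, `fit-ml`, `benchmark-ml`, `predict-lai`, `simulate`,
`calibrate`, `evaluate`).

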