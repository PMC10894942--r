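---
title: "Assimilating machine-learned LAI into a daily crop simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assimilating machine-learned LAI into a daily crop simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rscmlai)
```

## The problem

Leaf area index (LAI, one-sided green leaf area per unit ground area, m²
m⁻²) is the central state variable linking canopy light interception to
crop growth, but direct measurement is laborious. Proximal multispectral
sensing offers a shortcut: canopy reflectance at a few wavebands is
condensed into vegetation indices (VIs), a regression model maps VIs to
LAI, and those LAI estimates are assimilated into a process-based crop
simulator by recalibrating its growth parameters within the season. This
package implements that full chain for rice and soybean: VI computation,
a benchmarked family of LAI-from-VI regressors, a daily crop simulator,
and Powell-based within-season recalibration, together with a synthetic
field-campaign generator that makes every stage testable without
proprietary field data.

## Vegetation indices and the formula dialects

Four indices are computed from reflectance fractions at 560, 660 and
800 nm: MTVI1, NDVI, OSAVI and RDVI. NDVI and OSAVI have a single
accepted form. For MTVI1 and RDVI the package exposes two dialects,
because the forms these indices are sometimes typeset in differ from the
original index publications: `as_printed` uses
MTVI1 = 1.2(R800 − R660) − 2.5(R660 + R560) and RDVI = NDVI, while
`literature` uses the Haboudane MTVI1
(1.2·[1.2(R800 − R560) − 2.5(R660 − R560)]) and the Roujean–Bréon RDVI
((R800 − R660)/√(R800 + R660)). The `as_printed` RDVI is an exact
duplicate of NDVI — almost certainly a typesetting loss of the square
root — so the package defaults to `literature` everywhere downstream,
and keeps `as_printed` available for strict comparability. Which dialect
any particular published study actually computed cannot be established
from formulas alone; both are first-class here and the choice is recorded
in every VI table.

Reflectance units are declared, never sniffed: proximal radiometers
commonly report percent, the canonical internal unit is the [0, 1]
fraction (`normalize_reflectance()`). The indices are ratio-based except
MTVI1, which is scale-sensitive — the wrong unit declaration would
corrupt it silently, which is why the reader refuses undeclared units.

## The daily crop simulator

The process model steps five equations forward on a daily grid:

* thermal time: ΔD = max(T − T_b, 0), with T = (Tmax + Tmin)/2 — the
  arithmetic mean is the standard agronomic aggregation when only daily
  extremes are available;
* light interception: Q = β·R·(1 − e^(−k·LAI)), Beer–Lambert with
  extinction coefficient k, incident solar radiation R and the
  photosynthetically active fraction β = 0.45;
* growth: ΔM = ε·Q, with radiation use efficiency ε (g MJ⁻¹);
* leaf allocation: P₁ = max(1 − a·e^(b·D), 0), a fraction that starts
  near 1 − a and declines with cumulative thermal time D;
* leaf expansion: ΔL = ΔM·P₁·S, with specific leaf area S (m² g⁻¹).

Built-in coefficients: rice ε = 3.49, k = 0.60, S = 0.016, T_b = 12.0;
soybean ε = 1.65, k = 0.71, S = 0.017, T_b = 10.0.

Three numerical choices were genuinely open and are fixed as follows.
First, the discretization: explicit forward stepping, with the
light-interception term using the previous day's LAI; with constant
forcing and a = 0 this makes the LAI series exactly the recurrence
L_{t+1} = L_t + ε·S·β·R·(1 − e^(−k·L_t)), which the test suite checks
directly. Second, the senescence term: the calibrated parameter set
includes a rate c, but the five equations above contain no process for
it, so the package adopts a post-expansion exponential decline in thermal
time, ΔL_sen = c·ΔD·LAI, active only once P₁ has reached 0 and clamped
so LAI never goes negative. This reproduces the late-season LAI decline
a senescing canopy shows, uses a single nonnegative rate, and is exactly
disabled by c = 0 (or `senescence = FALSE`), recovering the plain
five-equation dynamics. It is documented as this package's choice, not
asserted as any other implementation's. Third, initial biomass at the
simulation start is l0/S — the leaf mass consistent with the initial LAI
— which only shifts the biomass series by a constant since biomass does
not feed back into the LAI dynamics.

The simulation window is user-defined (transplanting/sowing to harvest);
no phenology-stage logic is modelled, and neither are yield formation or
water/nitrogen stress.

## Within-season calibration

Four parameters are recalibrated against observed or ML-estimated LAI:
initial LAI L₀, allocation magnitude a, allocation shape b, and the
senescence rate c, starting from the consistent initial values L₀ = 0.2,
a = 0.325, b = 1.25×10⁻³, c = 1.25×10⁻³. The objective is the plain sum
of squared LAI mismatches on the observation dates — all dates weighted
equally regardless of whether the observation is field-measured or
ML-estimated — plus an optional Gaussian prior penalty Σ((θ − μ)/σ)² per
parameter, the quadratic-penalty reading of a Bayesian prior. Priors
default to none.

Minimization uses Powell's conjugate-direction method, implemented in
the package (direction-set sweeps; each line search brackets by golden
expansion and then applies Brent minimization; the direction of largest
decrease is replaced by the sweep's net displacement under the standard
acceptance criterion). Two robustness details matter in practice:

* line-search steps are only accepted when they improve the objective,
  which makes every calibration a descent and the reported objective
  never worse than the starting one;
* when a sweep stalls, the direction set is reset to the identity and
  the search continues; it stops only when a whole restart cycle brings
  no further relative improvement (tolerance 10⁻⁶, at most 1000 sweeps).
  Without restarts the accumulated directions occasionally become
  degenerate and the search stalls far from the minimum on this
  objective's curved valleys.

Nonnegativity of all four parameters is enforced by optimizing
θ = e^φ — Powell stays unconstrained, no penalty tuning is needed, and a
parameter starting at zero is floored at 10⁻¹². The in-season schedule
re-optimizes on all observations accumulated so far, warm-starting from
the previous fit; an empty increment returns the previous result
unchanged.

## LAI-from-VI regression

The feature vector is the four VIs in the fixed order MTVI1, NDVI,
OSAVI, RDVI; the target is LAI. Datasets are split 80:20 with test size
⌈0.2·n⌉ (a rounding convention has to be fixed for reproducibility).
Eleven families are available behind one interface: degree-2 polynomial
least squares (all pairwise interactions), ridge (penalty 0.1) and lasso
(penalty 0.01) in the RSS/(2n) + α·penalty convention, RBF-kernel
support vector regression (unit cost), random forest, extremely
randomized trees (no bootstrap, one random split per feature), three
gradient-boosting variants (depth-wise exact, histogram leaf-wise, and a
higher-rate exact variant), a leaf-wise histogram stand-in for the
LightGBM configuration (no native backend is installed; a notice is
logged), and a feed-forward network: six ReLU hidden layers of widths
1000–100, dropout 0.17, Adam at learning rate 0.001, 1000 epochs, batch
100, implemented in plain matrix code. Whether such a network's widths
should ascend or descend is unspecified in the sources this design
follows; descending widths are used. The network is expensive at its
default size and is excluded from the default benchmark set; tests
exercise a scaled-down configuration. Features are standardized for the
polynomial/ridge/lasso/SVR/network families and left raw for trees;
"score" throughout means the coefficient of determination, computed with
the same formula as Nash–Sutcliffe efficiency on (prediction, target)
pairs. Predictions are clamped at zero — a negative LAI is physically
meaningless. Unstated ensemble hyperparameters default to 500 trees and
unlimited depth, all overridable per spec.

The exponential baseline LAI = u·e^(v·VI) is fit by nonlinear least
squares seeded from the log-linear closed form (OLS of log LAI on the
VI); rows with LAI ≤ 0 cannot enter the initializer and are excluded
with a message. The nonlinear refinement never has worse RMSE than its
initializer on the fitting data.

## The synthetic field campaign

The generator emulates the structure of a multi-treatment proximal
sensing campaign so that every pipeline stage has realistic, fully
controlled inputs:

* **Weather**: daily mean temperature is a full-period cosine peaking
  mid-season around a 24 °C seasonal mean (amplitude 4 °C, daily noise
  sd 1.5 °C, diurnal range 10 °C); solar radiation is 16.5 MJ m⁻² d⁻¹
  plus noise (sd 3, floored at 0.1). These means match a temperate
  rice-growing site's season climatology. Precipitation is generated
  (35% wet days, gamma amounts) but does not drive the dynamics.
* **Truth trajectories**: the simulator itself, run per nitrogen
  treatment with the treatment's RUE multiplier (defaults 0.6/1.0/1.2
  for no/full/heavy fertilization — nitrogen response is emulated
  purely as an ε multiplier, no N-process is modelled). The default
  generating parameters (L₀ = 0.15, a = 0.40, b = 1.5×10⁻³,
  c = 2.0×10⁻³) give a season peaking near 3.7–4.3 m² m⁻² with
  late-season senescence — a realistic paddy season, and deliberately
  distinct from the calibration starting values so recovery tests are
  non-trivial.
* **Reflectance**: a two-endmember optical model — fractional cover
  f = 1 − e^(−0.5·LAI) mixing a bare-soil spectrum (0.10, 0.14, 0.22)
  with a closed-canopy spectrum (0.06, 0.04, 0.48) at 560/660/800 nm —
  with independent multiplicative log-normal band noise (sd 0.05). This
  is the simplest mechanism that yields the saturating, monotone,
  invertible LAI→VI relation the exponential LAI–VI regressions
  presuppose; the endmember values are plausible textbook spectra,
  synthetic by construction, and configurable.
* **Datasets**: 552 rows for rice and 556 for soybean (the campaign
  sizes being emulated), drawn uniformly over treatments and season
  days, with additive LAI measurement noise sd 0.4 m² m⁻² (clamped at
  zero). Observation series for calibration use the six-date schedule
  DOY 194/210/224/238/259/273 with measurement noise sd 0.1 m² m⁻².

Everything is seeded at every level; identical configuration and seed
give bit-identical outputs.

What the generator does *not* emulate bounds what the tests can show:
there is no radiative-transfer realism (no PROSAIL-class canopy optics,
no soil moisture or view-geometry effects), no spatial structure, no
sensor drift, and the generating model and the fitted model share the
same process equations — so parameter-recovery results demonstrate that
the optimizer and pipeline work, not that the process model is an
adequate description of any real field. Scores on synthetic data
likewise characterize the pipeline under its own assumptions, not
expected field performance.

## Problem sizes and determinism

The shipped checks run at desk scale: 100 random seasons for
simulator-oracle agreement (tolerance 10⁻¹² relative), 20 seeded seasons
for parameter recovery (observation noise sd 0.1; at least 18 of 20 must
reach season-wide NSE ≥ 0.95, and noise-free recovery NSE ≥ 0.99), the
552-row default rice dataset for the regression benchmark (extremely
randomized trees test score ≥ 0.80 and ≥ the ridge score; ≥ 0.99 on the
noiseless variant), 1000 random pairs for the metrics identity
(tolerance 10⁻¹²), and one full assimilation loop (final NSE vs.
synthetic truth ≥ 0.90). `scripts/acceptance.R` recomputes all of these
from scratch under a caller-supplied seed.

## Known limitations

* The senescence formulation is this package's documented choice; other
  implementations calibrating a fourth parameter c may use a different
  process, so fitted c values are not transferable.
* Powell's method is a local optimizer; calibration finds the local
  minimum reachable from its start (global/multi-start search is out of
  scope by design). The restart strategy makes stalls rare but cannot
  guarantee a global minimum.
* The LightGBM-style family runs on a histogram-boosting stand-in, and
  the network family is CPU-bound plain R — adequate for the four-VI
  feature space, not for wide feature sets.
* No yield, biomass validation, water/carbon fluxes, sub-daily steps,
  atmospheric correction, or satellite imagery ingestion.
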