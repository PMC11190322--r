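---
title: "Methods: from canopy spectra to a tillering nitrogen prescription"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from canopy spectra to a tillering nitrogen prescription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`paddydose` implements the decision chain behind variable-rate tillering
topdressing in paddy rice: invert aboveground biomass (TAGP, kg/ha) from
canopy hyperspectra, assimilate the inverted biomass into a daily
nitrogen-limited crop growth simulation, and search the smallest tillering
nitrogen dose that drives simulated yield to the variety's average yield.
This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic test bed does and does not demonstrate.

## 1. Biomass inversion from canopy reflectance

### Band selection (SPA)

Hyperspectral canopies are measured on ~170 collinear bands; regression on
all of them is ill-conditioned and slow. The successive projections
algorithm (SPA) greedily builds a minimally collinear subset: starting from a
band $k_0$, each iteration replaces every remaining candidate column by its
residual orthogonal to the most recently selected column,

$$P x_j = x_j - \frac{(x_j^\top x_i)\, x_i}{x_i^\top x_i},$$

and selects the candidate with the largest residual norm,
$k_n = \arg\max_j \lVert P x_j \rVert$. Because the working columns are
residualized in place, the step-$n$ residual equals the projection onto the
orthogonal complement of **all** previously selected columns; the test suite
verifies this against a from-scratch Gram–Schmidt reimplementation.

Numerical choices:

* **Start band $k_0$.** No single start band is canonical, so
  `rmsecv_scan()` runs a chain from *every* candidate $k_0$ and scores each
  subset by fast k-fold linear-regression RMSE; a fixed `k0` is available as
  a fast mode. Greedy chains are prefix-nested in the band count, so one
  chain of length `n_max` per start band serves the whole count scan.
* **Mean-centering.** Columns are mean-centered before projection (flag
  `center`), otherwise the common reflectance offset dominates the first
  norms. The raw-reflectance variant is available because practice varies.
* **Ties** in the norm criterion go to the lowest band index, for
  determinism.
* **Degenerate rank** (all residual norms below 1e-12) raises an error
  naming the iteration rather than silently returning duplicated directions.

The band **count** is chosen by RMSECV: for each count in `n_min:n_max`
(default 5–30) the selected subset is scored by k-fold cross-validated RMSE
of the ELM inversion itself (5 folds, seeded shuffle), and the count with
the lowest RMSECV wins, ties toward fewer bands.

### Extreme learning machine (ELM)

The inversion is a single-hidden-layer network whose hidden layer is random
and fixed: after min–max scaling of each feature to $[-1, 1]$ (stored in the
model), hidden weights and biases are drawn from Uniform($-1, 1$) with a
seed, and only the output weights are fitted, by minimum-norm least squares

$$\beta = H^{+} y, \qquad H = \sigma(X W^\top + b),$$

with an SVD pseudoinverse cut at $10^{-10}$ of the leading singular value
(`ridge > 0` switches to a ridge solution). Defaults: logistic sigmoid, 50
hidden nodes — enough capacity for fewer than a dozen selected bands while
keeping the least-squares problem overdetermined at the training sizes used
here. Hidden nodes are drawn node-by-node so that enlarging `n_hidden`
appends nodes without changing existing ones; training error is then
provably non-increasing in `n_hidden`, which the tests check.

Data are split 7:3 into training and test sets by a seeded shuffle, and both
splits are reported with $R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$ and
$\mathrm{RMSE} = \sqrt{\tfrac1n \sum (pred - meas)^2}$. We compute $R^2$
only in the $1 - \mathrm{RSS}/\mathrm{TSS}$ form: the alternative
$\mathrm{ESS}/\mathrm{TSS}$ form agrees with it only for fits whose
residuals are orthogonal to the predictions, which a nonlinear inversion
does not guarantee.

## 2. The crop growth engine

The engine is a deliberately minimal daily-step, nitrogen-limited
production model — the causal chain fertilization → soil N → growth → yield
that the dose decision exploits — not a full physiological crop model. The
state is (DVS, LAI, TAGP, soil N, grain). Each day, in fixed order:

1. fertilizer enters the available soil pool at recovery fraction
   `n_recovery`;
2. phenology advances by thermal time: `dvs` gains
   $\max(0, \bar T - T_{base})/tsum_1$ before anthesis (DVS 1) and
   $/tsum_2$ after, capped at maturity (DVS 2);
3. potential growth is radiation-limited Monteith production
   $\Delta W_{pot} = RUE \cdot PAR \cdot (1 - e^{-k\,LAI})$ with
   $PAR = 0.5\,rad$; `rue` is in g DM per MJ PAR and converted to kg/ha by
   the factor 10;
4. nitrogen demand is `n_conc_target` per kg of new dry matter; uptake is
   capped by the soil pool, and the stress factor
   $f_N = uptake/demand$ scales growth;
5. realized growth $\Delta W = f_N \Delta W_{pot}$ accrues to TAGP;
6. before anthesis, leaf area expands at
   $sla \cdot leaf\_frac_0 (1 - dvs) \Delta W$; after anthesis the canopy
   senesces at `r_sen` per day and grain gains $grain\_frac \cdot \Delta W$.

All rates are clamped non-negative; TAGP and DVS are non-decreasing and the
soil pool obeys exact mass balance (both tested to 1e-9 over a season).

### Default parameters

Defaults describe a mid-late japonica paddy crop and were fixed once so
that the standard management (200 kg N/ha split 50% base / tillering /
20% panicle) yields on the order of 9 t/ha grain dry matter, with the
tillering-date biomass in the 0.3–1.3 t/ha range the inversion model is
trained on:

| parameter | default | units | role |
|---|---|---|---|
| `tbase_C` | 8 | °C | base temperature for thermal time |
| `tsum1`, `tsum2` | 900, 950 | °Cd | emergence→anthesis, anthesis→maturity |
| `rue` | 3.0 | g DM/MJ PAR | radiation-use efficiency |
| `k_ext` | 0.6 | – | canopy light extinction |
| `sla` | 0.0018 | ha/kg | specific leaf area |
| `leaf_frac0` | 0.55 | – | initial leaf partitioning (declines with DVS) |
| `grain_frac` | 0.8 | – | post-anthesis grain partitioning |
| `r_sen` | 0.006 | d⁻¹ | relative canopy senescence |
| `n_conc_target` | 0.009 | kg N/kg DM | N concentration of new biomass |
| `n_recovery` | 0.65 | – | fertilizer recovery fraction |
| `lai0`, `tagp0`, `soil_n0` | 0.012, 50, 28 | –, kg/ha, kg/ha | initial state |

Two emergent consequences of this N-budget formulation are worth knowing.
First, early TAGP is a pure accumulator: it does not feed back on growth, so
yield responds to the initial state only through LAI and soil N. Second, a
*more* vigorous early canopy can yield *less* under the same budget, because
it spends nitrogen on vegetative growth that is then unavailable for grain
fill. Both are respected in the tests (e.g. dose monotonicity is asserted
against soil N, not against early biomass).

### Calibration ("localization")

`calibrate()` fits unmeasurable parameters to an observed LAI series and a
yield target by minimizing

$$\sum_t \frac{(LAI_{sim}(t) - LAI_{obs}(t))^2}{\mathrm{var}(LAI_{obs})} +
  \left(\frac{yield_{sim} - target}{target}\right)^2 .$$

The optimizer is derivative-free — Nelder–Mead on a logistic transform of
the box bounds (Brent in one dimension) — because the day-stepped model
makes finite-difference gradients unreliable at phenology breakpoints. The
suite validates calibration by twin experiment: `tsum1` and `rue` are
recovered to well under 2% from noiseless weekly LAI plus the season yield.

## 3. Assimilating the inverted biomass

Observed TAGP (the inverted biomass, converted t/ha → kg/ha) corrects the
simulation at the observation date; the corrected state then simply
continues forward. The assimilated state vector is (LAI, TAGP, soil N);
only TAGP is observed, and the other components are corrected through their
covariance with TAGP (EnKF) or through the model dynamics (4D-Var).

**Ensemble Kalman filter.** The ensemble (default M = 100) perturbs the
initial state multiplicatively (lognormal, CV 0.25 per component, unit
mean) and is propagated by the engine. At an observation, with anomalies
$A = X^F - \bar X^F$ and $h$ the TAGP selector,

$$K = P^F H^\top \left[R + H P^F H^\top\right]^{-1},\qquad
  X^A = X^F + K\,(y + \eta - H X^F),$$

where $P^F H^\top$ and $H P^F H^\top$ are the sample (cross-)covariances of
the anomalies and each member sees an independently perturbed observation
$\eta \sim N(0, R)$ — the stochastic EnKF, which keeps the analysis spread
consistent with the Kalman posterior. A deterministic-mean mode (no
perturbations) exists for diagnostics; in that mode the analysis mean obeys
the Kalman identity to 1e-8 and the analysed variance never exceeds the
forecast variance. Negative post-analysis components are clamped to zero
and counted. With zero ensemble spread the gain is zero and the filter
warns instead of dividing by zero.

**4D-Var.** The control vector is the initial state
$(LAI_0, TAGP_0, soilN_0)$; the cost is

$$J(x_0) = \tfrac12 (x_0 - x_b)^\top B^{-1} (x_0 - x_b) +
  \tfrac12 \sum_t \frac{(h(x_t) - y_t)^2}{R_t},$$

with the model run from $x_0$ as the constraint. $B$ defaults to a diagonal
with (20% of background)² per component. The gradient is obtained by finite
differences inside bounded L-BFGS-B (with per-component `parscale`, since
LAI ~0.01 and TAGP ~50 live on very different scales); an adjoint is not
worth its complexity at this model size. After the solve, the full season is
re-run from the analysed initial state.

**Observation error.** The default is $R = (0.08\,y)^2$, tying the
assimilation's trust in the observation to the inversion model's relative
accuracy; it is configurable per observation.

**Consistency.** On linear-Gaussian toys both schemes match closed forms
(scalar Kalman update; normal-equations solution), and in the crop twin
experiment — truth with a 30% more vigorous initial state (TAGP and LAI
inflated together, since a heavier transplant carries proportionally more
leaf area), one tillering-date TAGP observation at 5% noise — both cut the
terminal-yield error by far more than half relative to the open loop.

## 4. The dose decision and prescription map

`yield_response()` inserts a tillering dressing of dose $d$ into the
remaining schedule and integrates the engine from the corrected state to
maturity; on the default parameters this response is non-decreasing in $d$
up to saturation (tested by scan). "Approach the average yield" is
operationalized as the **smallest** dose whose predicted yield reaches
`target_yield - tolerance` (defaults 9000 and 50 kg/ha): among equal-yield
doses the cheapest is preferred, and the tolerance makes ties deterministic.
The search scans a 5 kg/ha grid and refines the bracketing step by bisection
to 0.5 kg/ha; it matches an exhaustive 0.5 kg grid search in the tests. Two
shortcuts: if dose 0 already suffices, prescribe 0; if even the cap
(default 150 kg N/ha, an agronomic plausibility ceiling) falls short,
prescribe the cap with a `shortfall` flag — poor early growth cannot always
be compensated later, and the map should say so rather than fail.

Each plot is split into two equal management zones; in the packaged field
design zone A is corrected by the EnKF and zone B by 4D-Var, mirroring a
paired comparison of the two schemes. Doses are converted to urea at 46% N
(`urea = dose / 0.46`, rounded to 1 kg/ha) and written as a GeoJSON
FeatureCollection (planar coordinates in metres — desk-scale layouts do not
warrant projection machinery) plus flat CSV. Unfertilized control plots
(N0) are carried in the map flagged `excluded`. `compare_methods()` reports
per-zone and mean dose differences (4D-Var − EnKF) and each method's total
as a percentage of the uniform standard scheme; the sign of the difference
is data-dependent and the package asserts nothing about it.

## 5. The synthetic test bed

The generators are first-class, tested code, and define the study
conditions:

* **Spectra** are two-endmember mixtures: vegetation (green bump at 550 nm,
  red absorption trough at 670 nm, logistic red edge to a 0.50 NIR plateau)
  and a rising soil ramp, mixed by cover fraction
  $w = 1 - e^{-3\,biomass}$ (so $w$ spans ~0.03–0.98 over 0.009–1.34 t/ha)
  plus Gaussian noise (default sd 0.01 reflectance, a sensor-scale level).
* **Biomass labels** are Beta(1.2, 3.2) rescaled to 0.009–1.34 t/ha:
  right-skewed with mean ≈ 0.37 t/ha, the tillering-stage marginal the
  inversion is meant to cover.
* **Weather** is a sinusoidal temperate-monsoon season with seeded daily
  noise; `tmax ≥ tmin` holds by construction (mean ± positive half-range).
* **Plots** are rectangles assigned the five base-fertilizer gradients
  N0–N4 (0/100/150/200/250 kg N/ha, 50% applied as base dressing)
  cyclically and halved into zones.
* **The demo field** gives every plot its own lognormal soil-fertility
  (CV 0.3) and transplant-vigor (CV 0.2) multipliers; per-plot truths are
  run with base dressing only, their tillering-date spectra are inverted by
  the trained ELM, and those inverted values are what the assimilation sees.

What passing on this bed shows: the algorithms are implemented correctly
(oracle equivalence), the chain is internally consistent (twin-experiment
recovery), and the decision logic is exact against exhaustive search. What
it does **not** show: performance on real canopies. Real spectra contain
water, soil-moisture and view-geometry effects and mixed pixels that a
two-endmember mixture cannot produce; real initial-state and model errors
are not lognormal with known CV; and the reduced engine has no water
limitation, P/K response, organ-level respiration or pest/disease stress.
The engine's nitrogen response is also front-loaded: base-dressing
differences barely separate tillering-date biomass because early N demand
is small, so in the demo the observation signal comes mostly from the
per-plot vigor/fertility heterogeneity — which is precisely what the
assimilation is supposed to recover.

## 6. Problem sizes and tolerances used by the test suite

Training sets of 120–300 spectra, band-count scans to N = 30, ensembles of
100 (10⁵ for the scalar closed-form check), 130-day seasons and ten-plot
fields keep the full suite and the acceptance script each within a few
minutes on one CPU. Oracle comparisons are exact (`identical`) for SPA
orders, 1e-6 for ELM weights against normal equations, 1e-8 for the
deterministic Kalman identity, 1e-4 relative for 4D-Var against the
normal-equations solution, and 0.5 kg/ha for the dose search against the
exhaustive grid.
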