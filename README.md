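# paddydose

Variable-rate nitrogen topdressing for paddy rice at the tillering stage —
the first nitrogen-demand peak, when the topdress decision must be made from
how the crop is actually growing, not from a fixed calendar rate.

`paddydose` implements the full decision chain for users working on
remote-sensing-driven fertilization (precision-agriculture researchers and
crop modellers):

1. **Biomass inversion.** Aboveground dry biomass (TAGP, t/ha) is inverted
   from canopy hyperspectra (400–1000 nm, ~170 bands). The successive
   projections algorithm (SPA) picks a minimally collinear band subset —
   at each step the candidate maximizing the residual norm
   `‖x_j − (x_jᵀx_i)x_i/(x_iᵀx_i)‖` orthogonal to the selected bands — with
   the band count chosen by cross-validated RMSE (RMSECV, counts 5–30).
   An extreme learning machine (ELM: random fixed hidden layer, output
   weights `β = H⁺y` by minimum-norm least squares) maps the selected
   reflectances to biomass, trained on a seeded 7:3 split and scored by
   `R² = 1 − RSS/TSS` and RMSE.
2. **Data assimilation.** The inverted biomass corrects a daily
   nitrogen-limited crop growth engine (thermal-time phenology, Monteith
   radiation-limited growth `RUE·PAR·(1−e^{−k·LAI})`, N-uptake stress,
   post-anthesis grain partitioning) by either a stochastic **ensemble
   Kalman filter** (`K = PᶠHᵀ[R + HPᶠHᵀ]⁻¹`, perturbed observations,
   sample cross-covariances) or windowed **4D-Var** over the initial state
   (`J(x₀) = ½(x₀−x_b)ᵀB⁻¹(x₀−x_b) + ½Σ(h(x_t)−y_t)ᵀR⁻¹(h(x_t)−y_t)`).
3. **Dose decision.** From the corrected tillering-date state, the package
   searches the **smallest** tillering N dose whose simulated final yield
   reaches the variety's average yield (default 9000 kg/ha, tolerance
   50 kg/ha, cap 150 kg/ha), and emits a per-zone GeoJSON prescription map
   in urea equivalent (46% N).

A synthetic-data module (endmember-mixing spectra tied to biomass, seasonal
weather, gradient plot layouts N0–N4, twin-experiment truths) makes every
stage runnable and testable without field data. See the methods vignette
(`vignettes/paddydose-methods.Rmd`) for the model equations, parameter
defaults and limitations.

## Worked example

Invert biomass from synthetic canopy spectra, then decide a tillering dose:

```r
library(paddydose)

ds  <- generate_inversion_dataset(300, seed = 21)      # spectra + biomass, t/ha
sp  <- split_dataset(ds, ratio = 0.7, seed = 5)        # seeded 7:3 split
sel <- rmsecv_scan(ds, n_min = 5, n_max = 15, folds = 5, seed = 3)
sel
#> <band_selection> 9 bands (RMSECV 0.0284)
#>   wavelengths (nm): 734, 812, 766, 751, 744, 773, 741, 723, 826

model <- elm_train(sp$train, bands = sel, n_hidden = 50, seed = 6)
compute_metrics(sp$train$y, predict(model, sp$train), "train")
#> <regression_report> [train] n = 210, R2 = 0.993, RMSE = 0.0222
compute_metrics(sp$test$y, predict(model, sp$test), "test")
#> <regression_report> [test] n = 90, R2 = 0.978, RMSE = 0.0371
```

The selected bands sit on the red edge and NIR plateau, where reflectance
responds most to canopy density; test R² ≈ 0.98 with RMSE ≈ 0.037 t/ha over
the 0.009–1.34 t/ha tillering range.

```r
w    <- generate_weather("2021-05-19", 130, seed = 1)
sch  <- build_schedule("N2", tillering_n = 0, dates = schedule_dates(w))
traj <- run(crop_params(), w, sch[1, ])                 # base dressing only
st   <- state_at(traj, schedule_dates(w)[["tillering"]])
decide_dose(st, crop_params(), w, sch[3, ],             # panicle dressing remains
            decision_config(target_yield = 9000, tolerance = 50))
#> $dose
#> [1] 86.25
#> $predicted_yield
#> [1] 8958.125
#> $shortfall
#> [1] FALSE
```

An N2 plot (75 kg/ha base) needs ≈ 86 kg N/ha at tillering to bring
simulated yield within tolerance of the 9000 kg/ha target — about
`round(86.25/0.46)` = 188 kg/ha of urea for that zone.

The whole chain, from synthesis to prescription map:

```r
res <- run_pipeline(default_config(seed = 1))
#> inputs ready (130 weather days, 20 zones, 200 training spectra)
#> selected 11 bands: 947, 819, 769, 805, 862, 808, 869, 737, 581, 776, 844 nm
#> inversion R2 train 0.992 / test 0.992, RMSE test 0.022 t/ha
#> inverted biomass observations for 10 plots on 2021-06-18
#> assimilated 8 plots (EnKF M = 100; 4D-Var window to 2021-06-18)
#> prescription written (20 zones)
res$maps$mixed
#> <prescription_map> 20 zones (16 prescribed, 4 excluded)
#>   N dose: 26.6-150.0 kg/ha (mean 77.7), urea mean 169 kg/ha
```

Each plot's A half is corrected by the EnKF and its B half by 4D-Var; the
N0 control plots are carried in the map flagged `excluded`. All artifacts
(`selection.json`, `model.json`, `report.json`, `obs.csv`, `traj_enkf.csv`,
`traj_4dvar.csv`, `rx.geojson`, `summary.json`, `manifest.json`) land in the
configured output directory, and reruns with the same configuration are
byte-identical.

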