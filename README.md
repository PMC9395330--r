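# reefrange

Fine-scale acoustic-telemetry analysis of reef-associated fish, for
movement ecologists working with hyperbolic (time-difference-of-
arrival) positioning arrays: VPS-style exports of fish positions with
a unitless precision score (HPE), surveyed receiver stations, gridded
bathymetry, buoy meteorology and assigned fates.

The package implements the full analysis chain:

* **Error calibration and filtering.** Receiver self-positions with
  known deviations are binned by HPE; per bin,
  2DRMS = 2 √(MSE_x + MSE_y) about the surveyed truth, and an
  ordinary least-squares fit of 2DRMS on bin midpoints converts each
  animal fix's HPE into an estimated 95%-level error in meters
  (HPE_m*). The upper 5% of HPE values are excluded before
  calibration; movement analyses then keep fixes with HPE_m* ≤ 10 m
  (≤ 5 m for fine-scale distance-to-reef work). A drift-test routine
  scores absolute error of a towed transmitter against interpolated
  GPS truth.
* **Reef association.** Nearest-reef assignment in 2-D, the 20-m
  visit rule, run-collapsed visit events, reef switches (a transition
  between visits to *different* reefs), average days per reef =
  days tracked / (switches + 1), super-switcher flagging (< 2 d per
  reef), distance-to-reef series, and height above bottom from
  pressure-sensor depth and an ESRI-ASCII bathymetry grid.
* **Residency and site fidelity.** Release-reef residency records
  (departure = first visit to another reef or emigration from the
  array; predation / tag loss / harvest / unknown / at-large are
  right-censored; 4-day post-release screen), a native Kaplan–Meier
  estimator Ŝ(t) = Π (1 − dᵢ/nᵢ) with Greenwood variance and
  log(−log) confidence limits, median residency t₅₀ with a
  band-intersection CI, and the exponential-decay algebra linking
  site fidelity, emigration rate and median residency:
  R_E = −ln(SF)/t_SF and t₅₀ = t_SF · ln 0.5 / ln SF (annual fidelity
  is the t_SF = 365 case).
* **Home ranges.** Movement-based kernel density estimation from
  Brownian-bridge modelled steps (max 1500 s between fixes,
  σ² = 0.14 m²/s per axis, 1-m cells), bivariate in 2-D and
  trivariate in 3-D with surface/seabed clipping, and 95% contours
  (smallest cell set holding 95% of mass) as areas or volumes, over
  clock-aligned hourly, daily or whole-track windows.
* **Covariates.** Hourly model-ready tables: UTC hour, day of year,
  lunar phase (elongation ÷ π: 0 new, 1 full), nautical dawn/dusk,
  NDBC-style buoy series, bottom temperature.
* **Synthetic data.** A seascape/trajectory/observation generator
  (reef-attracted Ornstein–Uhlenbeck movement, diel modulation,
  Poisson reef switching, exponential emigration, spatially varying
  positional error with a recoverable linear HPE model) so the whole
  pipeline is testable closed-loop without any proprietary data.

## Worked example

```r
library(reefrange)

cfg <- sim_config(seed = 7, n_reefs = 12, extent = 2500, horizon_days = 20)
sim <- simulate_cohort(cfg, n_fish = 8)
out <- run_pipeline(sim$fixes, sim$receiver_fixes, sim$seascape$stations,
                    sim$fates, sim$releases)

print(out$calibration)
#> HPE calibration: error_m = 1.0933 * HPE + 0.64634
#>   fitted from 14 bins; HPE cutoff 13.969
```

The fitted slope/intercept recover the generator's error model
(truth: 1.1 and 0.5). Filtering at 10 m and the per-fish switching
summary:

```r
out$filter10
#>   threshold  n_in n_out retention
#> 1        10 89934 53981 0.6002291

head(out$switching, 3)
#>   fish_id n_reefs_visited n_switches days_tracked avg_days_per_reef super_switcher
#> 1    F001               4          3     20.00000          5.000000          FALSE
#> 2    F002               6          7     20.00000          2.500000          FALSE
#> 3    F003               5          4     20.00000          4.000000          FALSE
```

(Retention is lower than in a full-size array because this small demo
array has proportionally more high-error edge area.) Site-fidelity
algebra — e.g. a study reporting 37% annual fidelity implies:

```r
convert_fidelity(sf = 0.37, t_sf = 365)
#> Site-fidelity parameters (exponential decay):
#>   SF = 0.37 over t_SF = 365 d
#>   R_E = 0.00272398 /d;  t50 = 254.461 d;  AF = 0.37
```

so a daily emigration rate of 0.0027 and a median residency of 254 d.
Daily 95% home ranges for one fish:

```r
fx <- out$fixes10[out$fixes10$fish_id == "F001", ]
windowed_home_range(fx[fx$t <= min(fx$t) + 3 * 86400, ], window = "day")
#>   fish_id window_start n_steps   hr
#> 1    F001   2016-05-01     243 1621
#> 2    F001   2016-05-02     242 1629
#> 3    F001   2016-05-03     230 1456
```

`hr` is the 95% kernel-density area in m² (a fish holding station
within ~8 m of its reef uses a little over 1500 m² per day at these
movement parameters); `dims = 3` gives volumes in m³, clipped to the
water column when a bathymetry grid is supplied.

See `vignette("reefrange-methods")` for the models, parameter
meanings, numerical choices and the scope of the synthetic
validation.

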