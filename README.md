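# minitrap

Analysis of **mini-ensemble myosin laser-trap records**: displacement-vs-time
data from three-bead optical trap assays in which a small team (~4-5) of
myosin motor heads binds an actin filament, displaces the trapped
bead-actin-bead dumbbell, and detaches under the resistive load of the trap.
The package is aimed at single-molecule biophysicists who want a tested,
scriptable version of the standard pipeline for such records:

1. **Synthetic records with ground truth** — Ornstein-Uhlenbeck bead noise
   (stationary variance `kT/k_trap`) overlaid with Gillespie attachment /
   detachment kinetics; attached heads stiffen the trap and shift the mean,
   and detach with the Bell-type hazard
   `h(f) = k_adp0 exp(-f d_adp / kT) + [Pi] k_pi0 exp(+f d_pi / kT)`
   at the per-head load `f = F/N`.
2. **Trap calibration** — equipartition stiffness `k = kT / var(x)` from
   bead-only records, plus positional densities ("energy wells").
3. **Event detection** — running mean/variance features (100-sample windows,
   25-sample advance), a two-state Gaussian HMM over (window mean, log
   window variance) fitted by Baum-Welch and decoded by Viterbi, and exact
   two-segment Gaussian changepoint refinement of event boundaries.
4. **Event mechanics** — lifetime `t_on`, peak displacement (maximal 5 ms
   running mean), peak force `F = k_trap x displacement`, time at peak force
   `T_PF` (peak window to event end) and detachment rate `k_det = 1/T_PF`.
5. **Bell-bond fitting** — weighted nonlinear least squares of
   `k_det = k0 exp(F d / kT)` across trap stiffnesses, with standard errors
   and 95% confidence intervals on `k0` and the distance parameter `d`
   (negative `d` = load-slowed pathway), and CI-overlap comparison of fits.
6. **Ensemble bookkeeping** — head counts `displacement / 7 nm`, force per
   head, and the per-condition summary table.
7. **Reach geometry** — nearest-neighbour spacing of surface motors from
   2-D localization coordinates and the chord length `2 sqrt(2Rh - h^2)` of
   filament within reach `h` of a pedestal bead of radius `R`.

See `vignettes/minitrap-methods.Rmd` for the models, assumptions and design
choices.

## Worked example

```r
library(minitrap)

# calibrate a bead-only record
tr <- simulate_bead_only(sim_config(k_trap = 0.06, duration_s = 10, seed = 1))
equipartition_stiffness(tr)
#> equipartition stiffness: 0.0595 pN/nm (var 69.13 nm^2, n = 50000, T = 298.15 K)

# simulate a mini-ensemble record at 30 mM Pi and detect its events
cfg <- sim_config(n_heads = 4, k_trap = 0.10, k_attach = 1, k_adp0 = 0,
                  d_adp = 0, pi_mM = 30, k_pi0_per_mM = 1/12, d_pi = 4.1,
                  duration_s = 120, seed = 2)
sim <- simulate_ensemble_trace(cfg)
ev  <- detect_events(sim$trace)
nrow(sim$truth$events); nrow(ev)
#> [1] 211
#> [1] 191

m <- event_metrics(sim$trace, ev)
summarize_conditions(m)[, c("n_events", "mean_peak_force_pN", "k_det_per_s")]
#>   n_events mean_peak_force_pN k_det_per_s
#> 1      191           1.042351    6.099937
```

The detected event count sits a little under the truth count because events
shorter than one HMM window (20 ms) are unresolvable and closely spaced
events can merge. `k_det` is the reciprocal of the mean time at peak force:
at 0.10 pN/nm the 30 mM Pi pathway has roughly doubled the unloaded 2.5/s
detachment rate, which is the load dependence the Bell fit quantifies.
Fitting across the three stiffnesses (see `run_pipeline()` or the
acceptance script) returns `d` close to the generating 4.1 nm with a 95%
interval.

The same analysis runs as a configured pipeline with per-stage seeds,
an artifact manifest and a run log:

```r
cfg <- yaml::read_yaml(system.file("extdata", "demo_config.yaml",
                                   package = "minitrap"))
run_pipeline(cfg)   # simulate -> detect -> features -> table1 -> fit_bell
```

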