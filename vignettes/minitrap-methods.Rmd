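---
title: "Models and methods behind minitrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind minitrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`minitrap` analyses displacement records from mini-ensemble optical trap
assays: a small team of myosin motor heads (typically 4-5 within reach of
the actin filament) binds, displaces a trapped bead-actin-bead dumbbell,
and detaches under the resistive load of the trap. This vignette explains
the models implemented, the parameters that matter, and the design choices
made where the published analysis procedure left the details open.

## The synthetic record generator

Real trap records for this assay are rarely deposited, so the package
ships a generator whose output has the statistical structure the analysis
assumes. It serves two purposes: ground-truth benchmarking of the detector
and end-to-end validation of the kinetic fits.

### Bead mechanics

A bead in a harmonic optical trap of stiffness $k_{trap}$ with drag
$\gamma$ is an Ornstein-Uhlenbeck process with stationary variance
$k_BT/k_{trap}$ and autocorrelation time $\gamma/k_{trap}$. We simulate it
by exact discretization,

$$x_{i+1} = \mu + (x_i - \mu)\,e^{-k\Delta t/\gamma}
  + \sqrt{\tfrac{k_BT}{k}\bigl(1 - e^{-2k\Delta t/\gamma}\bigr)}\; z_i,$$

so the sampled process is exactly stationary at any sampling rate (no
time-step bias). At the default $\gamma = 1.9\times10^{-5}$ pN s/nm
(a 1 µm bead in water) and 5 kHz sampling the relaxation time
($\approx 0.5$ ms at $k = 0.04$ pN/nm) is comparable to the sample
spacing, giving the realistic lag-1 autocorrelation of ~0.66.

When $N$ heads are attached, each modelled as a linear spring
$k_{head}$ that has delivered a $\delta = 7$ nm powerstroke, the bead
relaxes around the quasi-static series-spring mean

$$\mu_N = N\delta \cdot \frac{N\,k_{head}}{k_{trap} + N\,k_{head}},$$

with effective stiffness $k_{trap} + N\,k_{head}$. This reproduces the two
features the detector relies on — a mean shift and a variance drop during
binding — and bounds the displacement staircase the way plateauing
ensemble records do. Bead inertia, dumbbell two-bead coupling, actin
compliance and filament pretension are not modelled; pretension is carried
as metadata only.

### Attachment/detachment kinetics

Head counts evolve by a continuous-time Markov (Gillespie) simulation.
Detached heads attach at `k_attach` each. An attached head carrying a
per-head load $f = F/N$ (equal sharing of the ensemble force
$F = k_{trap}\,\mu_N$, the assumption also used when converting measured
displacements to per-head forces) detaches with hazard

$$h(f) = k_{adp,0}\, e^{-f d_{adp}/k_BT}
       + [\mathrm{P_i}]\; k_{pi,0}\, e^{+f d_{pi}/k_BT} .$$

The first term is the ADP-release-limited pathway (slowed by resistive
load when $d_{adp} > 0$; ATP-induced detachment after ADP release is
lumped into $k_{adp,0}$, since at the assay's ATP level ATP binding is
fast relative to ADP release). The second is phosphate rebinding to the
AM.ADP state, which accelerates detachment under load when $d_{pi} > 0$.
A binding event is a maximal interval with at least one head attached.
Transition times are kept in continuous time in the ground truth and
rounded to the nearest sample when the trace is painted; events shorter
than one sample are dropped from the truth table because no detector can
resolve them.

### Defaults and why

| parameter | default | rationale |
|---|---|---|
| `n_heads` | 4 | heads within reach measured by localization microscopy |
| `step_nm` | 7 | single-molecule powerstroke of this construct |
| `k_trap` | 0.04 (also 0.06, 0.10) | the three two-trap stiffnesses of the assay |
| `k_head` | 0.3 pN/nm | order-of-magnitude myosin stiffness; not a measured value for this construct |
| `gamma` | 1.9e-5 pN s/nm | Stokes drag of a ~1 µm bead in water |
| `temperature_K` | 298.15 | 25 °C; $k_BT$ = 4.116 pN nm |
| `sample_rate_hz` | 5000 | acquisition rate of the assay |
| `k_attach` | 1 /s per head | gives duty ratios and event rates of the order seen in mini-ensemble records |
| `k_adp0`, `d_adp` | 15 /s, 4 nm | per-head values chosen so the unloaded detachment rate and the ~50% lifetime prolongation between the softest and stiffest trap match the no-phosphate behaviour |
| `k_pi0_per_mM` | 1/12 /s/mM | 2.5 /s of Pi-induced detachment at 30 mM Pi, the fitted unloaded rate of the Pi-sensitive mutant condition |
| `d_pi` | 4.1 nm | the strongly load-sensitive Pi pathway of the mutant condition |

The per-head $d$ values are not the ensemble-level fitted distances: the
hazard acts on the per-head load $f = F/N$, so an ensemble-level distance
$d_{ens}$ corresponds roughly to $N\,d_{ens}$ per head. These defaults are
the simulation study conditions; tests and the acceptance script override
only the fields each experiment isolates (e.g. `k_adp0 = 0` when the Pi
pathway is the estimand).

## Trap calibration

`equipartition_stiffness()` implements the equipartition estimate
$\hat k = k_BT/\mathrm{var}(x)$ on a bead-only record, subtracting the
sample mean first so that a trap-center offset or slow drift of the zero
does not bias the variance. The unbiased $(n-1)$ variance is used. No
power-spectrum or Allan-variance calibration is provided; equipartition is
the method used for this assay. The caller must supply an event-free
record — binding events inflate the variance and bias $\hat k$ low.
`positional_pdf()` exposes the positional density (the "energy well"):
stiffer traps narrow it, and a Gaussian fit to the density cross-checks
the variance.

## Event detection

1. **Window transform.** Running mean and unbiased variance in 100-sample
   windows advanced 25 samples. The published description ("one-quarter
   overlap") is ambiguous between an advance of `width/4` and `3*width/4`;
   we default to 25 samples (denser grid, better coarse bounds) and expose
   `step`, and both readings are exercised in the tests.
2. **Two-state HMM.** Baum-Welch EM over the window features, emissions
   modelled as independent Gaussians on the window mean and on
   `log(variance + 1e-6)`; the log transform makes the right-skewed
   variance feature near-Gaussian within each regime. Initialisation is
   deterministic: Lloyd k-means on the log-variance with the 10%/90%
   quantiles as starting centres, so repeated runs decode identically.
   Convergence at relative log-likelihood change below 1e-6, at most 500
   iterations. States are relabelled so state 1 is always the
   high-variance (unbound) regime.
3. **Single-regime guard.** On a motor-free record EM happily splits pure
   noise into two near-identical regimes. We require the log-variance
   emission means to separate by at least 3 pooled within-state SDs
   (d' ≥ 3); below that the model is flagged degenerate and decodes
   all-unbound. On simulated records the two sides are far apart (d' ≈ 2
   for bead-only noise, d' ≥ 4.5 for true two-regime records), so the
   guard is not a sensitive tuning knob.
4. **Decoding.** Viterbi (the published account does not state whether
   Viterbi or posterior thresholding was used; Viterbi gives coherent
   runs). Maximal bound runs become coarse events; the coarse bounds are
   the start sample of the first bound window and the start of the last
   bound window plus the window width. The original description
   ("multiplying the first and last running window position by the window
   width") conflicts with overlapping windows, where window index times
   width overshoots; our mapping reduces to it exactly for non-overlapping
   windows. Runs shorter than one window (20 ms) are discarded.
5. **Changepoint refinement.** Within two window widths on either side of
   each coarse bound, the boundary is re-estimated as the sample
   maximising the exact two-segment Gaussian log-likelihood (each segment
   its own mean and variance) — the deterministic limit of scanning a
   50-point running mean/variance for the most probable transition point,
   which is also available as `cp_method = "window50"`. Neighbourhoods
   with fewer than 10 samples on a side keep the coarse bound with a
   warning; refinement never inverts an event.

Detected events never overlap: each refinement is clipped at the previous
refined end, and boundaries are kept ordered.

## Per-event mechanics

Peak displacement is the maximum of a 5 ms (25 samples at 5 kHz, rounded
to the nearest sample at other rates) running mean inside the refined
event, ties to the earliest window; events shorter than 5 ms fall back to
the whole-event mean and are flagged. Peak force is the trace's
`k_trap` times peak displacement (a calibrated estimate can be passed
instead). The time at peak force $T_{PF}$ runs from the start of the
maximal window to the refined event end, and $k_{det} = 1/T_{PF}$.

At the condition level the default detachment rate is the *rate of the
mean*, $1/\overline{T_{PF}}$, with SEM by first-order propagation
($\mathrm{SEM}(1/m) \approx \mathrm{SEM}(m)/m^2$). The mean of per-event
reciprocals is also reported but is bias-prone for short $T_{PF}$ (the
expectation of $1/T$ diverges for exponential $T$), so it is not used for
fitting. Head counts divide displacement by the 7 nm powerstroke; with
force = stiffness x displacement this makes force-per-head exactly
`k_trap * step_nm`, an identity the table builder asserts.

## Bell-bond fitting

`fit_bell()` fits $k_{det} = k_0 e^{F d / k_BT}$ by weighted nonlinear
least squares in $(\ln k_0, d)$ — the exponential is linear in the log, so
an OLS fit of $\ln k$ on $F$ supplies a start that is already exact on
noiseless data, and the parameterization keeps $k_0 > 0$ without
constraints. $d$ may be negative (a load-slowed pathway). Weights are
$1/\mathrm{SEM}^2$ when condition SEMs are available. In that case the
parameter covariance is reported *unscaled* (generalized least squares
with known variances) rather than rescaled by the residual variance: with
three stiffnesses and two parameters there is a single residual degree of
freedom, and a variance estimate with 1 df is far too unstable to base
intervals on, whereas the SEMs come from hundreds of events each and are
effectively known. The 95% intervals are normal-theory ($\pm 1.96$ SE);
with the unscaled covariance they cover the generating $d$ at close to the
nominal rate in the package's replication tests. A start that happens to
sit exactly on a zero-residual solution can trip the optimizer's rank
check, in which case the fit restarts from a nudged start and converges
back. `compare_fits()` reports CI overlap between two fits and the ratio
of their $d$ values (the relative load sensitivity).

## Reach geometry

For surface motor densities measured by localization microscopy,
`nearest_neighbor_distances()` computes exact all-pairs nearest-neighbour
distances, `fit_nn_center()` fits a Gaussian to their histogram
(Freedman-Diaconis bins unless given) and falls back to the median if the
fit fails, and `accessible_length()` gives the filament length within a
motor's reach $h$ of a pedestal bead of radius $R$ as the chord
$2\sqrt{2Rh - h^2}$ (488.3 nm for $R = 1.5$ µm, $h = 20$ nm). The head
count divides the chord by the spacing — 1-D counting along the filament,
matching the "length available" framing; a 2-D strip-density estimate is
reported alongside. No correction is applied for repeated localizations of
one molecule.

## Validation experiments and problem sizes

The test suite and `scripts/acceptance.R` regenerate everything from
seeds; the sizes below were chosen to keep a full run to a few minutes on
one core while leaving comfortable statistical margins.

* **Calibration recovery**: 10 s bead-only records at 0.04/0.06/0.10
  pN/nm recover the stiffness within 5% (the estimator's relative error at
  5 kHz x 10 s with this autocorrelation is ~1%).
* **Detector benchmark**: four seeded 240 s ensemble records at 0.10
  pN/nm; recall and precision are scored on truth events at least two
  window widths long with mean shift at least $2\sigma$ of the baseline,
  boundary error as the median over matched starts and ends.
* **End-to-end recovery**: three 450 s records (>= 500 events per
  stiffness) at the Pi-pathway parameters ($d_{pi} = 4.1$ nm, 2.5 /s
  unloaded at 30 mM), full pipeline, weighted Bell fit on force per head.
  The recovered $\hat d$ lands within +-30% of truth; the residual bias
  comes from detection noise and from the spread of attached head counts
  (the fit sees per-head force at the displacement peak, the hazard acts
  on the instantaneous per-head load).
* **Interval calibration**: 100 seeded replicates of three single-head
  conditions (>= 500 events each). With one head the attached lifetime is
  exactly exponential in the Bell hazard at a constant per-head load, so
  the experiment isolates the fit's coverage from ensemble-mechanics bias;
  the 95% CI covers the generating $d$ in >= 90% of replicates.

What passing these tests does **not** show: robustness to instrument
drift, low-frequency noise, dumbbell compliance or non-equal load sharing,
none of which the generator emulates. On real records those effects make
boundary refinement and peak-force estimates noisier than the synthetic
benchmarks suggest.

## Known limitations

* The quasi-static mean-field mechanics ignore the sub-millisecond
  transient after each attachment; at relaxation times comparable to the
  sample spacing this mainly softens the painted step edges.
* The detector cannot resolve events shorter than one window (20 ms) and
  may merge events separated by less than a window of unbound time; merged
  counts inflate lifetimes slightly at high event rates.
* Condition-level $k_{det} = 1/\overline{T_{PF}}$ mixes the detachment
  cascade of multi-head events into a single effective rate; its Bell
  distance is an effective ensemble parameter, not the per-head distance,
  unless the force axis is also per-head.
* The unscaled-covariance intervals assume the supplied SEMs are correct;
  with very few events per condition they will be anti-conservative.
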