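---
title: "Methods: estimating crystallization kinetics and MSMPR design targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating crystallization kinetics and MSMPR design targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crystkin)
```

This vignette records the statistical models, estimator definitions, numerical
choices, and known limitations behind `crystkin`. The README gives the
workflow overview; this document is the reference for *why* each estimator is
built the way it is.

## 1. Primary nucleation from censored induction times

### Model

Nucleation of the first crystal in a small, quiescent, clear volume is
treated as a homogeneous Poisson process with rate `J·V` (nuclei per minute
in the whole vial). The observable event — the operator or camera seeing a
crystal — lags the nucleation event by a growth time `t_g`, during which the
single nucleus grows to a visible size. The probability that a vial has
visibly crystallized by time `t` is therefore a shifted exponential:

$$P(t) = 1 - \exp\bigl(-J V (t - t_g)\bigr), \qquad t > t_g.$$

Assumptions: one dominant nucleus per vial (secondary nucleation from that
nucleus is what makes it visible, but does not change the timing statistics);
constant supersaturation over the observation window; vials are independent
and identically prepared.

### Estimation

With `M` vials per condition and a censoring time `t_c` (default 240 min),
the empirical CDF is `P̂(t) = M⁺(t)/M` with the censored vials kept in the
denominator — dropping them would bias `J` upward, badly so at low
supersaturation where most vials never nucleate. `fit_induction_model()`
minimizes the sum of squared deviations between `P̂` and the model by
Levenberg–Marquardt (`minpack.lm::nlsLM`), with:

- starting values from the data: `t_g⁰` = minimum observed induction time
  (MIT), `J⁰` solved from the final observed `P̂`;
- box constraints `J ≥ 0`, `0 ≤ t_g ≤ MIT` (the offset cannot exceed the
  earliest observation);
- jittered restarts if the first attempt fails;
- a final `stats::nlminb` polish on the same objective with per-parameter
  scaling. The polish matters: `J` and `t_g` differ by 3–4 orders of
  magnitude, and Levenberg–Marquardt's relative-tolerance stop can trigger
  while the gradient in `J` is still significant. On noise-free data the
  polished fit recovers truth to ~1e-12 relative; without it, errors of
  ~1e-3 remain.
- standard errors from the numeric Jacobian at the optimum.

A condition is only fitted when at least `min_nucleated` (default 5) vials
nucleated; below that the CDF carries too little curvature to separate `J`
from `t_g`, and the fit raises a classed `crystkin_insufficient_data` error
rather than returning garbage.

`fit_induction_mle()` provides an independent cross-check: the exact
censored-exponential likelihood, profiled over `t_g`. Least squares on the
CDF is the primary estimator because it weights the whole trajectory and is
robust to the discreteness of small `M`; the MLE agrees closely at study
scales and is exercised in the test suite.

## 2. Secondary nucleation and growth from seeded imaging

### Count traces → B

Particles per image are converted to number density by a calibration factor
(default 100 particles/mL per count/image). Counting is unreliable below a
background floor (10 counts/image) and above a crowding ceiling (160
counts/image, where particle overlap causes undercounting), so
`select_window()` restricts the fit to the first floor crossing through the
last frame before the ceiling is exceeded. `B` is the ordinary least-squares
slope of density versus time in that window.

**Boundary-frame trimming.** When the window is selected automatically,
`estimate_secondary_rate()` drops the window's two boundary frames (provided
at least five frames remain ≥ 3). The boundary frames enter the window
*conditional on their own counting noise* — the first frame crossed the floor
partly by fluctuating high, the last stayed under the ceiling partly by
fluctuating low — and both effects flatten the fitted slope. In replicate
studies at study scales (B = 2000–5000 particles/(mL·min), frame intervals
0.25–1 min) this selection bias is a systematic ≈ 2.5–3% underestimate;
trimming reduces it below 1%. A user-supplied window is used verbatim, since
an explicit window carries no selection conditioning.

The delay time (`detect_delay_time()`) is the first frame at or above the
floor; a trace that never reaches it returns `NA` ("not detected"), which is
deliberately distinct from an error.

### PSD traces → G

Size histograms use 99 linear bins spanning 3–300 µm (3 µm width), matching
the imaging instrument's detection floor and field of view. Per frame, each
bin is weighted by `count × midpoint³` — the volume shape factor cancels in
the volume *fraction* — and `d90` is interpolated linearly within the bin
containing the 0.90 crossing of the cumulative volume fraction. Frames with
fewer than `min_count = 10` particles are skipped as indistinguishable from
background. `G` is the OLS slope of `d90` versus time.

`d90` rather than a mean size is used because it tracks the largest (seed-
descended, longest-growing) particles and is therefore insensitive to the
continuous injection of new small particles by secondary nucleation, which
drags number-weighted means down even at constant `G`.

**Resolution caveat.** Binned `d90` agrees with a brute-force per-particle
computation to within about one bin width (3 µm) for frames populated by
≳ 100 particles. In sparse frames a single large crystal can carry > 10% of
total volume, and the midpoint-cubed weighting can shift the interpolated
crossing by several bins; the `min_count` floor removes the worst cases but
`d90` values from frames of a few dozen particles should be treated as
±1–2 bins.

## 3. Power laws and mechanism syntheses

Both rates are condensed to `rate = k (S−1)^n` by OLS on
`ln(rate) ~ ln(S−1)`, using only strictly positive rates at `S > 1`. Log-
space fitting weights relative (not absolute) errors, which is appropriate
when rates span orders of magnitude across the supersaturation range; `R²`
is reported in log space.

The single-nucleus size `L_sn` comes from a through-origin fit of the
induction offset against inverse growth rate, `t ≈ L_sn / G(S)`, evaluated
two ways: with `t = t_g` (the fitted offset) and with `t = MIT` (the minimum
observed induction time). The two are kept as **separate estimates** rather
than pooled: `t_g` is a model parameter with fitting uncertainty, MIT is an
order statistic biased high by finite sampling, and their difference is
itself informative (MIT-based `L_sn` runs ~15–20% above `t_g`-based in both
simulation and practice). The seeded delay time is regressed on `1/G` with a
*free* intercept, splitting it into a growth-independent minimum delay
(intercept, ≈ attachment/lag time) and a detectable-size slope `L_det`.

## 4. MSMPR design relations

For a steady-state MSMPR with size-independent growth and negligible
breakage/agglomeration, the population density is
`n(L) = n₀ exp(−L/Gτ)`. For cubic crystals (volume shape factor `k_v`,
default 1) the moment integrals give

$$d_{43} = 4 G \tau, \qquad \phi = 6 k_v n_0 (G\tau)^4, \qquad B = n_0 G.$$

`msmpr_required_rates()` inverts these for the `(G, B)` required to hit a
target `(φ, d43, τ)`; `msmpr_forward()` is the forward map, and the pair
round-trips to ~1e-9 relative over six orders of magnitude of designs (an
acceptance test). Internally everything is SI; the public interface reports
`G` in µm/min and `B` in particles/(mL·min) to match the bench-scale
estimators. `operating_point()` inverts the growth power law for the
supersaturation delivering the required `G`, evaluates the secondary power
law there, and flags whether the available `B` meets the requirement.

## 5. The simulator

`sim_config()` defaults are the study conditions, not tuning knobs: 3 mL
vials, 240 min censoring, 100× calibration, 3–300 µm detector, 1 min frames.
`simulate_workflow_suite()` defaults encode a glycine-like system:
`G = 3400 (S−1)^{2.86}` µm/min, `B = 6×10⁶ (S−1)^{3.5}` particles/(mL·min),
`J = 7 (S−1)^{3.4}` nuclei/(mL·min), `L_sn = 150` µm, seeded delay
`5 + 9/G` min. These were fixed once, at the physical scales of the system,
before the truth-recovery tests were written.

Stochastic modes draw exponential induction waits, Poisson frame counts, and
Poisson particle births. Deterministic modes are designed for verification:

- induction times are placed at the exponential quantiles `i/M` (with the
  top quantiles censored), so the empirical CDF lies *exactly* on the model
  curve and estimator error isolates numerical error;
- count traces are exact expectations (possibly non-integer — the
  integer-count invariant applies to the stochastic mode only);
- PSD births accumulate as `floor(λ·i)` with the carry placed at step ends,
  so frame totals exactly match cumulative births when every particle is
  within the detector range.

What the simulator does *not* emulate: supersaturation depletion during an
experiment (rates are constant per condition), growth-rate dispersion,
agglomeration/breakage, imaging segmentation artifacts beyond the
floor/ceiling window, and temperature transients. Per-condition frame
intervals in the suite are chosen from the generative rates so the count
window and PSD range are well sampled — mirroring how an experimentalist sets
a camera rate after a scoping run.

## 6. Other recorded decisions

- **Solubility basis.** `fit_vant_hoff()` regresses `ln(C_s)` in mass
  concentration (mg solute / g solvent) on `1/T(K)`. Mole-fraction and mass
  bases differ by a slowly varying factor; only relative trends feed the
  downstream kinetics, so the basis is fixed rather than configurable, and
  users with mole-fraction data can transform before fitting.
- **Supersaturation grid.** The suite accepts any `S > 1` grid. At the low
  end of the study range (S ≈ 1.06) only ~15% of 3 mL vials nucleate within
  4 h, which is below the `min_nucleated` floor at 25 vials; the pipeline
  then records the skipped condition in `report$errors` and proceeds — a
  deliberate degradation mode, since real campaigns routinely lose their
  lowest-supersaturation condition to censoring.
- **Report JSON.** `write_report()` uses `jsonlite` with `digits = NA` (full
  precision) and explicit unit strings in every block, so downstream
  consumers never guess units.

## 7. Limitations

- The induction model assumes a single mechanism; systems with competing
  heterogeneous nucleation populations show curved `ln(1−P)` plots that this
  model will average over.
- `B` from imaging counts all detectable particles; it cannot distinguish
  secondary nuclei from attrition fragments.
- The MSMPR relations assume `G` independent of size and of `L`-dependent
  removal; classified-product or fines-dissolution configurations need
  different closures.
- Power laws are empirical interpolations over the measured range;
  extrapolating far outside it (as `operating_point()` will happily do) is a
  design *screen*, not a prediction.
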