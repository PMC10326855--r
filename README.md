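# crystkin

Rapid assessment of crystallization kinetics from small-volume experiments,
and translation of the fitted kinetics into continuous (MSMPR) crystallizer
design targets. The workflow is built around α-glycine crystallizing from
aqueous solution, but every rate law and estimator is parameterized, so other
solute/solvent systems fit the same pipeline.

## The science

Designing a crystallization process requires, at minimum, kinetics for three
competing mechanisms as functions of supersaturation `S = C / C_s` (solution
concentration over solubility; for glycine in water `C_s = 249.52` mg/g
solvent at 25 °C):

1. **Primary nucleation.** Nucleation of a stochastic single nucleus in a
   small clear volume is a Poisson process, so the probability that a vial of
   volume `V` has nucleated by time `t` is

   ```
   P(t) = 1 − exp(−J·V·(t − t_g)),   t > t_g
   ```

   where `J` is the primary nucleation rate (nuclei/(mL·min)) and `t_g` is a
   growth/detection offset: the nucleus must grow to a visible size before it
   registers. Fitting this model to the empirical cumulative fraction of
   nucleated vials — with vials that never nucleate before the 4 h cutoff kept
   in the denominator as censored observations — yields `J` and `t_g` per
   supersaturation (`fit_induction_model()`, Levenberg–Marquardt with a
   censored-exponential maximum-likelihood cross-check in
   `fit_induction_mle()`).

2. **Secondary nucleation.** After seeding, in-situ imaging counts particles
   per frame. Counts between a background floor of 10 and a crowding ceiling
   of 160 per image are reliable (`select_window()`); multiplied by a
   calibration factor (particles/mL per count/image) they give a number
   density whose slope over time is the secondary nucleation rate `B`
   (`estimate_secondary_rate()`). The delay before counts first cross the
   floor (`detect_delay_time()`) carries mechanistic information of its own.

3. **Growth.** The same images give number-weighted size histograms (99
   linear bins spanning 3–300 µm). Per frame, the volume-weighted `d90` — the
   size below which 90% of particle volume lies — is interpolated from the
   cumulative volume fraction (`d90_series()`); its slope over time is the
   linear growth rate `G` in µm/min (`estimate_growth_rate()`), insensitive
   to ongoing nucleation because it tracks the largest particles.

Both `B` and `G` are condensed into empirical power laws
`rate = k·(S − 1)^n` (`fit_power_law()`). Two syntheses then connect the
mechanisms:

- **Single-nucleus mechanism.** If unseeded vials crystallize by one primary
  nucleus growing to a size `L_sn` at which it triggers secondary nucleation,
  then `t_g ≈ L_sn / G(S)`: a through-origin fit of `t_g` (or the minimum
  induction time) against `1/G` estimates `L_sn`
  (`offset_fit_through_origin()`). A free-intercept fit of the seeded delay
  time against `1/G` splits it into a minimum (attachment/lag) delay and a
  detectable-size term (`delay_fit_free_intercept()`).
- **MSMPR design targets.** For a mixed-suspension mixed-product-removal
  crystallizer at steady state with size-independent growth, the population
  density is `n(L) = n₀·exp(−L / Gτ)`; for cubic crystals the volume-weighted
  mean size is `d43 = 4Gτ` and the solids fraction is
  `φ = 6·k_v·n₀·(Gτ)⁴`. Inverting these gives the growth and nucleation
  rates *required* to hit a target `(φ, d43, τ)`
  (`msmpr_required_rates()`), which can be compared against what the fitted
  power laws say the system can *deliver* (`operating_point()`).

A simulator (`sim_config()`, `simulate_induction_times()`,
`simulate_seeded_counts()`, `simulate_psd_series()`,
`simulate_workflow_suite()`) generates synthetic campaigns at the study's
experimental scales — 3 mL vials, 240 min censoring, 10–160 count windows,
3–300 µm detectors — with exact-expectation deterministic modes for
verification and Poisson/exponential stochastic modes for realism.

## Worked example

Simulate a six-supersaturation campaign (25 induction vials, 3 seeded count
traces, and a PSD series per condition), run the full analysis pipeline, and
check it against an MSMPR design point:

```r
library(crystkin)

S <- 1 + c(0.08, 0.10, 0.13, 0.15, 0.16, 0.18)
suite  <- simulate_workflow_suite(S, sim_config(seed = 42))
design <- msmpr_required_rates(phi = 0.1, d43_m = 1e-4, tau_s = 1000)
report <- run_pipeline(suite, msmpr_design = design)
print(report)
```

```
crystallization kinetics report
  primary nucleation: 6 supersaturation(s) fitted
    S = 1.08   J = 0.00159 /(mL min)  t_g = 79.5 min  (14/25 nucleated)
    S = 1.1    J = 0.00273 /(mL min)  t_g = 30 min  (18/25 nucleated)
    S = 1.13   J = 0.00774 /(mL min)  t_g = 15.6 min  (25/25 nucleated)
    S = 1.15   J = 0.0147 /(mL min)  t_g = 10.7 min  (25/25 nucleated)
    S = 1.16   J = 0.0129 /(mL min)  t_g = 6.64 min  (25/25 nucleated)
    S = 1.18   J = 0.0215 /(mL min)  t_g = 6.56 min  (25/25 nucleated)
  secondary nucleation: 18 trace(s) fitted
  growth: 6 supersaturation(s) with d90 slopes
  growth power law:    G = 3457 (S-1)^2.88 um/min  (R^2 1.0000)
  secondary power law: B = 5.916e+06 (S-1)^3.48 /(mL min)  (R^2 0.9915)
  single-nucleus size L_sn: 175 um (from t_g), 208 um (from MIT)
  delay fit: minimum delay 5.01 min, detectable size 12.1 um
  MSMPR: S for required G = 1.068; B available 523.2 vs required 6.4e+04 -> infeasible
```

The simulator's generative truth here was `G = 3400 (S−1)^2.86` and
`B = 6×10⁶ (S−1)^3.5` with `L_sn = 150` µm and a 5 min minimum delay — the
noisy campaign recovers the exponents to ~1%, the prefactors to within a few
percent, and the mechanistic constants within the scatter expected at this
sample size. The design stage is also the campaign's punchline: at the modest
supersaturation where growth matches the target (S ≈ 1.07), secondary
nucleation delivers orders of magnitude fewer nuclei than a 100 µm-product
MSMPR requires, so seeding or another nuclei source is needed.

```r
print(design)
#> MSMPR design point (cubic crystals, k_v = 1)
#>   phi = 0.1, d43 = 0.0001 m, tau = 1000 s
#>   required G = 1.5 um/min
#>   required B = 6.4e+04 particles/(mL min)
```

Serialize any report with `write_report(report, "report.json")`. Measured
data enter through the CSV readers (`read_induction_csv()`,
`read_counts_csv()`, `read_psd_csv()`, `read_clear_points_csv()`,
`read_solubility_csv()`), which validate row-by-row and return the same
objects the simulator produces.

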