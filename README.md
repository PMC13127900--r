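# uterodyn

Quantitative analysis of dynamic utero-placental MRI.

During pregnancy the uterus shows two kinds of spontaneous contraction on
dynamic (time-resolved, multislice) R2\*-weighted MRI. *Uterine* (Braxton
Hicks-type) contractions thicken the uterine wall and thin the placenta
slightly; *placental* contractions are confined to the placental bed, which
shortens while the placenta balloons (its sphericity rises) and maternal
blood is expelled from the intervillous space, so placental volume falls.
`uterodyn` is for imaging scientists who have segmented such a series
(placenta / non-placental uterine wall / intra-uterine contents /
background, plus co-registered signal volumes) and want reproducible
contraction measurements: per-frame morphometry, event detection, duration
and feature extraction, motion screening, placental-vs-uterine
classification, and cohort statistics.

## The quantities at the core

For each frame the pipeline measures compartment volumes (gap-aware voxel
counts on the anisotropic multislice grid), surface areas (signed-distance
interpolation across the slice gap, then isosurface triangulation), and the
placental sphericity

&nbsp;&nbsp;&nbsp;&nbsp;Ψ(t) = π^(1/3) (6V(t))^(2/3) / A(t) ∈ (0, 1],

together with the relaxation-rate change from the mean placental signal
S(t) and its earliest-rest baseline S_b:

&nbsp;&nbsp;&nbsp;&nbsp;ΔR₂\*(t) = −(1/TE) · ln(S(t)/S_b)   [ms⁻¹].

Series are smoothed with a 5-point moving average, contraction events are
detected as excursions below an interpolated rest reference, each event
gets a local baseline (linear between its flanking rest volumes) and a
half-maximum duration, and the rule *volume drop > 10 % and sphericity
increase > 0.005 → placental* classifies the gated events. Group contrasts
use the Mann-Whitney U test (exact for small samples) with a Bonferroni-
adjusted threshold of 0.01/5 = 0.002.

Because no clinical data ship with the package, a parametric
utero-placental phantom generates synthetic sessions (ellipsoidal cavity,
spherical-cap placenta, incompressible contents, mono-exponential TE
signal, respiratory-triggered irregular sampling) with closed-form ground
truth for every injected contraction. See the methods vignette
(`vignettes/uterodyn-methods.Rmd`) for the model and all numerical choices.

## Worked example

Simulate a 30-minute session containing one placental and one uterine
contraction, then run the full analysis:

```r
library(uterodyn)

cfg <- scenario_config(
  n_frames = 120,
  events = list(
    event_spec("placental",       onset_s = 300,  duration_s = 360,
               amplitude = 0.20),
    event_spec("uterine_uniform", onset_s = 1100, duration_s = 330,
               amplitude = 0.15)),
  noise_sd_fraction = 0.02, rng_seed = 7)

session <- simulate_session(cfg)
res <- analyze_session(session, measures = c("volumes", "sphericity"))

res$events[, c("label", "max_volume_drop_pct", "max_sphericity_change",
               "halfmax_duration_min", "dr2s_change_per_ms")]
#>       label max_volume_drop_pct max_sphericity_change halfmax_duration_min
#> 1 placental                20.7                0.0276                 2.81
#> 2   uterine                14.7               -0.0520                 2.75
#>   dr2s_change_per_ms
#> 1            0.00383
#> 2            0.00375
```

Reading the output: the first event dropped placental volume by 20.7 %
versus its local baseline (amplitude 0.20 was injected), raised sphericity
by 0.028 (> 0.005, so with the > 10 % gate it is labelled placental), ran
2.8 minutes between half-maximum crossings (analytic ground truth: half
the 360 s raised-cosine, i.e. 3.0 min), and raised placental R₂\* by
0.0038 ms⁻¹. The second event thinned the placenta (sphericity fell), so
it is uterine. Session-level numbers:

```r
res$summary$rate_all_per_h
#> [1] 4.2
res$motion$high_movement_scan
#> [1] FALSE
```

`write_session()` / `read_session()` exchange sessions as NIfTI volumes
with a JSON sidecar and ground-truth CSV, and `inst/cli/uterodyn` offers
`simulate`, `analyze` and `report` subcommands for shell pipelines.

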