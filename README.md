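# prismwalk

Severe peripheral field loss (PFL, "tunnel vision") leaves a residual
central field of 20° diameter or less. A pedestrian approaching on a
**center-to-center collision course** keeps a constant bearing angle β while
the range decreases — similar triangles guarantee it — so they stay at a
fixed eccentricity outside the residual field until moments before impact
and seem to "pop up". Oblique high-power Fresnel prisms placed above and
below the visual axis shift unseen lateral scene regions onto functioning
retina, creating peripheral islands of vision at the eccentricities where
collision risk concentrates.

`prismwalk` is a simulator and analysis toolkit for virtual
pedestrian-encounter experiments that evaluate this situation. It is aimed
at low-vision rehabilitation researchers and visual-psychophysics modelers,
and provides:

- **Encounter kinematics** — constant-velocity paths solved from design
  parameters (initial bearing β₀, path-crossing distance d_pc, 19.4 m
  initial separation, 6 s crossing time, 1.94 m/s walking speed, 0.6 m body
  diameter); bearing and bearing-span dynamics, closed-form closest
  approach, field-entry times.
- **Scenario batteries** — reproducible, counterbalanced 20-trial scenarios
  (10 per side: two parallel sidewalk-like encounters plus 10° and 30°
  bearings crossed with d_pc ∈ {−2, 0, +2, +12} m) with seeded segment
  plans.
- **Goggle and prism optics** — exact two-surface Snell traces of 57Δ
  oblique Fresnel prisms (17° tilt, ±7.5° vertical shift) on 20°-aperture
  goggles, including total internal reflection and the lateral island
  extent (default ≈[11°, 40°] of eccentricity).
- **Collision cues** — accumulated bearing deviation, bearing-span overlap
  with the matched center-to-center collision, and closest distance.
- **A synthetic observer** — region-dependent Poisson detection hazards, a
  noisy threshold rule on closest distance, and RT models, plus
  maximum-likelihood parameter recovery (`estimate_observer()`, with
  broom-style `tidy()`/`glance()`).
- **An analysis pipeline** — detection rates, decision accuracy among
  detected trials, RT summaries by condition × field position, and
  cue-response correlations, with ggplot2 figures.

## Worked example

```r
library(prismwalk)
library(dplyr)

battery <- build_battery(seed = 42)
cues <- compute_cues(battery)
cues |> filter(side == "right") |> arrange(beta0_deg, dpc_m)
#>    trial_id  side beta0_deg dpc_m abd_deg abd_degs overlap_pct   dmin_m tmin_s
#> 1       T13 right       2.5   Inf     516    47.20        4.48 1.69e+00   6.00
#> 2       T07 right       5.0   Inf     777    73.48        5.02 1.69e+00   6.00
#> 3       T12 right      10.0    -2     973    88.88       30.89 3.15e-01   5.45
#> 4       T04 right      10.0     0       0     0.00      100.00 3.79e-15   6.00
#> 5       T20 right      10.0     2     101     9.65       41.97 3.86e-01   6.68
#> 6       T17 right      10.0    12     247    24.24        6.66 5.14e+00  14.27
#> 7       T19 right      30.0    -2    1020    94.78        7.84 9.17e-01   5.50
#> 8       T15 right      30.0     0       0     0.00      100.00 1.78e-15   6.00
#> 9       T16 right      30.0     2     299    28.62       14.67 1.10e+00   6.57
#> 10      T11 right      30.0    12     741    72.61        1.89 1.08e+01   8.95
```

Reading the cue table: the d_pc = 0 trials are true center-to-center
collisions — zero bearing drift (`abd_deg`), 100% span overlap, zero closest
distance. The ±2 m near-misses stay under ~1 m closest distance (hence count
as collisions), the +12 m and parallel (`Inf`) trials are clear
noncollisions, and overlap falls while bearing drift grows as the miss gets
wider. The parallel trials bottom out at exactly the designed 1.69 m lateral
offset.

Simulate an observer with and without the prisms and summarize:

```r
log_pfl <- simulate_responses(battery, observer_params(), "PFL")
log_pr  <- simulate_responses(battery, observer_params(), "PFL+PR", seed = 2)
summarize_responses(bind_rows(log_pfl, log_pr), battery)
#>   condition field_group detection_rate_pct decision_accuracy_pct
#> 1       PFL     central                100                   100
#> 2       PFL  peripheral                 25                   100
#> 3    PFL+PR     central                100                   100
#> 4    PFL+PR  peripheral                100                   100
#>   mean_detection_rt_s mean_decision_rt_s n_trials
#> 1               0.793              1.155       12
#> 2               5.645              0.428        8
#> 3               0.934              1.134       12
#> 4               1.691              1.026        8
```

With the 20° residual field alone (PFL), the 30° pedestrians are detected on
only a quarter of trials in this battery — and only very late (mean
detection RT 5.6 s), when the bearing span finally looms into the central
field. Adding the prism islands (PFL+PR) restores peripheral detection and
cuts the detection RT by about 4 s, while central-field performance is
untouched. The prism-expanded island itself:

```r
island_extent(goggle_spec(), prism_spec())
#>   inner_deg outer_deg tir_from_deg
#> 1      10.8      40.2         40.2
```

so a pedestrian at 30° bearing falls comfortably inside the expanded field.
`run_selftest()` prints the worked-example quantities and the closest
distances of the near-miss conditions under both supported path-crossing
conventions, flagging where they disagree.

A thin command-line interface over the same functions lives at
`inst/scripts/prismwalk.R` (subcommands `generate-battery`, `prism-field`,
`compute-cues`, `simulate-observer`, `analyze`, `selftest`).

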