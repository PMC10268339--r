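# batmotus

Fall migration, over-water flight, and site-residency activity of coastal
migratory bats from automated radio telemetry (Motus-style) detections.

Small VHF "nanotags" glued to bats are logged — with timestamps and signal
strengths — whenever the animal passes within range (~12 km) of fixed
receiver towers. For a fall-tagged coastal cohort, this package turns those
detection tables into three analyses:

1. **Movement classification.** After a cleaning cascade (reception runs
   ≤ 3 discarded, towers > 1,000 km from both the release point and
   neighbouring detections discarded, steady-signal tag-drop segments ≥ 7
   days trimmed), each bat is classed as *site resident* (local detections
   < 12 km from release spanning > 1 night), *migrant* (a > 50 km
   tower-to-tower displacement with no return near its origin), or
   *long-distance return* (the excursion exists but the bat is later
   detected back near its origin). The cohort summary reports counts, the
   circular mean and range of migration bearings, and the mean and 5/95%
   quantiles of minimum residency times.

2. **Over-water flight selection.** Same-night detections on opposite
   shores of a labelled bay are crossing events, timed at the
   departure–arrival midpoint rounded to the whole hour. Each used hour is
   contrasted with 10× randomly sampled available hours within 40 days of
   release in a use–availability design: a logistic regression with a
   per-tag random intercept,

   logit P(use) = β₀ + β·x + b_tag,  b_tag ~ N(0, σ²),

   fitted by adaptive Gauss–Hermite quadrature (15 nodes). Covariates x
   are hours since sunset plus ten atmospheric variables (wind speed,
   temperature, precipitation, visibility, pressure, zonal/meridional wind
   components, 1-h wind and temperature changes, 24-h nightly pressure
   change). All 2¹⁰ = 1,024 additive subsets (hours-since-sunset held in
   every model) are ranked by AICc; models within 2 ΔAICc compete, and the
   top model yields marginal-effect curves with 95% delta-method
   intervals.

3. **Activity states of residents.** For bats resident > 20 days without
   gaps > 2 days, hourly SDs of antenna-scaled signal strength form an
   activity series (flight churns the signal; rest does not). A per-bat
   two-state Gaussian HMM whose transition probabilities depend on
   sine/cosine of hours since sunset —

   P(next = active | state i) = logit⁻¹(α_i + β_sin,i sin + β_cos,i cos)

   — is fitted by EM (forward–backward, weighted-logistic M-step, seeded
   restarts) and decoded by Viterbi; night-hour states are regressed on
   date, hours since sunset, wind speed, and temperature.

A seeded synthetic-data generator (`simulate_scenario()`) emulates the
study: towers on both shores of two bays plus a migration-corridor fan,
hourly coastal weather with diurnal and frontal structure, and four bat
archetypes (resident / migrant / bay-crosser / long-distance-returner)
with ground-truth labels — so the whole pipeline is testable without any
field download.

## Worked example

```r
library(batmotus)
out <- run_pipeline(scenario_config(seed = 1), out_dir = "results")
```

which logs, for the default synthetic cohort of 36 tagged bats
(equivalently, `Rscript analysis/05_report.R --seed 1`):

```
Cohort: 36 tagged, 36 detected, 10 migrants (bearing 235 deg), 36 residents (mean 16.8 d)
```

i.e. every simulated bat was detected; the ten migrant-archetype bats were
all recovered as migrants with a circular-mean bearing near the generator's
230° heading; every bat — including the migrants before they departed —
met the residency definition (local detections across more than one
night), and the mean minimum residency (~17 days) reflects the simulated
15–30 day tag lives. `results/` then holds the cleaned
detections, per-bat behavior table, cohort JSON, crossing events, the
429-row use–availability table, the 1,024-row AICc model ranking,
marginal-effect curves, per-bat activity series, HMM fits, decoded states,
and trend slopes, plus a manifest auditing each filter's record counts.

The same stages can be run one at a time with printed narrative:

```sh
Rscript analysis/01_simulate.R      --seed 1
Rscript analysis/02_clean_classify.R --seed 1
Rscript analysis/03_overwater_rsf.R  --seed 1   # ~3 min: 1,024 model fits
Rscript analysis/04_activity_hmm.R   --seed 1
Rscript analysis/05_report.R         --seed 1   # figures under results/figures/
```

## Package layout

- `R/` — geodesy/solar utilities, CSV I/O, cleaning filters, the
  synthetic-data generator, movement classification, crossing detection
  and the use–availability table, the quadrature mixed logit + AICc
  dredge + marginal effects, and the covariate-transition HMM.
- `analysis/` — numbered narrative drivers for the five stages.
- `tests/testthat/` — unit and property tests with independent oracles
  (almanac solar position, exhaustive HMM path enumeration, IRLS/glmer
  cross-checks) and the statistical acceptance suite.
- `vignettes/telemetry-pipeline.Rmd` — the methods account: model
  assumptions, parameter meanings and defaults, what the simulator does
  and does not emulate, numerical choices, and limitations.
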