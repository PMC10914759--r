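# leap

Simulation and analysis of an 18-sensor serum protease-activity panel
(Lung Enzyme Activity Profile) for lung-cancer detection.

Activity-based biosensors release a fluorescent peptide-TCPP fragment when
serum proteases cleave their tether; across a panel of 18 such sensors
read at six timepoints, overall activity is slightly *decreased* in lung
cancer (on average ~5.4%, with seven sensors decreased 7.7–12.3%). This
package is for biostatisticians and method developers who want a fully
reproducible desk-scale model of that analysis — every stage from plate
reads to classifier operating points runs on synthetic data with the
cohort's statistical structure, so the machinery is testable end to end
without any patient data.

It provides:

* **Synthetic data** — quota-sampled donor cohorts (450 donors, 132 lung
  cancer, 150 assayed in triplicate for 750 assays) and plate-read
  fluorescence with per-plate BM19 standard-dilution series, a shared
  lognormal donor effect, 6% assay CV, and planted per-sensor activity
  decreases.
* **Quantitation** — per-plate OLS standard curves (QC at r² ≥ 0.999),
  conversion to ng/ml, censoring below the 2.98 ng/ml LLOQ, and the
  750 × 108 `sensor_time` feature matrix.
* **Cohort statistics** — the percent-difference effect statistic,
  per-feature pooled-variance t tests, two-sample Hotelling's T²,
  Clopper–Pearson intervals, classification metrics, and triplicate
  precision.
* **An evolutionary classifier** — linear genetic programs (48-function
  protected instruction set, compiled execution) evolved on islands with
  tournament selection, mutation/recombination and toroidal migration;
  Selection-set ranking by accuracy × reliability; a 95-member voting
  committee with five biased operating points (Spec Max → Sens Max); and
  ablation-based sensor impact ranking.
* **A screening-triage model** — deterministic expected-value comparison
  of LDCT-only screening with blood-test-triaged LDCT in a 100,000-person
  at-risk population.

## Worked example

```r
library(leap)

report <- run_pipeline(seed = 1)
print(report)
```

```
LEAP pipeline report
  cohort: 450 donors (132 lung cancer), 750 assays
  features: 108; intra-assay CV 6.0%
  mean percent decrease 4.4% (designated sensors 8.5%); 39% of features p<=0.01
  Test spec_max  sensitivity  61%  specificity  99%
  Test spec_bias sensitivity  82%  specificity  96%
  Test ensemble  sensitivity  89%  specificity  87%
  Test sens_bias sensitivity  97%  specificity  70%
  Test sens_max  sensitivity  99%  specificity  52%
  Test triplicate precision: 61%
  triage: 30 vs 520 detected (17-fold)
```

Reading this: the simulated cohort reproduces the study design (450/132
donors, 750 assays, 108 features); the quantitation recovers the
configured 6% intra-assay CV; the panel-wide and designated-sensor
activity decreases estimate the planted 5.4% and 9.5% effects (4.4% and
8.5% on this seed — single-cohort estimates carry a couple of percentage
points of Monte-Carlo noise from the shared donor effect); the evolved
committee's operating points trade sensitivity against specificity
monotonically, with the central Ensemble point at 0.88 balanced accuracy
on held-out Test assays for this seed; 61% of triplicate Test donors
receive three fully concordant calls (borderline vote fractions flip
under replicate noise); and the triage arithmetic projects 30 cancers
detected under LDCT-only screening versus 520 with a blood-test-triaged
program — a 17-fold increase.

Individual stages are available as plain functions (`generate_cohort()`,
`generate_plate_reads()`, `build_feature_matrix()`, `timepoint_tests()`,
`hotelling_t2()`, `split_data()`, `evolve()`, `ensemble_predict()`,
`relative_impact()`, `simulate_leap_triage()`, …); see the methods
vignette (`vignettes/leap-methods.Rmd`) for the model and the reasoning
behind the defaults.

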