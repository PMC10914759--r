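---
title: "Methods: simulating and classifying a serum protease-activity panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying a serum protease-activity panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Protease activity in serum carries a diffuse signature of lung cancer: a
panel of 18 graphene-quenched peptide-TCPP biosensors releases fluorescent
peptide when cleaved by active proteases, and activity is slightly but
systematically *decreased* in cancer sera across most of the panel. The
`leap` package provides a complete, reproducible desk-scale model of this
analysis: a synthetic-data generator with the cohort's statistical
structure, fluorescence-to-concentration quantitation, the cohort
statistics, an island-model linear-genetic-programming (LGP) classifier
with biased ensemble operating points, and a deterministic screening-triage
projection.

Everything is driven by explicit configuration objects and seeds, so every
number the package produces is regenerable from a configuration plus a
seed.

## The synthetic-data generator

`generate_cohort()` quota-samples donor demographics: category counts are
fixed by largest-remainder rounding of the configured probabilities, not
drawn independently per donor. A generated default cohort therefore *is*
the study design — 450 donors, 132 with lung cancer, 84/235/131 by site,
150 donors assayed in triplicate (750 assays) with the triplicate subset
mirroring the site-by-diagnosis composition — which keeps the package's
design-count tests exact rather than probabilistic.

`signal_model()` fixes the measurement model. Released concentration for
sensor $s$ at time $t$ follows a saturating kinetic
$$ c_s(t) = \frac{A_s\,t}{t + K_s} \cdot \frac{1}{1 + \delta_s\,y} \cdot e^{u}, $$
where $y$ indicates lung cancer, $u \sim N(0, \sigma_d^2)$ is a donor-level
random effect shared across the panel, and $\delta_s$ is the planted
fractional decrease. Choices worth stating:

* **Saturating two-parameter form.** The assay's kinetics are only known to
  increase over the 10–60 min window; `A * t / (t + K)` is the simplest
  bounded monotone form. Per-sensor amplitudes (150–600 ng/ml) and
  half-times (8–35 min) are free parameters of the simulator; absolute
  signal ranges are not identified by any quantity the package tests.
* **Effect parameterised on the percent-difference scale.** The study's
  effect statistic is $100\,(\bar{x}_{\text{ctrl}} -
  \bar{x}_{\text{case}})/\bar{x}_{\text{case}}$. Dividing the cancer mean
  by $1 + \delta$ makes that statistic unbiased for $100\,\delta$, so a
  configured $\delta$ is exactly the percent decrease the downstream
  estimator recovers. Seven designated sensors (BM01, BM10, BM13, BM14,
  BM17, BM18, BM19) carry decreases of 7.7–12.3% averaging 9.5%; the other
  eleven share a small decrease chosen so the panel-wide mean is 5.4%.
* **Shared donor effect.** A single lognormal donor effect
  ($\sigma_d = 0.2$) multiplies every sensor, inducing the strong
  inter-sensor correlation real panels show. It is also what makes single
  features weak classifiers (the donor effect dwarfs the disease effect)
  while cross-sensor contrasts, which cancel it, are strong — the
  structure the evolutionary classifier must discover.
* **Noise.** Sample wells receive multiplicative assay noise (CV 6%) and
  additive 1-RFU read noise on the fluorescence scale
  (`intercept + slope * conc`). Standard wells are dilutions of purified
  peptide-TCPP, not enzymatic reactions, so they receive read noise only;
  this reproduces the R² > 0.9999 per-plate QC regime.
* **What is not emulated:** temperature dependence, plate-position
  effects, lyophilization stability, serum-vs-plasma differences, or any
  real kinetic heterogeneity across donors. Passing tests demonstrate that
  the analysis machinery recovers known structure; they say nothing about
  performance on real sera.

## Quantitation

Each plate carries a six-point two-fold BM19 peptide-TCPP dilution series
(800 → 25 ng/ml) fitted by ordinary least squares
(`fit_standard_curve()`); curves with $r^2$ below 0.999 are flagged with a
warning rather than an error, since a failing plate is a QC decision, not
a crash. Sample fluorescence is inverted through the plate's own curve and
floored at zero.

Two censoring conventions needed fixing where the protocol is ambiguous:
duplicate wells of a sensor are **averaged on the concentration scale
before** censoring (censor-then-average would bias near-LLOQ means
downward asymmetrically), and a value exactly at the LLOQ (2.98 ng/ml) is
**kept** — "below" is read strictly. The feature matrix has one row per
assay (replicates are separate rows) and 108 columns `BM01_10` …
`BM19_60`, sensor-major then time.

`intra_assay_cv()` reports the triplicate CV averaged over features then
donors. With $n = 3$ replicates the sample SD is biased low
($E[s] = c_4(3)\,\sigma \approx 0.886\,\sigma$), which would make a 6%
assay read out as ~5.3%; the estimator therefore divides by $c_4(n)$ by
default so the reported CV is unbiased for the underlying assay CV.

## Cohort statistics

Per-feature group comparisons use the pooled-variance Student's *t*
(Welch optional), two-sided, with no multiplicity correction by default
(the raw $p \le 0.01$ reporting convention; Benjamini–Hochberg available).
The multivariate comparison of the designated sensor-time features is a
two-sample Hotelling's $T^2$ with the standard F conversion, implemented
directly (base R has none) and tested against a brute-force matrix oracle
and its 1-D reduction to the squared pooled *t*. All binomial proportions
carry Clopper–Pearson intervals from Beta quantiles. Assay precision is
defined as *full triplicate concordance* — the percent of triplicate
donors whose three calls agree — with a per-call majority-agreement
variant available, since repeat-classification precision has no single
canonical definition.

## The evolutionary classifier

Programs are linear register machines: a sequence of instructions, each
applying one of a 48-function palette (protected arithmetic, comparisons,
trigonometric/hyperbolic, sigmoid/relu, kernels, ternary forms) to
registers, features, or private constants, writing a register; register 1
after the last instruction is the score, and score > 0 calls cancer. All
functions are total — guarded division, clamped exponentials, |x| under
roots and logs — so execution cannot produce NaN or Inf. The register
machine is compiled (Rcpp); everything else is R.

Donors are split into stratified Training/Selection/Test thirds
(`split_data()`), stratifying by label, site, and stage by default; all
assays of a donor share one subset, so replicates can never leak between
fitting and evaluation. Features are z-standardised on Training-set
statistics (stored in the fitted ensemble) so that score thresholds near
zero are meaningful and constants have a natural scale.

Fitness is balanced accuracy on the Training subset. Each generation,
every island pairs its programs at random; the fitter of each pair
survives (ties to the shorter program, then random) and reproduces —
a mutated copy, or with probability 0.7 crossover with another survivor —
until the island is back to size. After the Selection step ranks the pool
by `acc_sel * (1 - |acc_train - acc_sel|)`, the top distinct programs form
a 95-member voting committee whose five operating points are vote-fraction
thresholds 0.7/0.6/0.5/0.4/0.3 from specificity-maximising to
sensitivity-maximising; the ladder construction makes sensitivity
monotonically non-decreasing (and specificity non-increasing) across
operating points by design.

The engine's search parameters were chosen by experimentation on the
generator's own planted-signal task, and several are load-bearing enough
to justify:

* **Few edits per offspring.** The planted signal is a dense contrast —
  sums and differences over many standardized features. Hill-climbing such
  chains requires offspring close to their parents, so the per-instruction
  mutation rate is low (0.05, one or two edits per offspring), with an
  instruction-set biased toward arithmetic/aggregation functions and a
  "function swap within arity" mutation (add ↔ sub) as the smallest
  semantic step.
* **Chain-biased generation.** Uniformly random register code is dominated
  by structural introns. A fraction (0.6) of generated instructions are
  forced to extend the output-register chain (write register 1, read
  register 1), the standard effective-code remedy in linear GP.
* **Independent lineages, cross-island committees.** With early migration
  one lineage takes over every island and the "committee" is a set of
  near-clones whose votes cannot decorrelate. The default therefore runs
  16 islands of 124 essentially independently (warm-up 240 of 250
  generations; the top 5% migrate on the ring every 10 generations after
  that) and the committee drafts members round-robin across islands in
  rank order. Migration without replacement on a unidirectional ring
  conserves every island's size exactly, since each island emits and
  receives the same number of programs; the global best can move island
  but never disappears, so best fitness is non-decreasing.
* **Island bagging.** Each island scores fitness on its own bootstrap
  resample of the training rows, fixed for the whole run (so fitness stays
  cached and comparable within an island). Lineages then overfit
  *different* resamples and their committee votes decorrelate where it
  matters; without this, pushing the search deeper demonstrably lowered
  held-out accuracy by fitting shared training noise harder. The
  Selection-set ranking always uses the real, un-resampled data.
* **A heterogeneous island portfolio.** The length bounds are vectors
  recycled across islands — half the islands evolve short programs
  (16–48 instructions), half long ones (32–80). Which class generalises
  better varies with the data realisation; the committee simply drafts
  from both.

At these desk-scale settings one training run evaluates roughly 250,000
programs (about a minute on one CPU). On default synthetic cohorts the
central operating point typically reaches Test-set balanced accuracies of
0.78–0.92, above 0.80 in the large majority of seeds — the package's
planted-signal acceptance property — which is the appropriate expectation
for the simulated effect sizes, not a claim about real sera. For
reference, the oracle equal-weight contrast between the high- and
low-decrease sensor groups (which no fitted method can be expected to
beat by much) sits near 0.87 on the same data.

Sensor importance (`relative_impact()`) combines how often the committee
references each sensor with the drop in committee balanced accuracy when
that sensor's features are ablated to their training means, each term
normalised to its panel average; 100% marks an average contributor and the
panel mean is 100% by construction. When no ablation moves the accuracy,
the ablation term is dropped with a warning rather than manufacturing a
ranking from zeros.

## The screening-triage model

`simulate_ldct_only()` and `simulate_leap_triage()` are deterministic
expected-value arithmetic on a 100,000-person at-risk population
(prevalence 0.91%): LDCT alone at its observed 3.9% compliance and
Lung-RADS operating point (84.9% sensitivity / 87.2% specificity), versus
a 75%-compliant blood test (90% / 82%) whose positives proceed to LDCT.
Detected counts are reported at the printed precision of such projections
(nearest integer for the LDCT-only scenario, nearest ten for the triaged
one), with raw values always retained; the fold increase uses the raw
values. Clopper–Pearson intervals for the PPVs treat the rounded expected
counts as binomial counts. Recomputing the triaged PPV from these printed
parameters gives ≈ 23.3%, slightly below the 23.7% sometimes quoted for
this scenario; the package reports its own computed value.

## Problem sizes, tolerances, degenerate inputs

Default problem sizes are the study's: 450 donors, 750 assays, 108
features, thirds of 150 donors. The statistical property checks the test
suite runs use 10,000-draw coverage simulations and ~5,000 simulated null
features; the planted-signal acceptance property uses ten independent
cohort/training seeds. Exactness tolerances are 1e-9 to 1e-12 for
algebraic identities (round-trips, Hotelling oracles) and distributional
bounds elsewhere.

Degenerate inputs are contracts, not crashes: a standard series with
fewer than three levels or zero variance is an error; a flat series fits
with $r^2 = 0$ and a QC flag; an assay missing a sensor-time read raises
a completeness error naming the gap; classification metrics with empty
denominators (no positive calls, an absent stage) report `NA`, never 0;
triplicate precision refuses groups that are not exactly three.

## Known limitations

The generator's effects are time-constant per sensor, so the "best
timepoint" structure of real kinetics is flattened; the classifier and
statistics see a panel whose informative sensors are informative at every
timepoint. Real-data properties — batch effects between sites, LDCT
follow-up bias, inflammatory comorbidity overlap — are out of scope, as is
any reproduction of clinical performance figures, which depend on the
study sera. The evolutionary engine is desk-scale by design; it evaluates a few
hundred thousand candidate programs per run, with no attempt at the
industrial evaluation volumes such platforms can reach.
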