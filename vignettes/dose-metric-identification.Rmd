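---
title: "Dose-response modelling and dose-metric identification for nanoparticle reporter screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-response modelling and dose-metric identification for nanoparticle reporter screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanotoxtracker)
```

## The model

A ToxTracker screen measures, per well, the percentage of intact cells
relative to vehicle control (viability) and the mean GFP fluorescence of a
reporter line. The package models viability with a Hill curve of fixed unit
slope anchored at 100% at dose zero,

$$V(C) = \frac{100}{1 + C/\mathrm{LD50}},$$

which has one free parameter. Fixing the slope at 1 makes the curve
invertible in closed form: the dose producing an $x$% decrease in viability
is $\mathrm{ED}_x = \mathrm{LD50}\cdot x/(100-x)$, so the LD50 is
$\mathrm{ED}_{50}$ and the usual equi-response level for dose-metric work,
a 20% viability decrease, sits at exactly LD50/4. Equi-response doses are
therefore obtained by analytic inversion of the fitted curve rather than by
a separate benchmark-dose model-averaging step; this is a deliberate
simplification that keeps the equi-response dose an exact function of the
one fitted parameter.

The fit minimises ordinary least squares on viability percentages over
$\log(\mathrm{LD50})$, which enforces positivity and conditions the 1-D
search. Replicates are not weighted by their SEM — the screens this targets
report only mean ± SEM over at least three experiments, with no error model
to justify weights. Vehicle-control rows are excluded from the fit since
the model is anchored at 100% by construction.

**Censoring.** Many particles never reach 50% cytotoxicity in the tested
range (capped at 100 µg/mL). Extrapolating an LD50 beyond the data is not
meaningful, so a fit is reported as censored — "LD50 > max dose" — when the
mean viability at the top dose exceeds 75%, or when the fitted LD50 exceeds
twice the top tested dose. Censored fits refuse to produce equi-response
doses: the response level was never observed.

## Particle dosimetry

All particles are treated as monodisperse spheres at their nominal
diameter. With diameter $d$ (nm, converted internally to cm), density
$\rho$ (g/cm³) and a mass dose $C$ (µg/mL of whole particle),

$$N = \frac{C \times 10^{-6}}{\rho\,\frac{\pi}{6}d^3} \;\text{particles/mL},
\qquad
\mathrm{SA} = N\pi d^2 = \frac{6\,C \times 10^{-6}}{\rho\, d}\;\text{cm}^2/\text{mL}.$$

Particles dosed by the mass of one element (quantum dots dosed as µg Cd/mL)
are first converted to whole-particle mass by dividing by the element mass
fraction $f$; for stoichiometric CdTe,
$f = 112.414/(112.414+127.60) = 0.4684$ from standard atomic masses. The
CdTe density (5.85 g/cm³, bulk value) and $f$ are stated assumptions for
the worked example rather than measured quantities — both cancel out of the
dose-metric slope and shift only the intercept, which the test suite checks
explicitly. Agglomeration, sedimentation and delivered-dose kinetics are
out of scope: the dosimetry describes administered, not delivered, dose.

## Dose-metric identification

For a size series at equi-response doses, convert each dose to particles
per mL and regress

$$\log_{10} N = m \log_{10} d + q$$

by unweighted OLS. If a single physical metric governs toxicity the points
are collinear with a diagnostic slope: fixed total **surface area** gives
$N \propto d^{-2}$ ($m=-2$), fixed total **volume** (equivalently mass, at
one density) gives $m=-3$, and fixed **particle number** gives $m=0$. When
no canonical slope fits, the line still defines an intermediate metric
$N\,d^{-m} = 10^q$, constant across sizes.

**Classification rule.** The fitted slope is assigned to the canonical
metric strictly nearest to it, provided the distance is within a tolerance
(default 0.75). The canonical slopes are 1 apart at minimum, so 0.75 admits
every slope that is clearly nearest one metric (a slope of −1.44 is a
surface call) while rejecting nothing that the nearest-neighbour rule would
accept in the gaps' midzones; slopes exactly equidistant between two
canonical values — detected up to 1e-9 to absorb floating-point error in
the regression — classify as intermediate rather than being broken
arbitrarily. The tolerance is exposed as a parameter, since no published
decision rule pins it down.

The CdTe worked example ships with the package:

```{r}
qd <- cdte_qd_dose_metric()
qd$fit
qd$call
```

A slope of −1.44 with $r^2 = 0.98$: surface area is the metric, meaning
equal administered particle surface produces equal cytotoxicity regardless
of dot size.

## Reporter activation calls

Fold induction is mean autofluorescence-corrected GFP at a dose divided by
the corrected vehicle-control mean (replicates are averaged before the
ratio; autofluorescence is subtracted per well, before averaging — the
alternative order differs only for unbalanced replicates and is not
observable in mean-level data). Correction floors at zero and warns, since
particle fluorescence exceeding the reporter signal usually indicates a
saturated channel.

Verdicts per (particle, reporter): doses at viability ≤ 25% are excluded
(activation there is confounded with dying cells); among the rest the
maximum fold decides — **positive** strictly above 2, **weak positive** in
(1.5, 2], else **negative**. A fold of exactly 2.0 is assigned to the weak
band: the conventional inequalities (">1.5 but <2" and ">2") leave 2.0
unassigned, and closing the weak band on the right keeps the bands
exhaustive without promoting a boundary value to positive. If every dose is
gated out the cell is **uninterpretable**. No statistical test is applied
to folds; the decision rule is threshold-only, matching validated practice
for this assay.

**Dose selection.** The reporter ladder is five doses in two-fold steps
whose top dose is the smallest tested dose causing 50–75% cytotoxicity;
particles showing no cytotoxicity are tested up to 100 µg/mL. Two edge
cases need a rule the convention does not state: when cytotoxicity jumps
over the 50–75% band between consecutive tested doses, the package takes
the largest dose still under 50% cytotoxicity (the most informative dose
that is not overtly toxic); when even the lowest dose exceeds 75%
cytotoxicity, it errors and advises re-screening lower.

## The synthetic-data generator

`generate_screen()` emulates well-level flow-cytometry summaries — never
event-level data. Per (particle, reporter) cell it draws, for each dose and
replicate,

- viability: the exact Hill value times multiplicative lognormal noise,
  truncated to [0, 100] (it is a percentage of control);
- GFP: a control level times a saturating fold curve
  $1 + (F_{\max}-1)\,C/(C+D_{1/2})$ times independent lognormal noise, plus
  deterministic particle autofluorescence proportional to dose.

The noise is lognormal with mean exactly 1 (meanlog $=-\sigma^2/2$) because
the readouts are strictly positive ratios; published screens report only
mean ± SEM, so the distribution and its magnitude are modelling choices:
the default CV of 0.10 and $n=3$ replicates reflect the typical run-to-run
spread of a well-behaved reporter screen with three independent
experiments, and the control GFP level of 200 AU is an arbitrary scale that
cancels in every fold. One integer seed drives the whole table through a
counter-based substream per (particle, reporter), so regeneration is
byte-identical and independent of row order. The generator applies the same
dose-selection rule as the analysis, from each cell's noise-free viability
curve, so simulated ladders sit in the realistic 50–75% window.

What passing tests on these data do **not** show: robustness to
polydispersity, particle dissolution, dose-dependent agglomeration,
non-unit Hill slopes, or heteroscedastic noise — none of which the
generator emulates. They show that the estimators recover the truth when
the model's own assumptions hold, and at what noise level the dose-metric
call stays reliable.

## Numerical choices

- Hill fitting: golden-section/parabolic search (`optimize`) over
  log(LD50) in a bracket eight decades beyond the tested doses, polished by
  root-finding on the analytic SSE gradient; noise-free data then recover
  the generating LD50 to ~1e-12 relative.
- $r^2$ of a perfectly flat, perfectly fitted log-log line (pure
  number-metric series) is defined as 1, avoiding the 0/0 of a zero total
  sum of squares.
- Degenerate inputs fail loudly with typed conditions: fewer than 3 doses
  or sizes (`ntx_insufficient_data_error`), all-zero viability or
  non-positive controls (`ntx_degenerate_data_error`), schema and join
  problems (`ntx_schema_error`), invalid parameters
  (`ntx_validation_error`).

## Problem sizes used in the tests

Simulation-based checks use 200 replicate runs: LD50 recovery at CV 10%
with $n=3$ (median absolute relative error under 15%), dose-metric recovery
for each canonical metric at CV 10% over five sizes spanning a factor of 25
(at least 95% correct calls), and reporter-call accuracy on panels with
known $F_{\max}$. These sizes give stable Monte-Carlo estimates of the
pass rates while keeping the whole suite around ten seconds.

## Known limitations

- The unit-slope Hill model is an assumption, not a fit diagnostic; real
  steepness differences bias equi-response doses derived from it.
- Dosimetry is administered-dose only, for monodisperse spheres at nominal
  diameter.
- The dose-metric regression is unweighted; equi-response doses from
  censored or barely-cytotoxic fits are excluded rather than down-weighted.
- The classifier's tolerance (0.75) is a convention, not an inference; with
  noisy slopes near a gap midpoint the intermediate call is the honest
  output.
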