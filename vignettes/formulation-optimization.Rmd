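---
title: "Methods: CCD/RSM optimization and delivery statistics for proniosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CCD/RSM optimization and delivery statistics for proniosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pronioptim)
```

This vignette documents the statistical methods the package implements,
the choices made where the methodology left room, and what the test suite
does and does not establish. The running example is the published
formulation study whose printed tables ship as fixtures: three factors
(finasteride concentration, 1.5–5.0 mM; total lipid, 10–30 mM; cholesterol
as % of total lipid, 30–50%) optimized against vesicle size (minimize),
entrapment efficiency and drug loading (both maximize).

## The design

A rotatable central composite design in `k` factors consists of the `2^k`
factorial corners at coded ±1, `2k` axial points at ±α on one axis, and
replicated center points. Rotatability — prediction variance depending only
on the distance from the center — requires α = (2^k)^(1/4); at `k = 3`,
α = 1.6818, which is why the printed axial levels are 0.31/6.19 mM
finasteride, 3.18/36.82 mM lipid and 23.18/56.82% cholesterol around
centers 3.25/20/40 with half-widths 1.75/10/10.

```{r}
fac <- flp_factors()
round(coded_to_actual(c(-rotatable_alpha(3), rotatable_alpha(3)), fac[[1]]), 2)
```

Choices here:

* **Run order.** The bench study randomized its run sheet; the generator
  emits a deterministic canonical order (factorial in binary counting
  order, axial by factor, then centers) because reproducible fixtures
  matter more than randomization in a reanalysis; `shuffle_seed` restores a
  seeded permutation when randomization is wanted.
* **Precision.** Coded levels are stored at full precision (α as
  `(2^k)^(1/4)`, never 1.682 rounded); comparisons against printed tables
  round to 2 dp. The source tables themselves disagree at the last digit
  for one axial point (cholesterol +α printed as 56.81 in one table and
  56.82 in another — both are accepted where that level is checked;
  full-precision value 56.8179).
* **Units.** The lipid factor is labelled `%w/w` in one printed table and
  mM elsewhere in the same article; the fixture records mM, the label used
  by the design matrix and the running text.

## Response-surface regression

Each response is fitted with the full 10-term quadratic by OLS. The
diagnostics follow the conventions of commercial RSM software, since the
study's printed diagnostic table uses that software's column names:

* `R² = 1 − SSE/SST` (SST about the mean), `adj R² = 1 − (1−R²)(n−1)/(n−p)`;
* `PRESS = Σ (eᵢ/(1−hᵢᵢ))²` via the hat-matrix leave-one-out shortcut, and
  `predicted R² = 1 − PRESS/SST` (the shortcut is verified in the tests
  against explicit n-fold refitting);
* adequate precision — the signal-to-noise ratio
  `(max ŷ − min ŷ)/sqrt(p·MSE/n)` over the design points, adequate above 4;
* the overall F test with `(p−1, n−p)` degrees of freedom and two-sided
  per-term t tests.

Fits can be expressed in coded or actual units. All the diagnostics above
are invariant to that linear reparameterization (verified to 1e−10); only
the coefficients change. The package therefore reports diagnostics from the
coded fit and prints regression equations from the actual-units fit, which
is how formulation papers present them. Run means (one value per run) are
fitted, not the underlying triplicates: with equal replication the
coefficients coincide, and the printed design matrix only carries means.

Degenerate inputs are refused loudly: rank-deficient model matrices
(`singular design`), constant responses (`SST = 0`), and leverages at 1
(PRESS undefined). When the residual variance is zero up to rounding
(`SSE ≤ 1e−12·SST`, e.g. noiseless synthetic data), the t/F statistics are
reported as `NaN` sentinels and adequate precision as `Inf` rather than as
meaningless large numbers.

The full quadratic is always fitted by default. The study printed visibly
truncated equations for two responses (one omits an interaction, another
omits two terms); a reduced fit is available through the `terms` argument
but is deliberately not the default.

### A note on the packaged design matrix

The printed 20-run design matrix does **not** reproduce the diagnostics
printed alongside it. Honest OLS on the printed run means gives R² ≈ 0.96
for vesicle size (0.9987 was printed), predicted R² ≈ 0.58 for entrapment
(0.8745 printed), and an actual-units finasteride coefficient of +16.1
(−8.98 printed). The inconsistency is in the published tables themselves:
evaluating the study's own printed regression equations at the printed
factor settings reproduces the printed responses with R² of only
0.84/0.40/0.44, so the printed responses cannot be the data those equations
were fitted to (a plausible mechanism is a row-order mismatch between the
randomized run sheet and the sorted factor columns, which no reanalysis can
undo). The fixture preserves the print verbatim — including the duplicated
center rows — and the corresponding end-to-end assertions are left failing
rather than adjusted, as a permanent record. Notably, the desirability
optimum computed from the honest fits still lands exactly on the study's
validated optimum, so the inconsistency does not propagate to the
pipeline's conclusion.

## Desirability optimization

Each predicted response maps to an individual desirability by the linear
Derringer ramp between acceptability bounds (`maximize`: 0 at or below
`y_min`, 1 at or above `y_max`; `minimize` mirrored — the published
methodology prints only the maximize form, but declares size "minimize",
so the mirror is required). The overall objective is the geometric mean,
which annihilates whenever any individual desirability is zero. Choices:

* **Bounds** default to each response's observed min/max over the design
  runs (size 220.20–346.00 nm, EE 71.95–95.44%, DL 1.20–43.05%),
  overridable per goal; no importance weights or shape exponents (none were
  stated).
* **Search region** is the factorial cube `[−1, +1]^k`, not the axial
  sphere: predictions beyond the cube extrapolate, and the validated
  optimum sits on cube faces.
* **Algorithm**: deterministic 0.02-step grid (ties broken by first hit in
  canonical grid order) plus a Nelder–Mead polish clamped to the box;
  agreement with a seeded 1000-start random multistart is part of the test
  suite. If D is zero everywhere, the optimizer warns and reports the grid
  point maximizing the worst individual desirability.

## Release kinetics

Receptor/medium sampling with aliquot replacement removes drug with every
sample; the cumulative mass at sample `n` is reconstructed as
`Qₙ = Cₙ·V + Vₛ·Σᵢ<ₙCᵢ`. No correction formula was printed in the study;
this is the only mass-consistent rule for replace-with-fresh-medium
sampling, and the package's sampling simulator (below) inverts it to
machine precision.

Four empirical laws are fitted to `CR(t)` with `CR` as a fraction and `t`
in hours: zero-order and Higuchi are linear through the origin and solved
in closed form; first-order and Korsmeyer–Peppas are initialized by
log-linear (−ln(1−CR) on t) and log-log regression respectively and
refined by Levenberg–Marquardt. `t = 0` points participate in the
zero/first-order fits but are excluded from the log-log initialization.
Korsmeyer–Peppas is fitted on all points by default (no ≤60%-released
truncation rule was stated); fixing `n = 0.5` via `fix_n` reproduces the
Higuchi fit exactly, which the tests assert to 1e−8. Models are ranked by
R², ties broken toward fewer parameters.

The study's own fitted rate constants are *not* reproduction targets: its
raw time-series exists only as a figure, and its printed "×10⁻²" scaling
for the first-order constant is internally inconsistent with the narrative
(complete release within 12 h implies k₁ ≈ 0.4–0.6 h⁻¹, not 0.004). The
kinetic acceptance checks are therefore property-based, on synthetic curves
shaped to the narrative: a free-drug curve complete by 12 h and a vesicle
curve at 80% by 4 h / 98% by 48 h, both of which the first-order model must
win with R² ≥ 0.99.

## Delivery and safety metrics

Entrapment efficiency and drug loading are the printed formulas applied
literally; drug and lipid must share a unit for DL. Franz-cell permeation
uses the same replacement correction normalized per diffusion area
(defaults: 0.5 mL aliquots, 3.5 cm² skin; the receptor volume has no
default — it was not stated, and silently assuming one would bias every
number downstream). Transfollicular cumulation is the timepoint-wise
difference between unblocked and follicle-blocked skin, unit-agnostic by
design since the study applied it to percentages in one place and µg/cm²
in another.

The Draize primary irritation index is not given a formula in the study;
the package uses the mean of all recorded scores,
`PII = Σ(erythema + edema)/(2T)` over the `T = 4` recorded timepoints,
because it reproduces the printed index of the positive control
(5.25/8 = 0.656, printed 0.65 — apparently truncated; the package rounds,
giving 0.66, and the checks allow ±0.01) where the classic 24–72 h-only
Draize mean does not. Class bands: <0.5 none, <2.0 slight, <5.0 moderate,
else severe — reproducing both printed labels. One printed score-grid
header reads "2 h" where the protocol text says 24 h; the fixture follows
the protocol (1, 24, 48, 72 h).

## Synthetic data: what it emulates, and what it does not

`simulate_design_responses()` draws `y = quadratic_row(x)·β + N(0, σ²)`
independently per run — a smooth second-order surface plus additive
Gaussian noise, center replicates differing only in their noise draws. The
default study emulation uses the printed actual-units size equation for β
with σ = 3 response units, the order of the printed per-run SDs (2–8 nm).
`simulate_release_sampling()` models a well-mixed medium in which each
aliquot removes drug and is replaced by fresh medium, emitting both the
observed concentrations and the ground-truth released fraction, so the
reconstruction formula can be tested as an exact inverse.

What passing tests on these generators show: the estimators recover the
parameters of data that satisfy their own assumptions, at the study's
sample sizes (20-run designs; 8-point release curves; 200-replicate
recovery studies). What they do not show: robustness to run-order effects,
non-Gaussian or heteroscedastic noise, drifts between center replicates,
membrane lag times, or sink-condition violations — none of which the
generators emulate.

## Problem sizes

All simulations are sized to the study they emulate: 20-run designs,
8-timepoint release curves, 200-seed recovery studies, a 101³-point
desirability grid. The full test suite and the reproduction script each
run in well under a minute on a single core.
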