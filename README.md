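# pronioptim

Statistical pipeline for formulation optimization of finasteride-loaded
proniosomes (FLP) — vesicular carriers for transfollicular drug delivery —
and for the in-vitro delivery statistics that follow: drug-release
kinetics, Franz-cell permeation, and dermal irritation scoring.

It re-implements, as tested R functions plus a set of numbered analysis
drivers, every computation of a published central-composite-design (CCD)
study of proniosome preparation, and ships verbatim fixtures of that
study's printed tables so the whole pipeline runs without downloads.

## What it computes

**Design of experiments.** A rotatable CCD in k factors: the 2^k factorial
cube (coded ±1), 2k axial points at ±α with α = (2^k)^(1/4) (1.682 at
k = 3), and replicated center points; coded and actual units interconvert
exactly via `actual = center + coded × half_width`.

**Response-surface regression.** Full second-order polynomial per response,

y = β₀ + Σᵢ βᵢxᵢ + Σᵢ<ⱼ βᵢⱼxᵢxⱼ + Σᵢ βᵢᵢxᵢ² + ε,

fitted by ordinary least squares with the diagnostic suite conventional in
RSM software: R², adjusted R², PRESS from the leave-one-out hat-matrix
shortcut (PRESS = Σ(eᵢ/(1−hᵢᵢ))²), predicted R² = 1 − PRESS/SST, the
adequate-precision signal-to-noise ratio (ŷ range over √(p·MSE/n), adequate
when > 4), the overall F test and per-term t tests.

**Desirability optimization.** Derringer desirability: each predicted
response maps to dᵢ ∈ [0, 1] by a linear ramp between acceptability bounds
(minimize goals mirrored), combined as D = (Πdᵢ)^(1/m), maximized over the
coded cube by a 0.02-step grid search with local polish.

**Release kinetics.** Cumulative fraction released CR = Mt/Me reconstructed
from sampled concentrations with the withdraw-and-replace mass-balance
correction Qₙ = Cₙ·V + Vₛ·Σᵢ<ₙCᵢ, then fitted with zero-order (CR = k₀t),
first-order (CR = 1 − e^(−k₁t)), Korsmeyer–Peppas (CR = k·tⁿ) and Higuchi
(CR = k_H√t) laws, ranked by R².

**Delivery and safety metrics.** Entrapment efficiency
EE% = 100·(total − free)/total; drug loading
DL% = 100·(total − free)/((total − free) + lipid); Franz-cell cumulative
permeation per area (same replacement correction); transfollicular
cumulation = full-skin − follicle-blocked cumulation; Draize primary
irritation index PII = Σ(erythema + edema)/(2T) with the conventional
none/slight/moderate/severe bands.

## Worked example

```r
library(pronioptim)

design <- flp_design()                     # packaged 20-run CCD fixture
size <- fit_quadratic(design, "size_nm")   # coded-scale quadratic fit
models <- list(size,
               fit_quadratic(design, "ee_pct"),
               fit_quadratic(design, "dl_pct"))
goals <- goals_from_ranges(design, c(size_nm = "minimize",
                                     ee_pct = "maximize",
                                     dl_pct = "maximize"))
optimize_desirability(models, goals)
```

```
Desirability optimum (overall D = 0.7649 )
  coded:  fn_mM=1.000, lipid_mM=-1.000, chol_pct=1.000
  actual: fn_mM=5.000, lipid_mM=10.000, chol_pct=50.000
  predicted: size_nm=235.09 (d=0.882), ee_pct=87.62 (d=0.667), dl_pct=33.05 (d=0.761)
```

The optimizer lands on the cube faces: 5.0 mM finasteride, 10.0 mM total
lipid, 50% cholesterol — the smallest predicted vesicles compatible with
high entrapment and loading, and the optimum the source study validated at
the bench (it reported 5.0 mM / 10.1 mM / 50.0%).

The study stages live under `analysis/` as numbered drivers
(`01_build_design.R` … `06_irritation.R`); each prints what it found and
writes its tables under `results/`.

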