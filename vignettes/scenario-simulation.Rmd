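---
title: "Methods: logistic suitability, Markov demand and CLUE-S allocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: logistic suitability, Markov demand and CLUE-S allocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lulcsim)
```

`lulcsim` reconstructs the integrated LULC scenario-simulation chain used
for subsiding coal-mining landscapes. This vignette documents the model,
its assumptions, the parameters that matter, the synthetic data the tests
run on, and the numerical choices made where the method leaves room.

## The modelling chain and its assumptions

**Suitability.** Class occurrence is modelled per class as a one-vs-rest
binary logistic regression on seven drivers: two terrain factors
(elevation in meters, Horn slope in degrees) and five accessibility
factors (Euclidean distance in meters to the nearest residential area,
mine, road, river and ditch). Drivers are standardized to zero mean and
unit variance before fitting, so coefficients are comparable across
drivers. The assumptions are the usual ones: a monotone logit-linear
response per driver, cells treated as independent observations (spatial
autocorrelation inflates confidence, which is why the package reports no
p-values), and a static driver field over the simulation horizon.

**Demand.** Class areas follow a first-order Markov chain: the share of
class *u* converting to *v* per year is constant over the horizon. The
multi-year matrix estimated from a map pair is annualized by its
eigendecomposition matrix root — the assumption that a one-year matrix
exists (embeddability) holds comfortably for the diagonal-dominant
matrices LULC change produces, and `annualize()` refuses matrices with
complex or non-positive eigenvalues rather than returning a misleading
root. Policy scenarios are expressed either as multiplicative retention
rules on off-diagonal entries (`adjust_for_scenario()`, mass returned to
the diagonal so rows stay stochastic) or by calibrating a matrix directly
to published endpoint areas (`calibrate_transition()`, used for the
packaged scenario tables, whose source analysis prints endpoints but not
matrices).

**Allocation.** The CLUE-S composition scores every cell for every
allowed class:

\[ \mathrm{TPROP}_{i,u} = P_{i,u} + \mathrm{ELAS}_u \cdot [c_i = u] + \mathrm{ITER}_u \]

where \(P_{i,u}\) is the suitability probability, \(\mathrm{ELAS}_u \in
[0,1]\) the conversion elasticity rewarding incumbency, and
\(\mathrm{ITER}_u\) a per-class balancing offset. Cells take their argmax
class; offsets are updated by the damped relative deficit
\(\mathrm{ITER}_u \leftarrow \mathrm{ITER}_u + d \cdot
(\mathrm{demand}_u - \mathrm{allocated}_u)/\mathrm{demand}_u\) until
every class matches its demand. The allocator is deliberately RNG-free.

**Validation.** Map agreement uses the uniform-chance kappa
\((P_o - P_c)/(P_p - P_c)\) with \(P_c = 1/n\) for \(n = 6\) classes —
the convention of the source analysis — rather than Cohen's
marginal-product expectation; Cohen's kappa is reported alongside under
its own name to avoid confusion. Kappa-for-quantity is pinned to the
proportion-disagreement form \(K_q = (A_q - 1/n)/(1 - 1/n)\),
\(A_q = 1 - \tfrac12\sum_u |p_u - q_u|\), since the source names the
statistic without defining it.

## Parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| cell size | m | 60 | the case study's working resolution, chosen there by a multi-scale AUC comparison (`scale_selection()` reproduces the workflow) |
| ELAS per class | – | packaged per scenario (0.5–0.9) | published calibrated values; 1 freezes a class entirely |
| allowed matrix | boolean 6×6 | all TRUE | scenario restrictions; diagonal always TRUE |
| damping `d` | – | 0.5 | halved automatically when every deficit flips sign (oscillation) |
| tolerance | ha | max(1 cell, 0.1% of class demand) | demands are quantized to whole cells, so sub-cell tolerances are unattainable |
| max_iterations | – | 2000 | comfortable: converged synthetic runs need tens of iterations |
| glm convergence | – | rel. ΔlogL < 1e-8, ≤ 100 iter | reported, with separation flagged rather than silently accepted |

## What the synthetic generator emulates — and what it does not

`generate_landscape()` produces a ~1,176 km²-at-scale stand-in (default
200×200 cells at 60 m = 14,400 ha; most tests use 100×100 for speed):

* a Gaussian-filtered DEM rescaled to a 30–60 m lake-plain range;
* roads/rivers/ditches as jittered rasterised polylines, mines as points,
  residential areas as patches; drivers derived exactly as the real
  pipeline would (distance transform, Horn slope);
* a t0 class map sampled from softmax-combined per-class logistic scores
  (guaranteeing one class per cell, while downstream fitting stays
  per-class binary, mirroring the real workflow), with class shares
  targeted at the natural-scenario proportions of the case-study demand
  table (farmland 0.220, other agricultural 0.355, construction 0.056,
  subsided 0.010, water 0.333, tidal 0.026);
* a t1 map evolved by a known row-stochastic transition matrix, with the
  most-suitable cells converting first.

Two texture knobs make the maps patch-structured instead of
salt-and-pepper: smooth per-class random fields added to the scores
(`patch_sigma = 4` cells, `patch_strength = 2.5` logits) and one 3×3
majority-filter pass. They are free texture parameters, not calibrated
claims — the source analysis publishes no spatial statistics to match.

The generating coefficients follow a *dominance design*: each class has
one or two strong drivers (|β| ≥ 1.2) whose signs follow the published
coefficient pattern, and all secondary effects stay below 0.45. The
reason is identifiability of the *marginal* associations: distance fields
over a single landscape correlate substantially by chance, so a secondary
coefficient of ±0.5–0.9 can be masked or even sign-flipped in the
marginal correlation by a stronger correlated driver. With the dominance
design, the sign of every association stronger than |β| = 0.5 is
recoverable both marginally and by refitting, which is what the test
suite asserts.

What passing tests show: the estimators recover known structure from data
generated under the model's own assumptions, at realistic sizes and class
imbalances. What they do not show: performance under interpretation error
in the input maps, non-stationary drivers, non-Markov change, or spatial
autocorrelation of residuals — all present in real data.

Intercepts are auto-tuned so realised class shares land within ±3
percentage points of their targets: an iterative multiplicative
(log-ratio) update on the expected softmax shares, wrapped in a short
outer loop that corrects for sampling and majority-filter drift. This
replaces per-class bisection; it solves the same fixed-point problem in
a handful of vectorised iterations.

## Numerical choices, tie-breaks and degenerate inputs

* **Majority resampling ties** go to the smallest class code;
  **majority-filter ties** keep the centre cell's current class when it
  is among the modes. Both make every run bit-reproducible.
* **Allocator ties** at the argmax go to the smallest class code, then
  cell index (`max.col(ties.method = "first")` semantics); no RNG.
* **Demand quantization**: demands in ha are converted to integer cell
  counts by largest-remainder rounding (counts sum exactly to the map
  size); allocated-vs-demand comparisons therefore carry up to one cell
  (0.36 ha at 60 m) of unavoidable granularity.
* **Frozen cells**: classes whose `allowed` row permits only themselves,
  or whose ELAS is 1, are excluded from scoring and from the balancing
  arithmetic.
* **Annualization clipping**: the eigen-root can carry tiny negative
  entries; they are clipped to zero and rows renormalised. The returned
  matrix records `root_residual`, the max-abs defect of the *raw* root
  raised back to the original period (≤ 1e-6 on diagonal-dominant
  matrices), so the clipping perturbation is auditable.
* **Standardization** uses the population (divide-by-n) standard
  deviation; either convention rescales coefficients consistently, one is
  pinned for reproducibility.
* **Transition rows for absent classes**: a class missing from both maps
  gets an inert identity row; missing at t0 but present at t1 is an
  error, since its row is genuinely undefined.
* **Logistic edge cases**: complete separation is flagged on the result
  (and warned) with coefficients still reported; constant drivers error
  by name.
* **ASCII grids** are written in canonical header order, integers bare,
  reals at ≤ 6 significant digits, so write∘read is a byte-level fixed
  point.

## Open design points, resolved

* The source analysis does not state how its distance rasters or slope
  were derived; the package pins center-to-center Euclidean distance and
  Horn's 3×3 operator — the de-facto GIS standards.
* The published dynamic-degree table is internally consistent with a
  5-year annualization span although its caption names a 9-year window;
  `span_years` is always an explicit argument and the packaged change
  table records the printed values, so either reading can be computed.
* The published coefficient table's slope row is typographically
  ambiguous for two classes; the packaged fixture marks those cells
  uncertain (one treated as excluded, one as −0.051) rather than
  guessing silently.
* The exact matrix adjustments behind the ecological- and
  farmland-protection demand endpoints are unpublished;
  `calibrate_transition()` reproduces the endpoints (within 1% per class)
  without claiming to recover the unpublished intermediate matrices.

## Problem sizes

The default test and example sizes — 200×200 cells (40,000 observations)
for regression and Markov recovery, 100×100 for allocation and
self-validation experiments, 9 annual allocation steps — were chosen so
that parameter-recovery tolerances (±0.1 on coefficients, ±0.02 on
transition entries) are comfortably above sampling noise while whole-suite
runs stay in the seconds-to-minutes range on a single core.

## Known limitations

Suitability is static over the horizon (no endogenous driver feedback);
demand is exogenous to allocation (no price- or congestion-like
coupling); the allocator has no neighbourhood-interaction term and no
region-specific restriction masks beyond the boolean conversion matrix;
kappa decompositions beyond quantity (location, randomness) are out of
scope, as is the separation of random from systematic transitions.
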