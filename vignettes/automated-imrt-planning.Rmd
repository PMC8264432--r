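---
title: "Automated IMRT planning against a predicted dose: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated IMRT planning against a predicted dose: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autoplan)
```

## The planning problem

Inverse IMRT planning chooses nonnegative beamlet fluences $w$ so that the
delivered dose $d^{calc} = A w$ — with $A$ the dose-influence matrix mapping
beamlet fluence to voxel dose — meets clinical goals: a homogeneous,
conformal prescription dose to the planning target volume (PTV) and low dose
to organs at risk (OARs). `autoplan` automates this for a pelvic (rectal)
protocol: 50 Gy in 25 fractions, nine equiangular coplanar beams.

Instead of hand-tuned dose-volume constraints, the optimizer is driven by a
voxel-wise *reference dose* $d^{pred}$ — the dose a good plan is expected to
deliver. The default reference is a deterministic geometric surrogate; a
miniature trainable 3D U-Net is provided as an alternative predictor with
the same contract (any nonnegative dose grid on the phantom geometry works).

The total objective is

$$F_{total} = \alpha\, F_{MSE} + W_{HI} F_{HI} + W_{CI} F_{CI},$$

with

* $F_{MSE} = \sum_{i \in V} (d_i^{calc} - d_i^{pred})^2$ over the body
  voxels $V$, normalized by $|V| \cdot \text{prescription}^2$;
* $F_{HI} = (D_{98} - D_{50})^2 + (D_2 - D_{50})^2$ on the PTV (normalized by
  prescription$^2$), where $D_X$ is the nearest-rank dose received by the
  hottest $X\%$ of the PTV;
* $F_{CI} = (f_{CI} - C_{index})^2$ with
  $f_{CI} = TV_{RI}^2 / (V_{RI} \cdot TV)$: $TV$ the PTV volume, $V_{RI}$
  the reference-isodose volume (prescription level, counted over the body)
  and $TV_{RI}$ their intersection; $C_{index} = 1$ is perfect conformity.

"MSE-only" mode uses the first term alone; "MSE-plus-clinical" adds the HI
and CI terms, which lets the optimized plan *exceed* the quality of its own
reference dose.

## Why each numerical choice

**Normalization.** The three terms live on different scales. Dividing the
MSE term by $|V|\cdot\text{prescription}^2$ and the HI term by
$\text{prescription}^2$ makes all three dimensionless and of order one near
a reasonable plan, so the default weights $\alpha = 1$, $W_{HI} = W_{CI} = 10$
are transferable across phantoms. The weights themselves are free
parameters of the method, exposed in `objective_weights()`.

**Order statistics.** $D_X$ uses the nearest-rank convention: sort structure
doses descending, take rank $\lceil X/100 \cdot N\rceil$. It is piecewise
linear in the dose vector, so the HI term admits a subgradient that routes
each $D_X$ contribution to the single voxel realizing its rank (ties broken
toward the lowest flat voxel index; $D_{50}$ accumulates both chain-rule
terms). A smooth rank-window alternative was considered and rejected as the
default: the subgradient is exact wherever ranks are strict, and the
monotone accepted-step rule below already guards against the kinks.

**Conformity smoothing.** $f_{CI}$ counts voxels above the prescription
isodose — a step function. During optimization the indicator is replaced by
the logistic $s_i = 1/(1 + e^{-(d_i - \text{ref})/\tau})$ with temperature
$\tau = 0.5$ Gy (about a quarter of the inter-voxel dose spacing a plan
exhibits near the PTV edge: large enough to carry gradient information a few
voxels deep, small enough that the smooth and hard counts agree closely).
The *hard* count is always reported alongside, and every evaluation-side
metric uses hard thresholds only — smoothing is an optimization device, not
a reporting convention. The $V_{RI}$ denominator is guarded with
$10^{-8}|PTV|$; a guarded evaluation is flagged rather than silent.

**Optimizer.** Projected spectral (Barzilai–Borwein) gradient descent with
nonnegativity bounds and a monotone Armijo backtracking line search: a step
is accepted only if $F_{total}$ decreases, so the objective trace is
non-increasing by construction, which is the property that makes subgradient
steps from the HI term safe. Convergence is declared when the projected
gradient falls below `gtol` (default $10^{-6}$) *relative to its initial
value* — an absolute threshold would be meaningless under the term
normalization — or when no decreasing step exists (a subgradient stall).
On a constructed achievable target ($d^{pred} = A w^\star$) the method drives
the residual objective below $10^{-6}$ of its initial value in a few hundred
iterations, which the test suite asserts.

## The dose engine

No treatment-planning system is emulated; the influence matrix comes from a
transparent parallel pencil-beam model. Per beamlet,
$\text{dose}(i) = e^{-\mu\, r(i)}\, e^{-\ell(i)^2/2\sigma^2}$, with $r(i)$
the radiological depth (density-weighted path from the body surface to the
voxel along the beam direction, by 2 mm fixed-step ray marching with
nearest-voxel density sampling — density is zero outside the body, so a
fixed step count covering the grid diagonal integrates exactly the in-body
path) and $\ell(i)$ the lateral distance to the beamlet axis. Defaults
$\mu = 0.005\,\text{mm}^{-1}$ and $\sigma = 5$ mm (cutoff $3\sigma$) give a
plausible megavoltage-like falloff; they are engine parameters, not
commissioned beam data, and absolute clinical dosimetry is out of scope.
Beamlets are $10 \times 10$ mm on the PTV beam's-eye-view footprint plus a
5 mm margin; per-beamlet entries below $10^{-3}$ of the beamlet maximum are
dropped for sparsity. After assembly, $A$ is rescaled once so that uniform
unit fluence delivers a mean PTV dose of 1 Gy — this anchors the default
initial fluence (uniform at prescription level) and makes objective weights
portable across phantoms.

## Synthetic phantoms

Each case is an elliptic-cylinder body (density 1.0), a posterior-central
ellipsoidal PTV, an anterior ellipsoidal bladder abutting the PTV across a
2 mm gap, and two lateral spherical femoral heads (density 1.5), voxelized
by centre-of-voxel inclusion on a 24×64×64 grid at (5, 4, 4) mm — 5 mm
slices as in a typical planning CT, with in-plane resolution reduced from
the clinical 512×512 for desk-scale runtimes. Structure sizes and positions
are jittered per case from a seeded RNG (±4% body, ±10% PTV axes, ±5 mm
centres); per-case seeds are `seed + case_index`, so cohorts are
prefix-stable. Geometry that cannot satisfy the containment invariants
(everything inside the body, PTV clear of both femoral heads) raises an
error rather than silently clipping. Because no published size
distributions are bound to this protocol, the jitter ranges are chosen to
look like plausible inter-patient variability, not calibrated to any cohort.

What the phantoms deliberately do **not** model: real CT texture and
heterogeneity (only water and a denser bone surrogate), realistic anatomy
or contour variability, couch/immobilization structures. Passing tests
therefore demonstrate the *mechanics* of the method — objectives, gradients,
optimization, evaluation — under controlled conditions, not clinical
performance on patients.

## The reference-dose predictors

**Geometric surrogate (default).** Prescription inside the PTV, an
exponential falloff $e^{-d/30\,\text{mm}}$ with Euclidean distance $d$ from
the PTV surface inside the body (exact anisotropic distance transform), zero
outside the body. The 30 mm falloff length halves the dose roughly every
2 cm, a typical planned-dose gradient; it is continuous at the PTV boundary.
Being deterministic, it makes the whole optimization pipeline exactly
reproducible, which is what the tests need.

**Miniature 3D U-Net (optional).** An encoder–decoder with filter ladder
32–64–128–256–512, 3×3×3 convolutions with "same" padding (so output matches
input spatially), max-pooling that halves the feature map per stage,
nearest-neighbour upsampling with skip concatenation, a linear 1×1×1 output
convolution, He-normal initialization, MSE loss on prescription-normalized
doses, and Adam. Inputs are the standardized density plus the five ROI masks
as channels. One convolution per stage (rather than the usual two) keeps the
desk-scale parameter count small; depth, filters, learning rate, epochs and
patch size are configuration, since no published values bind them. Training
visits cases in order with one Adam update per case, making runs
deterministic given the seed. The network path verifies architecture and
training mechanics — construction, shape contracts, parameter counts,
single-case overfitting — not prediction quality, which would require a
large clinical training corpus that synthetic phantoms cannot stand in for.

## Evaluation battery

All evaluation uses hard thresholds: cumulative DVHs; $D_{mean}$ everywhere;
$D_2, D_5, D_{95}, D_{98}$ on the PTV; $V_{15}, V_{25}, V_{35}, V_{50}$ on
each OAR; homogeneity index $HI = D_5/D_{95}$ (1 is ideal); conformity index
$CI = V_R^2/(V_{PTV} \cdot V_P)$ at the prescription level with $V_P$
counted over the body (1 is ideal); and the global maximum dose over the
body. `dose_at_volume()` is the single shared $D_X$ implementation for both
the optimizer and the evaluator, so there is exactly one percentile
convention in the package. Cohorts are compared index-by-index with a
two-sided paired t-test at $p < 0.05$, without multiplicity correction —
comparisons are reported per index, and degenerate zero-variance differences
are flagged rather than tested.

## Problem sizes used in the shipped checks

The test suite exercises hand-built 8×16×16 phantoms for engine and network
oracles, 16×32×32 generated phantoms for pipeline checks, and the full
default 24×64×64 grid for the optimizer-recovery and cohort-level checks.
The cohort experiment plans 10 phantoms in both modes end-to-end; with
~440 beamlets and ~47,000 body voxels per case this runs in a few minutes on
one CPU. On that cohort the clinical mode consistently lowers HI and raises
CI relative to MSE-only planning, and the paired t-test on HI is strongly
significant — the directional behaviour the post-optimization strategy is
designed to produce.

```{r example, eval = FALSE}
p <- generate_phantom(phantom_config(), seed = 1)
infl <- compute_influence(p, make_equiangular_beams(9))
plan_mse <- auto_plan(p, "mse_only", influence = infl)
plan_clin <- auto_plan(p, "mse_plus_clinical", influence = infl)
metrics_report(plan_clin, p)
```

## Known limitations

* The pencil-beam engine has no scatter, build-up, or heterogeneity-corrected
  convolution; fluence is one scalar per 10×10 mm beamlet with no leaf
  sequencing or deliverability constraints.
* The geometric reference dose is isotropic around the PTV and ignores
  beam-direction anatomy; a trained predictor would not.
* HI subgradients touch three voxels per evaluation; progress on the HI term
  is therefore slower than on the smooth terms and relies on the accepted-step
  rule. Plans stalling at a subgradient kink report `converged = TRUE` with
  the stall visible in the trace.
* The paired t-test assumes approximately normal paired differences; with 10
  synthetic cases this is a small-sample test, as in any 10-case test split.
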