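---
title: "Methods: deep-learning dose prediction for female-pelvis VMAT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep-learning dose prediction for female-pelvis VMAT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A VMAT plan for gynecologic cancer delivers a prescribed dose (here a
single level of 45 Gy in 25 fractions) to a planning target volume (PTV)
while limiting dose to organs at risk (OARs): bladder, bowel bag, rectum,
femoral heads, kidneys, liver and spinal cord. Plan quality depends
heavily on the planner; two clinically approved plans for similar anatomy
can differ substantially in normal-tissue sparing. `vmatdose` implements a
quality-assurance pipeline built around a learned dose predictor: a 3D
convolutional network predicts the achievable dose distribution from the
CT and the structure set, the prediction is compared against the actual
plan, plans whose prediction shows meaningfully better OAR sparing are
flagged, and concrete replanning objectives are extracted from the
predicted dose.

Because clinical plan collections cannot be redistributed, the package
ships a synthetic cohort generator that produces seeded pelvis phantoms
with a physically plausible analytic dose. Every stage of the pipeline is
exercised and tested against this generator.

## Synthetic phantom cohort

`phantom_config()` fixes the study conditions: a dose grid at 3 mm
spacing, a single 45 Gy / 25-fraction prescription, and an ellipsoid
anatomy model for the body, the PTV and the 14-structure vocabulary
(`structure_vocabulary()`). Per-plan anatomical variability comes from
Gaussian jitter of the ellipsoid centres (2 mm SD) and log-radii (5% SD),
clipped so every organ stays inside the grid; all organ masks are
intersected with the body so nesting holds voxel-wise. The jitter scales
were chosen once as a plausible stand-in for inter-patient variability:
large enough that the network must generalize across anatomies, small
enough that organs keep their topology.

The reference dose is analytic rather than a treatment-planning-system
output, chosen so that point values are available in closed form for
testing while the spatial pattern is still learnable:

* inside the PTV: `Rx * (1 + h * g(x))` with a Gaussian hotspot bump
  `g(x) <= 1`, hotspot fraction `h = 0.05` by default (a 105% in-target
  hotspot is at the upper end of what passes clinical review for this
  plan class, so `h` is capped at 0.10);
* outside the PTV: `Rx * exp(-d / tau) * s(x)`, where `d` is the
  Euclidean distance (mm) to the nearest PTV voxel centre (an anisotropic
  distance transform), `tau = 22` mm is the fall-off length, and
  `s(x) in (0, 1]` is the sparing factor of the nearest configured OAR
  when that OAR is within 30 mm (1 otherwise) — this emulates the
  directional sparing a VMAT optimizer produces;
* zero outside the body.

With `tau = 22` mm the 95% isodose (42.75 Gy) sits about 1 mm outside
the PTV surface — less than one 3 mm voxel — so the conformity index of
a phantom reference dose is exactly 1 rather than the 0.8 typical of
clinical plans; CI on phantoms exercises the computation, not the
clinical spread. What the generator does *not*
emulate: beam/arc geometry and deliverability, heterogeneity effects,
multi-dose-level (SIB) targets, the low-dose bath structure of rotational
delivery, and inter-planner variability in mid-to-low isodoses. Passing
tests on phantoms therefore demonstrate that the machinery is correct and
that the network can learn a spatially structured dose; they do not
certify clinical accuracy.

Cohorts are split 3:1:1 into training/validation/test by
largest-remainder allocation (`split_sizes()`), the only rounding
convention that reproduces 47/16/16 from 79 plans; ties in the fractional
remainders resolve in train, validation, test order.

## The 16-channel input representation

`assemble_inputs()` stacks, in fixed order: the CT normalized by clipping
to [-1000, 1000] HU and rescaling to [0, 1]; the target array (the PTV
mask carrying the prescription in Gy — the physical value, 45, not a
rescaled one; a rescale would only change the input scale the optimizer
sees and is left off); and the 14 structure masks. The L4 and L5
vertebral bodies are separate channels — with one channel the input count
would not reach 16. A structure missing from the input set becomes an
all-zero mask with a warning rather than an error, since bony structures
are routinely absent from clinical contour sets. Resampling to the dose
grid uses trilinear interpolation for continuous volumes and
nearest-neighbour for masks (which preserves binarity); the resampled
grid is centre-aligned and covers the same physical extent within one
voxel. No stochastic augmentation is applied anywhere: the normalization
is deterministic and the cohort variability comes from the generator.

## Network, loss, training

The predictor is a 3D dense dilated U-Net (`network_config()`): an
encoder–decoder with configurable resolution levels, dense
(concatenative) convolution blocks, dilation rates cycled through the
bottleneck block (default 1, 2, 4), and a softplus output head so the
predicted dose is non-negative by construction. Dense-block inputs wider
than twice the growth rate are compressed by a pointwise transition
convolution (as in DenseNet transitions), which bounds the cost of the
3×3×3 convolutions. The receptive field per axis is reported by
`build_network()`. Convolutions run on im2col + GEMM kernels with exact
reverse-mode gradients (verified against finite differences in the test
suite).

The training objective (`combined_loss()`) is

```
Loss = MSE(D_ref, D_pred) + 0.25 * (|dD1%| + |dD95%| + |dD98%|)
```

with `dD_V% = D_V%(pred) - D_V%(ref)` evaluated over the PTV. The
printed definition of the percentile differences carries no absolute
value, but the accompanying description calls them absolute errors, and
only `|.|` yields a loss bounded below at the target; the absolute value
is used. `D_V%` is the exact sort-based estimator — the minimum dose of
the hottest `ceil(V * N / 100)` voxels — and its subgradient flows to the
selected voxel, so the DVH terms are usable in gradient training without
a smooth surrogate (a soft percentile was considered and rejected: the
exact estimator matches the evaluation metric, and the subgradient is
adequate in practice). The MSE is taken over the whole training patch;
the DVH terms are computed from the PTV voxels inside the patch and are
skipped for patches containing no PTV voxel, which keeps every random
patch usable.

Training (`train_model()`) follows the published protocol: random cubic
patches (64^3 at clinical scale), Adam at an initial learning rate of
0.001, the learning rate halved after every 55 epochs without validation
improvement, a maximum of 1000 epochs with early stopping, and the
weights with the best validation loss returned. The early-stopping
patience is not part of the published protocol; the default is 150
epochs, configurable. Runs are reproducible given the seed. Three models
differing only by seed form the routine ensemble (`train_ensemble()`).

## Inference

`tile_patches()` enumerates overlapping patch offsets with stride 16 per
axis, the final offset clamped to the boundary (no padding — padding
would fabricate out-of-body context); every voxel is covered by at least
one patch. `predict_volume()` averages all (model, covering-patch)
predictions voxel-wise — a plain mean, no Gaussian window. The averaged
volume is then renormalized once (not per model) to the reference plan's
target coverage: `D_norm = D_pred * D95%(ref) / D95%(pred)`
(`normalize_to_reference_d95()`).

## Plan-quality analytics

`plan_dose_deltas()` computes, per plan: the PTV percentage differences
`dD_V%(%) = (D_V%(pred) - D_V%(ref)) / D_V%(ref) * 100` for D1%, D95%
and D98%; OAR differences in mean and maximum dose in Gy (`Dmax` is the
single hottest voxel — no near-max volume convention is applied); and the
voxel-wise mean dose difference, computed within the body mask because a
whole-grid mean would be diluted by surrounding air. The conformity index
`CI = TV_RI / V_RI` counts voxels at or above the reference isodose
(42.75 Gy, 95% of the prescription); an empty isodose volume raises an
error rather than returning 0/0. The homogeneity index is `HI =
D5%/D95%`. DVH curves (`compute_dvh()`) use a 0.1 Gy default bin width,
but all scalar percentile metrics use the exact sort-based estimator, so
they agree with brute-force oracles exactly rather than to bin
resolution.

Equivalence of predicted and reference mean doses uses a paired two
one-sided t-test (`tost_equivalence()`) with a 1 Gy bound at alpha 0.05:
equivalent iff both one-sided tests reject, i.e. `max(p_lower, p_upper) <
alpha`. With zero variance the t statistic is undefined and the verdict
falls back to `|mean| < bound`. Which paired vector enters the test is
left to the caller; the pipeline reports it for the per-plan body-mean
doses.

## Flagging and replanning objectives

The replanning candidates in routine use are the plans whose predictions
show the largest sparing gains; the package makes the selection explicit
with thresholds (`theta_mean = 2` Gy on mean dose, `theta_max = 3` Gy on
max dose, both configurable — chosen conservatively, since the underlying
clinical selection was qualitative). For each flagged OAR,
`flag_and_extract_objectives()` emits a max-dose point objective at the
predicted maximum and a max-DVH point objective at the predicted median
dose (50% volume), optionally scaled by a push factor below 1 to push
slightly beyond the prediction. To transfer the predicted dose fall-off
to tissue outside named OARs, it also derives planning structures `body -
isodose_volume(pred, L)` for configured levels `L` (default 40, 30,
20 Gy) with a max-dose objective of `L` on each; these are the
"normal-tissue" structures a planner would add when re-optimizing.

## Numerical conventions

* Voxel indices are 0-based for world coordinates: centre of voxel
  `(i, j, k)` at `origin + (i, j, k) * spacing`; the manifest records
  both.
* Percentiles use the `ceil` convention; for 100 voxels dosed 1..100 Gy,
  D95% = 6 Gy and D1% = 100 Gy. Ties in the sort resolve by R's stable
  order; the DVH-loss subgradient goes to the single selected voxel.
* The distance in the analytic dose model is the distance to the nearest
  PTV voxel centre, so the closest out-of-target voxel sits one spacing
  away; the in-target/out-of-target transition is a step, emulating the
  steep VMAT gradient at the target edge.
* Patch tiling requires patch dimensions divisible by `2^(levels - 1)`;
  pooling uses average pooling with factor 2, upsampling is
  nearest-neighbour.
* Degenerate inputs raise errors rather than propagating NaN: empty PTV,
  empty isodose volume at the CI level, zero predicted D95, non-finite
  training loss.

## Problem sizes in the shipped checks

The package's own test suite and the acceptance script run a scaled-down
version of the study: 48^3 grids at 3 mm (a ~144 mm pelvis crop), a
54-phantom cohort (32 training, 11 validation, 11 test plans by the
3:1:1 rule), a two-level network with growth 6 (~10^4 parameters), 24^3
training patches, and 10–20 epochs. These sizes were chosen so a
single-CPU run finishes in minutes while leaving the learning task
non-trivial: at this scale the held-out mean absolute voxel error within
the body is well under 10% of the prescription, against a
predict-nothing baseline of roughly 25%. Clinical-scale runs (full CT
extents, 64^3 patches, 1000-epoch budgets, three-model ensembles) use
the same code paths with the default configurations.

## Known limitations

The analytic dose is a surrogate: it has no beam structure, no
deliverability constraints, and its OAR sparing is imposed rather than
emergent, so absolute clinical metrics (CI, OAR deltas) from phantom runs
characterize the pipeline, not clinical performance. The network
implementation is CPU-bound and sized for method development, not for
training on hundreds of clinical plans. DICOM-RT ingestion is out of
scope; volumes enter and leave the package as NIfTI with a JSON manifest.
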