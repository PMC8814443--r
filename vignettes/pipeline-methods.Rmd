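---
title: "Methods: multimodal VOI imaging to seizure-outcome prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal VOI imaging to seizure-outcome prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

After resective surgery for drug-resistant focal epilepsy, roughly half of
patients have recurrent seizures. `voipredict` implements a pipeline that
predicts an individual's post-surgical outcome — seizure-free (SZF, Engel
class I; the positive class everywhere in this package) versus
seizure-recurrence (SZR, Engel II–IV) — from the co-registered
pre-surgical imaging (T1 MRI, FDG-PET, CT) of the *surgical target volume
of interest* (VOI), the region that was actually resected. The premise is
that the multimodal image content of the target volume carries signal
about whether its removal will stop the seizures.

The pipeline is, in order:

1. **VOI cube extraction** — crop the minimum circumscribed cube around
   the binary VOI mask and resample it to a canonical 64×64×64 grid;
2. **intensity normalization** — per-cube min–max to [0, 1], with CT first
   clipped to a Hounsfield window;
3. **mask attention** — multiply voxels inside the mask by 1 and outside
   by 0.7, concentrating the representation on the target;
4. **nine-view 2.5-D slicing** — represent the cube by nine fixed 64×64
   planar sections (axial, sagittal, coronal, six diagonals);
5. **deep features** — push each view through a ResNet-34 backbone and
   keep the 512-dimensional post-average-pool activations; a case and
   modality is the 9 × 512 = 4,608-dimensional concatenation;
6. **multi-kernel SVM (MKSVM)** — one trace-normalized kernel per
   modality, fused as a convex combination and fed to a soft-margin SVM on
   the precomputed kernel;
7. **evaluation** — leave-one-out cross-validation (LOOCV), confusion
   metrics at score threshold 0, midrank AUC, and paired DeLong tests
   between methods.

## The backbone

The feature extractor is a ResNet-34 for 64×64 single-channel input: a
3×3, 64-filter, stride-2 stem; four stages of two-convolution basic
blocks repeated {3, 4, 6, 3} at widths {64, 128, 256, 512}; global
average pooling; and a classification head used only during pretraining.
Counting 1 stem + 32 block + 3 projection-shortcut convolutions gives
exactly 36 convolutions and 36 batch normalizations, which the structural
audit asserts. Two architectural choices deserve notice:

* The first stage keeps the stem width (64), so its stride-2 first block
  downsamples through a *parameter-free* subsampled-identity shortcut;
  the three width-changing transitions use 1×1 stride-2 projection
  convolutions. This is what makes the convolution count 36.
* With stride-2 same-padding halving from a 64×64 input, the stage
  outputs are 32→16→8→4→2. A printed stage output of 3×3 for the
  third-width stage is not reachable with any standard padding
  convention; we implement the standard 8→4 halving. The structural
  quantities (counts, widths) are unaffected.

No tensor or autodiff library is available in this package's dependency
set, so the forward pass, batch-normalization statistics, backward pass
and SGD loop are implemented in single-precision RcppArmadillo: im2col +
BLAS GEMM convolutions over a channels × positions layout. The backward
pass is verified against finite differences in the test suite's pilot
history, and training determinism (fixed seed → identical weights) is a
tested contract. Pretraining defaults are SGD with momentum 0.9, cosine
learning-rate decay from 0.1, batch 128, weight decay 1e-4, 30 epochs — a
Tiny-ImageNet-scale recipe; the test profile trains 3 epochs on a
procedural texture corpus (6 classes × 50 images) in about half a minute
and must beat chance on held-out images. A *random-initialization*
backbone is a first-class extractor: deep random convolutional projections
preserve the lesion signal well enough for the desk-scale studies, and
they make the pipeline runnable with no pretraining corpus at all.

Calling `pretrain(..., epochs = 0)` returns the initial weights
untouched — exactly, in double precision; trained weights live in float32.

## Geometry choices

The nine view planes all pass through the cube centre (31.5, 31.5, 31.5)
in 0-based voxel coordinates. The axis-aligned views are therefore
*interpolated* halfway between the two central slices rather than taken at
an integer slice; this keeps the slicing geometry a single consistent
family (every plane through the centre) and is the convention the
brute-force oracle in the tests checks. The six diagonal planes are the
cube's edge-diagonal symmetry planes — each contains one coordinate axis
and bisects the other two at ±45°, with unit normals of the form
(1, ±1, 0)/√2 in lexicographic order. A diagonal section is sampled on a
native 64 × 91 unit-spaced grid (91 = ceil(64·√2)) and resized to 64×64
bilinearly. The native grid slightly overhangs the cube corners
(91 > 64·√2 ≈ 90.5); those sample points take the nearest boundary value
(edge clamping) rather than zero, so a constant cube yields exactly
constant views — the property the test suite pins down. In-plane axes are
fixed as `u` (the contained coordinate axis, or the first in-plane axis
for the axis-aligned views) and `v = normal × u`; the orientation of each
view is therefore deterministic, and the downstream 4,608-wide
concatenation order (`axial | sagittal | coronal | six diagonals`) is
recorded on every feature matrix.

Cropping: the cube side is the largest extent of the mask bounding box
plus twice the margin (default 0), centred on the bounding-box centre with
the odd voxel going to the high side; out-of-image regions are padded with
the volume minimum (mimicking background). Resampling is trilinear for
intensities and nearest-neighbour for the mask, pixel-centre aligned and
clamped so no value can overshoot the input range. CT is clipped to
[−100, 300] HU before min–max normalization — a generic soft-tissue window
that suppresses bone and air extremes; MRI and PET are min–max only. A
constant cube maps to all zeros.

Attention is applied after crop + resample + normalization, immediately
before view extraction, so the mask and the image live on one 64³ grid.
Whether the original work applied it before or after cropping is not
recoverable from its description; this ordering is declared in the
configuration and both arms (with/without attention) are first-class.

## The classifier

Deep features are standardized per training fold (zero-variance columns
dropped, never fatal), turned into a linear kernel per modality (RBF
available by configuration), trace-normalized (K ← n·K/tr K) so no
modality dominates by scale, and fused by a convex combination — uniform
weights by default, with optional selection over the 0.1-step simplex by
inner 5-fold cross-validation, as is the soft-margin cost C (default 1,
optional grid). All statistics and selections happen strictly inside each
LOOCV training fold.

The SVM dual on the precomputed kernel is assembled in-package and solved
with `kernlab::ipop` (interior-point quadratic programming), followed by
an active-set polish: with the bound/free support structure fixed, the
free dual coefficients and the bias satisfy an exact linear KKT system
whose solution removes the interior-point residual. The resulting decision
function satisfies the KKT conditions to ~1e−15 and is reproducible
bit-for-bit from the stored coefficients. The package deliberately does
*not* use kernlab's own precomputed-kernel interface: during development
it disagreed with the exact dual optimum by ~0.3 in decision value on a
toy problem, an error far above solver tolerance, so the dual is built
and verified here, with the explicit-feature route (w = Xᵀ(α∘y)) and an
independent solver as test-time cross-checks.

## Evaluation

The positive class is SZF throughout: with 79 seizure-free and 62
recurrence cases, a sensitivity of 96.20% is 76/79 and a specificity of
85.48% is 53/62, which forces the accuracy 129/141 = 91.49% — the
arithmetic-consistency check the acceptance tests reproduce. Confusion
metrics threshold the decision score at 0 (scores exactly 0 predict
negative); rates with empty denominators are reported as missing, never
as 0. AUC is the midrank Mann–Whitney statistic, identical to the
exhaustive concordant-pair count; the DeLong test is the placement-based
estimator with covariance S10/m + S01/n and a two-sided normal p-value,
cross-checked against a brute-force double-loop oracle and against pROC.
No multiple-testing correction is applied across the pairwise method
comparisons. The method-comparison harness runs the 8 methods
({CT, MRI, PET, fused} × {attention on, off}) and all 28 pairwise DeLong
tests.

## The synthetic cohort generator

Real patient volumes are not distributable, so every pipeline stage is
exercised on multimodal lesion phantoms. Per case, each modality is a
smooth correlated Gaussian background (white noise smoothed with a
σ = 3-voxel separable kernel, rescaled to unit voxel SD, around a
modality-typical baseline), sharing one random axis-aligned ellipsoid
mask (semi-axes 6–14 voxels on the default 96³ grid). SZR cases receive
an additive shift of `effect_size × modality_weight × σ` strictly inside
the mask — negative in PET (focal hypometabolism), positive in MRI/CT,
with weights (PET 1.0, MRI 0.7, CT 0.5) so PET carries the strongest
single-modality signal. Label-independent clutter ellipsoids outside the
mask, present in both classes, make the no-attention condition strictly
harder, giving the attention mechanism something to suppress. All
randomness flows from one seed through named substreams (geometry, noise,
clutter, corpus), so cohorts are bit-reproducible, and `write_cohort()`
emits exactly the NIfTI + CSV layout `load_cohort()` reads.

What the phantoms do *not* emulate: MR/PET physics (partial volume,
attenuation, bias fields), anatomy, registration error, lesion-shape
irregularity, or class imbalance in lesion geometry. Passing tests on
phantoms therefore demonstrate that the pipeline recovers a
mask-confined multimodal effect under controlled conditions — not
clinical performance. The published cohort results (e.g., 91.49%
accuracy, AUC 0.952 for the fused masked model on 141 patients) are not
reproducible without the patient data; the package covers them through
the arithmetic-consistency checks above and through *directional*
properties on phantoms: LOOCV AUC within the null band [0.35, 0.65] at
zero effect and above 0.9 at effect 2.0 (n = 60); AUC monotone
nondecreasing in effect size over {0, 0.5, 1, 2}; kernel fusion at least
matching the best single modality, and attention at least matching
no-attention, each averaged over 20 independent cohorts with a
two-standard-error tolerance.

## Problem sizes and numerical notes

The test suite sizes its simulations for a single-CPU run: property
cohorts use 64³ volumes with 5–12-voxel lesions and n = 12–60 cases; the
end-to-end run uses the generator defaults (40 + 40 cases, 96³);
`scripts/acceptance.R` runs a cohort-shaped study (79 SZF + 62 SZR,
generated in independently seeded batches to bound memory) with the
random-initialization backbone. Feature extraction batches ~108 views per
GEMM call, and cohorts stream through the extraction stage chunk-by-chunk
(the command-line stages pass lazy case loaders, and simulated cohorts can
be generated and written one case at a time), so memory stays around a
gigabyte even for hundred-case studies on 96³ grids. Forward passes are float32; run-to-run determinism at a fixed
seed and thread count is a tested contract. Known limitations: the
backbone's inference-mode batch normalization uses initialization-time
running statistics when the network is untrained (the random-init
extractor is a fixed random projection, not a calibrated network); kernel
weight selection is a grid search, not gradient-based multiple-kernel
learning; and LOOCV, as used throughout, is known to be an optimistic
estimator at these sample sizes.
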