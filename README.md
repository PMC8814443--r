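# voipredict

Predicting an individual's seizure outcome after epilepsy surgery —
seizure-free (SZF, Engel class I) versus seizure recurrence (SZR, Engel
II–IV) — from co-registered multimodal neuroimaging (T1 MRI, FDG-PET, CT)
of the **surgical target volume of interest** (VOI), the brain region that
was actually resected. The package is aimed at methods researchers in
neuroimaging-based outcome prediction: it provides the full pipeline, a
synthetic multimodal lesion-phantom generator so every stage is testable
without patient data, and a command-line front end.

## The method

For each patient case with volumes $I_m$ (modality $m$) and binary VOI
mask $M$ on a common grid:

1. **Cube extraction.** Crop the minimum circumscribed cube around $M$
   (side = largest bounding-box extent, centred), resample to
   $64^3$ (trilinear; nearest-neighbour for $M$), min–max normalize to
   $[0,1]$ (CT clipped to $[-100, 300]$ HU first).
2. **Mask attention.** $I \leftarrow I \cdot (1\,[M{=}1] + 0.7\,[M{=}0])$
   — amplify factor 1 inside the VOI, suppress factor 0.7 outside.
3. **2.5-D slicing.** Nine fixed $64\times64$ views through the cube
   centre: axial, sagittal, coronal, and the six edge-diagonal symmetry
   planes of the cube (normals $(1,\pm1,0)/\sqrt2$ etc.).
4. **Deep features.** Each view passes through a ResNet-34 backbone
   (36 convolutions, 36 batch normalizations, 512-wide penultimate
   layer; pretrainable on a labelled grayscale corpus, or used at random
   initialization); concatenating the nine 512-d view features gives a
   4,608-d vector per case and modality.
5. **Multi-kernel SVM.** Per modality, a linear kernel on fold-wise
   standardized features, trace-normalized ($K \leftarrow nK/\mathrm{tr}K$);
   kernels are fused as a convex combination
   $K_\beta = \sum_m \beta_m K_m$ ($\beta_m \ge 0$, $\sum\beta_m = 1$,
   uniform by default) and a soft-margin SVM is solved on the precomputed
   kernel (dual via interior-point QP with an exact active-set polish).
6. **Evaluation.** Leave-one-out cross-validation with fold-local
   standardization and hyperparameters; accuracy / sensitivity /
   specificity at decision threshold 0 (positive class SZF); midrank
   Mann–Whitney AUC; paired DeLong tests between methods
   ($z = (\hat A_1-\hat A_2)/\sqrt{S_{10}/m + S_{01}/n}$ on placement
   values).

## Worked example

Simulate a small multimodal phantom cohort, extract deep features with a
random-initialization backbone, and evaluate the fused masked model:

```r
library(voipredict)

cfg <- synthetic_config(n_per_class = c(SZF = 30, SZR = 30), shape = 64,
                        lesion_radius = c(5, 12), effect_size = 2.0,
                        seed = 11)
cohort <- generate_cohort(cfg)
net <- build_network(resnet_spec(), seed = 1)   # random-init extractor
fc  <- extract_cohort_features(cohort, net)     # mask attention on
rep <- loocv(fc$features, fc$labels, method_tag = "Multi-Kernel+Mask")
rep
#> <evaluation_report> Multi-Kernel+Mask (n = 60; positive class SZF)
#>   accuracy 91.67%  sensitivity 90.00%  specificity 93.33%  AUC 0.9922
```

The cohort has a 2-SD class effect confined to the lesion (largest in
PET), so the fused model separates the classes almost perfectly; with
`effect_size = 0` the same pipeline hovers at chance (AUC ≈ 0.5). The
accuracy/sensitivity/specificity are percentages at score threshold 0;
the AUC is the probability a random seizure-free case outscores a random
recurrence case.

The same pipeline is scriptable per stage:

```sh
Rscript inst/cli/voipredict.R simulate --config run.yaml
Rscript inst/cli/voipredict.R extract  --config run.yaml
Rscript inst/cli/voipredict.R evaluate --config run.yaml
Rscript inst/cli/voipredict.R compare  --config run.yaml   # 8 methods + DeLong matrix
```

Each stage writes its artifacts plus a JSON manifest (config, seed, file
hashes) sufficient to reproduce the run.

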