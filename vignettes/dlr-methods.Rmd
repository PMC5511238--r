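---
title: "Deep-learning-based radiomics: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep-learning-based radiomics: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dlradiomics)
```

## The method in one paragraph

Deep-learning-based radiomics (DLR) replaces hand-crafted radiomic features
with the internal representation of a segmentation network. A patch-based
convolutional network is trained to classify each voxel of an axial MR slice
as tumor or non-tumor from its 33x33 neighbourhood. Once the network
segments well, the scalar activations of its *last convolutional layer* —
harvested over the tumor region at ten spatial scales — are treated as a bag
of local texture measurements. A single scalar Gaussian mixture (the "visual
dictionary") is fit to pooled activations from an encoder subset of cases,
and each case is summarised by an improved Fisher vector: the gradient of
the bag's log-likelihood with respect to the mixture's means and variances.
With 128 deep filters and 64 mixture components this yields a fixed
16,384-dimensional descriptor (128 x 64 x 2) per case regardless of tumor
size. Descriptor dimensions are filtered by a two-sample t-test (p < 0.05,
uncorrected), ranked by F-score, and the top m feed a linear SVM (box
constraint 1) evaluated by leave-one-out cross-validation or by a
diagnosis-time split.

## The segmentation model

`network_spec()` describes the classifier: a stack of 3x3 convolutions with
ReLU, two fully connected layers with ReLU and dropout (rate 0.5), and a
2-way softmax. The reference configuration uses 6 convolutional layers
ending in 128 filters and 4096 fully connected neurons; both axes are
configurable because they are the published ablation axes (1-6 layers,
256-4096 neurons). With 3x3 kernels the receptive field is `2L + 1`, at most
13 for 6 layers, comfortably inside the 33x33 patch; we therefore insert no
pooling by default, and the dense test-time output is already at input
resolution. The per-layer filter counts other than the last (fixed at 128 by
the descriptor design) are configuration defaults `c(64, 64, 128, 128, 128,
128)`; the exact published schedule is not restated in the main protocol, so
these remain explicit knobs rather than constants.

Training uses minibatch SGD with momentum (defaults: learning rate 0.005,
momentum 0.9, batch 128, 30 epochs — the optimiser is named by the protocol,
its hyperparameters are ours, logged and configurable). Patches are sampled
with the deliberately unbalanced class mix of the protocol: ~40% of training
patches have tumor-centred voxels, compensating for how little of a brain
volume is tumor.

**Normalization.** Each patch is standardized to zero mean and unit variance
*per channel, per patch*. The protocol's wording ("the mean gray levels of
the patches in one channel were removed, and the gray values and variance
were normalized") scopes normalization to patches within a channel but does
not say whether the statistics are per-patch or global; we read it as
per-patch and apply exactly the same operation at inference time, where every
voxel's 33x33 neighbourhood is standardized before classification. This
makes the classifier a local-contrast-invariant texture detector. The
alternative (volume-global statistics) is a documented open choice, not
supported as a flag.

**Dense inference and post-processing.** `segment_volume()` classifies every
voxel of every axial slice (replicate-padding at borders); with `stride > 1`
it evaluates a sub-sampled grid and up-samples the probability map back to
input resolution with bicubic (Keys, a = -0.5) interpolation.
`postprocess_mask()` keeps, per slice, the largest 4-connected component of
the thresholded map (threshold 0.5 — the protocol does not state another
value), then smooths the binary stack with a 3x3x3 box filter and
re-thresholds at 0.5. A single isolated voxel has smoothed value 1/27 and is
removed; a mask slab several slices thick keeps its interior. Note that a
candidate region confined to one axial slice cannot survive the 3-D box
filter; at the volume shapes used here tumors always span several slices.

## Deep-feature harvesting

`multiscale_rois()` isolates the tumor: out-of-mask voxels are zeroed, the
per-slice bounding box is cropped (zero-padded up to the network's
convolutional receptive field if tiny), and each crop is resampled by ten
ratios spanning [0.5, 2]. We space the ratios *geometrically* (constant
successive quotient `4^(1/9)`), matching multiplicative scale perception;
the protocol states only the endpoint range. With this spacing ratio 1.0 is
not among the ten values — noted, and configurable via `scale_ratios()`.
Either the ground-truth mask (method-validation mode) or the predicted mask
(fully automatic mode) can be supplied.

`extract_filter_responses()` standardizes each scaled image per channel
(every network input goes through the same normalization), applies the
convolutional stack, and pools the post-ReLU maps of the last convolutional
layer: per filter, maps are flattened in a fixed order (slice-major, then
scale, then column-major raster). Downstream Fisher statistics are
order-invariant, so this order only needs to be stable, not canonical.

## The Fisher-vector encoder

`fit_gmm()` fits one shared univariate K-component mixture to activations
pooled across filters from the encoder-fit subset (default 30 cases; fitting
one global dictionary rather than one per filter follows the protocol's
singular "a GMM", and its worked example reuses component numbers across
features of one filter). The fit is EM with seeded k-means++ initialisation,
a log-likelihood gain threshold of 1e-6 (capped at 500 iterations) and a
variance floor of 1e-6 times the pool variance. Pools larger than 5e4 values
are subsampled (seeded) before fitting: the mixture is a density estimate
and more points change it negligibly while the E-step cost is linear in n.

`encode_case()` computes, per filter f and component k,

    G_fk = 1/(T sqrt(w_k))   * sum_t gamma_k(x_t) (x_t - mu_k)/s_k
    H_fk = 1/(T sqrt(2 w_k)) * sum_t gamma_k(x_t) [((x_t - mu_k)/s_k)^2 - 1]

— the closed-form Fisher-information-normalised gradients of the bag
log-likelihood with respect to mu_k and s_k. "Improved" post-processing is
element-wise signed square root followed by global L2 normalization, the
standard variance-stabilising refinement from the Fisher-vector literature;
both steps are flags so the raw vector is also available. The descriptor
layout is this package's canonical one, `idx(f, k, order) = f*2K + order*K +
k` (0-based), documented and versioned in `descriptor_index()`; published
feature numberings from other implementations are not reconstructible and we
do not attempt to match them. Responsibilities are computed in log space.

Two properties pin the implementation down in the test suite: equality with
a literal double-loop evaluation of the formulas on random small instances,
and the defining consistency property that descriptors of responses sampled
from the fitted mixture itself shrink toward zero as T grows.

## Selection and classification

`ttest_filter()` is the unpaired pooled-variance two-sample t-test per
dimension at alpha = 0.05 with *no* multiplicity correction — deliberately
faithful to the protocol. (The protocol's summary says "paired t-tests", its
methods say "Student's t-test"; the two phenotype groups are independent
patients, so the unpaired test is the defensible reading.) `fscore_rank()`
implements the feature-selection F-score (between-class over within-class
scatter); `select_top()` keeps the m best, ties toward the lower index.
The protocol never prints m; the default is 100, and the desk-scale
experiments use m = 50.

`loocv_predict()` re-runs the *entire* selection inside every fold, so the
held-out case never influences which features the SVM sees. Features are
z-scored with training-fold statistics before the SVM (a linear SVM at C = 1
is scale-sensitive; whether the original pipeline standardized is unstated —
this is our choice, applied uniformly). The decision threshold for the
confusion metrics is 0 on the SVM decision score; the ROC is built from the
continuous score with half-credit for ties (Mann-Whitney). MCC and the
predictive values return 0 with a warning when undefined.
`time_split_predict()` fits once on cases diagnosed up to a cutoff and
evaluates once on the later cases, mirroring the before/after-2015 split
protocol.

## The phantom generator

`generate_phantom()` emulates only what the pipeline needs from a
co-registered, skull-stripped low-grade-glioma scan:

* an ellipsoidal tumor (analytic mask = exact ground truth) with in-plane
  semi-axes drawn from `tumor_radius_range` (default 8-13 voxels inside
  64x64x8 volumes, leaving the required one-patch-half-width margin) and a
  fixed through-plane semi-axis of `floor(nz/2) - 1`;
* tumor contrast +3 intensity units over a zero background;
* an internal unit-variance texture: white Gaussian noise smoothed by an
  isotropic Gaussian of class-dependent correlation length (class 0: 4
  voxels, class 1: 1.2 voxels). One scalar knob controls phenotype
  separability; the class with the shorter correlation length carries
  strictly more in-mask high-frequency energy (`mask_highfreq_energy()`),
  which is what the deep filters can pick up — a deliberately simplified
  analogue of wild-type lesions looking more internally complicated than
  mutants;
* i.i.d. Gaussian noise of sd 0.5 everywhere;
* `diagnosis_time` equal to the case index, making the time split exact and
  deterministic.

What the phantom does *not* model: brain anatomy, bias fields, registration
error, partial-volume effects, scanner variation, irregular lesion shape.
Tests passing on phantoms therefore demonstrate that the machinery is
correct and that the pipeline can recover a texture-borne phenotype; they do
not demonstrate clinical performance, which in the published setting was
established on a private 151-patient cohort that is not redistributable.

## Desk-scale study conditions

The heavy experiments are scaled so the whole suite runs on a laptop CPU:

* **Segmentation** (`run_segmentation_experiment()`): reduced network with 2
  convolutional layers (8 and 16 filters) and 64 fc neurons, 5,000 patches,
  10 epochs, 8 training phantoms of 64x64x8 voxels, one held-out phantom.
  The held-out Dice coefficient lands around 0.95, far above the 0.6 sanity
  bar; at full protocol scale the published networks reach similar territory
  on real low-grade gliomas.
* **Phenotype recovery** (`run_phenotype_experiment()`): 40-case cohort
  (20 per class), ground-truth masks, the same reduced network trained
  briefly (2,000 patches, 3 epochs), K = 8 mixture components, top m = 50
  features, LOOCV. With the default (strongly separated) texture classes the
  AUC is essentially perfect; with both classes given the same correlation
  length the AUC stays near chance, confirming no leakage anywhere in the
  selection-inside-folds machinery.

The 2-conv/8-16-filter reduction is the package's chosen small
configuration; every width is a `network_spec()` argument, so the 6-layer
reference architecture is one call away (building it allocates the full
4096-neuron fully connected stack, ~230M parameters).

## Numerical choices and degenerate inputs

* Constant patches (zero variance in a channel) cannot be standardized and
  raise a typed condition; the samplers drop and log them. At inference,
  constant windows are mapped to all-zero inputs rather than erroring.
* Bicubic resampling uses the Keys kernel (a = -0.5) with border clamping
  and row-renormalised weights, so constants are reproduced exactly.
* Gaussian smoothing in the generator uses row-normalised truncated kernels,
  avoiding intensity droop at volume borders.
* The EM variance floor prevents component collapse onto duplicated values;
  posteriors and mixture densities are evaluated in log space throughout.
* `roc_auc()` on all-tied scores returns exactly 0.5; empty confusion
  denominators return 0 with warnings rather than NaN.
* All randomness flows through explicit seeds (`with_seed` restores the
  caller's RNG state); identical seeds reproduce cohorts, patch sets,
  networks and descriptors bit for bit.

## Known limitations

* The CNN engine is plain (vectorised) R over BLAS; it is sized for the
  desk-scale experiments above, not for training the full 6-layer/4096
  network on clinical volumes.
* Axial-only 2-D processing is inherited from the protocol; no 3-D
  convolutions, and no intra-tumor subregion labelling.
* The exact published fully connected/pooling schedule and Fisher-vector
  formula variant live in supplementary material that is not restated here;
  the standard forms implemented (no pooling needed at these depths;
  signed-sqrt + L2 improved FV) are flagged as such above.
* No DICOM ingestion; volumes enter as NIfTI plus a CSV manifest.
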