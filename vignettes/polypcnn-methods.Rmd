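---
title: "Classifying colorectal polyps on CT colonography with deep ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying colorectal polyps on CT colonography with deep ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

CT colonography detects colorectal polyps non-invasively, but it cannot by
itself tell a premalignant polyp (an adenoma, which warrants endoscopic
resection) from a benign one (a hyperplastic polyp or regular mucosa,
which does not). `polypcnn` implements a deep-learning approach to this
discrimination: small 3D convolutional networks read a 50^3-voxel HU
subvolume centred on a polyp and output a score between 0 (benign) and 1
(premalignant). Two model variants are provided:

* **SEG** — two input channels: the CT image and a binary expert
  segmentation mask of the polyp;
* **noSEG** — one input channel: the CT image only, so no expert
  segmentation is needed at prediction time.

Because single small CNNs trained on small cohorts have high variance,
each model is a *deep ensemble*: many members (50 in the reference
configuration) are trained independently, each on its own random 80-20
train-validation split, and the model score is the unweighted arithmetic
mean of the member scores.

## Member architecture

Each member is a 3D residual CNN. Block $b \in \{1,2,3\}$ maps its input
through a main branch of two $3^3$ convolutions with $F_b \in
\{16, 32, 64\}$ filters (the first at stride 2, both ReLU-activated)
while a shortcut branch applies a single-filter $3^3$ stride-2
convolution to the block input; the one-channel shortcut output is
broadcast-added to every main-branch channel. Spatial sizes follow
$50 \to 25 \to 13 \to 7$ (ceil-mode "same" padding; floor-mode
downsampling would give $12$ and $6$ and is therefore not used). After
block 3 the $7^3 \times 64$ features are globally average-pooled to a
64-vector, passed through dropout, and mapped by a dense unit with a
logistic output.

Two wiring details are worth recording. First, the shortcut carries a
*single* filter whose output is broadcast across all $F_b$ main-branch
channels; this is the only wiring consistent with a one-filter shortcut
kernel and a block output that carries $F_b$ channels. Second, no batch
normalisation is used anywhere. Both choices have strong consequences for
optimisation (below).

The network, including the convolution forward/backward passes, is
implemented in C++ over single-precision BLAS matrix products (im2col +
GEMM, one sample at a time so the working set stays cache-resident);
there is no deep-learning framework underneath. The analytic gradients
are finite-difference checked in development, and the training loop is
exercised end-to-end by the test suite.

## Training, and why this architecture is hard to optimise

The reference training configuration is plain SGD (learning rate 0.01),
binary cross-entropy, batch size 8, random-crop data augmentation (plus
label-invariant axis flips and right-angle rotations applied to all
channels identically), and early stopping on the validation AUC: when a
member's validation AUC has not strictly exceeded its running maximum
for `patience_epochs` (64 by default) consecutive epochs, training stops
and the best-epoch weights are restored. Validation inputs are never
augmented, only centre-cropped to $50^3$.

Three structural properties make this architecture genuinely difficult
to train at small sample sizes, and the package exposes documented,
optional remedies for each:

* **Ill-conditioned pooled features.** With no normalisation layers,
  rectified activations accumulate large means; after global average
  pooling, the feature means exceed their between-sample spread by two
  orders of magnitude, which leaves plain SGD on a long plateau.
  `training_params(center_init = TRUE)` (the default) applies an
  LSUV-style data-dependent initialisation: every convolution is scaled
  to unit pre-activation variance and centred on a reference batch, and
  the final block is rescaled so the pooled features have unit
  between-sample spread.
* **Exploding shortcut gradients.** The single-filter shortcut receives
  the gradient summed over all block channels, so momentum-accelerated
  SGD diverges easily; `clip_norm` bounds the global gradient norm.
* **Slow plateau escape.** Even so, plain SGD needs several hundred
  updates before generalisable features emerge. The desk profile
  therefore uses the adaptive optimiser (`optimizer = "adam"`,
  learning rate 1e-3); the training-parameter contract treats the
  optimiser like every other overridable field, and the `reference` profile
  keeps pure SGD.

### Profiles

* `reference`: 50 members, SGD at 0.01, batch 8, patience 64, up to 1000
  epochs, dropout 0.5, per-segmentation splits — the reference
  configuration.
* `desk`: 5 members, Adam at 1e-3, patience 6, at most 50 epochs,
  dropout 0.3, gradient clip 6, patient-grouped splits. The grouping
  matters: supine and prone renderings of one polyp share the lesion
  shape, so per-segmentation splits let members "validate" on siblings
  of training lesions and early stopping then tracks memorisation
  rather than generalisation.

## Synthetic phantom cohorts

No patient data ship with the package. The phantom module generates
CT-colonography-like subvolumes on which every downstream stage is
testable: an air lumen (about $-1000 \pm 30$ HU), a flat soft-tissue
wall ($40 \pm 20$ HU) through the grid centre, and one polyp protruding
from the wall into the lumen. A polyp is a star-convex body whose radius
is modulated by smooth angular bumps (12 broad lobes plus 24 fine
surface bumps, so large amplitudes read as spiculated); the radius field
is renormalised so the maximum antipodal radius sum equals the requested
diameter, keeping the mask-measured maximum 3D diameter close to
`diameter_mm` at any lobulation.

The class contrast at separability $s$:

* lobulation: benign 0.08, premalignant $0.08 + 0.42s$;
* intra-polyp heterogeneity: benign 5 HU, premalignant $5 + 75s$ HU,
  applied as a positively skewed, mostly coarse (correlation length of
  several mm) Gaussian field — the "mottled" look of heterogeneous
  adenomatous tissue with bright (enhancing or calcified) nests. The
  positive skew is deliberate: a sign-symmetric field is a pure variance
  signal, which a global-average-pooled network cannot express without
  long feature learning;
* size: the class-conditional mixes over the $\le 5 / 6\!-\!9 / \ge 10$
  mm strata deviate from the pooled `size_mix` in proportion to $s$,
  premalignant polyps skewing large — mirroring the strong size-class
  association of real screening cohorts. At $s = 0$ all three contrasts
  vanish and the two classes are generated from one distribution.

Every polyp is rendered in supine and prone positions sharing the lesion
geometry (same shape seed) with independently re-simulated noise, the
prone rendering additionally rotated by a random right angle about the
body axis; multiple polyps per patient are supported, and class labels
match the requested prevalence up to rounding.

What the phantoms do **not** emulate: colonic anatomy and haustral
folds, residual fluid/tagging artefacts, scanner physics, partial-volume
effects, or the histopathologic spectrum. Passing tests on phantoms
demonstrate that the pipeline's machinery (training, ensembling,
thresholding, attention mapping) behaves as specified — not that trained
weights would transfer to patient data. Conversely, the phantom task is
*harder* than it looks for this architecture: the lesion occupies only a
few percent of the subvolume, and at desk scale (about a hundred
training segmentations, a few dozen epochs) members typically recover
the size-mediated part of the signal and only part of the
texture-mediated part.

## Grad-CAM++ attention maps

For the image-only variant, Grad-CAM++ class-activation volumes quantify
where the model looks. Maps are computed at the final convolutional
stage (the third residual add, $7^3 \times 64$), the conventional choice
of last spatial feature map. Because the head is global average pooling
into a single dense unit, the gradient of the pre-logistic score with
respect to feature channel $k$ is spatially constant ($w_k / 343$), and
the class-score exponential in the Grad-CAM++ channel weights cancels
under the final normalisation; the implementation keeps the general
formulas with these simplifications noted inline. The rectified weighted
feature sum is upsampled trilinearly to the input grid
(nearest-neighbour would quantise coverage fractions) and normalised by
its maximum, all-zero maps remaining zero, so activations lie in
$[0,1]$. For an ensemble, member maps are averaged and re-normalised.

The attention statistic is the fraction of voxels inside the expert mask
with activation at or above 0.25 (threshold inclusive); the cohort value
is the unweighted mean over segmentations. Masks enter only as
evaluation references — the scored inputs are image-only. The matched
background used by the attention tests is the mask translated along x at
the same interface height, i.e. the most conservative control.

## Evaluation protocol

Histopathologic categories map to classes as: regular mucosa,
hyperplastic and lipomatous polyps are benign; tubular, tubulovillous,
villous and serrated adenomas and adenocarcinomas are premalignant.
Polyp size is the maximum 3D Euclidean distance between mask-voxel
centres, computed on boundary voxels (identical to the all-pairs
result), rounded half-up to integer millimetres and binned into
$\le 5 / 6\!-\!9 / \ge 10$ mm. The ROC-AUC is the Mann-Whitney statistic
with ties counted half. The classification threshold maximises
specificity subject to a sensitivity floor (80% by default) over the
midpoints of adjacent distinct scores plus sentinels, ties going to the
larger threshold; `score >= threshold` predicts premalignant. All
printed percentages are rounded half-up from exact integer fractions.
The threshold may be fitted on a calibration cohort or on the evaluated
scores themselves; the latter replicates the protocol in which the
operating point is chosen on the test set, and is used only when no
calibration manifest is supplied.

## Numerical choices and degenerate inputs

* Intensities are clipped to $[-1000, 400]$ HU (air through
  contrast-free soft tissue) and mapped affinely to $[0,1]$, exactly
  once per input.
* All network tensors are single precision; scores returned to R are
  doubles. Augmentation is single precision too.
* Coordinates are 0-based with axis order (x, y, z); crops use
  half-open windows $[c-25, c+25)$, and windows that exceed the volume
  are errors (no implicit padding).
* Early stopping uses *strict* improvement; a frozen network stops
  after exactly $1 + \text{patience}$ epochs. Single-class validation
  splits are rejected before training (the AUC would be undefined).
* The LSUV initialisation floors per-direction standard deviations so
  near-constant inputs are not amplified, and caps the pooled-feature
  rescaling factor.
* Empty masks are errors for sizing and coverage; all-zero activation
  maps are returned as zeros rather than renormalised.
* Every stage takes explicit integer seeds; ensembles record each
  member's split/init/train seed.

## Problem sizes used in the tests

The test suite exercises the full pipeline at desk scale: the recovery
experiment uses about 110 training and 60 test segmentations with a
5-member image-only ensemble (a 2-member two-channel ensemble is
reported alongside), the null control uses three independently seeded
small cohorts at separability 0 against a common test cohort, and the
contract checks use small toy datasets. These sizes are the package's
desk-scale reference conditions; the `reference` profile preserves the
reference configuration for full-scale runs.

## Known limitations

* The exact wiring of the printed layer table is ambiguous in one place
  (whether each block contains one or two residual adds); the
  single-add wiring implemented here is asserted against the printed
  output shapes.
* Activation functions, dropout rate, intensity normalisation, the full
  augmentation family, momentum and the weight initialisation are not
  fixed by the reference configuration; the package's choices are
  documented above and configurable.
* At desk scale this architecture under-fits the phantom task: single
  members approach honest validation AUC ~0.8 only after roughly a
  hundred epochs, so short-budget ensembles recover the class signal
  partially, and their attention maps concentrate on the air-tissue
  interface broadly rather than the lesion specifically. The test suite
  reports these quantities as measured.
* Real-data performance levels are not reproducible from phantoms and
  are out of scope for the test suite.
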