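# polypcnn

Deep ensembles of small 3D residual convolutional networks for
differentiating **premalignant** (adenomatous) from **benign** colorectal
polyps on CT colonography subvolumes, with Grad-CAM++ volumetric attention
maps and a fixed-sensitivity ROC evaluation protocol.

CT colonography finds polyps but cannot tell which ones need endoscopic
resection. This package implements a deep-learning classifier for that
decision: a member CNN reads a 50×50×50-voxel HU subvolume centred on a
polyp and outputs a score in [0, 1] (0 = benign, 1 = premalignant). Two
model variants exist — **SEG** (two channels: image + expert segmentation
mask) and **noSEG** (image only) — and each model is an ensemble whose
score is the arithmetic mean over members trained on independent random
80–20 train–validation splits with early stopping on validation AUC.

The member network is three residual blocks (main branch: two 3×3×3
convolutions with 16/32/64 filters, the first at stride 2; shortcut: a
single-filter strided 3×3×3 convolution broadcast-added across channels),
spatial sizes 50 → 25 → 13 → 7, global average pooling to 64 features,
dropout, and a logistic output unit. The classification threshold is
chosen to maximise specificity subject to a sensitivity floor (80 % by
default); Grad-CAM++ maps quantify attention as the fraction of mask
voxels with class activation ≥ 0.25.

No patient data are required anywhere: a phantom module simulates
CT-colonography-like subvolumes (air lumen, soft-tissue wall, one polyp at
the interface; benign = smooth/homogeneous/small-skewed, premalignant =
lobulated/heterogeneous/large-skewed, with a tunable class
`separability`), so the entire pipeline is testable end to end. The
convolution forward/backward passes are implemented in the package itself
(C++ over single-precision BLAS); no deep-learning framework is needed.

## Worked example

Simulate cohorts, train a small image-only ensemble at the desk-scale
profile, and evaluate it:

```r
library(polypcnn)

train_cohort <- generate_cohort(n_patients = 55, separability = 1, seed = 501)
test_cohort  <- generate_cohort(n_patients = 28, separability = 1, seed = 502)

params <- training_params(optimizer = "adam", learning_rate = 1e-3,
                          patience_epochs = 6, max_epochs = 50,
                          clip_norm = 6, dropout_rate = 0.3)
ds  <- build_model_inputs(train_cohort, "noSEG")
ens <- train_ensemble(ds, "noSEG", n_members = 5, base_seed = 42,
                      params = params, group_splits = TRUE)
ens
#> <polyp_ensemble> noSEG, 5 members (base seed 42)
#>   member validation AUC: median 0.724, range 0.667-0.964

ts     <- build_model_inputs(test_cohort, "noSEG", crop = "centre")
report <- evaluate_ensemble(ens, ts)
report
#> <polyp_eval> noSEG: AUC 0.670, threshold 0.260 (evaluation)
#>   sensitivity: 81% (29 of 36)
#>   specificity: 39% (15 of 38)
#>   subgroup AUC: <=5mm 0.56 (n=18), 6-9mm 0.53 (n=32), >=10mm 0.18 (n=24)

cov <- cohort_coverage(ens, test_cohort)
cov
#> <coverage_result> 74 segmentations, mean coverage 44.2% at threshold 0.25
```

Reading the output: ranking the 74 test segmentations by ensemble score
separates premalignant from benign with AUC 0.67 — at this desk scale
(about a hundred training segmentations, a few dozen epochs per member)
the ensemble recovers the class signal only partially, which the methods
vignette discusses in detail: this architecture has no normalisation
layers and needs on the order of a hundred epochs per member before its
validation AUC approaches 0.8. At the threshold chosen for 80 %
sensitivity, 29 of 36 premalignant and 15 of 38 benign segmentations are
classified correctly. The coverage result says that on average 44 % of
expert-labelled polyp voxels receive a Grad-CAM++ class activation of at
least 0.25. Exact numbers depend on the platform BLAS/compiler;
regenerate them with the snippet above (about 8 minutes on one CPU core).

`tidy(report)`, `glance(report)` and `autoplot(report)` give a per-metric
tibble, a one-row summary, and the ROC curve;
`plot_heatmap_overlay(volume, gradcampp(ens, input))` renders orthogonal
slices of the attention map.

A command-line wrapper for the simulate/train/predict/explain/evaluate
stages ships in `inst/cli/polypcnn.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/polypcnn.R", package="polypcnn"))')" \
    simulate --config cfg.yaml
```

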