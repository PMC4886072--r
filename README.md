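# vrrf — voting-ranking random forests for single-cell H&E image classification

`vrrf` is an R package for classifying single liver-cell images from
hematoxylin–eosin (H&E) stained pathology sections as **normal** or
**hepatocellular carcinoma (HCC)**. It is aimed at computational-pathology
researchers who need a complete, reproducible, grayscale single-cell
pipeline: denoising, nucleus segmentation into fixed-size crops, a
hand-crafted feature battery centered on nuclear *atypia*, and a
random-forest variant with a calibrated decision threshold.

## What is inside

**Segmentation.** After bilateral filtering and Otsu thresholding (nuclei
are dark, so foreground is *below* threshold), the center-proliferation
segmentation (CPS) step keeps connected regions with circularity
4πA/L² > 0.85 and grows a 51×51 window outward from each region center,
emitting three crops per cell: the binary mask (SBCI), the fixed-size gray
crop (SNSCI) and the gray bounding-rectangle crop (SMERCI).

**Features** (296 per cell): atypia — auxiliary circularity
C_f = 4πA / ((6.8/A + 0.625)·L²), amendment circularity
C_w = 4A / (π(w² + h²)), and cell symmetry
Sym = |F_a−F_b| + |F_a−F_c| + |F_b−F_d| + |F_c−F_d| over quadrant
box-counting dimensions of the Canny edge map; shape (area, perimeter,
roundness, elongation, rectangularity); fractal (box-counting dimension
plus 7 multifractal values D_q for q ∈ {−2..2}, Δα, Δf); gray texture
(mean, sd, entropy, 256-bin LBP histogram, 16 GLCM statistics, 5 Tamura
features).

**Classifier.** The voting-ranking random forest (VRRF) replaces the fixed
majority threshold (e.g. 250 of 500 trees) of a conventional forest: M = 50
calibration iterations each refit a bagged CART ensemble, take the maximum
HCC vote count as a candidate threshold and record its accuracy; the
candidates are ranked by accuracy, the top K·M = 30 % are averaged into the
final threshold `t_mean`, and a forest refit on all data predicts HCC
whenever its HCC vote count reaches `t_mean`.

**Evaluation.** Accuracy, sensitivity (HCC recall) and specificity (normal
recall) under repeated stratified 10-fold cross-validation.

Because the pipeline's reference data are hospital slides that are not
distributable, the package ships a synthetic tissue generator with exact
ground-truth masks: dark cell blobs on a textured brighter background, with
class differences in mean intensity, intensity heterogeneity and boundary
roughness that mirror the atypia the features measure.

## Worked example

```r
library(vrrf)

# a labeled synthetic crop dataset (60 cells per class)
ds    <- generate_crop_dataset(synthetic_config(seed = 1), n_per_class = 60)
feats <- extract_features(ds$crops, labels = ds$labels)
x     <- as.matrix(feats[, -(1:2)])

train <- rep(c(TRUE, FALSE), length.out = nrow(x))
fit   <- vrrf(x[train, ], feats$label[train], n_trees = 100, M = 20, seed = 1)
fit
#> Voting-ranking random forest
#>   trees: 100   calibration iterations M: 20   K: 0.3 (oob votes)
#>   calibrated vote threshold t_mean: 41.67 (fixed-threshold RF would use 50)
#>   classes: normal / HCC (positive: HCC)

confusion_metrics(predict(fit, x[!train, ]), feats$label[!train])
#> confusion (positive = HCC): TP 30  FN 0  TN 30  FP 0
#>   ACC 1.0000  SEN 1.0000  SPE 1.0000
```

The calibrated threshold (41.67 of 100 trees) sits below the fixed majority
threshold: the calibration ranks candidate thresholds by out-of-bag
accuracy and its tie-breaks lean toward sensitivity, so the model is
slightly more eager to call HCC. On the held-out half of the synthetic
crops the classifier is exact; the class-wise feature shifts driving this
(HCC cells darker by ~13 gray levels, noisier by ~19, lower amendment
circularity, higher asymmetry) match the atypia the features were designed
to capture.

The full image-to-report pipeline is one call:

```r
res <- run_pipeline(pipeline_config(n_images = 6, n_trees = 100, M = 10,
                                    cv_k = 5, cv_repeats = 1, seed = 4),
                    out_dir = "out")
res$cv$grand_mean   # cross-validated accuracy on segmented, labeled cells
#> [1] 1
```

A thin command-line front end with `simulate`, `segment`, `extract`,
`train`, `predict`, `evaluate` and `run` subcommands is installed at
`inst/cli/vrrf-pipeline.R`.

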