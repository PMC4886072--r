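---
title: "Methods: single-cell H&E classification with voting-ranking random forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell H&E classification with voting-ranking random forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vrrf)
```

## The problem

Hematoxylin–eosin (H&E) stained liver sections are the reference material
for diagnosing hepatocellular carcinoma (HCC). At the single-cell level the
malignant phenotype shows up as *atypia*: nuclei that are darker ("deeper
dye"), more unevenly stained, and less regular in outline than normal liver
nuclei. This package implements a complete pipeline that turns a grayscale
H&E field of view into per-cell class decisions:

1. **Preprocess** — edge-preserving bilateral filtering.
2. **Segment** — Otsu coarse segmentation plus morphological correction,
   then *center-proliferation segmentation* (CPS), which grows a fixed-size
   window outward from each round region's center and emits three crop
   formats per cell: the binary mask crop (SBCI), the fixed n×n gray crop
   (SNSCI), and the bounding-rectangle gray crop (SMERCI).
3. **Describe** — a 296-dimensional feature battery: atypia, shape, fractal
   and gray-level texture features.
4. **Classify** — a voting-ranking random forest (VRRF): a bagged CART
   ensemble whose decision threshold on HCC votes is calibrated by ranking
   candidate thresholds by achieved accuracy.
5. **Evaluate** — accuracy, sensitivity, specificity under repeated
   stratified k-fold cross-validation.

Color is deliberately discarded: stain batch and staining time shift H&E
hues so much that color features are unreliable, so every stage operates on
luminance.

## Preprocessing

The bilateral filter weights each neighbor by the product of a spatial
Gaussian (distance) and a range Gaussian (intensity difference), so flat
regions are averaged while strong edges — nuclear boundaries — are left in
place. Because the weights are non-negative and normalized, each output
pixel is a convex combination of the intensities in its window; the test
suite asserts this bound directly. No reference values for the filter
parameters exist for this pipeline, so the package chooses mild smoothing:

| parameter | default | unit | rationale |
|---|---|---|---|
| `sigma_spatial` | 3 | px | smooths texture at scales well below the ~16 px nuclear radius |
| `sigma_range` | 25 | gray levels | averages within-nucleus noise (~5–15 levels) but not across the ~60-level nucleus/background step |
| `radius` | `ceiling(2*sigma_spatial)` | px | truncation beyond 2 sigma changes weights negligibly |

Borders are reflect-padded; zero padding would ring a dark frame around the
image and bias the global threshold.

## Segmentation

"Coarse" segmentation is Otsu's parameter-free global threshold with
foreground taken *below* the threshold (nuclei are dark), followed by a
3×3 binary opening, hole filling, and removal of components smaller than
`min_area = 30` px. All three corrections are configurable.

CPS then filters regions by circularity $4\pi A/L^2 > 0.85$ (strict
inequality) and cuts windows. Three conventions matter and are therefore
fixed and documented:

* **Perimeter** is the 8-connected boundary chain length (axial steps 1,
  diagonal steps $\sqrt2$), measured by Moore-neighbor tracing. The
  perimeter convention decides which regions pass the 0.85 cut; with this
  convention digitized disks of radius ≥ 8 px score 0.93–0.97 and pass,
  while bars and merged clumps fail. Digitization lets tiny regions exceed
  1; the suite asserts the value stays ≤ 1.1 for blob-sized regions.
* **Circularity for filtering** is the plain isoperimetric ratio, not the
  corrected atypia circularities below — those are features, extracted
  later, not filters.
* **Crop geometry**: windows are `n = 51` px (odd, so a center pixel
  exists); a window that would cross the image border discards its cell
  rather than padding, because padded pixels would inject artificial
  texture into the LBP/GLCM/Tamura block. After the central component is
  isolated (ties between equidistant components go to the larger one), the
  window is re-extracted centered on the refined centroid, so SBCI and
  SNSCI share one center. The SMERCI is the axis-aligned bounding box of
  the kept component — no rotated rectangle, consistent with the width and
  height entering the amendment circularity. Neighboring cells clipped by
  the window are kept in the gray crops (separating touching nuclei is out
  of scope).

## Features

### Atypia

* Auxiliary circularity $C_f = 4\pi A \,/\, \big((6.8/A + 0.625)\,L^2\big)$.
  The correction factor $(6.8/A + 0.625)$ is stated without derivation in
  the source method and its constants are pixel-scale dependent; the
  package treats the factor as dividing the plain circularity (so the
  large-$A$ circular limit is $1/0.625 = 1.6$) and offers the
  multiplicative reading behind `feature_config(cf_form = "multiply")`.
* Amendment circularity $C_w = 4A / \big(\pi(w^2 + h^2)\big)$: nuclear area
  over the area of the circle circumscribing the bounding rectangle. A
  filled square scores $2/\pi$, a disk 0.5; ragged nuclei waste bounding
  box and score lower.
* Cell symmetry: the SBCI is edge-detected (Canny, $\sigma = 1$,
  hysteresis thresholds at the 10th/90th gradient-magnitude percentiles),
  split at the central row/column into quadrants a, b, c, d (center
  row/column assigned to the top/left halves — the split convention is
  arbitrary but must be fixed for the quadrant sizes to be reproducible),
  and each quadrant's box-counting dimension is computed. Then
  $Sym = |F_a-F_b| + |F_a-F_c| + |F_b-F_d| + |F_c-F_d|$. Near-circular
  cells have matching quadrants and $Sym \approx 0$.

### Shape

Area, chain-length perimeter, roundness $4\pi A/L^2$, elongation
(major/minor axis ratio from second central moments, with the $1/12$
per-pixel variance correction so a $w \times h$ rectangle scores exactly
$\max(w,h)/\min(w,h)$), and rectangularity $A/(wh)$.

### Fractal

Both estimators share one ladder of grid box sizes: the initial box is one
tenth of the shorter image side, halved down to 1 px.

* The box-counting dimension is the least-squares slope of $\log N(\epsilon)$
  against $\log(1/\epsilon)$.
* The multifractal block reports generalized (Rényi) dimensions $D_q$ for
  $q \in \{-2,-1,0,1,2\}$ from box-measure moments ($D_1$ via its entropy
  limit), plus the singularity-spectrum widths $\Delta\alpha$ and
  $\Delta f$ from the moment method — 7 values. Boxes that extend past the
  image border are excluded from the measure: their truncated support
  gives them artificially small mass, which severely biases negative-$q$
  moments (a uniform square would otherwise report $D_{-2} \approx 1.5$
  instead of 2). With complete boxes only, the suite verifies
  $D_q \approx 2$ for a filled square, $D_q \approx 0$ for a point, and
  $D_0$ equal to the box-counting dimension on random blobs.

### Gray-level texture (on the SNSCI)

* mean and population sd of the gray values; first-order entropy
  $H = -\sum_i p_i \log_2 p_i$ over 256 bins;
* LBP: one 8-bit code per interior pixel (strictly-greater comparison,
  bits clockwise from the top-left neighbor, MSB first), histogrammed into
  256 normalized bins. The per-pixel reading keeps the descriptor well
  populated on a 51×51 crop (2 401 codes over 256 bins) where a
  one-code-per-3×3-block reading would not;
* GLCM: 16 quantization levels, symmetric normalized matrices at 8 offsets
  (4 directions × distances 1 and 2); ASM, entropy (natural log), contrast
  and correlation per matrix, then mean and variance across directions per
  distance → 16 values. The correlation uses the standard marginal
  means/standard deviations; a degenerate marginal (constant image) yields
  correlation 0 by convention;
* Tamura coarseness, contrast, directionality, linelikeness, roughness
  (regularity omitted). Coarseness uses best-window averaging over windows
  $2^k$, $k = 1..5$; neighborhood differences whose windows would cross
  the image border are excluded, since border padding manufactures phantom
  edges that otherwise dominate the scale argmax on periodic textures.
  Directionality is the sharpness of a 16-bin Prewitt orientation
  histogram; linelikeness is the mean orientation-agreement cosine at
  distance 4 along the local edge direction.

The SMERCI can optionally receive the same gray block
(`feature_config(include_smerci = TRUE)`, default off — compact cells can
produce bounding boxes too small for the texture window ladder).

## The voting-ranking random forest

A conventional random forest predicts HCC when more than half of the trees
vote HCC. VRRF replaces that fixed threshold with a calibrated one:

1. Fit a bagged ensemble of `n_trees = 500` CART trees (Gini, $\sqrt d$
   features per split, grown to purity).
2. Collect per-sample HCC vote counts on calibration samples.
3. Take the *maximum* observed HCC vote count as the candidate threshold.
4. Score that candidate's accuracy on the same votes.
5. Repeat `M = 50` times with fresh seeds → the *pending matrix* of
   (candidate, accuracy) pairs.
6. Rank by accuracy (high to low; ties broken toward the smaller
   candidate, which favors sensitivity), keep the top `ceiling(K*M)` with
   `K = 0.3`, and average their candidates into the final threshold
   `t_mean`.
7. Refit one forest on all training data; at test time predict HCC iff
   the HCC vote count is `>= t_mean` (ties go to HCC — missing a carcinoma
   cell is the costlier error).

Two design points were genuinely open and are resolved as follows:

* **Which votes feed the calibration.** Training-set votes of purity-grown
  trees are memorized (every HCC training sample approaches a unanimous
  vote), so the candidate would pin at `n_trees` and the accuracy ranking
  would carry no information. The default therefore uses each sample's
  *out-of-bag* votes — the votes of the roughly `exp(-1) * n_trees` trees
  that did not see the sample. The candidate (a maximum over OOB counts)
  then lands slightly above the mean OOB tree count, i.e. near
  `0.4 * n_trees` once compared against full-ensemble votes at prediction
  time: a sensitivity-leaning operating point, consistent with replacing
  the fixed majority threshold. The literal training-vote variant remains
  available (`calibration = "train"`).
* **Which forest accompanies the threshold.** Each calibration iteration
  refits its own forest; the deployed model is a final forest refit on all
  training data under the base seed — standard bagging practice that
  wastes no data and keeps the reduction property exact: with `M = 1`,
  `K = 1` and the threshold forced to `n_trees/2`, predictions are
  identical to a plain majority-vote forest fit under the same seed (a
  tested invariant).

## Evaluation

Sensitivity is the proportion of HCC cells correctly classified,
specificity the proportion of normal cells; accuracy is their
prevalence-weighted blend (asserted algebraically in the tests). Ratios
with empty denominators are reported as `NA`, never silently as 0.
Cross-validation is stratified — with a strongly imbalanced dataset,
unstratified folds risk single-class test folds — and each repeat
reshuffles under a derived seed, so a fixed base seed reproduces the whole
table bit-for-bit.

## The synthetic benchmark

No public single-cell H&E dataset accompanies this method, so the package
ships a generator that emulates the statistical structure the pipeline
relies on: dark, roughly circular nuclei on a brighter textured background
(`background_noise_sd = 5` keeps thresholding and denoising non-trivial);
normal cells near-circular and brighter (mean 150); HCC cells darker
(mean 110), noisier inside (2.5× the normal within-cell sd), and with a
radially perturbed boundary — a truncated Fourier series over harmonics
2–5 with random phases, normalized to unit variance and scaled by
`hcc_boundary_roughness = 0.08`. That roughness keeps most HCC cells above
the 0.85 segmentation cut (mimicking a filter tuned to pass single intact
nuclei) while still separating the shape-feature distributions at
realistic effect sizes. Default fields are 384×384 px with 20 cells of
mean radius 16 px at ≥ 56 px spacing.

What the generator does *not* emulate — and what passing tests therefore
do not certify on clinical material: touching and overlapping nuclei,
stain gradients and batch effects, chromatin substructure, stromal
clutter, and any color information. Results on the synthetic benchmark
validate the machinery (contracts, conventions, invariances, end-to-end
determinism and separability), not clinical accuracy.

## Numerical conventions and degenerate inputs

* All intensities are 0–255 doubles; images are plain R matrices indexed
  `[row, col]`; generated images are rounded to 8-bit levels.
* Reflect padding everywhere a window leaves the image (filtering,
  convolution), except where a contract says "discard" (CPS windows) or
  "exclude" (fractal boxes, Tamura windows).
* Constant images: the bilateral filter is an exact identity; Otsu raises
  (threshold undefined); entropy and Tamura contrast are 0; GLCM has
  ASM 1, entropy 0, contrast 0, correlation 0 by convention.
* Empty masks: region lists are empty; fractal estimators raise.
* A single-pixel region has chain length 1 by convention, keeping
  circularity finite; such specks are normally removed by `min_area`.
* Seeds are plain integers; every derived seed stays far below $2^{31}$.

## Problem sizes

The shipped tests and the acceptance script run the classifier benchmark
at 200 samples per class with 100 trees and the full `M = 50` calibration,
and the end-to-end pipeline at 6 synthetic fields (~115 cells) with
5-fold cross-validation — sizes chosen so the whole suite documents the
method's behavior in about a minute while leaving every algorithmic
default (`M`, `K`, crop size, circularity cut) at its working value.
The fitted production configuration (500 trees, 10×10-fold CV) is the
package default.

## Known limitations

* The CPS stage deliberately refuses clusters (circularity cut) and
  border cells; recall on crowded tissue will be below the benchmark's.
* The auxiliary-circularity constants are pixel-scale dependent; features
  extracted at different magnifications are not comparable without
  recalibration.
* The candidate threshold is a *maximum* vote statistic, a conservative
  choice inherited from the method's definition; with OOB calibration it
  behaves like a slightly liberal majority vote, but its spread across
  iterations is small, so the accuracy ranking has limited leverage on
  strongly separable data.
* Binary classification only; grading into tumor stages would need a
  multi-class extension of the vote-threshold calibration.
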