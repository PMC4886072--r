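#' Configuration for the synthetic tissue-image generator
#'
#' Builds the parameter set used by [generate_tissue_image()] and
#' [generate_crop_dataset()]. The generator emulates a grayscale H&E field of
#' view: dark, roughly circular nuclei on a brighter, mildly textured
#' background. Two cell classes are simulated. Normal cells are near-circular
#' disks with a brighter, more homogeneous interior; carcinoma (HCC) cells
#' have a radially perturbed boundary, a darker mean intensity ("deeper dye")
#' and a larger within-cell intensity spread ("uneven dyeing").
#'
#' Boundary irregularity is modelled as a truncated Fourier series in polar
#' angle with random amplitudes and phases, giving smooth, controllable
#' perturbations and exact ground-truth masks: the radius at angle
#' \eqn{\theta} is \eqn{r(\theta) = r_0 (1 + \rho\, s(\theta))} where
#' \eqn{s} is a smooth zero-mean random function of unit standard deviation
#' and \eqn{\rho} is `hcc_boundary_roughness`.
#'
#' @param image_size integer length-2, image height and width in pixels.
#' @param n_cells number of cells to place.
#' @param class_mix fraction of cells that are HCC, in `[0, 1]`.
#' @param normal_radius_px,hcc_radius_px mean cell radius per class (pixels).
#' @param hcc_boundary_roughness amplitude of the radial boundary
#'   perturbation of HCC cells, as a fraction of the radius (>= 0). Normal
#'   cells are always generated with roughness 0 so that they pass the
#'   circularity filter of the segmentation stage.
#' @param normal_mean_intensity,hcc_mean_intensity mean interior gray level
#'   per class, in `[0, 255]`; must satisfy `normal > hcc` (cancer nuclei
#'   stain darker).
#' @param intensity_noise_sd per-pixel intensity noise inside normal cells
#'   (gray levels).
#' @param hcc_noise_factor multiplier applied to `intensity_noise_sd` inside
#'   HCC cells (> 1 emulates uneven dyeing).
#' @param background_intensity background gray level (brighter than both
#'   cell classes).
#' @param background_noise_sd gray-level standard deviation of the background
#'   texture; a non-zero value keeps thresholding and denoising non-trivial.
#' @param min_cell_spacing minimum pairwise distance between cell centers
#'   (pixels).
#' @param seed RNG seed; every generator is a pure function of its
#'   configuration and this seed.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(image_size = c(384L, 384L),
                             n_cells = 20L,
                             class_mix = 0.5,
                             normal_radius_px = 16,
                             hcc_radius_px = 16,
                             hcc_boundary_roughness = 0.08,
                             normal_mean_intensity = 150,
                             hcc_mean_intensity = 110,
                             intensity_noise_sd = 6,
                             hcc_noise_factor = 2.5,
                             background_intensity = 205,
                             background_noise_sd = 5,
                             min_cell_spacing = 56,
                             seed = 1L) {
  cfg <- list(
    image_size = as.integer(image_size),
    n_cells = as.integer(n_cells),
    class_mix = class_mix,
    normal_radius_px = normal_radius_px,
    hcc_radius_px = hcc_radius_px,
    hcc_boundary_roughness = hcc_boundary_roughness,
    normal_mean_intensity = normal_mean_intensity,
    hcc_mean_intensity = hcc_mean_intensity,
    intensity_noise_sd = intensity_noise_sd,
    hcc_noise_factor = hcc_noise_factor,
    background_intensity = background_intensity,
    background_noise_sd = background_noise_sd,
    min_cell_spacing = min_cell_spacing,
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (length(cfg$image_size) != 2L || any(cfg$image_size < 1L))
    stopf("image_size must be two positive integers")
  if (cfg$n_cells < 0L) stopf("n_cells must be >= 0")
  if (cfg$class_mix < 0 || cfg$class_mix > 1)
    stopf("class_mix must lie in [0, 1]")
  if (cfg$hcc_boundary_roughness < 0)
    stopf("hcc_boundary_roughness must be >= 0")
  ints <- c(cfg$normal_mean_intensity, cfg$hcc_mean_intensity,
            cfg$background_intensity)
  if (any(ints < 0 | ints > 255)) stopf("intensities must lie in [0, 255]")
  if (cfg$normal_mean_intensity <= cfg$hcc_mean_intensity)
    stopf("normal_mean_intensity must exceed hcc_mean_intensity (cancer cells stain darker)")
  if (cfg$normal_radius_px <= 0 || cfg$hcc_radius_px <= 0)
    stopf("cell radii must be positive")
  invisible(cfg)
}

cell_class_levels <- function() c("normal", "HCC")

# Smooth zero-mean radial perturbation: truncated Fourier series over
# harmonics 2..5 with random amplitudes/phases, normalized to unit sd.
radial_perturbation <- function() {
  harmonics <- 2:5
  amp <- stats::rnorm(length(harmonics))
  phase <- stats::runif(length(harmonics), 0, 2 * pi)
  norm <- sqrt(sum(amp^2) / 2)
  if (norm < 1e-12) { amp <- c(1, 0, 0, 0); norm <- sqrt(0.5) }
  function(theta) {
    s <- 0
    for (i in seq_along(harmonics))
      s <- s + amp[i] * cos(harmonics[i] * theta + phase[i])
    s / norm
  }
}

# Rasterize one blob into a logical mask of the given image size.
# Returns NULL if the blob would leave the image.
rasterize_blob <- function(center, radius, roughness, size) {
  s_fun <- radial_perturbation()
  rmax <- radius * (1 + 3 * roughness)
  lo_r <- max(1L, floor(center[1] - rmax)); hi_r <- min(size[1], ceiling(center[1] + rmax))
  lo_c <- max(1L, floor(center[2] - rmax)); hi_c <- min(size[2], ceiling(center[2] + rmax))
  rows <- lo_r:hi_r; cols <- lo_c:hi_c
  dy <- rows - center[1]
  dx <- matrix(cols - center[2], nrow = length(rows), ncol = length(cols), byrow = TRUE)
  dyM <- matrix(dy, nrow = length(rows), ncol = length(cols))
  dist <- sqrt(dyM^2 + dx^2)
  theta <- atan2(dyM, dx)
  rtheta <- radius * pmax(0.2, 1 + roughness * s_fun(theta))
  sub <- dist <= rtheta
  mask <- matrix(FALSE, size[1], size[2])
  mask[rows, cols] <- sub
  mask
}

#' Generate a synthetic tissue image with ground truth
#'
#' Renders `n_cells` dark cell blobs onto a brighter, noisy background and
#' returns both the 8-bit grayscale image and exact per-cell ground truth
#' (center, class label, pixel mask). Cell centers are placed by rejection
#' sampling with pairwise distance >= `min_cell_spacing` and a border margin
#' wide enough that a centered fixed-size crop window never clips.
#'
#' @param config a [synthetic_config()].
#' @param margin border margin for cell centers (pixels); defaults to a value
#'   that keeps a 51x51 crop window inside the image.
#' @return A list with components `image` (numeric matrix, gray levels
#'   0--255) and `truth`, itself a list with `centers` (n x 2 matrix of
#'   row/col), `labels` (factor `normal`/`HCC`) and `masks` (list of logical
#'   matrices, pairwise disjoint).
#' @export
generate_tissue_image <- function(config = synthetic_config(), margin = NULL) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  size <- config$image_size
  rad_max <- max(config$normal_radius_px, config$hcc_radius_px)
  margin <- margin %||% max(26, ceiling(rad_max * (1 + 3 * config$hcc_boundary_roughness)) + 2)

  img <- matrix(config$background_intensity, size[1], size[2]) +
    matrix(stats::rnorm(prod(size), 0, config$background_noise_sd), size[1], size[2])

  n <- config$n_cells
  if (n == 0L) {
    return(list(image = finalize_gray(img),
                truth = list(centers = matrix(numeric(0), 0, 2,
                                              dimnames = list(NULL, c("row", "col"))),
                             labels = factor(character(0), levels = cell_class_levels()),
                             masks = list())))
  }
  if (size[1] <= 2 * margin || size[2] <= 2 * margin)
    stopf("image too small for the requested cell radius/margin")

  n_hcc <- round(n * config$class_mix)
  labels <- factor(c(rep("normal", n - n_hcc), rep("HCC", n_hcc)),
                   levels = cell_class_levels())
  labels <- sample(labels)

  centers <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("row", "col")))
  placed <- 0L
  attempts <- 0L
  max_attempts <- 500L * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stopf("could not place %d cells at spacing %g within %d attempts",
            n, config$min_cell_spacing, max_attempts)
    cand <- c(stats::runif(1, margin + 1, size[1] - margin),
              stats::runif(1, margin + 1, size[2] - margin))
    if (placed > 0L) {
      d <- sqrt((centers[seq_len(placed), 1] - cand[1])^2 +
                (centers[seq_len(placed), 2] - cand[2])^2)
      if (any(d < config$min_cell_spacing)) next
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
  }

  masks <- vector("list", n)
  taken <- matrix(FALSE, size[1], size[2])
  for (i in seq_len(n)) {
    is_hcc <- labels[i] == "HCC"
    radius <- (if (is_hcc) config$hcc_radius_px else config$normal_radius_px) *
      stats::runif(1, 0.9, 1.1)
    rough <- if (is_hcc) config$hcc_boundary_roughness else 0
    mask <- rasterize_blob(centers[i, ], radius, rough, size)
    mask <- mask & !taken          # enforce disjoint ground-truth masks
    taken <- taken | mask
    masks[[i]] <- mask
    mu <- if (is_hcc) config$hcc_mean_intensity else config$normal_mean_intensity
    sd <- config$intensity_noise_sd * (if (is_hcc) config$hcc_noise_factor else 1)
    img[mask] <- mu + stats::rnorm(sum(mask), 0, sd)
  }

  list(image = finalize_gray(img),
       truth = list(centers = centers, labels = labels, masks = masks))
}

finalize_gray <- function(img) {
  img <- round(clamp(img, 0, 255))
  storage.mode(img) <- "double"
  img
}

#' Generate a labeled single-cell crop dataset
#'
#' Directly synthesizes centered single-cell crops in the three formats the
#' segmentation stage produces -- a binary mask crop (SBCI), a fixed-size
#' gray crop (SNSCI) and the gray bounding-rectangle crop (SMERCI) --
#' bypassing segmentation so that the feature and classifier stages can be
#' exercised in isolation. Class-dependent shape and intensity follow the
#' configuration.
#'
#' @param config a [synthetic_config()].
#' @param n_per_class number of crops per class (>= 1).
#' @param crop_size odd crop side length (default 51).
#' @return A list with `crops` (list of [cell_crop] objects) and `labels`
#'   (factor aligned 1:1 with `crops`).
#' @export
generate_crop_dataset <- function(config = synthetic_config(), n_per_class,
                                  crop_size = 51L) {
  validate_synthetic_config(config)
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 1L) stopf("n_per_class must be >= 1")
  crop_size <- as.integer(crop_size)
  if (crop_size %% 2L == 0L) stopf("crop_size must be odd")
  half <- (crop_size - 1L) %/% 2L
  for (cls in cell_class_levels()) {
    r <- if (cls == "HCC") config$hcc_radius_px else config$normal_radius_px
    rough <- if (cls == "HCC") config$hcc_boundary_roughness else 0
    if (ceiling(r * 1.1 * (1 + 3 * rough)) + 1 > half)
      stopf("crop_size %d cannot contain cells of radius %g", crop_size, r)
  }
  set.seed(config$seed)
  labels <- factor(rep(cell_class_levels(), each = n_per_class),
                   levels = cell_class_levels())
  center <- c(half + 1L, half + 1L)
  crops <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    is_hcc <- labels[i] == "HCC"
    radius <- (if (is_hcc) config$hcc_radius_px else config$normal_radius_px) *
      stats::runif(1, 0.9, 1.1)
    rough <- if (is_hcc) config$hcc_boundary_roughness else 0
    sbci <- rasterize_blob(center, radius, rough, c(crop_size, crop_size))
    gray <- matrix(config$background_intensity, crop_size, crop_size) +
      matrix(stats::rnorm(crop_size^2, 0, config$background_noise_sd),
             crop_size, crop_size)
    mu <- if (is_hcc) config$hcc_mean_intensity else config$normal_mean_intensity
    sd <- config$intensity_noise_sd * (if (is_hcc) config$hcc_noise_factor else 1)
    gray[sbci] <- mu + stats::rnorm(sum(sbci), 0, sd)
    gray <- finalize_gray(gray)
    bb <- mask_bbox(sbci)
    smerci <- gray[bb[1]:(bb[1] + bb[3] - 1L), bb[2]:(bb[2] + bb[4] - 1L), drop = FALSE]
    crops[[i]] <- cell_crop(sbci = sbci, snsci = gray, smerci = smerci,
                            center = center, n = crop_size)
  }
  list(crops = crops, labels = labels)
}

# bounding box as (min_row, min_col, height, width)
mask_bbox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) stopf("empty mask has no bounding box")
  c(min(w[, 1]), min(w[, 2]),
    max(w[, 1]) - min(w[, 1]) + 1L, max(w[, 2]) - min(w[, 2]) + 1L)
}

#' Generate a two-class Gaussian feature table
#'
#' Produces a multivariate-Gaussian two-class dataset for classifier tests:
#' the first `min(3, n_features)` dimensions differ in mean by `separation`
#' standard deviations between classes; the remaining dimensions are pure
#' noise.
#'
#' @param n_per_class samples per class.
#' @param separation between-class mean shift in sd units (>= 0).
#' @param n_features total feature count.
#' @param seed RNG seed.
#' @return list with `x` (numeric matrix, `2 * n_per_class` rows) and
#'   `labels` (factor `normal`/`HCC`).
#' @export
generate_feature_table <- function(n_per_class, separation, n_features = 10L,
                                   seed = 1L) {
  if (separation < 0) stopf("separation must be >= 0")
  n_per_class <- as.integer(n_per_class)
  n_features <- as.integer(n_features)
  if (n_per_class < 1L || n_features < 1L)
    stopf("n_per_class and n_features must be >= 1")
  set.seed(as.integer(seed))
  n <- 2L * n_per_class
  x <- matrix(stats::rnorm(n * n_features), n, n_features)
  labels <- factor(rep(cell_class_levels(), each = n_per_class),
                   levels = cell_class_levels())
  shift_dims <- seq_len(min(3L, n_features))
  x[labels == "HCC", shift_dims] <- x[labels == "HCC", shift_dims] + separation
  colnames(x) <- sprintf("f%02d", seq_len(n_features))
  list(x = x, labels = labels)
}
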