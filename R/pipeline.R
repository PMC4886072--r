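# End-to-end orchestration: simulate/read -> preprocess -> segment ->
# extract -> cross-validate, with file outputs for every stage.

#' Read a grayscale image from PNG or TIFF
#'
#' @param path image file; PNG always supported, TIFF when the `tiff`
#'   package is installed. RGB images are converted by [to_grayscale()].
#' @return numeric matrix with intensities in 0--255.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stopf("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(raw)) == 3L && dim(raw)[3] == 4L) raw <- raw[, , 1:3]  # drop alpha
  to_grayscale(if (is.matrix(raw)) raw * 255 else raw * 255)
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param img numeric matrix, gray levels 0--255.
#' @param path output path.
#' @export
write_gray_image <- function(img, path) {
  assert_gray(img)
  png::writePNG(clamp(img, 0, 255) / 255, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Nested configuration for [run_pipeline()]. Stage defaults are the
#' pipeline's working values: crop size 51, circularity cut 0.85, 500 trees
#' with fixed-threshold fallback 250, M = 50 calibration iterations,
#' K = 0.3, and 10 x 10-fold cross-validation.
#'
#' @param simulate if `TRUE`, images come from the synthetic generator; if
#'   `FALSE`, `input_dir` must point at PNG/TIFF images (unlabeled; the
#'   evaluation stage is then skipped).
#' @param n_images number of synthetic images to simulate.
#' @param input_dir directory of input images when `simulate = FALSE`.
#' @param synthetic a [synthetic_config()].
#' @param bf_sigma_spatial,bf_sigma_range,bf_radius bilateral-filter
#'   parameters, see [bilateral_filter()].
#' @param min_area minimum component area in coarse segmentation.
#' @param crop_size,circ_threshold CPS parameters, see [cps_extract()].
#' @param features a [feature_config()].
#' @param n_trees,M,K,calibration classifier parameters, see [vrrf()].
#' @param cv_k,cv_repeats cross-validation layout.
#' @param match_dist maximum center distance (px) when matching extracted
#'   crops to ground-truth cells for labeling.
#' @param seed global seed.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulate = TRUE, n_images = 8L, input_dir = NULL,
                            synthetic = synthetic_config(),
                            bf_sigma_spatial = 3, bf_sigma_range = 25,
                            bf_radius = NULL,
                            min_area = 30L, crop_size = 51L,
                            circ_threshold = 0.85,
                            features = feature_config(),
                            n_trees = 500L, M = 50L, K = 0.3,
                            calibration = "oob",
                            cv_k = 10L, cv_repeats = 10L,
                            match_dist = 10, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

validate_pipeline_config <- function(config) {
  if (!inherits(config, "pipeline_config")) stopf("not a pipeline_config")
  if (!isTRUE(config$simulate)) {
    if (is.null(config$input_dir))
      stopf("validation error: simulate = FALSE requires input_dir")
    if (!dir.exists(config$input_dir))
      stopf("validation error: input_dir '%s' does not exist", config$input_dir)
  }
  if (config$crop_size %% 2L == 0L) stopf("validation error: crop_size must be odd")
  invisible(config)
}

#' Run the full classification pipeline
#'
#' Executes preprocess -> segment -> extract -> evaluate and writes every
#' stage artifact under `out_dir`: the feature table (`features.csv`), the
#' cross-validation report (`cv_report.json`), the fitted model summary
#' (`model.json`), and a run manifest (`manifest.json`) carrying the
#' configuration and seed so that a rerun reproduces identical outputs.
#' With `simulate = TRUE` the input images come from the synthetic tissue
#' generator (image `i` uses `synthetic$seed + i`) and extracted crops are
#' labeled by matching their centers to ground-truth cell centers within
#' `match_dist` pixels; unmatched crops are dropped.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if missing.
#' @param write_crops also write per-crop PNG files and a `crops.csv`
#'   manifest.
#' @return (invisibly) a list with the feature data frame, the CV report
#'   (when labels exist) and the output paths.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         write_crops = FALSE) {
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # ---- acquire images ----
  images <- list(); truths <- list()
  if (isTRUE(config$simulate)) {
    for (i in seq_len(config$n_images)) {
      cfg_i <- config$synthetic
      cfg_i$seed <- config$synthetic$seed + i
      sim <- stage("simulate", generate_tissue_image(cfg_i))
      images[[i]] <- sim$image
      truths[[i]] <- sim$truth
    }
  } else {
    paths <- list.files(config$input_dir, "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (!length(paths)) stopf("no input images found in %s", config$input_dir)
    images <- lapply(paths, function(p) stage("read", read_gray_image(p)))
    truths <- vector("list", length(images))
  }

  # ---- preprocess + segment + label ----
  crops <- list(); labels <- character(0); crop_meta <- NULL
  for (i in seq_along(images)) {
    filt <- stage("preprocess", bilateral_filter(
      images[[i]], config$bf_sigma_spatial, config$bf_sigma_range,
      config$bf_radius))
    mask <- stage("segment", coarse_segment(filt, config$min_area))
    cc <- stage("segment", cps_extract(mask, filt, n = config$crop_size,
                                       circ_threshold = config$circ_threshold))
    for (cr in cc) {
      lab <- NA_character_
      if (!is.null(truths[[i]]) && nrow(truths[[i]]$centers)) {
        d <- sqrt((truths[[i]]$centers[, 1] - cr$center[1])^2 +
                  (truths[[i]]$centers[, 2] - cr$center[2])^2)
        j <- which.min(d)
        if (d[j] <= config$match_dist)
          lab <- as.character(truths[[i]]$labels[j])
      }
      if (isTRUE(config$simulate) && is.na(lab)) next  # unmatched -> drop
      crops[[length(crops) + 1L]] <- cr
      labels <- c(labels, lab)
      crop_meta <- rbind(crop_meta,
                         data.frame(image = i, center_row = cr$center[1],
                                    center_col = cr$center[2],
                                    circularity = cr$circularity))
    }
  }
  if (!length(crops)) stopf("segmentation produced no usable crops")

  # ---- features ----
  labf <- if (isTRUE(config$simulate))
    factor(labels, levels = cell_class_levels()) else NULL
  feats <- stage("extract", extract_features(crops, labels = labf,
                                             config = config$features))
  features_path <- file.path(out_dir, "features.csv")
  utils::write.csv(feats, features_path, row.names = FALSE)

  if (write_crops) {
    crop_dir <- file.path(out_dir, "crops")
    dir.create(crop_dir, showWarnings = FALSE)
    for (i in seq_along(crops)) {
      write_gray_image(matrix(as.numeric(crops[[i]]$sbci) * 255,
                              config$crop_size, config$crop_size),
                       file.path(crop_dir, sprintf("sbci_%03d.png", i)))
      write_gray_image(crops[[i]]$snsci,
                       file.path(crop_dir, sprintf("snsci_%03d.png", i)))
      write_gray_image(crops[[i]]$smerci,
                       file.path(crop_dir, sprintf("smerci_%03d.png", i)))
    }
    utils::write.csv(cbind(id = seq_along(crops), crop_meta),
                     file.path(crop_dir, "crops.csv"), row.names = FALSE)
  }

  # ---- evaluate ----
  report <- NULL
  if (!is.null(labf)) {
    xm <- as.matrix(feats[, setdiff(colnames(feats), c("id", "label")),
                          drop = FALSE])
    cv <- stage("evaluate", cross_validate(
      xm, labf, k = config$cv_k, repeats = config$cv_repeats,
      seed = config$seed, n_trees = config$n_trees, M = config$M,
      K = config$K, calibration = config$calibration))
    fit <- stage("train", vrrf(xm, labf, n_trees = config$n_trees,
                               M = config$M, K = config$K,
                               calibration = config$calibration,
                               seed = config$seed))
    report <- list(
      accuracy = unname(as.data.frame(cv$accuracy)),
      repeat_means = unname(cv$repeat_means),
      grand_mean = cv$grand_mean,
      sensitivity = cv$sensitivity,
      specificity = cv$specificity,
      k = cv$k, repeats = cv$repeats, seed = cv$seed)
    jsonlite::write_json(report, file.path(out_dir, "cv_report.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(t_mean = fit$t_mean, n_trees = fit$n_trees,
                              M = fit$M, K = fit$K, seed = fit$seed,
                              positive = fit$positive,
                              feature_names = fit$feature_names),
                         file.path(out_dir, "model.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("vrrf")),
    seed = config$seed,
    n_crops = length(crops),
    config = config_to_list(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(features = feats, cv = report, out_dir = out_dir,
                 features_path = features_path))
}

config_to_list <- function(config) {
  lapply(unclass(config), function(v) if (is.list(v)) unclass(v) else v)
}
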