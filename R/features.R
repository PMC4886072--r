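#' Auxiliary circularity
#'
#' A corrected circularity for nuclear atypia scoring:
#' \deqn{C_f = \frac{4 \pi A}{(6.8/A + 0.625)\, L^2}}
#' where `A` is the region area (px^2) and `L` its perimeter (px). The
#' correction factor `(6.8/A + 0.625)` rescales the plain circularity
#' `4*pi*A/L^2`; as `A` grows with a circular area/perimeter relation the
#' value tends to `1/0.625 = 1.6`. The factor's constants are tied to pixel
#' units. The alternative reading with the factor multiplying (rather than
#' dividing) the plain circularity is available via `form = "multiply"`.
#'
#' @param area region area in pixels (> 0).
#' @param perimeter region perimeter in pixels (> 0).
#' @param form where the correction factor enters.
#' @return auxiliary circularity value.
#' @export
auxiliary_circularity <- function(area, perimeter,
                                  form = c("divide", "multiply")) {
  form <- match.arg(form)
  if (!is.numeric(area) || area <= 0) stopf("area must be > 0")
  if (!is.numeric(perimeter) || perimeter <= 0) stopf("perimeter must be > 0")
  factor <- 6.8 / area + 0.625
  base <- 4 * pi * area / perimeter^2
  if (form == "divide") base / factor else base * factor
}

#' Amendment circularity
#'
#' Ratio of the nuclear area to the area of the circle circumscribing the
#' cell's bounding rectangle (diameter `sqrt(w^2 + h^2)`):
#' \deqn{C_w = \frac{4 A}{\pi (w^2 + h^2)}}
#' A filled square gives `2/pi`; a disk in its tight bounding box gives 0.5.
#' Irregular cells waste bounding-box space and score lower.
#'
#' @param area region area in pixels (> 0).
#' @param width,height bounding-box dimensions in pixels (> 0).
#' @return amendment circularity in `(0, 1]` up to digitization slack.
#' @export
amendment_circularity <- function(area, width, height) {
  if (!is.numeric(area) || area <= 0) stopf("area must be > 0")
  if (!is.numeric(width) || width <= 0 || !is.numeric(height) || height <= 0)
    stopf("width and height must be > 0")
  4 * area / (pi * (width^2 + height^2))
}

#' Split an edge map into four quadrants
#'
#' Cuts the crop at its central row and column into top-left (a), top-right
#' (b), bottom-left (c) and bottom-right (d) parts; the central row and
#' column are assigned to the top/left halves. A 51x51 input yields parts of
#' 26x26, 26x25, 25x26 and 25x25.
#'
#' @param edge_map logical or numeric matrix, at least 2x2.
#' @return named list `a`, `b`, `c`, `d`.
#' @export
quadrant_split <- function(edge_map) {
  nr <- nrow(edge_map); nc <- ncol(edge_map)
  if (is.null(nr) || nr < 2L || nc < 2L) stopf("edge map must be at least 2x2")
  r0 <- ceiling(nr / 2); c0 <- ceiling(nc / 2)
  list(a = edge_map[1:r0, 1:c0, drop = FALSE],
       b = edge_map[1:r0, (c0 + 1L):nc, drop = FALSE],
       c = edge_map[(r0 + 1L):nr, 1:c0, drop = FALSE],
       d = edge_map[(r0 + 1L):nr, (c0 + 1L):nc, drop = FALSE])
}

#' Cell symmetry from quadrant fractal dimensions
#'
#' Sums the absolute differences of box-counting dimensions between
#' neighboring quadrants of the cell's edge map:
#' \deqn{Sym = |F_a - F_b| + |F_a - F_c| + |F_b - F_d| + |F_c - F_d|}
#' A symmetric (near-circular) cell has nearly equal quadrant dimensions and
#' `Sym` close to 0; irregular cells score higher. The formula is invariant
#' under horizontal and vertical mirroring of the quadrant labels.
#'
#' @param fd numeric vector of length 4: quadrant dimensions
#'   `(Fa, Fb, Fc, Fd)` for top-left, top-right, bottom-left, bottom-right.
#' @return non-negative symmetry score; 0 iff all four dimensions are equal.
#' @export
cell_symmetry <- function(fd) {
  if (length(fd) != 4L || any(!is.finite(fd)))
    stopf("fd must be four finite quadrant dimensions")
  abs(fd[1] - fd[2]) + abs(fd[1] - fd[3]) + abs(fd[2] - fd[4]) + abs(fd[3] - fd[4])
}

# quadrant box-counting dimensions of an edge map; empty quadrants score 0
quadrant_dimensions <- function(edge_map) {
  qs <- quadrant_split(edge_map)
  vapply(qs, function(q) {
    if (!any(q)) 0 else box_counting_dimension(q)
  }, numeric(1))
}

#' Shape features of a single-cell mask
#'
#' Classic binary shape descriptors: area (pixel count), perimeter
#' (8-connected boundary chain length), roundness `4*pi*A/L^2`, elongation
#' (major/minor axis ratio from second central moments, with the 1/12
#' per-pixel variance correction so a `w x h` rectangle scores exactly
#' `max(w,h)/min(w,h)`), and rectangularity (area over bounding-box area).
#'
#' @param x a `"cell_region"` from [connected_regions()] or a logical mask
#'   containing a single component.
#' @return named numeric vector of length 5.
#' @export
shape_features <- function(x) {
  if (inherits(x, "cell_region")) {
    reg <- x
  } else {
    assert_mask(x, "x")
    if (!any(x)) stopf("empty region has no shape")
    px <- which(x, arr.ind = TRUE)
    reg <- list(area = nrow(px), perimeter = boundary_chain_length(x),
                bbox = c(min(px[, 1]), min(px[, 2]),
                         max(px[, 1]) - min(px[, 1]) + 1L,
                         max(px[, 2]) - min(px[, 2]) + 1L),
                pixels = px)
  }
  px <- reg$pixels
  mu_r <- mean(px[, 1]); mu_c <- mean(px[, 2])
  m20 <- mean((px[, 1] - mu_r)^2)
  m02 <- mean((px[, 2] - mu_c)^2)
  m11 <- mean((px[, 1] - mu_r) * (px[, 2] - mu_c))
  common <- sqrt(((m20 - m02) / 2)^2 + m11^2)
  lam_max <- (m20 + m02) / 2 + common
  lam_min <- (m20 + m02) / 2 - common
  elongation <- sqrt((lam_max + 1 / 12) / (lam_min + 1 / 12))
  c(shape_area = reg$area,
    shape_perimeter = reg$perimeter,
    shape_roundness = 4 * pi * reg$area / reg$perimeter^2,
    shape_elongation = elongation,
    shape_rectangularity = reg$area / (reg$bbox[3] * reg$bbox[4]))
}

#' Feature-extraction configuration
#'
#' @param q_list moment orders for [multifractal_dimensions()].
#' @param include_smerci also compute the gray/texture block on the SMERCI
#'   crop (off by default; the bounding-rectangle crop can be too small for
#'   the texture window ladder on compact cells).
#' @param cf_form reading of the auxiliary-circularity correction factor,
#'   see [auxiliary_circularity()].
#' @param canny_sigma,canny_low,canny_high Canny parameters for the SBCI
#'   edge map, see [canny_edges()].
#' @return list of class `"feature_config"`.
#' @export
feature_config <- function(q_list = c(-2, -1, 0, 1, 2),
                           include_smerci = FALSE,
                           cf_form = "divide",
                           canny_sigma = 1, canny_low = 0.1, canny_high = 0.9) {
  structure(list(q_list = q_list, include_smerci = include_smerci,
                 cf_form = cf_form, canny_sigma = canny_sigma,
                 canny_low = canny_low, canny_high = canny_high),
            class = "feature_config")
}

gray_texture_block <- function(img, prefix = NULL) {
  v <- c(gray_mean_std(img),
         gray_entropy = gray_entropy(img),
         lbp_histogram(img),
         glcm_features(img),
         tamura_features(img))
  if (!is.null(prefix)) names(v) <- paste0(prefix, "_", names(v))
  v
}

#' Extract the full feature vector of one cell crop
#'
#' Assembles the fixed-order feature battery for a [cell_crop]:
#' atypia (auxiliary circularity, amendment circularity, symmetry), shape
#' (area, perimeter, roundness, elongation, rectangularity), fractal
#' (box-counting dimension of the Canny edge map of the SBCI, plus the
#' 7-value multifractal block), and gray/texture features of the SNSCI
#' (mean, sd, entropy, 256-bin LBP histogram, 16 GLCM statistics, 5 Tamura
#' features). With the default configuration the vector has
#' `3 + 5 + 1 + 7 + 3 + 256 + 16 + 5 = 296` entries; enabling
#' `include_smerci` appends the same gray block computed on the SMERCI.
#' The extraction is fully deterministic.
#'
#' @param crop a [cell_crop].
#' @param config a [feature_config()].
#' @return named numeric vector.
#' @export
extract_feature_vector <- function(crop, config = feature_config()) {
  if (!inherits(crop, "cell_crop")) stopf("`crop` must be a cell_crop")
  shp <- shape_features(crop$sbci)
  bb <- mask_bbox(crop$sbci)
  edge <- canny_edges(crop$sbci, sigma = config$canny_sigma,
                      low_quantile = config$canny_low,
                      high_quantile = config$canny_high)
  fd_box <- if (any(edge)) box_counting_dimension(edge) else 0
  mfd <- if (any(edge)) multifractal_dimensions(edge, config$q_list) else {
    qn <- ifelse(config$q_list < 0, paste0("qm", abs(config$q_list)),
                 paste0("q", config$q_list))
    stats::setNames(numeric(length(config$q_list) + 2),
                    c(paste0("mfd_", qn), "mfd_dalpha", "mfd_df"))
  }
  vec <- c(
    cf = auxiliary_circularity(shp[["shape_area"]], shp[["shape_perimeter"]],
                               form = config$cf_form),
    cw = amendment_circularity(shp[["shape_area"]], bb[4], bb[3]),
    sym = unname(cell_symmetry(quadrant_dimensions(edge))),
    shp,
    fd_box = fd_box,
    mfd,
    gray_texture_block(crop$snsci)
  )
  if (isTRUE(config$include_smerci))
    vec <- c(vec, gray_texture_block(crop$smerci, prefix = "smerci"))
  vec
}

#' Extract features for a list of crops
#'
#' @param crops list of [cell_crop] objects.
#' @param labels optional factor/character labels aligned with `crops`.
#' @param config a [feature_config()].
#' @return a `data.frame` with columns `id`, optionally `label`, and one
#'   column per feature in the documented order.
#' @export
extract_features <- function(crops, labels = NULL, config = feature_config()) {
  if (!length(crops)) stopf("no crops to extract features from")
  rows <- lapply(seq_along(crops), function(i) {
    tryCatch(extract_feature_vector(crops[[i]], config),
             error = function(e) stopf("crop %d: %s", i, conditionMessage(e)))
  })
  mat <- do.call(rbind, rows)
  df <- data.frame(id = seq_along(crops), mat, check.names = FALSE)
  if (!is.null(labels)) {
    if (length(labels) != length(crops)) stopf("labels must align with crops")
    df <- data.frame(id = df$id, label = labels, mat, check.names = FALSE)
  }
  df
}
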