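#' Coarse binary segmentation of a gray tissue image
#'
#' Applies a global Otsu threshold and keeps the pixels *below* it: H&E
#' nuclei stain dark, so foreground polarity is "darker than threshold"
#' throughout the pipeline. The raw mask is then morphologically corrected:
#' binary opening with a 3x3 structuring element, hole filling, and removal
#' of connected components smaller than `min_area` pixels.
#'
#' @param img numeric matrix, gray levels 0--255; must contain at least two
#'   distinct values (the threshold is undefined on a constant image).
#' @param min_area minimum component area kept, in pixels.
#' @return logical matrix; `TRUE` marks cell/nucleus pixels.
#' @export
coarse_segment <- function(img, min_area = 30L) {
  assert_gray(img)
  if (diff(range(img)) == 0)
    stopf("cannot threshold a constant image")
  th <- EBImage::otsu(EBImage::Image(img / 255), range = c(0, 1), levels = 256) * 255
  mask <- img < th

  m01 <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  m01 <- EBImage::opening(m01, EBImage::makeBrush(3L, shape = "disc"))
  m01 <- EBImage::fillHull(m01)
  mask <- matrix(as.logical(m01 > 0.5), nrow(mask), ncol(mask))

  lab <- label_components(mask)
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = max(lab))
    drop <- which(areas < min_area)
    if (length(drop)) mask[lab %in% drop] <- FALSE
  }
  mask
}

#' 8-connected component labeling
#'
#' Labels foreground components of a binary mask with 8-connectivity, so
#' pixels touching only diagonally belong to one component. (The underlying
#' 4-connected labeling is merged across diagonal adjacencies with a
#' union-find pass.)
#'
#' @param mask logical matrix.
#' @return integer matrix of labels, `0` for background, `1..n` for the
#'   components.
#' @export
label_components <- function(mask) {
  assert_mask(mask)
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab > 1L && nrow(mask) > 1L && ncol(mask) > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # \ diagonal adjacency
    a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]    # / diagonal adjacency
    sel1 <- a1 > 0L & b1 > 0L & a1 != b1
    sel2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
    if (nrow(pairs)) {
      parent <- seq_len(nlab)
      find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(nlab), find, integer(1))
      dense <- match(root, sort(unique(root)))
      lab[lab > 0L] <- dense[lab[lab > 0L]]
    }
  }
  lab
}

#' Connected regions of a binary mask
#'
#' Labels the mask with 8-connectivity and summarizes each component.
#' The perimeter is the 8-connected boundary chain length (axial steps count
#' 1, diagonal steps sqrt(2)); this convention matters because it decides
#' which regions pass the circularity filter of [cps_extract()].
#'
#' @param mask logical matrix.
#' @return a list of `"cell_region"` objects, each with fields `area`
#'   (pixel count), `perimeter` (chain length), `centroid` (`c(row, col)`),
#'   `bbox` (`c(min_row, min_col, height, width)`) and `pixels` (2-column
#'   index matrix). Empty mask gives an empty list.
#' @export
connected_regions <- function(mask) {
  lab <- label_components(mask)
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  out <- vector("list", nlab)
  idx <- which(lab > 0L, arr.ind = TRUE)
  labs <- lab[lab > 0L]
  for (k in seq_len(nlab)) {
    px <- idx[labs == k, , drop = FALSE]
    sub <- matrix(FALSE, nrow(mask), ncol(mask))
    sub[px] <- TRUE
    out[[k]] <- structure(list(
      area = nrow(px),
      perimeter = boundary_chain_length(sub),
      centroid = c(mean(px[, 1]), mean(px[, 2])),
      bbox = c(min(px[, 1]), min(px[, 2]),
               max(px[, 1]) - min(px[, 1]) + 1L,
               max(px[, 2]) - min(px[, 2]) + 1L),
      pixels = px
    ), class = "cell_region")
  }
  out
}

# Outer-boundary chain length by clockwise Moore-neighbor tracing with
# Jacob's stopping criterion. Single-pixel regions get length 1 by
# convention (the chain degenerates); interior holes are ignored.
boundary_chain_length <- function(mask) {
  fg <- which(mask, arr.ind = TRUE)
  if (nrow(fg) == 0L) stopf("empty mask has no boundary")
  if (nrow(fg) == 1L) return(1)
  # topmost, then leftmost foreground pixel; its W and N neighbors are bg
  start <- fg[order(fg[, 1], fg[, 2])[1L], ]
  dirs <- rbind(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))  # N..NW clockwise
  inside <- function(p) p[1] >= 1L && p[1] <= nrow(mask) &&
    p[2] >= 1L && p[2] <= ncol(mask) && mask[p[1], p[2]]
  cur <- start
  back <- start + c(0L, -1L)      # entered from the west
  len <- 0
  first_move <- NULL
  steps <- 0L
  max_steps <- 8L * nrow(fg) + 16L
  repeat {
    rel <- back - cur
    bi <- which(dirs[, 1] == rel[1] & dirs[, 2] == rel[2])
    nxt <- NULL
    prev <- back
    for (k in seq_len(8L)) {
      di <- ((bi - 1L + k) %% 8L) + 1L
      cand <- cur + dirs[di, ]
      if (inside(cand)) { nxt <- cand; break }
      prev <- cand
    }
    if (is.null(nxt)) return(1)   # isolated pixel reached via degenerate mask
    step_len <- if (all(abs(nxt - cur) == c(1L, 1L))) sqrt(2) else 1
    if (is.null(first_move)) first_move <- c(cur, nxt)
    else if (all(c(cur, nxt) == first_move)) break   # Jacob's criterion
    len <- len + step_len
    back <- prev
    cur <- nxt
    steps <- steps + 1L
    if (steps > max_steps) break  # safety net; should not trigger
  }
  len
}

#' Circularity of a region
#'
#' Returns \eqn{4 \pi A / L^2} with the perimeter `L` measured as the
#' 8-connected boundary chain length. For reasonably sized digital disks the
#' value is close to 1 and may slightly exceed it (digitization lets the
#' chain undershoot the isoperimetric bound); very small regions overshoot
#' further and should be filtered by area first.
#'
#' @param r a `"cell_region"` from [connected_regions()], or a list with
#'   fields `area` and `perimeter`.
#' @return circularity ratio.
#' @export
region_circularity <- function(r) {
  if (is.null(r$area) || is.null(r$perimeter))
    stopf("`r` must carry `area` and `perimeter`")
  if (r$area < 1) stopf("region area must be >= 1")
  if (r$perimeter <= 0) stopf("region perimeter must be > 0")
  4 * pi * r$area / r$perimeter^2
}

#' Keep only the central connected component of a crop mask
#'
#' A fixed-size window cut around one cell frequently clips neighboring
#' cells; this keeps only the component containing the crop's center pixel
#' (or, if the center pixel is background, the component whose centroid is
#' nearest to the center; ties go to the larger component) and zeroes all
#' others.
#'
#' @param crop_mask logical matrix (square crop).
#' @return list with `mask` (cleaned crop) and `centroid` (`c(row, col)` of
#'   the kept component, in crop coordinates).
#' @export
isolate_center_region <- function(crop_mask) {
  assert_mask(crop_mask, "crop_mask")
  if (!any(crop_mask)) stopf("crop has no foreground")
  lab <- label_components(crop_mask)
  center <- c((nrow(crop_mask) + 1L) %/% 2L, (ncol(crop_mask) + 1L) %/% 2L)
  keep <- lab[center[1], center[2]]
  nlab <- max(lab)
  if (keep == 0L) {
    stats <- t(vapply(seq_len(nlab), function(k) {
      px <- which(lab == k, arr.ind = TRUE)
      c(dist = sqrt((mean(px[, 1]) - center[1])^2 + (mean(px[, 2]) - center[2])^2),
        area = nrow(px))
    }, numeric(2)))
    keep <- order(stats[, "dist"], -stats[, "area"])[1L]
  }
  mask <- lab == keep
  px <- which(mask, arr.ind = TRUE)
  list(mask = mask, centroid = c(mean(px[, 1]), mean(px[, 2])))
}

#' Single-cell crop container
#'
#' Bundles the three crop formats produced by the center-proliferation
#' segmentation for one cell: `sbci` (binary mask crop, n x n), `snsci`
#' (gray crop, n x n, same center) and `smerci` (gray crop of the cell's
#' axis-aligned bounding rectangle), plus the cell's center coordinate in
#' the source image.
#'
#' @param sbci logical n x n matrix with exactly one connected component.
#' @param snsci numeric n x n matrix.
#' @param smerci numeric matrix, dimensions equal to the SBCI component's
#'   bounding box.
#' @param center numeric `c(row, col)` in source-image coordinates.
#' @param n odd crop side length.
#' @param circularity optional circularity of the originating region.
#' @return an object of class `"cell_crop"`.
#' @export
cell_crop <- function(sbci, snsci, smerci, center, n = nrow(sbci),
                      circularity = NA_real_) {
  assert_mask(sbci, "sbci"); assert_gray(snsci, "snsci"); assert_gray(smerci, "smerci")
  if (!all(dim(sbci) == c(n, n)) || !all(dim(snsci) == c(n, n)))
    stopf("sbci and snsci must be exactly %d x %d", n, n)
  structure(list(sbci = sbci, snsci = snsci, smerci = smerci,
                 center = center, n = as.integer(n), circularity = circularity),
            class = "cell_crop")
}

#' @export
print.cell_crop <- function(x, ...) {
  cat(sprintf("<cell_crop> %dx%d at (%.1f, %.1f), SMERCI %dx%d\n",
              x$n, x$n, x$center[1], x$center[2],
              nrow(x$smerci), ncol(x$smerci)))
  invisible(x)
}

#' Center-proliferation segmentation (CPS)
#'
#' Extracts fixed-size single-cell crops from a coarse segmentation mask.
#' For every connected region whose circularity exceeds `circ_threshold`,
#' an `n x n` binary window is grown outward from the region centroid, the
#' central component is isolated, the centroid is re-derived from the kept
#' component, and both the binary window and the gray window (from the same
#' gray image used for segmentation) are re-extracted centered on that
#' refined centroid, so SBCI and SNSCI share one center. The gray crop of
#' the kept component's axis-aligned bounding rectangle forms the SMERCI.
#' Regions whose window would cross the image border are discarded rather
#' than padded, since padding would inject artificial texture into the
#' GLCM/LBP/Tamura features downstream.
#'
#' @param mask logical matrix from [coarse_segment()].
#' @param gray numeric matrix with the same shape as `mask`.
#' @param n odd crop size; 51 is the working value for this pipeline.
#' @param circ_threshold circularity cut, strict inequality (regions with
#'   circularity `> circ_threshold` are kept).
#' @return list of [cell_crop] objects (possibly empty).
#' @export
cps_extract <- function(mask, gray, n = 51L, circ_threshold = 0.85) {
  assert_mask(mask); assert_gray(gray, "gray")
  if (!all(dim(mask) == dim(gray)))
    stopf("mask and gray must have identical shape")
  n <- as.integer(n)
  if (n %% 2L == 0L) stopf("crop size n must be odd")
  if (n > nrow(mask) || n > ncol(mask))
    stopf("crop size n exceeds image dimensions")
  half <- (n - 1L) %/% 2L

  window <- function(m, center) {
    r <- round(center[1]); c <- round(center[2])
    if (r - half < 1L || r + half > nrow(m) || c - half < 1L || c + half > ncol(m))
      return(NULL)
    m[(r - half):(r + half), (c - half):(c + half), drop = FALSE]
  }

  crops <- list()
  for (reg in connected_regions(mask)) {
    if (region_circularity(reg) <= circ_threshold) next
    w0 <- window(mask, reg$centroid)
    if (is.null(w0)) next
    iso0 <- isolate_center_region(w0)
    # refined centroid in source-image coordinates
    refined <- c(round(reg$centroid[1]) - half - 1L, round(reg$centroid[2]) - half - 1L) +
      iso0$centroid
    sb <- window(mask, refined)
    sn <- window(gray, refined)
    if (is.null(sb) || is.null(sn)) next
    iso <- isolate_center_region(sb)
    bb <- mask_bbox(iso$mask)
    r0 <- round(refined[1]) - half - 1L
    c0 <- round(refined[2]) - half - 1L
    smerci <- gray[(r0 + bb[1]):(r0 + bb[1] + bb[3] - 1L),
                   (c0 + bb[2]):(c0 + bb[2] + bb[4] - 1L), drop = FALSE]
    crops[[length(crops) + 1L]] <-
      cell_crop(sbci = iso$mask, snsci = sn, smerci = smerci,
                center = refined, n = n,
                circularity = region_circularity(reg))
  }
  crops
}
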