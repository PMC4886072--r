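#' Canny edge detection
#'
#' Small, dependency-free Canny implementation used to turn the binary cell
#' mask (SBCI) into a one-pixel boundary map before the fractal and symmetry
#' features are computed: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression along the discretized gradient direction, and hysteresis
#' linking (8-connected) between two magnitude thresholds placed at
#' gradient-magnitude quantiles.
#'
#' @param img numeric or logical matrix; logical input is scaled to 0/255.
#' @param sigma Gaussian smoothing sd in pixels.
#' @param low_quantile,high_quantile quantiles of the non-zero gradient
#'   magnitudes used as the hysteresis thresholds.
#' @return logical matrix of edge pixels.
#' @export
canny_edges <- function(img, sigma = 1, low_quantile = 0.1,
                        high_quantile = 0.9) {
  if (is.logical(img)) img <- matrix(as.numeric(img) * 255, nrow(img), ncol(img))
  assert_gray(img)
  if (nrow(img) < 3L || ncol(img) < 3L) stopf("image too small for edge detection")

  sm <- conv_sep(img, gaussian_kernel1d(sigma))
  sobel_x <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- conv2(sm, sobel_x)          # column (x) gradient
  gy <- conv2(sm, t(sobel_x))       # row (y) gradient
  mag <- sqrt(gx^2 + gy^2)
  if (all(mag == 0)) return(matrix(FALSE, nrow(img), ncol(img)))

  # non-maximum suppression over 4 discretized directions
  ang <- atan2(gy, gx) %% pi
  sector <- (floor(ang / (pi / 4) + 0.5)) %% 4  # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  pm <- pad_reflect(mag, 1L)
  nr <- nrow(img); nc <- ncol(img)
  sh <- function(dy, dx) pm[(1 + dy) + seq_len(nr), (1 + dx) + seq_len(nc), drop = FALSE]
  n1 <- matrix(0, nr, nc); n2 <- matrix(0, nr, nc)
  pick <- function(sec, a, b) { n1[sector == sec] <<- a[sector == sec]
                                n2[sector == sec] <<- b[sector == sec] }
  pick(0, sh(0, -1), sh(0, 1))
  pick(1, sh(-1, 1), sh(1, -1))
  pick(2, sh(-1, 0), sh(1, 0))
  pick(3, sh(-1, -1), sh(1, 1))
  nms <- mag >= n1 & mag >= n2 & mag > 0

  qs <- stats::quantile(mag[mag > 0], c(low_quantile, high_quantile), names = FALSE)
  strong <- nms & mag >= qs[2]
  weak <- nms & mag >= qs[1]
  if (!any(strong)) return(strong)
  lab <- label_components(weak)
  keep <- unique(lab[strong])
  matrix(lab %in% keep & lab > 0L, nr, nc)
}
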