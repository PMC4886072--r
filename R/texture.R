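#' Gray-level mean and standard deviation
#'
#' Computed per pixel over the whole crop. On H&E material, cancer nuclei
#' stain darker (lower mean) and more unevenly (higher sd) than normal
#' nuclei, which is why this pair is discriminative.
#'
#' @param img numeric matrix.
#' @return named numeric `c(gray_mean, gray_sd)`; the sd is the population
#'   standard deviation.
#' @export
gray_mean_std <- function(img) {
  assert_gray(img)
  m <- mean(img)
  c(gray_mean = m, gray_sd = sqrt(mean((img - m)^2)))
}

#' First-order gray entropy
#'
#' Shannon entropy (base 2) of the 256-bin gray-level histogram:
#' \eqn{H = -\sum_i p_i \log_2 p_i}, with empty bins contributing zero.
#' Ranges from 0 (constant image) to 8 bits (all 256 levels equally likely).
#'
#' @param img numeric matrix with intensities in `[0, 255]`.
#' @return entropy in bits.
#' @export
gray_entropy <- function(img) {
  assert_gray(img)
  counts <- tabulate(floor(clamp(img, 0, 255)) + 1L, nbins = 256L)
  p <- counts[counts > 0] / sum(counts)
  max(-sum(p * log2(p)), 0)   # clamp the -0 of a single-bin image
}

#' Local binary pattern histogram
#'
#' Computes an 8-bit LBP code for every interior pixel from its 3x3
#' neighborhood: a neighbor strictly greater than the center contributes a 1
#' bit. Bits are ordered clockwise starting at the top-left neighbor
#' (top-left is the most significant bit). The codes of all interior pixels
#' are histogrammed into 256 bins and normalized to sum 1. The strict
#' comparison makes the descriptor invariant to additive gray shifts.
#'
#' @param img numeric matrix, at least 3x3.
#' @return numeric vector of length 256 summing to 1.
#' @export
lbp_histogram <- function(img) {
  assert_gray(img)
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 3L || nc < 3L) stopf("LBP needs an image of at least 3x3")
  ri <- 2:(nr - 1L); ci <- 2:(nc - 1L)
  center <- img[ri, ci, drop = FALSE]
  # clockwise from top-left; weights 128 down to 1
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  w <- 2^(7:0)
  code <- matrix(0, length(ri), length(ci))
  for (k in seq_along(offs)) {
    nb <- img[ri + offs[[k]][1], ci + offs[[k]][2], drop = FALSE]
    code <- code + w[k] * (nb > center)
  }
  h <- tabulate(as.integer(code) + 1L, nbins = 256L)
  stats::setNames(h / sum(h), sprintf("lbp_%03d", 0:255))
}

# normalized symmetric co-occurrence matrix for one (dr, dc) offset
glcm_matrix <- function(q, dr, dc, levels = 16L) {
  nr <- nrow(q); nc <- ncol(q)
  r0 <- max(1L, 1L - dr):min(nr, nr - dr)
  c0 <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(r0) < 1L || length(c0) < 1L)
    stopf("offset (%d, %d) has no valid pixel pairs", dr, dc)
  a <- q[r0, c0, drop = FALSE]
  b <- q[r0 + dr, c0 + dc, drop = FALSE]
  counts <- tabulate(as.integer(a) + levels * as.integer(b) + 1L,
                     nbins = levels * levels)
  m <- matrix(counts, levels, levels)
  m <- m + t(m)
  m / sum(m)
}

glcm_stats <- function(p) {
  lv <- 0:(nrow(p) - 1L)
  asm <- sum(p^2)
  ent <- { pp <- p[p > 0]; -sum(pp * log(pp)) }
  con <- sum(outer(lv, lv, function(i, j) (i - j)^2) * p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(lv * px); muy <- sum(lv * py)
  sx <- sqrt(sum((lv - mux)^2 * px)); sy <- sqrt(sum((lv - muy)^2 * py))
  cor <- if (sx * sy > 0) (sum(outer(lv, lv) * p) - mux * muy) / (sx * sy) else 0
  c(asm = asm, ent = ent, con = con, cor = cor)
}

#' GLCM texture features
#'
#' Haralick-style texture statistics from gray-level co-occurrence matrices.
#' Intensities are quantized to 16 levels (so the 51x51 crop matrices stay
#' well populated); symmetric normalized co-occurrence matrices are built
#' for 8 offsets -- four directions (0, 45, 90, 135 degrees) at two
#' distances (1 and 2 px). Per matrix, angular second moment (ASM), entropy
#' (ENT, natural log), contrast (CON) and correlation (COR, standard
#' marginal-moment form; defined as 0 when a marginal is degenerate) are
#' computed; for each statistic the mean and variance across the four
#' directions at each distance are reported: 4 stats x 2 distances x
#' \{mean, variance\} = 16 values.
#'
#' @param img numeric matrix with intensities in `[0, 255]`, at least 3x3.
#' @param levels number of quantization levels.
#' @return named numeric vector of length 16
#'   (`glcm_<stat>_d<distance>_<mean|var>`).
#' @export
glcm_features <- function(img, levels = 16L) {
  assert_gray(img)
  if (nrow(img) < 3L || ncol(img) < 3L) stopf("GLCM needs an image of at least 3x3")
  q <- floor(clamp(img, 0, 255) / (256 / levels))
  angles <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                 `90` = c(-1L, 0L), `135` = c(-1L, -1L))
  out <- numeric(0)
  for (stat in c("asm", "ent", "con", "cor")) {
    for (d in c(1L, 2L)) {
      vals <- vapply(angles, function(o) {
        glcm_stats(glcm_matrix(q, o[1] * d, o[2] * d, levels))[[stat]]
      }, numeric(1))
      out[sprintf("glcm_%s_d%d_mean", stat, d)] <- mean(vals)
      out[sprintf("glcm_%s_d%d_var", stat, d)] <- stats::var(vals)
    }
  }
  out
}

#' Tamura texture features
#'
#' Perceptually motivated texture measures: coarseness (preferred local
#' scale, from best-window-size averaging over windows of side `2^k`,
#' `k = 1..kmax`), contrast (sd divided by the fourth root of kurtosis),
#' directionality (sharpness of the 16-bin gradient-orientation histogram,
#' Prewitt gradients), linelikeness (orientation co-occurrence along the
#' local edge direction) and roughness (coarseness + contrast). Regularity
#' is deliberately omitted.
#'
#' @param img numeric matrix; needs at least 8 px in each dimension.
#' @param kmax largest window exponent; 5 suits 51-px crops.
#' @return named numeric vector of length 5.
#' @export
tamura_features <- function(img, kmax = 5L) {
  assert_gray(img)
  nr <- nrow(img); nc <- ncol(img)
  if (min(nr, nc) < 8L) stopf("image too small for Tamura features")

  # --- coarseness ---
  pad <- 2L^kmax
  p <- pad_reflect(img, pad)
  S <- integral_image(p)
  best_e <- matrix(-Inf, nr, nc)
  best_s <- matrix(2, nr, nc)
  for (k in seq_len(kmax)) {
    h <- 2L^(k - 1L)
    # mean over the 2^k x 2^k window centered at (y, x) (rows y-h..y+h-1),
    # evaluated on padded coordinates via the summed-area table
    ak <- function(y0, x0) {
      g <- function(a, b) S[cbind(a, b)]
      (g(y0 + h, x0 + h) - g(y0 - h, x0 + h) -
         g(y0 + h, x0 - h) + g(y0 - h, x0 - h)) / (4^k)
    }
    yy <- rep(pad + seq_len(nr), times = nc)
    xx <- rep(pad + seq_len(nc), each = nr)
    eh <- matrix(abs(ak(yy, xx + h) - ak(yy, xx - h)), nr, nc)
    ev <- matrix(abs(ak(yy + h, xx) - ak(yy - h, xx)), nr, nc)
    # ignore differences whose windows cross the true image border: the
    # padding would otherwise manufacture phantom edges that dominate the
    # scale argmax on strongly periodic textures
    ch <- seq_len(nc); rh <- seq_len(nr)
    eh[, ch - 2 * h < 1 | ch + 2 * h > nc] <- 0
    ev[rh - 2 * h < 1 | rh + 2 * h > nr, ] <- 0
    e <- pmax(eh, ev)
    upd <- e > best_e
    best_e[upd] <- e[upd]
    best_s[upd] <- 2^k
  }
  coarseness <- mean(best_s)

  # --- contrast ---
  m <- mean(img); s2 <- mean((img - m)^2)
  contrast <- if (s2 > 0) sqrt(s2) / (mean((img - m)^4) / s2^2)^0.25 else 0

  # --- directionality / linelikeness ---
  prewitt <- matrix(c(-1, 0, 1, -1, 0, 1, -1, 0, 1), 3, 3, byrow = TRUE)
  dh <- conv2(img, prewitt)
  dv <- conv2(img, t(prewitt))
  mag <- (abs(dh) + abs(dv)) / 2
  theta <- atan2(dv, dh) %% pi
  nbin <- 16L
  qual <- mag >= 12
  if (!any(qual)) {
    directionality <- 0; linelike <- 0
  } else {
    bin <- pmin(floor(theta / pi * nbin), nbin - 1L)
    h <- tabulate(bin[qual] + 1L, nbins = nbin)
    h <- h / sum(h)
    peak <- which.max(h)
    phi <- (seq_len(nbin) - 0.5) * pi / nbin
    dphi <- abs(phi - phi[peak])
    dphi <- pmin(dphi, pi - dphi)
    directionality <- 1 - (4 / pi^2) * sum(h * dphi^2)

    dlin <- 4
    qi <- which(qual, arr.ind = TRUE)
    r2 <- qi[, 1] + round(dlin * sin(theta[qual]))
    c2 <- qi[, 2] + round(dlin * cos(theta[qual]))
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    if (any(ok)) {
      j <- cbind(r2[ok], c2[ok])
      ok2 <- qual[j]
      if (any(ok2)) {
        bi <- bin[qual][ok][ok2]
        bj <- bin[j][ok2]
        linelike <- mean(cos((bi - bj) * 2 * pi / nbin))
      } else linelike <- 0
    } else linelike <- 0
  }

  c(tamura_coarseness = coarseness, tamura_contrast = contrast,
    tamura_directionality = directionality, tamura_linelikeness = linelike,
    tamura_roughness = coarseness + contrast)
}
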