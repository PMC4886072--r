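# Independent brute-force oracles used across the suite. These deliberately
# recompute quantities with naive per-pixel loops, not by calling package
# internals.

# rasterized disk mask
make_disk <- function(n, radius, center = c((n + 1) / 2, (n + 1) / 2)) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  sqrt((rows - center[1])^2 + (cols - center[2])^2) <= radius
}

# naive per-pixel LBP recomputation (clockwise from top-left, MSB first)
brute_lbp_histogram <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  codes <- integer(0)
  for (r in 2:(nr - 1)) for (c in 2:(nc - 1)) {
    code <- 0
    for (k in 1:8)
      if (img[r + offs[[k]][1], c + offs[[k]][2]] > img[r, c])
        code <- code + 2^(8 - k)
    codes <- c(codes, code)
  }
  tabulate(codes + 1L, nbins = 256L) / length(codes)
}

# naive symmetric co-occurrence contrast for one offset, 16 quantized levels
brute_glcm_contrast <- function(img, dr, dc) {
  q <- floor(pmin(pmax(img, 0), 255) / 16)
  nr <- nrow(q); nc <- ncol(q)
  num <- 0; den <- 0
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
      num <- num + 2 * (q[r, c] - q[r2, c2])^2   # both orderings
      den <- den + 2
    }
  }
  num / den
}

# direct truncated-Gaussian convolution with symmetric reflection, used as
# the limit oracle for the bilateral filter
brute_gaussian_blur <- function(img, sigma, radius) {
  nr <- nrow(img); nc <- ncol(img)
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    num <- 0; den <- 0
    for (dy in -radius:radius) for (dx in -radius:radius) {
      w <- exp(-(dy^2 + dx^2) / (2 * sigma^2))
      num <- num + w * img[refl(r + dy, nr), refl(c + dx, nc)]
      den <- den + w
    }
    out[r, c] <- num / den
  }
  out
}

# brute-force grid box count
brute_box_count <- function(mask, eps) {
  nr <- nrow(mask); nc <- ncol(mask)
  n <- 0
  for (bi in seq_len(ceiling(nr / eps))) for (bj in seq_len(ceiling(nc / eps))) {
    rows <- ((bi - 1) * eps + 1):min(bi * eps, nr)
    cols <- ((bj - 1) * eps + 1):min(bj * eps, nc)
    if (any(mask[rows, cols])) n <- n + 1
  }
  n
}

# random blob helper for property tests (Fourier-perturbed star-convex blob)
random_blob <- function(size = 128, rmin = 8, rmax = 25, rough = 0.25) {
  center <- runif(2, rmax + 5, size - rmax - 5)
  radius <- runif(1, rmin, rmax)
  amp <- rnorm(4); phase <- runif(4, 0, 2 * pi)
  amp <- amp / sqrt(sum(amp^2) / 2)
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  theta <- atan2(rows - center[1], cols - center[2])
  s <- 0
  for (k in 1:4) s <- s + amp[k] * cos((k + 1) * theta + phase[k])
  rt <- radius * pmax(0.3, 1 + rough * runif(1) * s)
  sqrt((rows - center[1])^2 + (cols - center[2])^2) <= rt
}
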