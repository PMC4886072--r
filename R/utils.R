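# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
assert_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stopf("`%s` must be a numeric matrix (grayscale image)", arg)
  if (nrow(img) < 1L || ncol(img) < 1L)
    stopf("`%s` must have at least one row and one column", arg)
  if (any(!is.finite(img)))
    stopf("`%s` contains non-finite intensities", arg)
  invisible(img)
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stopf("`%s` must be a logical matrix (binary mask)", arg)
  invisible(mask)
}

# Symmetric (edge-inclusive) reflection padding. Returns a matrix with `r`
# extra rows/columns on each side. Reflection rather than zero padding avoids
# injecting a dark frame that would bias thresholding near borders.
pad_reflect <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  if (r < 1L) return(m)
  ridx <- reflect_index(nr, r)
  cidx <- reflect_index(nc, r)
  m[ridx, cidx, drop = FALSE]
}

# Index vector implementing symmetric reflection (1 2 .. n -> r..1 1..n n..n-r+1),
# folding repeatedly so r may exceed n.
reflect_index <- function(n, r) {
  idx <- seq_len(n)
  period <- c(idx, rev(idx))           # symmetric extension of period 2n
  pos <- (seq.int(1L - r, n + r) - 1L) %% (2L * n) + 1L
  period[pos]
}

gaussian_kernel1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq.int(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution with symmetric reflection at the borders.
conv_sep <- function(img, k) {
  r <- (length(k) - 1L) %/% 2L
  p <- pad_reflect(img, r)
  # rows pass
  out <- matrix(0, nrow(p), ncol(img))
  for (j in seq_along(k))
    out <- out + k[j] * p[, j:(j + ncol(img) - 1L), drop = FALSE]
  # cols pass
  res <- matrix(0, nrow(img), ncol(img))
  for (i in seq_along(k))
    res <- res + k[i] * out[i:(i + nrow(img) - 1L), , drop = FALSE]
  res
}

# 2-D convolution with a small kernel, reflection padding.
conv2 <- function(img, kern) {
  rr <- (nrow(kern) - 1L) %/% 2L
  rc <- (ncol(kern) - 1L) %/% 2L
  p <- pad_reflect(img, max(rr, rc))
  off <- max(rr, rc)
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(nrow(kern))) for (j in seq_len(ncol(kern))) {
    w <- kern[i, j]
    if (w == 0) next
    out <- out + w * p[(off - rr + i - 1L) + seq_len(nrow(img)),
                       (off - rc + j - 1L) + seq_len(ncol(img)), drop = FALSE]
  }
  out
}

# Summed-area table with a leading zero row/column so that
# box sums are S[r2+1,c2+1]-S[r1,c2+1]-S[r2+1,c1]+S[r1,c1].
integral_image <- function(m) {
  s <- apply(m, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  rbind(0, cbind(0, s))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
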