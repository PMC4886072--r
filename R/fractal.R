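# Box-counting and multifractal (generalized Renyi) dimension estimators.
# Both share one geometric ladder of box sizes: the initial box is 1/10 of
# the (shorter) image side, halved down to single-pixel boxes.

box_size_ladder <- function(side) {
  e <- max(2L, as.integer(side %/% 10L))
  sizes <- integer(0)
  while (e >= 1L) { sizes <- c(sizes, e); e <- e %/% 2L }
  sizes <- unique(c(sizes, 1L))
  if (length(sizes) < 2L) sizes <- c(2L, 1L)
  sizes
}

# per-box foreground counts for one box size. With `complete_only`, boxes
# that extend past the image border are excluded: their truncated area gives
# them an artificially small measure, which badly biases negative-q moments.
box_measure <- function(fg, eps, dims = NULL, complete_only = FALSE) {
  bi <- (fg[, 1] - 1L) %/% eps
  bj <- (fg[, 2] - 1L) %/% eps
  if (complete_only) {
    keep <- (bi + 1L) * eps <= dims[1] & (bj + 1L) * eps <= dims[2]
    if (any(keep)) { bi <- bi[keep]; bj <- bj[keep] }
  }
  as.numeric(table(bi * (max(bj) + 1L) + bj))
}

#' Box-counting fractal dimension
#'
#' Estimates the capacity dimension of a binary pattern as the slope of the
#' least-squares fit of `log N(eps)` against `log(1/eps)`, where `N(eps)` is
#' the number of grid boxes of side `eps` containing at least one foreground
#' pixel. The ladder of box sizes starts at one tenth of the shorter image
#' side and halves down to 1 px.
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @return estimated dimension (about 0 for a point, 1 for a curve, 2 for a
#'   filled region).
#' @export
box_counting_dimension <- function(mask) {
  assert_mask(mask)
  fg <- which(mask, arr.ind = TRUE)
  if (nrow(fg) == 0L) stopf("cannot estimate a fractal dimension of an empty mask")
  sizes <- box_size_ladder(min(dim(mask)))
  n_boxes <- vapply(sizes, function(e) length(box_measure(fg, e)), numeric(1))
  stats::coef(stats::lm(log(n_boxes) ~ log(1 / sizes)))[[2]]
}

#' Generalized (Renyi) multifractal dimensions
#'
#' Estimates the moment-order-q dimension family \eqn{D_q} from box-measure
#' moments on the same box-size ladder as [box_counting_dimension()]. The
#' measure of box *i* is its share \eqn{p_i} of the foreground pixels. For
#' \eqn{q \ne 1}, \eqn{D_q} is the slope of
#' \eqn{\log \sum_i p_i^q} versus \eqn{\log \epsilon}, divided by
#' \eqn{q - 1}; \eqn{D_1} uses the entropy limit (slope of
#' \eqn{\sum_i p_i \log p_i}). The singularity strengths \eqn{\alpha(q)} and
#' spectrum values \eqn{f(q)} are estimated with the moment method, and the
#' spectrum widths \eqn{\Delta\alpha} and \eqn{\Delta f} over the requested
#' q grid are appended, giving `length(q_list) + 2` values (7 by default).
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @param q_list moment orders.
#' @return named numeric vector: one `D_q` per requested order plus
#'   `d_alpha` and `d_f`.
#' @export
multifractal_dimensions <- function(mask, q_list = c(-2, -1, 0, 1, 2)) {
  assert_mask(mask)
  fg <- which(mask, arr.ind = TRUE)
  if (nrow(fg) == 0L) stopf("cannot estimate multifractal dimensions of an empty mask")
  sizes <- box_size_ladder(min(dim(mask)))
  loge <- log(sizes)

  nq <- length(q_list)
  zq <- matrix(NA_real_, length(sizes), nq)   # log moment sums (or entropy for q=1)
  aq <- matrix(NA_real_, length(sizes), nq)   # numerators for alpha(q)
  fq <- matrix(NA_real_, length(sizes), nq)   # numerators for f(q)
  for (s in seq_along(sizes)) {
    cnt <- box_measure(fg, sizes[s], dims = dim(mask), complete_only = TRUE)
    p <- cnt / sum(cnt)
    for (k in seq_len(nq)) {
      q <- q_list[k]
      if (q == 1) {
        zq[s, k] <- sum(p * log(p))
        mu <- p
      } else {
        pq <- p^q
        zq[s, k] <- log(sum(pq))
        mu <- pq / sum(pq)
      }
      aq[s, k] <- sum(mu * log(p))
      fq[s, k] <- sum(mu * log(mu))
    }
  }
  slope <- function(y) stats::coef(stats::lm(y ~ loge))[[2]]
  d <- numeric(nq); alpha <- numeric(nq); f <- numeric(nq)
  for (k in seq_len(nq)) {
    q <- q_list[k]
    d[k] <- if (q == 1) slope(zq[, k]) else slope(zq[, k]) / (q - 1)
    alpha[k] <- slope(aq[, k])
    f[k] <- slope(fq[, k])
  }
  qn <- ifelse(q_list < 0, paste0("qm", abs(q_list)), paste0("q", q_list))
  stats::setNames(c(d, max(alpha) - min(alpha), max(f) - min(f)),
                  c(paste0("mfd_", qn), "mfd_dalpha", "mfd_df"))
}
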