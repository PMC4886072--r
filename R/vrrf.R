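#' Fit a bagged CART forest
#'
#' Thin wrapper around [randomForest::randomForest()] with the tree settings
#' used throughout this package: each of `n_trees` CART trees is grown on a
#' bootstrap resample of the training set (same size, with replacement),
#' Gini split criterion, `sqrt(d)` candidate features per split, grown to
#' purity. Deterministic given `seed`.
#'
#' @param x numeric feature matrix (samples x features).
#' @param y factor of class labels; both classes must be present. The second
#'   level is the positive (HCC) class.
#' @param n_trees ensemble size.
#' @param seed RNG seed; `NULL` leaves the RNG state alone.
#' @return a `randomForest` ensemble.
#' @export
fit_forest <- function(x, y, n_trees = 500L, seed = NULL) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nrow(x) < 2L) stopf("need at least 2 samples")
  if (nlevels(y) < 2L) stopf("both classes must be present in `y`")
  if (!is.null(seed)) set.seed(as.integer(seed))
  randomForest::randomForest(x, y, ntree = as.integer(n_trees))
}

#' Per-sample vote counts of a forest
#'
#' Collects the class predicted by every tree for every sample into a
#' `samples x 2` vote matrix (columns: negative class, positive class). The
#' counts in each row sum to the ensemble size.
#'
#' @param ensemble a fitted `randomForest`.
#' @param x feature matrix with the training feature ordering.
#' @return integer matrix with one column per class.
#' @export
forest_votes <- function(ensemble, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(ensemble$forest$ncat))
    stopf("feature dimension mismatch: model has %d features, data has %d",
          length(ensemble$forest$ncat), ncol(x))
  v <- stats::predict(ensemble, x, type = "vote", norm.votes = FALSE)
  storage.mode(v) <- "double"
  rownames(v) <- NULL
  v
}

#' Candidate vote threshold
#'
#' The candidate decision threshold of one calibration iteration: the
#' maximum positive-class (HCC) vote count observed over the calibration
#' samples.
#'
#' @param votes vote matrix (samples x 2, positive class in column 2), as
#'   from [forest_votes()].
#' @return scalar candidate threshold.
#' @export
candidate_threshold <- function(votes) {
  if (is.null(dim(votes)) || nrow(votes) < 1L)
    stopf("vote matrix is empty")
  max(votes[, 2L])
}

#' Accuracy of thresholded votes
#'
#' Predicts the positive class wherever the positive vote count reaches the
#' threshold (`>=`) and returns the fraction of correct predictions.
#'
#' @param votes vote matrix (samples x 2, positive class in column 2).
#' @param labels factor aligned with `votes`; its second level is positive.
#' @param threshold vote threshold.
#' @return accuracy in `[0, 1]`.
#' @export
threshold_accuracy <- function(votes, labels, threshold) {
  labels <- as.factor(labels)
  if (nrow(votes) != length(labels))
    stopf("votes and labels have different lengths")
  pred_pos <- votes[, 2L] >= threshold
  truth_pos <- labels == levels(labels)[length(levels(labels))]
  mean(pred_pos == truth_pos)
}

#' Average the accuracy-ranked candidate thresholds
#'
#' Ranks the `(candidate, accuracy)` pairs by accuracy from high to low
#' (accuracy ties broken by the smaller candidate first, which favors
#' sensitivity), keeps the top `ceiling(k_frac * M)` rows and returns the
#' mean of their candidate values.
#'
#' @param pending numeric matrix with columns `candidate` and `accuracy`,
#'   one row per calibration iteration.
#' @param k_frac fraction of rows kept, in `(0, 1]`.
#' @return the calibrated threshold `t_mean`.
#' @export
calibrate_threshold <- function(pending, k_frac) {
  if (is.null(dim(pending)) || nrow(pending) < 1L)
    stopf("pending matrix is empty")
  n_keep <- ceiling(k_frac * nrow(pending))
  if (n_keep < 1L) stopf("k_frac keeps no rows")
  ord <- order(-pending[, 2L], pending[, 1L])
  mean(pending[ord[seq_len(n_keep)], 1L])
}

#' Voting-ranking random forest
#'
#' Fits a random-forest classifier whose decision threshold on positive
#' (HCC) votes is calibrated by voting ranking instead of being fixed at
#' half the ensemble. The calibration runs `M` iterations; each refits a
#' forest under a fresh derived seed, takes as candidate threshold the
#' maximum HCC vote count over the calibration samples, and scores that
#' candidate's accuracy on the same votes. The `M` (candidate, accuracy)
#' pairs -- the pending matrix -- are ranked by accuracy from high to low,
#' the top `ceiling(K * M)` candidates are kept, and their mean becomes the
#' threshold `t_mean`. A final forest is refit on all training data and is
#' used together with `t_mean` at prediction time.
#'
#' With `calibration = "oob"` (default) each iteration's votes are the
#' out-of-bag vote counts: for each training sample, the votes of the trees
#' whose bootstrap resample omitted it (about `exp(-1)` of the ensemble).
#' Training-set votes of purity-grown trees are almost perfectly memorized,
#' which would make the accuracy ranking meaningless; `calibration =
#' "train"` exposes that literal variant regardless. Note that with OOB
#' calibration the candidate thresholds live on the out-of-bag vote scale,
#' so the calibrated threshold typically lands near
#' `exp(-1) * n_trees` -- a sensitivity-leaning operating point compared
#' with the fixed majority threshold `n_trees / 2`.
#'
#' @param x numeric feature matrix, or a formula.
#' @param y factor of class labels (two classes; the second level --
#'   conventionally `"HCC"` -- is the positive class).
#' @param n_trees trees per forest (500 by default).
#' @param M number of calibration iterations (50 by default).
#' @param K fraction of accuracy-ranked candidates averaged into the final
#'   threshold (0.3 by default).
#' @param calibration which votes the calibration uses, see Details.
#' @param seed integer seed; iteration `m` uses `seed + m` and the final
#'   forest uses `seed`, so the whole fit is reproducible.
#' @param ... passed between methods.
#' @return an object of class `"vrrf"`: the final forest, the calibrated
#'   threshold `t_mean`, the pending matrix and the hyperparameters.
#' @seealso [predict.vrrf()], [cross_validate()]
#' @examples
#' tab <- generate_feature_table(50, separation = 5, seed = 1)
#' fit <- vrrf(tab$x, tab$labels, n_trees = 50, M = 5, seed = 1)
#' fit
#' @export
vrrf <- function(x, ...) UseMethod("vrrf")

#' @rdname vrrf
#' @param data data frame holding the formula variables.
#' @export
vrrf.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  xm <- stats::model.matrix(attr(mf, "terms"), mf)
  xm <- xm[, colnames(xm) != "(Intercept)", drop = FALSE]
  out <- vrrf.default(xm, y, ...)
  out$call <- match.call()
  out
}

#' @rdname vrrf
#' @export
vrrf.default <- function(x, y, n_trees = 500L, M = 50L, K = 0.3,
                         calibration = c("oob", "train"), seed = 1L, ...) {
  calibration <- match.arg(calibration)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stopf("vrrf is a binary classifier; got %d classes", nlevels(y))
  if (M < 1L) stopf("M must be >= 1")
  if (K <= 0 || K > 1) stopf("K must lie in (0, 1]")
  if (ceiling(K * M) < 1L) stopf("ceiling(K * M) must be >= 1")
  n_trees <- as.integer(n_trees)
  seed <- as.integer(seed)

  pos <- levels(y)[2L]
  pending <- matrix(NA_real_, M, 2L, dimnames = list(NULL, c("candidate", "accuracy")))
  for (m in seq_len(M)) {
    set.seed(seed + m)
    rf <- randomForest::randomForest(x, y, ntree = n_trees)
    if (calibration == "oob") {
      counts <- rf$votes * rf$oob.times   # OOB vote fractions -> counts
      keep <- rf$oob.times > 0
      v <- cbind(counts[keep, 1L], counts[keep, 2L])
      lab <- y[keep]
    } else {
      v <- forest_votes(rf, x)
      lab <- y
    }
    cand <- candidate_threshold(v)
    pending[m, ] <- c(cand, threshold_accuracy(v, lab, cand))
  }
  t_mean <- calibrate_threshold(pending, K)

  set.seed(seed)
  forest <- randomForest::randomForest(x, y, ntree = n_trees)

  structure(list(forest = forest, t_mean = t_mean, n_trees = n_trees,
                 M = as.integer(M), K = K, calibration = calibration,
                 pending_matrix = pending, levels = levels(y), positive = pos,
                 feature_names = colnames(x), seed = seed,
                 call = match.call()),
            class = "vrrf")
}

#' Predict with a voting-ranking random forest
#'
#' Collects the full-ensemble vote counts on `newdata` and predicts the
#' positive class wherever the positive vote count is at least the
#' calibrated threshold (`votes_hcc >= t_mean`; a tie at a fractional
#' threshold resolves to the positive class, since missing a carcinoma cell
#' is the costlier error).
#'
#' @param object a fitted [vrrf] model.
#' @param newdata feature matrix with the training feature ordering.
#' @param type `"class"` for labels, `"votes"` for the vote matrix.
#' @param threshold decision threshold; defaults to the calibrated
#'   `object$t_mean`. Forcing `n_trees / 2` recovers the conventional
#'   majority-vote random forest.
#' @param ... unused.
#' @return factor of predicted labels, or the vote matrix.
#' @export
predict.vrrf <- function(object, newdata, type = c("class", "votes"),
                         threshold = object$t_mean, ...) {
  type <- match.arg(type)
  v <- forest_votes(object$forest, newdata)
  if (type == "votes") return(v)
  pred <- ifelse(v[, 2L] >= threshold, object$levels[2L], object$levels[1L])
  factor(pred, levels = object$levels)
}

#' @export
print.vrrf <- function(x, ...) {
  cat("Voting-ranking random forest\n")
  cat(sprintf("  trees: %d   calibration iterations M: %d   K: %g (%s votes)\n",
              x$n_trees, x$M, x$K, x$calibration))
  cat(sprintf("  calibrated vote threshold t_mean: %.2f (fixed-threshold RF would use %g)\n",
              x$t_mean, x$n_trees / 2))
  cat(sprintf("  classes: %s (positive: %s)\n",
              paste(x$levels, collapse = " / "), x$positive))
  invisible(x)
}

#' @export
summary.vrrf <- function(object, ...) {
  out <- list(model = object,
              pending = object$pending_matrix,
              kept = ceiling(object$K * object$M))
  class(out) <- "summary.vrrf"
  out
}

#' @export
print.summary.vrrf <- function(x, ...) {
  print(x$model)
  pm <- x$pending[order(-x$pending[, "accuracy"], x$pending[, "candidate"]), ,
                  drop = FALSE]
  cat(sprintf("  pending matrix (top %d of %d averaged):\n", x$kept, nrow(pm)))
  print(utils::head(pm, x$kept))
  invisible(x)
}

#' @export
plot.vrrf <- function(x, ...) {
  pm <- x$pending_matrix
  graphics::plot(pm[, "candidate"], pm[, "accuracy"],
                 xlab = "candidate vote threshold", ylab = "calibration accuracy",
                 main = "Voting-ranking calibration", ...)
  graphics::abline(v = x$t_mean, lty = 2)
  invisible(x)
}
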