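#' Confusion-matrix metrics
#'
#' Counts true/false positives and negatives with HCC (the second factor
#' level of `truth` by default) as the positive class, and reports
#' \deqn{ACC = \frac{TP+TN}{TP+FN+TN+FP},\quad SEN = \frac{TP}{TP+FN},\quad
#'       SPE = \frac{TN}{TN+FP}.}
#' Sensitivity is the proportion of HCC cells correctly classified;
#' specificity the proportion of normal cells correctly classified. A ratio
#' with a zero denominator is reported as `NA` (flagged missing), never as 0.
#'
#' @param pred,truth factors or character vectors of equal length.
#' @param positive label of the positive class; defaults to the second level
#'   of `truth`.
#' @return object of class `"confusion_metrics"`: a list with counts
#'   `TP, FN, TN, FP` and ratios `ACC, SEN, SPE`.
#' @export
confusion_metrics <- function(pred, truth, positive = NULL) {
  if (length(pred) != length(truth)) stopf("pred and truth lengths differ")
  if (length(pred) == 0L) stopf("empty input")
  truth <- as.factor(truth)
  positive <- positive %||% levels(truth)[nlevels(truth)]
  p_pos <- as.character(pred) == positive
  t_pos <- as.character(truth) == positive
  tp <- sum(p_pos & t_pos); fn <- sum(!p_pos & t_pos)
  tn <- sum(!p_pos & !t_pos); fp <- sum(p_pos & !t_pos)
  ratio <- function(a, b) if (b > 0) a / b else NA_real_
  structure(list(TP = tp, FN = fn, TN = tn, FP = fp,
                 ACC = ratio(tp + tn, tp + fn + tn + fp),
                 SEN = ratio(tp, tp + fn),
                 SPE = ratio(tn, tn + fp),
                 positive = positive),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("confusion (positive = %s): TP %d  FN %d  TN %d  FP %d\n",
              x$positive, x$TP, x$FN, x$TN, x$FP))
  cat(sprintf("  ACC %.4f  SEN %.4f  SPE %.4f\n", x$ACC, x$SEN, x$SPE))
  invisible(x)
}

# stratified fold assignment: within each class, shuffle and deal 1..k
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in levels(y)) {
    idx <- which(y == cls)
    if (length(idx) < k)
      stopf("class '%s' has %d members, fewer than k = %d", cls, length(idx), k)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Repeated stratified k-fold cross-validation
#'
#' Evaluates the voting-ranking random forest (or the plain majority-vote
#' forest baseline) by `repeats` rounds of stratified `k`-fold
#' cross-validation. Each repeat reshuffles the folds under a distinct
#' derived seed; within a repeat, the classifier is trained on `k - 1` folds
#' and evaluated on the held-out fold. Per-fold accuracies are collected
#' into a `repeats x k` table; sensitivity and specificity are aggregated
#' from the confusion counts pooled over each repeat's folds. Folds are
#' stratified because a heavily imbalanced dataset would otherwise risk
#' single-class test folds.
#'
#' @param x feature matrix.
#' @param y factor of class labels (second level = positive class); every
#'   class needs at least `k` members.
#' @param k number of folds.
#' @param repeats number of repetitions.
#' @param seed base seed; repeat `r` shuffles with `seed + 1000 * r` and the
#'   fold-`f` model trains with `seed + 1000 * r + f`.
#' @param method `"vrrf"` or the fixed-threshold majority-vote baseline
#'   `"rf"`.
#' @param n_trees,M,K,calibration classifier hyperparameters, see [vrrf()].
#' @return object of class `"vrrf_cv"`: accuracy matrix (`repeats x k`),
#'   per-repeat means, `grand_mean`, pooled per-repeat sensitivity and
#'   specificity, and the seeds used.
#' @export
cross_validate <- function(x, y, k = 10L, repeats = 10L, seed = 1L,
                           method = c("vrrf", "rf"),
                           n_trees = 500L, M = 50L, K = 0.3,
                           calibration = "oob") {
  method <- match.arg(method)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stopf("cross_validate needs exactly two classes")
  k <- as.integer(k); repeats <- as.integer(repeats); seed <- as.integer(seed)

  acc <- matrix(NA_real_, repeats, k,
                dimnames = list(paste0("repeat", seq_len(repeats)),
                                paste0("fold", seq_len(k))))
  sen <- numeric(repeats); spe <- numeric(repeats)
  for (r in seq_len(repeats)) {
    set.seed(seed + 1000L * r)
    folds <- stratified_folds(y, k)
    counts <- c(TP = 0L, FN = 0L, TN = 0L, FP = 0L)
    for (f in seq_len(k)) {
      test <- folds == f
      fit_seed <- seed + 1000L * r + f
      if (method == "vrrf") {
        fit <- vrrf(x[!test, , drop = FALSE], y[!test], n_trees = n_trees,
                    M = M, K = K, calibration = calibration, seed = fit_seed)
        pred <- stats::predict(fit, x[test, , drop = FALSE])
      } else {
        set.seed(fit_seed)
        rf <- randomForest::randomForest(x[!test, , drop = FALSE], y[!test],
                                         ntree = as.integer(n_trees))
        pred <- stats::predict(rf, x[test, , drop = FALSE])
      }
      cm <- confusion_metrics(pred, y[test], positive = levels(y)[2L])
      acc[r, f] <- cm$ACC
      counts <- counts + c(TP = cm$TP, FN = cm$FN, TN = cm$TN, FP = cm$FP)
    }
    sen[r] <- counts[["TP"]] / (counts[["TP"]] + counts[["FN"]])
    spe[r] <- counts[["TN"]] / (counts[["TN"]] + counts[["FP"]])
  }
  structure(list(accuracy = acc,
                 repeat_means = rowMeans(acc),
                 grand_mean = mean(acc),
                 sensitivity = sen, specificity = spe,
                 method = method, k = k, repeats = repeats, seed = seed),
            class = "vrrf_cv")
}

#' @export
print.vrrf_cv <- function(x, digits = 4, ...) {
  cat(sprintf("%d x %d-fold cross-validation (%s)\n",
              x$repeats, x$k, x$method))
  print(round(x$accuracy, digits))
  cat(sprintf("per-repeat mean accuracy: %s\n",
              paste(round(x$repeat_means, digits), collapse = " ")))
  cat(sprintf("grand mean accuracy %.4f | pooled SEN %.4f | pooled SPE %.4f\n",
              x$grand_mean, mean(x$sensitivity), mean(x$specificity)))
  invisible(x)
}
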