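make_table <- function(n = 60, sep = 10, seed = 1)
  generate_feature_table(n, separation = sep, seed = seed)

test_that("fit_forest builds deterministic bagged ensembles", {
  tab <- make_table(30)
  f1 <- fit_forest(tab$x, tab$labels, n_trees = 1, seed = 3)
  expect_equal(f1$ntree, 1)

  fa <- fit_forest(tab$x, tab$labels, n_trees = 25, seed = 3)
  fb <- fit_forest(tab$x, tab$labels, n_trees = 25, seed = 3)
  expect_identical(fa$oob.times, fb$oob.times)
  expect_identical(fa$votes, fb$votes)

  expect_error(fit_forest(tab$x[tab$labels == "HCC", ],
                          tab$labels[tab$labels == "HCC"]), "both classes")

  # separable data: training votes at the majority threshold are perfect
  fc <- fit_forest(tab$x, tab$labels, n_trees = 50, seed = 1)
  v <- forest_votes(fc, tab$x)
  expect_equal(threshold_accuracy(v, tab$labels, 25), 1.0)
})

test_that("vote matrices conserve the ensemble size", {
  tab <- make_table(20, sep = 2)
  f <- fit_forest(tab$x, tab$labels, n_trees = 30, seed = 2)
  v <- forest_votes(f, tab$x)
  expect_true(all(rowSums(v) == 30))
  expect_identical(colnames(v), c("normal", "HCC"))

  f1 <- fit_forest(tab$x, tab$labels, n_trees = 1, seed = 2)
  v1 <- forest_votes(f1, tab$x)
  expect_true(all(v1 %in% c(0, 1)) && all(rowSums(v1) == 1))

  vdup <- forest_votes(f, tab$x[c(1, 1, 5, 5), ])
  expect_identical(vdup[1, ], vdup[2, ])
  expect_identical(vdup[3, ], vdup[4, ])

  expect_error(forest_votes(f, tab$x[, 1:3]), "dimension mismatch")
})

test_that("candidate threshold is the maximum HCC vote", {
  v <- cbind(c(20, 188, 405), c(480, 312, 95))
  expect_equal(candidate_threshold(v), 480)
  expect_equal(candidate_threshold(cbind(c(500, 500), c(0, 0))), 0)
  expect_equal(candidate_threshold(cbind(130, 370)), 370)
  expect_error(candidate_threshold(v[0, , drop = FALSE]), "empty")
})

test_that("threshold accuracy handles degenerate thresholds", {
  v <- cbind(c(100, 400, 250, 50), c(400, 100, 250, 450))
  y <- factor(c("HCC", "normal", "HCC", "normal"),
              levels = c("normal", "HCC"))
  expect_equal(threshold_accuracy(v, y, 0), 0.5)        # everything HCC
  expect_equal(threshold_accuracy(v, y, 501), 0.5)      # nothing HCC
  v2 <- cbind(c(100, 400), c(400, 100))
  y2 <- factor(c("HCC", "normal"), levels = c("normal", "HCC"))
  expect_equal(threshold_accuracy(v2, y2, 250), 1.0)
  expect_error(threshold_accuracy(v2, y, 250), "lengths")
})

test_that("voting-ranking calibration reproduces hand-worked examples", {
  pend <- cbind(candidate = c(480, 300, 350), accuracy = c(0.9, 0.99, 0.95))
  expect_equal(calibrate_threshold(pend, 2 / 3), (300 + 350) / 2)
  expect_equal(calibrate_threshold(pend, 1), mean(c(480, 300, 350)))
  # accuracy ties break toward the smaller candidate
  tied <- cbind(candidate = c(400, 200, 300), accuracy = c(0.8, 0.8, 0.8))
  expect_equal(calibrate_threshold(tied, 1 / 3), 200)

  tab <- make_table(40)
  m1 <- vrrf(tab$x, tab$labels, n_trees = 50, M = 1, seed = 6)
  expect_equal(m1$t_mean, m1$pending_matrix[1, "candidate"][[1]])
  mk <- vrrf(tab$x, tab$labels, n_trees = 50, M = 5, K = 1, seed = 6)
  expect_equal(mk$t_mean, mean(mk$pending_matrix[, "candidate"]))
})

test_that("vrrf reduces to a plain majority-vote forest when forced", {
  tab <- make_table(60, sep = 3, seed = 2)
  test <- make_table(40, sep = 3, seed = 9)
  fit <- vrrf(tab$x, tab$labels, n_trees = 101, M = 1, K = 1, seed = 17)
  set.seed(17)
  rf <- randomForest::randomForest(tab$x, tab$labels, ntree = 101)
  expect_identical(as.character(predict(fit, test$x, threshold = 101 / 2)),
                   as.character(predict(rf, test$x)))
})

test_that("vrrf predicts separable data perfectly and degenerates sanely", {
  tab <- make_table(100)
  test <- make_table(50, seed = 5)
  fit <- vrrf(tab$x, tab$labels, n_trees = 100, M = 10, seed = 1)
  expect_equal(mean(predict(fit, test$x) == test$labels), 1.0)
  expect_true(fit$t_mean >= 0 && fit$t_mean <= fit$n_trees)

  # threshold 0 predicts everything positive
  all_hcc <- predict(fit, test$x, threshold = 0)
  expect_true(all(all_hcc == "HCC"))

  # raising the threshold never increases the number of HCC calls
  v <- predict(fit, test$x, type = "votes")
  n_hcc <- vapply(seq(0, 100, by = 10),
                  function(t) sum(v[, 2] >= t), numeric(1))
  expect_true(all(diff(n_hcc) <= 0))

  expect_error(vrrf(tab$x, tab$labels, M = 0), "M must be")
  expect_error(vrrf(tab$x, tab$labels, K = 0), "K must lie")
  expect_error(predict(fit, test$x[, 1:4]), "dimension mismatch")
})

test_that("vrrf matches plain RF accuracy on moderately separated data", {
  tab <- make_table(150, sep = 3, seed = 8)
  test <- make_table(100, sep = 3, seed = 21)
  fit <- vrrf(tab$x, tab$labels, n_trees = 100, M = 20, seed = 2)
  set.seed(2)
  rf <- randomForest::randomForest(tab$x, tab$labels, ntree = 100)
  acc_v <- mean(predict(fit, test$x) == test$labels)
  acc_r <- mean(predict(rf, test$x) == test$labels)
  expect_gte(acc_v, acc_r - 0.02)
  expect_gte(acc_v, 0.95)
})
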