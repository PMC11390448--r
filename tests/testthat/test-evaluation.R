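test_that("confusion_at_threshold partitions the cohort", {
  cm <- confusion_at_threshold(c(0.9, 0.1), c(1, 0), 0.5)
  expect_identical(unclass(cm)[c("TP", "FP", "TN", "FN")],
                   list(TP = 1L, FP = 0L, TN = 1L, FN = 0L))
  all_pos <- confusion_at_threshold(c(0.2, 0.7, 0.4), c(1, 0, 1), 0)
  expect_identical(all_pos$TN + all_pos$FN, 0L)
  none <- confusion_at_threshold(c(0.2, 0.7), c(1, 0), 0.71)
  expect_identical(none$TP + none$FP, 0L)
  expect_error(confusion_at_threshold(c(0.1), c(1, 0)), "length")
})

test_that("summary_metrics computes the standard ratios and refuses 0/0", {
  expect_equal(summary_metrics(list(TP = 9, FN = 1, TN = 1, FP = 1))$sensitivity, 0.9)
  expect_equal(summary_metrics(list(TP = 1, FN = 1, TN = 0, FP = 5))$specificity, 0)
  expect_equal(summary_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))$accuracy, 1)
  expect_error(summary_metrics(list(TP = 0, FN = 0, TN = 3, FP = 1)), "sensitivity undefined")
  expect_error(summary_metrics(list(TP = 2, FN = 1, TN = 0, FP = 0)), "specificity undefined")
})

test_that("roc_auc equals pair counting, with ties and symmetry", {
  expect_identical(roc_auc(c(0.9, 0.8, 0.1, 0.7), c(1, 1, 0, 0)), 1)
  # derived by exhaustive pair counting: 3 of 4 pairs concordant
  expect_identical(roc_auc(c(0.9, 0.4, 0.1, 0.7), c(1, 1, 0, 0)), 0.75)
  s <- c(0.9, 0.4, 0.1, 0.7)
  y <- c(1, 1, 0, 0)
  expect_equal(roc_auc(s, 1 - y), 1 - roc_auc(s, y))
  expect_error(roc_auc(c(0.5, 0.6), c(1, 1)), "one class")

  set.seed(7)
  for (trial in 1:50) {
    n <- sample(4:20, 1)
    y <- c(0, 1, sample(0:1, n - 2, TRUE))
    s <- round(runif(n), sample(c(1, 2), 1))  # rounding forces ties
    expect_identical(roc_auc(s, y), brute_auc(s, y))
  }
})

test_that("roc_points spans (0,0) to (1,1) monotonically", {
  pts <- roc_points(c(0.9, 0.4, 0.1, 0.7), c(1, 1, 0, 0))
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})

test_that("delong_ci handles separation, containment and degenerate input", {
  est <- delong_ci(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_identical(est$auc, 1)
  expect_identical(est$variance, 0)
  expect_identical(c(est$ci_low, est$ci_high), c(1, 1))

  set.seed(11)
  for (trial in 1:25) {
    n1 <- sample(2:15, 1); n0 <- sample(2:15, 1)
    s <- c(rnorm(n1, 0.5), rnorm(n0))
    y <- rep(c(1, 0), c(n1, n0))
    est <- delong_ci(s, y)
    expect_gte(est$ci_low, 0); expect_lte(est$ci_high, 1)
    expect_lte(est$ci_low, est$auc); expect_gte(est$ci_high, est$auc)
    expect_equal(est$auc, roc_auc(s, y))
    expect_gte(est$variance, 0)
  }
  expect_error(delong_ci(c(0.1, 0.5, 0.9), c(1, 0, 0)), "at least 2")
})

test_that("dice_score follows the overlap formula with the both-empty convention", {
  a <- array(0L, c(4, 4, 2)); a[1:2, 1:2, 1] <- 1L
  expect_identical(dice_score(a, a), 1)
  b <- array(0L, c(4, 4, 2)); b[3:4, 3:4, 2] <- 1L
  expect_identical(dice_score(a, b), 0)
  # |A| = |B| = 4, overlap 2
  c1 <- array(0L, c(4, 4, 1)); c1[1:4, 1, 1] <- 1L
  c2 <- array(0L, c(4, 4, 1)); c2[3:4, 1, 1] <- 1L; c2[1:2, 2, 1] <- 1L
  expect_identical(dice_score(c1, c2), 0.5)
  empty <- array(0L, c(4, 4, 1))
  expect_identical(dice_score(empty, empty), 1)
  expect_error(dice_score(a, array(0L, c(4, 4, 3))), "shape")
})
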