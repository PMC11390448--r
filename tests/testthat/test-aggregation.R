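test_that("summarize_probs builds a normalized, invariant histogram", {
  expect_identical(summarize_probs(c(0, 0, 0), 10), c(1, rep(0, 9)))
  expect_identical(summarize_probs(0.95, 10), c(rep(0, 9), 1))
  expect_identical(summarize_probs(1, 10)[10], 1)  # last bin right-closed
  p <- c(0.12, 0.55, 0.55, 0.98)
  expect_equal(sum(summarize_probs(p, 7)), 1)
  expect_identical(summarize_probs(p, 10), summarize_probs(rep(p, 2), 10))
  expect_identical(summarize_probs(p, 10), summarize_probs(rev(p), 10))
  expect_error(summarize_probs(numeric(0)), "empty")
  expect_error(summarize_probs(c(0.5, 1.2)), "\\[0, 1\\]")
})

sep_toy <- function(n = 12) {
  # controls concentrated in the first bin, cases in the last
  s_ctrl <- matrix(rep(c(1, rep(0, 9)), n), n, 10, byrow = TRUE)
  s_case <- matrix(rep(c(rep(0, 9), 1), n), n, 10, byrow = TRUE)
  list(x = rbind(s_ctrl, s_case), y = rep(c(0L, 1L), each = n))
}

test_that("the aggregator fits separable summaries (logistic-regression oracle agrees)", {
  toy <- sep_toy()
  # oracle: plain logistic regression separates these summaries perfectly
  oracle <- suppressWarnings(
    stats::glm(toy$y ~ toy$x[, 1] + toy$x[, 10], family = stats::binomial())
  )
  expect_identical(mean((stats::fitted(oracle) >= 0.5) == (toy$y == 1)), 1)

  agg <- train_aggregator(toy$x, toy$y, aggregator_config(), seed = 4, epochs = 200)
  p <- vapply(seq_len(nrow(toy$x)), function(i) {
    predict_patient(agg, toy$x[i, ], summarized = TRUE)$probability
  }, numeric(1))
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(mean((p >= 0.5) == (toy$y == 1)), 1)  # training accuracy 1.0

  # all-zero instance probabilities -> first-bin summary -> decision 0
  pred0 <- predict_patient(agg, rep(0, 25), threshold = 0.5)
  expect_identical(pred0$decision, 0L)

  # same seed twice -> identical weights
  agg2 <- train_aggregator(toy$x, toy$y, aggregator_config(), seed = 4, epochs = 200)
  expect_identical(agg$net$par, agg2$net$par)

  expect_error(train_aggregator(toy$x, rep(0L, nrow(toy$x))), "both classes")
})

test_that("validation split selects the stored parameters deterministically", {
  toy <- sep_toy(8)
  val <- sep_toy(4)
  agg <- train_aggregator(toy$x, toy$y, aggregator_config(), seed = 9,
                          epochs = 120, validation = list(summaries = val$x, labels = val$y))
  expect_false(is.na(agg$net$best_epoch))
  expect_lte(agg$net$best_epoch, 120)
  p <- predict_patient(agg, val$x[1, ], summarized = TRUE)$probability
  expect_lt(p, 0.5)
})

test_that("patient predictions are permutation-invariant and thresholded", {
  toy <- sep_toy()
  agg <- train_aggregator(toy$x, toy$y, aggregator_config(), seed = 4, epochs = 150)
  probs <- c(0.1, 0.8, 0.3, 0.95, 0.2)
  a <- predict_patient(agg, probs, threshold = 0.5, patient_id = "z")
  b <- predict_patient(agg, sample(probs), threshold = 0.5)
  expect_identical(a$probability, b$probability)
  expect_true(a$decision %in% c(0L, 1L))
  expect_identical(a$decision, as.integer(a$probability >= 0.5))
  expect_error(predict_patient(agg, numeric(0)), "empty")
})
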