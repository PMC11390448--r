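toy_stack <- function(n, value = 0, id = "p", size = 8) {
  arr <- array(value, c(size, size, n))
  structure(list(instances = arr, slice_indices = seq_len(n), patient_id = id),
            class = "instance_stack")
}

test_that("make_bags pairs stacks with labels and validates", {
  stacks <- list(toy_stack(3, id = "a"), toy_stack(2, id = "b"), toy_stack(4, id = "c"))
  bags <- make_bags(stacks, c(a = 1, b = 0, c = 0))
  expect_identical(vapply(bags, `[[`, integer(1), "label"), c(1L, 0L, 0L))
  expect_identical(dim(bags[[1]]$instances$instances)[3], 3L)
  expect_error(make_bags(stacks, c(a = 1, b = 0)), "missing label for patient c")
  expect_error(make_bags(stacks, c(a = 2, b = 0, c = 0)), "0 or 1")
})

test_that("extract_features is deterministic with constant width", {
  arr <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  arr[, , 3] <- arr[, , 1]  # identical instances -> identical features
  ext <- extractor_cnn(seed = 4)
  f <- extract_features(arr, ext)
  expect_identical(dim(f)[1], 5L)
  expect_identical(f[1, ], f[3, ])
  expect_identical(f, extract_features(arr, extractor_cnn(seed = 4)))
  expect_false(identical(f, extract_features(arr, extractor_cnn(seed = 5))))

  # mean-pool baseline on a constant image gives a constant feature vector
  const <- array(2.5, c(16, 16, 2))
  fp <- extract_features(const, extractor_pool(pool = c(4, 4)))
  expect_true(all(fp == 2.5))
})

test_that("assign_pseudo_labels follows the far-cluster rule with deterministic ties", {
  f <- rbind(matrix(10, 3, 2), matrix(1, 4, 2))
  cl <- c(1L, 1L, 1L, 2L, 2L, 2L, 2L)
  neg <- c(0, 0)
  expect_identical(assign_pseudo_labels(f, cl, neg), c(1L, 1L, 1L, 0L, 0L, 0L, 0L))
  # swap: cluster 2 is far
  expect_identical(assign_pseudo_labels(f, c(2L, 2L, 2L, 1L, 1L, 1L, 1L), neg),
                   c(1L, 1L, 1L, 0L, 0L, 0L, 0L))
  # equidistant clusters tie-break to cluster 1 with a warning
  tied <- rbind(matrix(c(1, 0), 2, 2, byrow = TRUE), matrix(c(-1, 0), 2, 2, byrow = TRUE))
  expect_warning(out <- assign_pseudo_labels(tied, c(1L, 1L, 2L, 2L), c(0, 0)), "tie")
  expect_identical(out, c(1L, 1L, 0L, 0L))
})

test_that("feature standardization centers the reference set", {
  x <- matrix(rnorm(200, 3, 2), 50, 4)
  st <- feature_stats(x)
  z <- standardize_features(x, st)
  expect_true(all(abs(colMeans(z)) < 1e-10))
  expect_equal(unname(apply(z, 2, sd)), rep(1, 4), tolerance = 1e-10)
})

test_that("negative bags never receive positive pseudo-labels; positive bags get >= 1", {
  fx <- mil_fixture(ph_small(n_cases = 3, n_controls = 3, noise_sd = 5))
  pl <- pseudo_label_bags(fx$bags, fx$features, fx$negative_features, seed = 2)
  for (i in seq_along(fx$bags)) {
    if (fx$bags[[i]]$label == 0L) {
      expect_true(all(pl[[i]] == 0L))  # hard bag-label consistency
    } else {
      expect_gte(sum(pl[[i]]), 1L)
    }
    expect_length(pl[[i]], dim(fx$bags[[i]]$instances$instances)[3])
  }
  # pooled mode keeps the same guarantees
  plp <- pseudo_label_bags(fx$bags, fx$features, fx$negative_features,
                           seed = 2, pooled = TRUE)
  for (i in seq_along(fx$bags)) {
    if (fx$bags[[i]]$label == 0L) expect_true(all(plp[[i]] == 0L))
    else expect_gte(sum(plp[[i]]), 1L)
  }
})

test_that("single-instance positive bags skip clustering and get label 1", {
  stacks <- list(toy_stack(1, 5, "solo"), toy_stack(3, 0, "neg"))
  bags <- make_bags(stacks, c(solo = 1, neg = 0))
  feats <- list(matrix(5, 1, 4), matrix(rnorm(12), 3, 4))
  pl <- pseudo_label_bags(bags, feats, feats[2], seed = 1)
  expect_identical(pl[[1]], 1L)
})

test_that("pseudo-labels recover tumor slices on a noiseless high-contrast cohort", {
  fx <- mil_fixture(ph_small(n_cases = 4, n_controls = 4, noise_sd = 0,
                             tumor_intensity = -100, seed = 17))
  pl <- pseudo_label_bags(fx$bags, fx$features, fx$negative_features, seed = 3)
  pos <- which(fx$labels == 1)
  pred <- unlist(pl[pos])
  gt <- unlist(lapply(fx$stacks[pos], `[[`, "gt"))
  # the tiny fixture's organ spans only ~5 axial slices, so boundary slices
  # (tumor cap clipping a slice) weigh heavily; the full-size cohort bound
  # (>= 0.95) lives in test-acceptance.R
  expect_gte(mean(pred == gt), 0.7)
  # orientation is never inverted: tumor slices are enriched for label 1
  expect_gt(mean(pred[gt == 1]), mean(pred[gt == 0]))
})

test_that("the instance classifier trains to a separable optimum and predicts probabilities", {
  set.seed(42)
  n <- 60
  f1 <- matrix(rnorm(n * 6, 3), n, 6)
  f0 <- matrix(rnorm(n * 6, -3), n, 6)
  x <- rbind(f1, f0)
  y <- rep(c(1L, 0L), each = n)
  # margin-check oracle: projection on the class-mean difference separates
  w <- colMeans(f1) - colMeans(f0)
  margin <- min(f1 %*% w) - max(f0 %*% w)
  expect_gt(margin, 0)

  clf <- train_instance_classifier(x, y, head_config(dense_units = 32),
                                   epochs = 150, seed = 6)
  p <- predict_instance_probs(clf, x)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(mean((p >= 0.5) == (y == 1)), 1)  # training accuracy 1.0
  P <- milct:::mlp_predict(clf$net, x)  # both softmax components
  expect_equal(unname(rowSums(P)), rep(1, nrow(x)), tolerance = 1e-6)

  # seeded determinism
  clf2 <- train_instance_classifier(x, y, head_config(dense_units = 32),
                                    epochs = 150, seed = 6)
  expect_identical(predict_instance_probs(clf2, x), p)

  expect_error(train_instance_classifier(x, rep(1L, nrow(x))), "single")
})

test_that("instance probabilities are per-instance maps (order invariant)", {
  set.seed(1)
  x <- matrix(rnorm(80), 10, 8)
  clf <- train_instance_classifier(rbind(x + 2, x - 2),
                                   rep(c(1L, 0L), each = 10),
                                   head_config(dense_units = 16),
                                   epochs = 60, seed = 2)
  p <- predict_instance_probs(clf, x)
  perm <- sample(10)
  expect_equal(predict_instance_probs(clf, x[perm, ]), p[perm], tolerance = 1e-12)
  # identical instances give identical probabilities
  xx <- x[c(1, 1, 1), ]
  expect_length(unique(predict_instance_probs(clf, xx)), 1L)
})
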