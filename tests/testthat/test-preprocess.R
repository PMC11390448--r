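rec <- function(id = "p1", slices = 1:5, spacing = c(0.7, 0.7), orient = "axial",
                qa = FALSE) {
  series_record(id, slices, spacing, orient, qa)
}

test_that("screen_series applies each exclusion rule", {
  report <- screen_series(list(
    rec("gap", slices = c(1, 2, 4)),
    rec("spc", spacing = rbind(c(0.7, 0.7), c(0.8, 0.8), c(0.7, 0.7), c(0.7, 0.7), c(0.7, 0.7))),
    rec("ori", orient = c("axial", "axial", "coronal", "axial", "axial")),
    rec("qa", qa = TRUE),
    rec("ok")
  ))
  expect_s3_class(report, "exclusion_report")
  expect_identical(report$status, c(rep("excluded", 4), "included"))
  expect_identical(report$reason[1:4],
                   c("incomplete_series", "inconsistent_spacing",
                     "inconsistent_orientation", "segmentation_error"))
  expect_true(is.na(report$reason[5]))
  # included and excluded partition the input
  expect_setequal(report$patient_id, c("gap", "spc", "ori", "qa", "ok"))

  empty <- screen_series(list())
  expect_identical(nrow(empty), 0L)
})

test_that("first failing check wins, in a stable priority order", {
  # a record failing several checks always reports the highest-priority reason,
  # however the defects are combined
  defects <- list(
    incomplete_series = function(r) { r$slices <- c(1, 3, 4, 5, 6); r },
    inconsistent_spacing = function(r) { r$spacing <- rbind(c(0.7, 0.7), c(0.9, 0.9), c(0.7, 0.7), c(0.7, 0.7), c(0.7, 0.7)); r },
    inconsistent_orientation = function(r) { r$orient <- c("axial", "sagittal", "axial", "axial", "axial"); r },
    segmentation_error = function(r) { r$qa <- TRUE; r }
  )
  priority <- names(defects)
  base <- list(slices = 1:5, spacing = c(0.7, 0.7), orient = "axial", qa = FALSE)
  for (perm in list(1:4, 4:1, c(2, 4, 1, 3), c(3, 1, 4, 2))) {
    for (k in 2:4) {
      chosen <- perm[1:k]
      r <- base
      for (d in chosen) r <- defects[[d]](r)
      rep <- screen_series(list(series_record("x", r$slices, r$spacing, r$orient, r$qa)))
      expect_identical(rep$reason, priority[min(chosen)])
    }
  }
})

test_that("spacing tolerance of 1e-3 mm is honored", {
  ok <- rec("tol", spacing = rbind(c(0.7, 0.7), c(0.7005, 0.7), c(0.7, 0.7), c(0.7, 0.7), c(0.7, 0.7)))
  expect_identical(screen_series(list(ok))$status, "included")
  bad <- rec("tol", spacing = rbind(c(0.7, 0.7), c(0.702, 0.7), c(0.7, 0.7), c(0.7, 0.7), c(0.7, 0.7)))
  expect_identical(screen_series(list(bad))$reason, "inconsistent_spacing")
})

test_that("resample_image follows the stated shape convention and preserves constants", {
  img <- array(3.25, c(8, 8, 32))
  out <- resample_image(img, spacing = c(1, 1, 2), target_spacing = c(1, 1, 1))
  expect_identical(dim(out$data), c(8L, 8L, 64L))
  expect_equal(out$spacing, c(1, 1, 1))
  expect_equal(max(abs(out$data - 3.25)), 0, tolerance = 1e-10)

  # identity target returns the array unchanged
  x <- array(rnorm(6 * 7 * 8), c(6, 7, 8))
  same <- resample_image(x, c(1, 1.5, 2.5), c(1, 1.5, 2.5))
  expect_identical(same$data, x)

  expect_error(resample_image(x, c(1, 1, 1), c(1, 0, 1)), "target_spacing")
})

test_that("resampling there and back restores the original shape for ratio-compatible spacings", {
  # the round() shape convention guarantees the round trip whenever
  # n * s1 / s2 is (near-)integral, which covers the spacings used here;
  # e.g. 64 slices at 1 mm -> 2.5 mm (round(25.6) = 26) does not round-trip
  for (case in list(c(32, 2.5, 1), c(16, 1.5, 1), c(20, 1, 2), c(25, 1, 2.5))) {
    n <- case[1]
    x <- array(rnorm(4 * 4 * n), c(4, 4, n))
    there <- resample_image(x, c(1, 1, case[2]), c(1, 1, case[3]))
    back <- resample_image(there$data, there$spacing, c(1, 1, case[2]))
    expect_identical(dim(back$data)[3], as.integer(n))
  }
})

test_that("mask resampling is nearest-neighbor: value set preserved, oracle-exact", {
  m <- array(0L, c(6, 6, 6)); m[2:3, 4, 2] <- 1L; m[5, 5, 5] <- 2L
  out <- resample_mask(m, c(1, 1, 1), c(0.8, 0.8, 0.8))
  expect_true(all(out$data %in% c(0, 1, 2)))

  # independent brute-force nearest-neighbor oracle on the same grid
  nn_oracle <- function(mask, s, t) {
    d <- dim(mask)
    nd <- pmax(round(d * s / t), 1)
    out <- array(0, nd)
    for (i in seq_len(nd[1])) for (j in seq_len(nd[2])) for (k in seq_len(nd[3])) {
      src <- vapply(1:3, function(a) {
        coord <- (c(i, j, k)[a] - 1) * t[a] / s[a]
        which.min(abs(seq_len(d[a]) - 1 - coord))
      }, integer(1))
      out[i, j, k] <- mask[src[1], src[2], src[3]]
    }
    out
  }
  expect_identical(out$data + 0, nn_oracle(m, c(1, 1, 1), c(0.8, 0.8, 0.8)) + 0)

  # single positive voxel survives 2x upsampling
  single <- array(0L, c(5, 5, 5)); single[3, 3, 3] <- 1L
  up <- resample_mask(single, c(1, 1, 1), c(0.5, 0.5, 0.5))
  expect_gte(sum(up$data), 1)

  zero <- resample_mask(array(0L, c(5, 5, 5)), c(1, 1, 1), c(0.8, 1, 1.3))
  expect_true(all(zero$data == 0))
})

test_that("global normalization is the stated affine map", {
  expect_equal(normalize_global(array(5, c(2, 2, 2)), list(mean = 5, sd = 1)),
               array(0, c(2, 2, 2)))
  expect_equal(normalize_global(c(0, 2), list(mean = 1, sd = 1)), c(-1, 1))

  x <- rnorm(500, 40, 7)
  st <- normalization_stats(x)
  z <- normalize_global(x, st)
  expect_lt(abs(mean(z)), 1e-9)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)

  expect_error(normalize_global(x, list(mean = 0, sd = 0)), "sd")
  expect_error(normalization_stats(rep(3, 10)), "sd")
})
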