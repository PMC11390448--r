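test_that("phantom_config validates fields and names the offender", {
  expect_error(phantom_config(grid_shape = c(4, 64, 32)), "grid_shape")
  expect_error(phantom_config(spacing = c(1, -1, 2)), "spacing")
  expect_error(phantom_config(tumor_radius = 25, organ_radius = 20), "tumor_radius")
  expect_error(phantom_config(noise_sd = -1), "noise_sd")
  expect_error(phantom_config(n_cases = -2), "n_cases")
  expect_error(generate_patient(ph_small(tumor_radius = 0), 1, 1), "tumor_radius")
})

test_that("generate_patient is deterministic and satisfies the volume invariants", {
  cfg <- ph_small(noise_sd = 6)
  for (label in c(0L, 1L)) {
    a <- generate_patient(cfg, label, seed = 11)
    b <- generate_patient(cfg, label, seed = 11)
    expect_identical(a$image, b$image)
    expect_identical(a$tumor_mask, b$tumor_mask)
    c <- generate_patient(cfg, label, seed = 12)
    expect_false(identical(a$image, c$image))
  }
  # property loop: containment, label rule, minority of axial slices
  for (seed in 1:10) {
    label <- seed %% 2L
    v <- generate_patient(cfg, label, seed)
    expect_true(all(v$tumor_mask <= v$organ_mask))
    expect_identical(v$label == 1L, any(v$tumor_mask > 0))
    n_organ_slices <- length(slices_with_organ(v$organ_mask))
    expect_gt(n_organ_slices, 0)
    expect_lt(n_organ_slices, dim(v$organ_mask)[3] / 2)
  }
})

test_that("noiseless construction paints exact intensities and is threshold-separable", {
  cfg <- ph_small(noise_sd = 0)
  v <- generate_patient(cfg, 1, seed = 3)
  expect_true(all(v$image[v$tumor_mask == 1] == cfg$tumor_intensity))
  organ_only <- v$organ_mask == 1 & v$tumor_mask == 0
  expect_true(all(v$image[organ_only] == cfg$organ_intensity))
  expect_true(all(v$image[v$organ_mask == 0] == cfg$background_intensity))
  # a single intensity threshold separates tumor from organ voxels
  thr <- (cfg$tumor_intensity + cfg$organ_intensity) / 2
  inside <- v$organ_mask == 1
  expect_identical(v$image[inside] < thr, v$tumor_mask[inside] == 1)
})

test_that("control volumes carry no tumor", {
  v <- generate_patient(ph_small(), 0, seed = 2)
  expect_identical(sum(v$tumor_mask), 0L)
  expect_identical(v$label, 0L)
})

test_that("generate_cohort matches requested composition and is reproducible", {
  cfg <- ph_small(n_cases = 3, n_controls = 5, seed = 21)
  cohort <- generate_cohort(cfg)
  expect_length(cohort, 8)
  expect_identical(sum(vapply(cohort, `[[`, integer(1), "label")), 3L)
  again <- generate_cohort(cfg)
  expect_identical(lapply(cohort, `[[`, "image"), lapply(again, `[[`, "image"))

  none <- generate_cohort(ph_small(n_cases = 0, n_controls = 3))
  expect_true(all(vapply(none, `[[`, integer(1), "label") == 0L))
  expect_error(generate_cohort(ph_small(n_cases = 0, n_controls = 0)), "n_cases")
})

test_that("write_study round-trips arrays, spacing and label", {
  v <- generate_patient(ph_small(noise_sd = 4), 1, seed = 9)
  dir <- withr::local_tempdir()
  paths <- write_study(v, dir)
  expect_true(all(file.exists(paths)))
  back <- read_study(dir)
  expect_equal(back$image, v$image, tolerance = 1e-5)
  expect_identical(back$organ_mask, v$organ_mask)
  expect_identical(back$tumor_mask, v$tumor_mask)
  expect_equal(back$spacing, v$spacing, tolerance = 1e-6)  # anisotropic survives
  expect_identical(back$label, 1L)

  ctrl <- generate_patient(ph_small(), 0, seed = 10)
  dir2 <- withr::local_tempdir()
  write_study(ctrl, dir2)
  expect_identical(sum(read_study(dir2)$tumor_mask), 0L)
})
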