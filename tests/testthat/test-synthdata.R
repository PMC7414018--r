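test_that("phantom masks are disjoint, sized, fully parcellated, reproducible", {
  masks <- phantom_masks(grid_shape = c(40, 48, 40), voxel_size_mm = 2, seed = 1)
  counts <- table(masks$nucleus_labels[masks$nucleus_labels > 0])
  expect_length(counts, 4)
  expect_true(all(counts >= 150 & counts <= 1500))
  # every in-nucleus voxel carries a territory code in 1..7, each code present
  for (nuc in 1:4) {
    terr <- masks$territory_labels[masks$nucleus_labels == nuc]
    expect_true(all(terr %in% 1:7))
    expect_setequal(unique(terr), 1:7)
    # partition: territory counts sum to the nucleus size
    expect_equal(sum(table(terr)), sum(masks$nucleus_labels == nuc))
  }
  expect_true(all(masks$territory_labels[masks$nucleus_labels == 0] == 0))

  # determinism given seed; different seed, different phantom
  expect_identical(masks$nucleus_labels,
                   phantom_masks(seed = 1)$nucleus_labels)
  expect_false(identical(masks$nucleus_labels,
                         phantom_masks(seed = 2)$nucleus_labels))
})

test_that("a too-small grid names the nucleus that does not fit", {
  expect_error(phantom_masks(grid_shape = c(10, 12, 10), voxel_size_mm = 2),
               "too small.*left_putamen")
})

test_that("beta generator enforces exact per-voxel class-mean balance", {
  masks <- small_masks()
  des <- synthetic_design(n_subjects = 3, seed = 2)
  ds <- simulate_betas(des, masks,
                       pattern_spec(n_informative_voxels = 15, pattern_sd = 1,
                                    noise_sd = 1e-8, subject_offset_sd = 0,
                                    run_offset_sd = 0,
                                    baseline_map_amplitude = 0))
  # with noise switched (almost) off, the per-voxel class mean of each
  # subject x run block is the centred pattern: zero to machine precision
  for (s in 1:3) for (r in 1:6) {
    rows <- ds$index$row[ds$index$subject == s & ds$index$run == r]
    expect_lt(max(abs(colMeans(ds$betas[rows, ]))), 1e-6)
  }
  # pattern confined to the informative voxels
  info_cols <- match(ds$truth$informative_voxels, ds$voxels$voxel)
  quiet <- ds$betas[, -info_cols]
  expect_lt(max(abs(quiet)), 1e-6)
  expect_gt(max(abs(ds$betas[, info_cols])), 0.1)
})

test_that("beta datasets are bit-identical under one seed, distinct under another", {
  masks <- small_masks()
  des <- synthetic_design(n_subjects = 2, seed = 9)
  spec <- pattern_spec(n_informative_voxels = 5)
  expect_identical(simulate_betas(des, masks, spec)$betas,
                   simulate_betas(des, masks, spec)$betas)
  des2 <- synthetic_design(n_subjects = 2, seed = 10)
  expect_false(identical(simulate_betas(des, masks, spec)$betas,
                         simulate_betas(des2, masks, spec)$betas))
})

test_that("informative voxels respect ROI bounds and clustered placement", {
  masks <- small_masks()
  des <- synthetic_design(n_subjects = 2, seed = 4)
  expect_error(
    simulate_betas(des, masks, pattern_spec(n_informative_voxels = 10000)),
    "exceeds ROI size")

  ds <- simulate_betas(des, masks, pattern_spec(n_informative_voxels = 8),
                       placement = "clustered")
  info <- ds$truth$informative_voxels
  expect_length(info, 8)
  co <- ds$voxels[match(info, ds$voxels$voxel), ]
  # clustered voxels span a tight neighbourhood
  expect_lt(max(dist(cbind(co$i, co$j, co$k))), 6)
  expect_true(all(info %in% roi_voxels(masks, "left_putamen")))
})

test_that("smoothing the noise field preserves class-mean balance and scale", {
  masks <- small_masks()
  des <- synthetic_design(n_subjects = 2, seed = 6)
  ds <- simulate_betas(des, masks,
                       pattern_spec(n_informative_voxels = 0,
                                    subject_offset_sd = 0, run_offset_sd = 0,
                                    baseline_map_amplitude = 0,
                                    smoothing_fwhm_mm = 8))
  # energy-normalised kernel keeps the marginal noise SD near noise_sd
  expect_gt(sd(ds$betas), 0.8)
  expect_lt(sd(ds$betas), 1.2)
  # neighbouring voxels are positively correlated after smoothing
  nb <- which(diff(ds$voxels$voxel) == 1)[1:50]
  r <- cor(as.vector(ds$betas[, nb]), as.vector(ds$betas[, nb + 1]))
  expect_gt(r, 0.3)
})

test_that("mask and beta volumes round-trip through NIfTI", {
  masks <- small_masks()
  dir <- tempfile("nifti_")
  paths <- write_masks_nifti(masks, dir)
  lab <- RNifti::readNifti(paths[["nucleus_labels"]])
  expect_equal(as.array(lab), masks$nucleus_labels, ignore_attr = TRUE)
  expect_equal(RNifti::pixdim(lab), rep(4, 3))

  des <- synthetic_design(n_subjects = 2, n_runs = 2, analysis_runs = 1:2,
                          seed = 3)
  ds <- simulate_betas(des, masks, pattern_spec(n_informative_voxels = 5))
  files <- write_beta_dataset(ds, dir)
  expect_true(all(file.exists(files$file)))
  back <- read_beta_dataset(files, masks$nucleus_labels > 0, des)
  expect_equal(back$betas, ds$betas, tolerance = 1e-6)
  expect_equal(back$voxels$voxel, ds$voxels$voxel)
  meta <- jsonlite::read_json(file.path(dir, "dataset.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$informative_voxels, ds$truth$informative_voxels)
  unlink(dir, recursive = TRUE)
})
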