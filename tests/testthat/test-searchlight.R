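test_that("sphere extraction matches the brute-force offset oracle", {
  mask <- array(TRUE, c(15, 15, 15))
  # brute force: integer offsets with (2 dx)^2 + (2 dy)^2 + (2 dz)^2 <= 25
  brute <- function(center, radius_mm, voxel_mm) {
    hits <- 0
    for (dx in -5:5) for (dy in -5:5) for (dz in -5:5) {
      if (voxel_mm^2 * (dx^2 + dy^2 + dz^2) <= radius_mm^2) hits <- hits + 1
    }
    hits
  }
  sph <- sphere_indices(c(8, 8, 8), mask, 5, 2)
  expect_length(sph, brute(c(8, 8, 8), 5, 2))
  expect_length(sph, 81)
  # centre voxel always included
  ctr_lin <- 8 + 15 * 7 + 225 * 7
  expect_true(ctr_lin %in% sph)

  # radius below voxel size keeps only the centre
  expect_equal(sphere_indices(c(8, 8, 8), mask, 1.9, 2), ctr_lin)
  # boundary centre: strict subset of the deep-interior sphere size
  edge <- sphere_indices(c(1, 8, 8), mask, 5, 2)
  expect_lt(length(edge), 81)
  # monotone in radius; symmetric under axis permutations deep inside
  for (r in c(2, 3, 4, 5, 6)) {
    expect_gte(length(sphere_indices(c(8, 8, 8), mask, r + 0.5, 2)),
               length(sphere_indices(c(8, 8, 8), mask, r, 2)))
  }
  expect_error(sphere_indices(c(1, 1, 1), array(FALSE, c(3, 3, 3)), 5, 2),
               "outside the mask")
})

test_that("spheres are intersected with the mask", {
  mask <- array(FALSE, c(11, 11, 11))
  mask[4:8, 4:8, 4:8] <- TRUE
  # centre at the cube's corner: the sphere is clipped to in-mask voxels
  sph <- sphere_indices(c(4, 4, 4), mask, 5, 2)
  expect_true(all(mask[sph]))
  expect_lt(length(sph), 81)
  # deep centre of the 5-wide cube still holds the full 81-voxel sphere
  expect_length(sphere_indices(c(6, 6, 6), mask, 5, 2), 81)
})

# small planted-signal dataset on the coarse phantom for map tests
sl_fixture <- function(tau = 3, seed = 2) {
  masks <- small_masks()
  ds <- simulate_betas(synthetic_design(n_subjects = 4, seed = seed), masks,
                       pattern_spec(n_informative_voxels = 6, pattern_sd = tau,
                                    subject_consistency = 1),
                       informative_roi = "left_caudate",
                       placement = "clustered")
  sm <- extract_roi_samples(ds, masks, "left_caudate") |> demean_by_run()
  list(masks = masks, ds = ds, sm = sm)
}

test_that("searchlight map covers the ROI and peaks at the planted site", {
  fx <- sl_fixture()
  cfg <- searchlight_config(radius_mm = 6, seed = 1)
  slm <- searchlight_map(fx$sm, cfg, decoder_config())
  # support is exactly the ROI voxel set
  expect_setequal(slm$map$voxel, fx$sm$voxels$voxel)
  expect_true(all(slm$map$accuracy >= 0 & slm$map$accuracy <= 1))
  expect_true(all(slm$map$sphere_size >= 1))

  # peak accuracy within 2 voxels of the planted cluster centroid
  info <- fx$ds$truth$informative_voxels
  co <- fx$ds$voxels[match(info, fx$ds$voxels$voxel), ]
  ctr <- c(mean(co$i), mean(co$j), mean(co$k))
  peak <- slm$map[which.max(slm$map$accuracy), ]
  expect_lte(sqrt(sum((c(peak$i, peak$j, peak$k) - ctr)^2)), 2)
})

test_that("pooled permutation null sizes, p-values and FDR behave", {
  fx <- sl_fixture()
  cfg <- searchlight_config(radius_mm = 6, n_perm_per_voxel = 3, seed = 5)
  slm <- searchlight_map(fx$sm, cfg, decoder_config())
  sig <- searchlight_significance(fx$sm, slm, cfg, decoder_config())
  # pooled null has one entry per voxel per permutation
  expect_length(sig$null, 3 * nrow(slm$map))
  expect_true(all(sig$map$p_value > 0 & sig$map$p_value <= 1))
  expect_equal(sig$map$p_value,
               vapply(sig$map$accuracy,
                      function(a) (1 + sum(sig$null >= a)) / (length(sig$null) + 1),
                      numeric(1)))
  # the strong planted signal survives FDR and sets the accuracy threshold
  expect_true(any(sig$map$fdr_significant))
  expect_equal(sig$accuracy_threshold,
               min(sig$map$accuracy[sig$map$fdr_significant]))
})

test_that("single-voxel searchlight reduces to single-column decoding", {
  fx <- sl_fixture()
  sm_small <- select_voxels(fx$sm, 1:8)
  cfg <- searchlight_config(radius_mm = 1, seed = 1) # below the 4 mm voxel size
  slm <- searchlight_map(sm_small, cfg, decoder_config())
  expect_true(all(slm$map$sphere_size == 1))
  one <- select_voxels(sm_small, 3)
  expect_equal(slm$map$accuracy[3], loso_cross_validate(one)$accuracy)
})

test_that("territory quantification counts and percentages add up", {
  masks <- small_masks()
  # synthetic significance table: 4 voxels in left putamen territories
  lp <- which(masks$nucleus_labels == 1)
  pick <- c(lp[masks$territory_labels[lp] == 1][1:2],
            lp[masks$territory_labels[lp] == 3][1],
            lp[masks$territory_labels[lp] == 5][1])
  tbl <- tibble::tibble(voxel = c(pick, which(masks$nucleus_labels == 2)[1]),
                        fdr_significant = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  out <- quantify_by_atlas(tbl, masks)
  lp_out <- out[out$nucleus == "left_putamen", ]
  expect_equal(lp_out$n[lp_out$territory == "limbic"], 2L)
  expect_equal(lp_out$n[lp_out$territory == "rostral_motor"], 1L)
  expect_equal(lp_out$n[lp_out$territory == "parietal"], 1L)
  expect_equal(sum(lp_out$n), 4L)
  expect_equal(sum(lp_out$percent), 100, tolerance = 0.1)
  expect_equal(lp_out$percent[lp_out$territory == "limbic"], 50)
  # untouched nuclei: zero counts, no division by zero
  rc <- out[out$nucleus == "right_caudate", ]
  expect_true(all(rc$n == 0) && all(rc$percent == 0))
  # empty mask: all-zero table
  empty <- quantify_by_atlas(tibble::tibble(voxel = integer(0),
                                            fdr_significant = logical(0)),
                             masks)
  expect_true(all(empty$n == 0))
})
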