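test_that("sensitivity is the mean squared weight across pairs", {
  mk <- function(ws) {
    structure(list(
      pairs = tibble::tibble(class_a = utils::combn(1:4, 2)[1, ],
                             class_b = utils::combn(1:4, 2)[2, ],
                             weights = ws, bias = 0, n_support = 0L),
      classes = 1:4, n_voxels = length(ws[[1]]), cost = 1),
      class = "pairwise_svm_set")
  }
  # hand-computed: weights (1, -1, 2, 0, 0, 0) at one voxel -> (1+1+4)/6 = 1
  models <- mk(lapply(c(1, -1, 2, 0, 0, 0), function(w) w))
  expect_equal(compute_sensitivity(models), 1)
  # all-zero weights -> 0
  expect_equal(compute_sensitivity(mk(lapply(rep(0, 6), identity))), 0)
  # invariant under sign flips of any pairwise weight vector
  set.seed(3)
  ws <- lapply(1:6, function(i) rnorm(5))
  flipped <- ws
  flipped[[2]] <- -flipped[[2]]
  flipped[[5]] <- -flipped[[5]]
  expect_equal(compute_sensitivity(mk(ws)), compute_sensitivity(mk(flipped)))
  # a single pair: sensitivity is the squared weight
  one <- structure(list(
    pairs = tibble::tibble(class_a = 1L, class_b = 2L,
                           weights = list(c(2, -3)), bias = 0, n_support = 0L),
    classes = 1:2, n_voxels = 2L, cost = 1), class = "pairwise_svm_set")
  expect_equal(compute_sensitivity(one), c(4, 9))
})

test_that("full-data weight maps place pair weights on the grid, zero outside", {
  masks <- small_masks()
  ds <- simulate_betas(synthetic_design(n_subjects = 3, seed = 2), masks,
                       pattern_spec(n_informative_voxels = 10, pattern_sd = 1))
  sm <- extract_roi_samples(ds, masks, "left_caudate") |> demean_by_run()
  wm <- weight_maps(sm)
  expect_length(wm$weight_volumes, 6)
  vol <- wm$weight_volumes[[1]]
  expect_equal(vol[sm$voxels$voxel], wm$models$pairs$weights[[1]],
               ignore_attr = TRUE)
  outside <- setdiff(seq_along(vol), sm$voxels$voxel)
  expect_true(all(vol[outside] == 0))
  # sensitivity volume equals the voxelwise mean of squared pair maps
  mean_sq <- Reduce(`+`, lapply(wm$weight_volumes, function(v) v^2)) / 6
  expect_equal(wm$sensitivity_volume, mean_sq)
})

test_that("elimination trace covers every voxel count with valid fold orders", {
  sm <- toy_samples(n_subjects = 3, n_voxels = 3, seed = 1, signal = 2,
                    signal_cols = 1:2)
  tr <- backward_elimination(sm, decoder_config(n_permutations = 20, seed = 2))
  expect_equal(tr$curve$m, 1:3)
  expect_true(all(tr$curve$accuracy >= 0 & tr$curve$accuracy <= 1))
  expect_equal(dim(tr$order), c(3, nrow(sm$values)))
  for (f in seq_len(ncol(tr$order))) {
    expect_setequal(tr$order[, f], 1:3)
  }
  # whole-ROI accuracy equals the decoder's LOSO accuracy exactly
  expect_equal(tr$curve$accuracy[tr$curve$m == 3],
               loso_cross_validate(sm)$accuracy)
})

test_that("a pure-noise voxel is eliminated before clean signal voxels", {
  sm <- toy_samples(n_subjects = 4, n_voxels = 3, seed = 5, signal = 8,
                    signal_cols = 1:2)
  tr <- backward_elimination(sm, decoder_config(n_permutations = 10, seed = 1))
  # voxel 3 carries no signal: dropped first in at least 95% of folds
  expect_gte(mean(tr$order[1, ] == 3), 0.95)
})

test_that("elimination is deterministic and breaks sensitivity ties by index", {
  sm <- toy_samples(n_subjects = 3, n_voxels = 5, seed = 9)
  cfg <- decoder_config(n_permutations = 5, seed = 4)
  tr1 <- backward_elimination(sm, cfg)
  tr2 <- backward_elimination(sm, cfg)
  expect_identical(tr1$order, tr2$order)
  expect_identical(tr1$curve, tr2$curve)

  # duplicated columns give exactly tied sensitivities; the lower index goes
  dup <- sm
  dup$values <- cbind(sm$values[, 1], sm$values[, 1], sm$values[, 2])
  dup$voxels <- sm$voxels[1:3, ]
  trd <- backward_elimination(dup, cfg)
  first_of_pair <- apply(trd$order, 2, function(o) which(o %in% 1:2)[1])
  expect_true(all(trd$order[cbind(first_of_pair, seq_len(ncol(trd$order)))] == 1))
})

test_that("binomial and permutation significance agree on obvious cases", {
  sm <- toy_samples(n_subjects = 4, n_voxels = 4, seed = 11, signal = 10,
                    signal_cols = 1:3)
  trp <- backward_elimination(sm, decoder_config(n_permutations = 50, seed = 3))
  trb <- backward_elimination(sm, decoder_config(seed = 3),
                              signif_method = "binomial")
  # strong signal: significant at the full voxel set under both nulls
  expect_true(trp$curve$fdr_significant[trp$curve$m == 4])
  expect_true(trb$curve$fdr_significant[trb$curve$m == 4])
})

test_that("top selected voxels rank ground-truth signal first", {
  sm <- toy_samples(n_subjects = 4, n_voxels = 12, seed = 7, signal = 8,
                    signal_cols = 1:5)
  tr <- backward_elimination(sm, decoder_config(n_permutations = 5, seed = 2))
  top <- top_selected_voxels(tr, k = 10, survival_depth = 10)
  expect_equal(nrow(top), 10)
  expect_true(all(1:5 %in% top$column))
  # a voxel surviving to the end in every fold has the maximal score
  last <- tr$order[nrow(tr$order), ]
  if (length(unique(last)) == 1) {
    expect_equal(top$score[top$column == unique(last)], ncol(tr$order))
  }
  expect_warning(top_selected_voxels(tr, k = 20), "exceeds")
})
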