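test_that("four classes give six pairwise classifiers, two give one", {
  sm <- toy_samples(n_subjects = 2, n_voxels = 6, seed = 1)
  fit <- train_pairwise(sm)
  expect_equal(nrow(fit$pairs), 6)
  expect_equal(fit$pairs$class_a, c(1, 1, 1, 2, 2, 3))
  expect_equal(fit$pairs$class_b, c(2, 3, 4, 3, 4, 4))
  expect_true(all(lengths(fit$pairs$weights) == 6))

  x2 <- sm$values[sm$info$class %in% 1:2, ]
  y2 <- sm$info$class[sm$info$class %in% 1:2]
  expect_equal(nrow(train_pairwise(x2, y2)$pairs), 1)

  expect_error(train_pairwise(x2, rep(1, length(y2))), "at least 2 classes")
  xdeg <- matrix(1, 8, 3)
  expect_error(train_pairwise(xdeg, rep(1:2, 4)), "degenerate pair \\(1 vs 2\\)")
})

test_that("pairwise solutions match libsvm and separate separable toys", {
  skip_if_not_installed("e1071")
  set.seed(42)
  # linearly separable 2-class toy: margin constraints hold exactly
  x <- rbind(matrix(rnorm(8, 3, 0.3), 4, 2), matrix(rnorm(8, -3, 0.3), 4, 2))
  y <- rep(1:2, each = 4)
  fit <- train_pairwise(x, y)
  f <- drop(x %*% fit$pairs$weights[[1]]) + fit$pairs$bias[1]
  expect_true(all(sign(f) == ifelse(y == 1, 1, -1)))
  expect_true(all(f[y == 1] >= 1 - 1e-6) && all(f[y == 2] <= -1 + 1e-6))

  # agreement with libsvm (the engine the analysis convention comes from)
  for (s in 1:3) {
    set.seed(s)
    x <- matrix(rnorm(60 * 8), 60, 8)
    y <- rep(1:2, each = 30)
    x[y == 1, 1:2] <- x[y == 1, 1:2] + 1
    fit <- train_pairwise(x, y)
    m <- e1071::svm(x, factor(y), kernel = "linear", cost = 1, scale = FALSE)
    w_ref <- drop(crossprod(m$SV, m$coefs))
    b_ref <- -m$rho
    expect_equal(fit$pairs$weights[[1]], w_ref, tolerance = 5e-3,
                 ignore_attr = TRUE)
    expect_equal(fit$pairs$bias[1], b_ref, tolerance = 5e-3)
  }
})

test_that("majority vote matches exhaustive tally enumeration", {
  # build a classifier set whose 6 pairwise decisions we control by sign,
  # and check the vote against an independent brute-force tally
  pairs <- utils::combn(1:4, 2)
  sample_x <- 1
  for (pattern in 0:63) {
    signs <- ifelse(bitwAnd(pattern, 2^(0:5)) > 0, 1, -1)
    models <- structure(list(
      pairs = tibble::tibble(
        class_a = pairs[1, ], class_b = pairs[2, ],
        weights = lapply(signs, function(s) 0),
        bias = signs * seq(0.1, 0.6, by = 0.1),
        n_support = 0L),
      classes = 1:4, n_voxels = 1L, cost = 1), class = "pairwise_svm_set")
    # brute force: tally votes, argmax, lowest label on ties
    votes <- integer(4)
    for (k in 1:6) {
      win <- if (signs[k] > 0) pairs[1, k] else pairs[2, k]
      votes[win] <- votes[win] + 1L
    }
    expected <- which(votes == max(votes))[1]
    expect_equal(predict_vote(models, sample_x), expected)

    # decision_sum tie rule: among tied classes, largest summed decision
    dsum <- numeric(4)
    for (k in 1:6) {
      f <- signs[k] * 0.1 * k
      dsum[pairs[1, k]] <- dsum[pairs[1, k]] + f
      dsum[pairs[2, k]] <- dsum[pairs[2, k]] - f
    }
    tied <- which(votes == max(votes))
    expected_ds <- tied[which.max(dsum[tied])]
    expect_equal(predict_vote(models, sample_x, tie_rule = "decision_sum"),
                 expected_ds)
  }
})

test_that("two-class prediction equals the single model's sign decision", {
  sm <- toy_samples(n_classes = 2, n_voxels = 4, seed = 3, signal = 2,
                    signal_cols = 1:2)
  fit <- train_pairwise(sm)
  f <- drop(sm$values %*% fit$pairs$weights[[1]]) + fit$pairs$bias[1]
  expect_equal(predict_vote(fit, sm$values), ifelse(f > 0, 1L, 2L))
})

test_that("LOSO produces one prediction per sample and finds strong signal", {
  sm <- toy_samples(n_subjects = 4, n_voxels = 10, seed = 2, signal = 50,
                    signal_cols = 1:5)
  res <- loso_cross_validate(sm, decoder_config(seed = 1))
  expect_equal(nrow(res$predictions), nrow(sm$values))
  expect_equal(res$chance, 0.25)
  expect_equal(res$accuracy, 1) # near-noiseless signal decodes perfectly
  expect_equal(res$accuracy, mean(res$predictions$correct))

  # LOSO agrees with a brute-force per-fold refit via libsvm
  skip_if_not_installed("e1071")
  smn <- toy_samples(n_subjects = 2, n_runs = 2, n_voxels = 8, seed = 4)
  mine <- loso_cross_validate(smn)$predictions$predicted
  ref <- vapply(seq_len(nrow(smn$values)), function(t) {
    m <- e1071::svm(smn$values[-t, ], factor(smn$info$class[-t]),
                    kernel = "linear", cost = 1, scale = FALSE)
    as.integer(as.character(predict(m, smn$values[t, , drop = FALSE])))
  }, integer(1))
  expect_gte(mean(mine == ref), 0.9)
})

test_that("LOSO errors when a class would vanish from training", {
  sm <- toy_samples(n_subjects = 1, n_runs = 1, seed = 1)
  expect_error(loso_cross_validate(sm), "single sample")
})

test_that("accuracy is invariant to voxel order and consistent label relabelling", {
  sm <- toy_samples(n_subjects = 3, n_voxels = 12, seed = 6, signal = 1,
                    signal_cols = 1:4)
  acc <- loso_cross_validate(sm)$accuracy
  perm_cols <- select_voxels(sm, sample(ncol(sm$values)))
  expect_equal(loso_cross_validate(perm_cols)$accuracy, acc)

  # relabelling classes by a fixed permutation permutes predictions
  # identically under the decision_sum tie rule (the lowest-label rule is a
  # fixed reproducible convention and deliberately not relabel-equivariant
  # on exact vote ties)
  cfg <- decoder_config(vote_tie_rule = "decision_sum")
  relab <- c(3L, 1L, 4L, 2L)
  sm2 <- sm
  sm2$info$class <- relab[sm$info$class]
  p1 <- loso_cross_validate(sm, cfg)$predictions
  p2 <- loso_cross_validate(sm2, cfg)$predictions
  expect_equal(p2$predicted, relab[p1$predicted])
  expect_equal(mean(p2$correct), mean(p1$correct))
})

test_that("permutation test follows the (1+)/(N+1) rule and is seed-stable", {
  sm <- toy_samples(n_subjects = 3, n_voxels = 8, seed = 7, signal = 50,
                    signal_cols = 1:4)
  cfg <- decoder_config(n_permutations = 100, seed = 5)
  pt <- permutation_test(sm, cfg)
  expect_equal(pt$observed, 1)
  expect_equal(pt$p_value, (1 + sum(pt$null >= 1)) / 101)
  expect_gt(pt$p_value, 0)
  # identical seed, identical null; different seed, different null
  pt2 <- permutation_test(sm, cfg)
  expect_identical(pt$null, pt2$null)
  pt3 <- permutation_test(sm, decoder_config(n_permutations = 100, seed = 6))
  expect_false(identical(pt$null, pt3$null))
  # null stays near chance for the global scheme
  expect_lt(abs(mean(pt$null) - 0.25), 0.05)
})

test_that("within-block permutations preserve block class balance", {
  sm <- toy_samples(n_subjects = 3, seed = 2)
  cfg <- decoder_config(n_permutations = 20, seed = 3,
                        permutation_scheme = "within_block")
  perms <- striamvpa:::with_stage_seed(cfg$seed, "permutation",
    striamvpa:::permuted_labels(sm$info, cfg$n_permutations,
                                cfg$permutation_scheme))
  block <- paste(sm$info$subject, sm$info$run)
  for (p in seq_len(ncol(perms))) {
    counts <- table(block, perms[, p])
    expect_true(all(counts == 1))
  }
})

test_that("Benjamini-Hochberg flags match the definitional brute force", {
  # worked example: only the smallest p-value survives
  p <- c(0.001, 0.02, 0.03, 0.2, 0.5, 0.9)
  expect_equal(fdr_correct(p, 0.05), c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(fdr_correct(p, 0.05), bh_brute_force(p, 0.05))

  expect_equal(fdr_correct(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_true(fdr_correct(0.01, 0.05))
  expect_equal(fdr_correct(numeric(0)), logical(0))

  set.seed(1)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_equal(fdr_correct(p, q), bh_brute_force(p, q))
  }
})
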