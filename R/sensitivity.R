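#' Voxel sensitivity: mean squared classifier weight
#'
#' The sensitivity of a voxel is the mean, across the pairwise classifiers,
#' of its squared linear weight -- a nonnegative importance score invariant
#' to the sign of any weight vector.
#'
#' @param models A `pairwise_svm_set` from [train_pairwise()].
#' @return Numeric vector, one value per voxel.
#' @export
compute_sensitivity <- function(models) {
  stopifnot(inherits(models, "pairwise_svm_set"), nrow(models$pairs) >= 1)
  w2 <- vapply(models$pairs$weights, function(w) w^2,
               numeric(models$n_voxels))
  if (models$n_voxels == 1) w2 <- matrix(w2, nrow = 1)
  rowMeans(w2)
}

#' Full-data weight and sensitivity maps
#'
#' Trains one model per class pair on all samples (no cross-validation;
#' for visualisation of the discriminative pattern) and writes the weights
#' back onto the grid, zero outside the ROI.
#'
#' @param samples A demeaned `sample_matrix`.
#' @param cost SVM penalty C.
#' @return List with `models` (the `pairwise_svm_set`), `weights` tibble
#'   (one row per pair x voxel, with grid coordinates), `weight_volumes`
#'   (list of 3D arrays named `"a_vs_b"`), and `sensitivity_volume`
#'   (3D array of mean squared weights).
#' @export
weight_maps <- function(samples, cost = 1) {
  stopifnot(inherits(samples, "sample_matrix"))
  models <- train_pairwise(samples, cost = cost)
  vox <- samples$voxels
  vols <- purrr::map(seq_len(nrow(models$pairs)), function(k) {
    vol <- array(0, samples$grid_shape)
    vol[vox$voxel] <- models$pairs$weights[[k]]
    vol
  })
  names(vols) <- sprintf("%d_vs_%d", models$pairs$class_a,
                         models$pairs$class_b)
  sens <- compute_sensitivity(models)
  svol <- array(0, samples$grid_shape)
  svol[vox$voxel] <- sens
  weights <- purrr::map_dfr(seq_len(nrow(models$pairs)), function(pair) {
    w <- models$pairs$weights[[pair]]
    tibble::tibble(class_a = models$pairs$class_a[pair],
                   class_b = models$pairs$class_b[pair],
                   voxel = vox$voxel, i = vox$i, j = vox$j, k = vox$k,
                   weight = w)
  })
  list(models = models, weights = weights, weight_volumes = vols,
       sensitivity = sens, sensitivity_volume = svol)
}

#' Cross-validated backward voxel elimination
#'
#' For every leave-one-sample-out fold: train the pairwise classifiers on
#' the training rows, predict the held-out sample, compute each remaining
#' voxel's sensitivity (mean squared weight across pairs) on the training
#' data, drop the single least-sensitive voxel (ties to the lowest voxel
#' index), and repeat until one voxel is left. Pooled accuracy is recorded
#' at every voxel count m. Significance per m comes from label-permutation
#' null curves (the same elimination procedure under permuted labels) or a
#' binomial approximation, with Benjamini-Hochberg FDR across all m.
#'
#' @param samples A demeaned `sample_matrix`.
#' @param config A [decoder_config()]; `n_permutations` here is the
#'   (typically reduced) permutation count for the per-m null curves.
#' @param signif_method `"permutation"` (default) or `"binomial"`.
#' @return An `elimination_trace`: `curve` tibble (m, accuracy, p_value,
#'   fdr_significant), `order` matrix (elimination order per fold),
#'   `selection` tibble of per-voxel survival scores, and metadata.
#' @export
backward_elimination <- function(samples, config = decoder_config(),
                                 signif_method = c("permutation", "binomial")) {
  stopifnot(inherits(samples, "sample_matrix"))
  signif_method <- match.arg(signif_method)
  check_loso_feasible(samples$info$class)
  labels <- as.integer(samples$info$class)
  p <- ncol(samples$values)
  if (p < 1) stop("empty ROI")
  tie <- tie_rule_code(config$vote_tie_rule)

  res <- cpp_rfe(samples$values, labels, config$cost, tie)
  acc <- rowMeans(res$correct) # row m: accuracy with m voxels
  n <- nrow(samples$values)

  if (signif_method == "permutation") {
    perms <- with_stage_seed(config$seed, "rfe",
      permuted_labels(samples$info, config$n_permutations,
                      config$permutation_scheme))
    null_acc <- cpp_rfe_perm_null(samples$values, perms, config$cost, tie)
    # per m: pooled rank p-value against that m's null accuracies
    pv <- vapply(seq_len(p), function(m) {
      (1 + sum(null_acc[m, ] >= acc[m])) / (ncol(null_acc) + 1)
    }, numeric(1))
  } else {
    chance <- 1 / length(unique(labels))
    pv <- vapply(seq_len(p), function(m) {
      stats::binom.test(round(acc[m] * n), n, chance,
                        alternative = "greater")$p.value
    }, numeric(1))
  }

  curve <- tibble::tibble(m = seq_len(p), accuracy = acc, p_value = pv,
                          fdr_significant = fdr_correct(pv, config$fdr_q))

  structure(
    list(curve = curve, order = res$order, voxels = samples$voxels,
         n_folds = n, roi = samples$roi, signif_method = signif_method,
         config = config),
    class = "elimination_trace"
  )
}

#' @export
print.elimination_trace <- function(x, ...) {
  sig <- x$curve$m[x$curve$fdr_significant]
  cat(sprintf("<elimination_trace> %s: %d voxels, %d folds; FDR-significant down to m = %s\n",
              x$roi, nrow(x$curve), x$n_folds,
              if (length(sig)) min(sig) else "none"))
  invisible(x)
}

#' Most-selected voxels of an elimination trace
#'
#' A voxel's selection score is the number of folds in which it survives
#' into the final `survival_depth` voxels of that fold's elimination order.
#'
#' @param trace An [backward_elimination()] result.
#' @param k How many top voxels to return (default 10).
#' @param survival_depth Survival window (default 10).
#' @return Tibble of `k` rows (fewer, with a warning, if the ROI is
#'   smaller): voxel, grid coordinates, score; ties broken by lower voxel
#'   index.
#' @export
top_selected_voxels <- function(trace, k = 10, survival_depth = 10) {
  stopifnot(inherits(trace, "elimination_trace"))
  p <- nrow(trace$order)
  depth <- min(survival_depth, p)
  last <- trace$order[(p - depth + 1):p, , drop = FALSE]
  score <- vapply(seq_len(p), function(v) sum(last == v), numeric(1))
  if (k > p) {
    warning(sprintf("k = %d exceeds the %d available voxels; returning %d", k, p, p))
    k <- p
  }
  ord <- order(-score, seq_len(p))[seq_len(k)]
  tibble::tibble(
    rank = seq_len(k),
    column = ord,
    voxel = trace$voxels$voxel[ord],
    i = trace$voxels$i[ord], j = trace$voxels$j[ord],
    k_coord = trace$voxels$k[ord],
    score = score[ord],
    n_folds = ncol(trace$order)
  )
}
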