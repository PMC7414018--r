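#' One-against-one linear support-vector classifiers
#'
#' Trains one soft-margin linear SVM per unordered pair of classes, each on
#' that pair's samples only, exactly as libsvm's one-against-one multiclass
#' scheme does. The penalty parameter `cost` (C) defaults to 1, the
#' conventional default for this kind of decoding analysis. Weight vectors
#' are recovered from the dual solution as `w = X' (alpha * y)`.
#'
#' @param x A [sample_matrix] or a numeric matrix (samples x voxels).
#' @param labels Class labels, one per row; taken from `x` when it is a
#'   `sample_matrix`.
#' @param cost Soft-margin penalty C (> 0).
#' @return An object of class `pairwise_svm_set`: a list with a tibble
#'   `pairs` (one row per class pair, with list-columns `weights` and scalar
#'   `bias`), the class label vector, and the voxel count.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40), 20, 2)
#' y <- rep(1:4, each = 5)
#' fit <- train_pairwise(x, y)
#' nrow(fit$pairs) # 6 pairwise classifiers for 4 classes
#' @export
train_pairwise <- function(x, labels = NULL, cost = 1) {
  if (inherits(x, "sample_matrix")) {
    labels <- x$info$class
    x <- x$values
  }
  x <- as.matrix(x)
  stopifnot(is.numeric(cost), length(cost) == 1, cost > 0)
  if (is.null(labels) || length(labels) != nrow(x)) {
    stop("`labels` must supply one class label per sample row")
  }
  if (anyNA(x) || any(!is.finite(x))) stop("sample values must be finite")
  classes <- sort(unique(as.integer(labels)))
  if (length(classes) < 2) stop("need at least 2 classes, found ", length(classes))
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 1)) {
    stop("class absent from training data: ", classes[counts < 1][1])
  }

  combos <- utils::combn(classes, 2)
  pair_rows <- lapply(seq_len(ncol(combos)), function(k) {
    a <- combos[1, k]; b <- combos[2, k]
    rows <- which(labels %in% c(a, b))
    y <- ifelse(labels[rows] == a, 1L, -1L)
    xs <- x[rows, , drop = FALSE]
    if (all(abs(sweep(xs, 2, xs[1, ], "-")) < 1e-12)) {
      stop(sprintf("degenerate pair (%d vs %d): all samples identical", a, b))
    }
    gram <- tcrossprod(xs)
    fit <- cpp_svm_train(gram, seq_len(nrow(xs)) - 1L, y, cost)
    w <- drop(crossprod(xs, fit$alpha * y))
    tibble::tibble(
      class_a = a, class_b = b,
      weights = list(w), bias = -fit$rho,
      n_support = sum(fit$alpha > 0)
    )
  })
  structure(
    list(
      pairs = dplyr::bind_rows(pair_rows),
      classes = classes,
      n_voxels = ncol(x),
      cost = cost
    ),
    class = "pairwise_svm_set"
  )
}

#' @export
print.pairwise_svm_set <- function(x, ...) {
  cat(sprintf(
    "<pairwise_svm_set> %d classes, %d pairwise linear SVMs, %d voxels, C = %g\n",
    length(x$classes), nrow(x$pairs), x$n_voxels, x$cost
  ))
  invisible(x)
}

#' Predict class labels by majority vote across pairwise classifiers
#'
#' Each pairwise model casts one vote: for pair (a, b) the vote goes to `a`
#' when the decision value `w . x + b` is positive and to `b` otherwise. The
#' predicted class is the vote-count argmax. Ties are resolved by
#' `tie_rule`: `"lowest_label"` picks the smallest class label among the
#' tied ones; `"decision_sum"` picks the tied class with the largest summed
#' signed decision value in its favour.
#'
#' @param models A `pairwise_svm_set` from [train_pairwise()].
#' @param newdata Numeric matrix (or single vector) of samples to classify.
#' @param tie_rule `"lowest_label"` (default) or `"decision_sum"`.
#' @return Integer vector of predicted class labels.
#' @export
predict_vote <- function(models, newdata,
                         tie_rule = c("lowest_label", "decision_sum")) {
  tie_rule <- match.arg(tie_rule)
  stopifnot(inherits(models, "pairwise_svm_set"))
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != models$n_voxels) {
    stop(sprintf("sample has %d voxels but the models were trained on %d",
                 ncol(newdata), models$n_voxels))
  }
  classes <- models$classes
  votes <- matrix(0, nrow(newdata), length(classes))
  dsum <- matrix(0, nrow(newdata), length(classes))
  for (k in seq_len(nrow(models$pairs))) {
    a <- match(models$pairs$class_a[k], classes)
    b <- match(models$pairs$class_b[k], classes)
    f <- drop(newdata %*% models$pairs$weights[[k]]) + models$pairs$bias[k]
    win <- ifelse(f > 0, a, b)
    for (i in seq_along(win)) votes[i, win[i]] <- votes[i, win[i]] + 1
    dsum[, a] <- dsum[, a] + f
    dsum[, b] <- dsum[, b] - f
  }
  pick <- function(i) {
    tied <- which(votes[i, ] == max(votes[i, ]))
    if (length(tied) > 1 && tie_rule == "decision_sum") {
      tied <- tied[which.max(dsum[i, tied])]
    }
    classes[tied[1]]
  }
  vapply(seq_len(nrow(newdata)), pick, integer(1))
}

#' Decision values of every pairwise classifier for new samples
#'
#' @inheritParams predict_vote
#' @return Tibble with one row per (sample, pair): `sample`, `class_a`,
#'   `class_b`, `decision` (`w . x + b`).
#' @export
decision_values <- function(models, newdata) {
  stopifnot(inherits(models, "pairwise_svm_set"))
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  purrr::map_dfr(seq_len(nrow(models$pairs)), function(k) {
    tibble::tibble(
      sample = seq_len(nrow(newdata)),
      class_a = models$pairs$class_a[k],
      class_b = models$pairs$class_b[k],
      decision = drop(newdata %*% models$pairs$weights[[k]]) + models$pairs$bias[k]
    )
  })
}
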