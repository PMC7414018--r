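#' Group-level binary mask from individual masks
#'
#' A voxel enters the group mask when the fraction of subjects whose
#' individual mask contains it is at least `overlap_threshold` (default
#' 0.5: "at least 50% of the subjects"). With `overlap_threshold = 1` this
#' is the intersection of all masks.
#'
#' @param individual_masks List of binary/logical 3D arrays on a common
#'   grid (list names are used in error messages).
#' @param overlap_threshold Fraction in (0, 1].
#' @return Logical 3D array (the group mask).
#' @export
build_group_mask <- function(individual_masks, overlap_threshold = 0.5) {
  stopifnot(length(individual_masks) >= 1,
            overlap_threshold > 0, overlap_threshold <= 1)
  ref <- dim(individual_masks[[1]])
  for (i in seq_along(individual_masks)) {
    if (!identical(dim(individual_masks[[i]]), ref)) {
      nm <- names(individual_masks)[i]
      stop(sprintf("mask %s grid %s does not match reference grid %s",
                   if (is.null(nm) || nm == "") i else nm,
                   paste(dim(individual_masks[[i]]), collapse = "x"),
                   paste(ref, collapse = "x")))
    }
  }
  counts <- Reduce(`+`, lapply(individual_masks, function(m) {
    array(as.numeric(m != 0), dim = ref)
  }))
  frac <- counts / length(individual_masks)
  array(frac >= overlap_threshold - 1e-12, dim = ref)
}

#' Extract an ROI sample matrix from a beta dataset
#'
#' One row per (subject, run, class) volume, one column per in-ROI voxel.
#' Voxel columns follow the package's fixed scan order: ascending linear
#' grid index (x fastest), so weight maps are alignable back onto the grid;
#' a combined ROI (e.g. putamen + caudate) is the sorted union of its
#' nuclei's voxels.
#'
#' @param dataset A `beta_dataset` ([simulate_betas()] or
#'   [read_beta_dataset()]).
#' @param masks A [phantom_masks()] (or compatible mask set).
#' @param roi Character vector of nucleus names, or an integer vector of
#'   linear voxel indices to use directly.
#' @param runs Runs to include (default: the design's analysis runs, if
#'   known, else all runs present).
#' @param classes Classes to include (default all present).
#' @return A `sample_matrix`: `values` (samples x voxels), `info` tibble
#'   (subject, run, class), `voxels` tibble (voxel, i, j, k), `roi` name,
#'   `demeaned` flag.
#' @examples
#' masks <- phantom_masks(grid_shape = c(24, 28, 24), seed = 1)
#' ds <- simulate_betas(synthetic_design(n_subjects = 2, seed = 1), masks,
#'                      pattern_spec(n_informative_voxels = 0))
#' sm <- extract_roi_samples(ds, masks, "left_putamen")
#' dim(sm$values)
#' @export
extract_roi_samples <- function(dataset, masks, roi, runs = NULL,
                                classes = NULL) {
  stopifnot(inherits(dataset, "beta_dataset"))
  if (is.character(roi)) {
    vox <- roi_voxels(masks, roi)
    roi_name <- paste(roi, collapse = "+")
  } else {
    vox <- sort(as.integer(roi))
    roi_name <- "custom"
  }
  cols <- match(vox, dataset$voxels$voxel)
  if (anyNA(cols)) {
    stop(sprintf("%d ROI voxel(s) missing from the beta dataset (first: %d)",
                 sum(is.na(cols)), vox[which(is.na(cols))[1]]))
  }
  if (is.null(runs)) {
    runs <- if (!is.null(dataset$truth$design)) {
      dataset$truth$design$analysis_runs
    } else {
      sort(unique(dataset$index$run))
    }
  }
  if (is.null(classes)) classes <- sort(unique(dataset$index$class))

  want <- tidyr::expand_grid(subject = sort(unique(dataset$index$subject)),
                             run = sort(unique(as.integer(runs))),
                             class = sort(unique(as.integer(classes))))
  hit <- dplyr::left_join(want, dataset$index,
                          by = c("subject", "run", "class"))
  if (anyNA(hit$row)) {
    miss <- hit[is.na(hit$row), c("subject", "run", "class")]
    stop("missing beta volume(s): ",
         paste(utils::capture.output(print(as.data.frame(utils::head(miss, 5)))),
               collapse = "\n"))
  }

  structure(
    list(
      values = dataset$betas[hit$row, cols, drop = FALSE],
      info = tibble::tibble(subject = hit$subject, run = hit$run,
                            class = hit$class),
      voxels = dataset$voxels[cols, ],
      roi = roi_name,
      voxel_size_mm = dataset$voxel_size_mm,
      grid_shape = dataset$grid_shape,
      demeaned = FALSE
    ),
    class = "sample_matrix"
  )
}

#' @export
print.sample_matrix <- function(x, ...) {
  cat(sprintf("<sample_matrix> %s: %d samples x %d voxels (%d subjects, runs %s, classes %s)%s\n",
              x$roi, nrow(x$values), ncol(x$values),
              dplyr::n_distinct(x$info$subject),
              paste(sort(unique(x$info$run)), collapse = ","),
              paste(sort(unique(x$info$class)), collapse = ","),
              if (x$demeaned) ", demeaned" else ""))
  invisible(x)
}

#' Remove run-wise voxel means
#'
#' Within every subject x run block, subtracts each voxel's mean across the
#' block's classes, so block offsets (scanner/session effects) cancel
#' exactly. Idempotent; applied once to the full matrix before any
#' training, prior to cross-validation.
#'
#' @param samples A `sample_matrix` whose subject x run blocks each contain
#'   every included class exactly once.
#' @return The demeaned `sample_matrix` (`demeaned = TRUE`).
#' @export
demean_by_run <- function(samples) {
  stopifnot(inherits(samples, "sample_matrix"))
  info <- samples$info
  classes <- sort(unique(info$class))
  block <- interaction(info$subject, info$run, drop = TRUE)
  for (b in levels(block)) {
    rows <- which(block == b)
    if (!identical(sort(info$class[rows]), classes)) {
      stop("incomplete subject x run block: ", b,
           " (each block must contain every included class exactly once)")
    }
    samples$values[rows, ] <- sweep(samples$values[rows, , drop = FALSE], 2,
                                    colMeans(samples$values[rows, , drop = FALSE]))
  }
  samples$demeaned <- TRUE
  samples
}

#' Leave-one-sample-out decoding with within-training-fold demeaning
#'
#' Methodological comparison path for [demean_by_run()]: instead of
#' demeaning the full matrix once before cross-validation (the published
#' procedure), each fold demeans every subject x run block using only the
#' training samples of that block, and the held-out sample is centred with
#' its block's training-class mean. This removes the dependence between
#' folds that whole-matrix demeaning induces, at the price of deviating
#' from the published procedure. Plain R reference implementation; intended
#' for small problems.
#'
#' @param samples A non-demeaned `sample_matrix`.
#' @param config A [decoder_config()] (cost and tie rule are used).
#' @return A `decoding_result`, as from [loso_cross_validate()].
#' @export
loso_within_fold_demean <- function(samples, config = decoder_config()) {
  stopifnot(inherits(samples, "sample_matrix"))
  if (samples$demeaned) {
    warning("samples are already demeaned; the comparison is vacuous")
  }
  check_loso_feasible(samples$info$class)
  info <- samples$info
  block <- paste(info$subject, info$run)
  pred <- integer(nrow(samples$values))
  for (t in seq_len(nrow(samples$values))) {
    train <- samples$values[-t, , drop = FALSE]
    btr <- block[-t]
    centred <- train
    for (b in unique(btr)) {
      rows <- which(btr == b)
      centred[rows, ] <- sweep(train[rows, , drop = FALSE], 2,
                               colMeans(train[rows, , drop = FALSE]))
    }
    mine <- which(btr == block[t])
    test <- samples$values[t, ] - colMeans(train[mine, , drop = FALSE])
    fit <- train_pairwise(centred, info$class[-t], cost = config$cost)
    pred[t] <- predict_vote(fit, test, tie_rule = config$vote_tie_rule)
  }
  predictions <- dplyr::mutate(info, predicted = pred,
                               correct = .data$class == pred)
  structure(
    list(accuracy = mean(predictions$correct),
         chance = 1 / dplyr::n_distinct(info$class),
         n_samples = nrow(samples$values), n_voxels = ncol(samples$values),
         roi = samples$roi, predictions = predictions, config = config),
    class = "decoding_result"
  )
}

#' Restrict a sample matrix to a subset of voxel columns
#'
#' @param samples A `sample_matrix`.
#' @param cols Integer column positions (into the current voxel order).
#' @return The subset `sample_matrix`.
#' @export
select_voxels <- function(samples, cols) {
  stopifnot(inherits(samples, "sample_matrix"),
            all(cols >= 1), all(cols <= ncol(samples$values)))
  samples$values <- samples$values[, cols, drop = FALSE]
  samples$voxels <- samples$voxels[cols, ]
  samples
}

#' Write sample-matrix rows back into grid volumes
#'
#' Inverse of [extract_roi_samples()]: places each row's voxel values at
#' their grid coordinates (zero elsewhere).
#'
#' @param samples A `sample_matrix`.
#' @param rows Which sample rows to export (default all).
#' @return List of 3D arrays, one per requested row.
#' @export
samples_to_volumes <- function(samples, rows = seq_len(nrow(samples$values))) {
  lapply(rows, function(r) {
    vol <- array(0, samples$grid_shape)
    vol[samples$voxels$voxel] <- samples$values[r, ]
    vol
  })
}
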