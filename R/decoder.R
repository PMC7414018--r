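#' Decoder configuration
#'
#' @param cost Soft-margin penalty C of the linear SVMs (default 1, the
#'   conventional default setting).
#' @param n_permutations Label permutations for the null distribution
#'   (default 10000; reduce for desk-scale runs).
#' @param fdr_q Benjamini-Hochberg false-discovery level across ROIs.
#' @param seed Integer seed driving the label permutations.
#' @param vote_tie_rule `"lowest_label"` (default) or `"decision_sum"`; see
#'   [predict_vote()].
#' @param permutation_scheme `"global"` permutes the full label vector (the
#'   literal reading of label-permutation testing; default). `"within_block"`
#'   permutes labels within each subject x run block, preserving the
#'   one-of-each-class block structure that run-wise demeaning couples to
#'   the folds; it is the exactly exchangeable scheme for this design and
#'   the one used by the package's type-I calibration checks.
#' @return A `decoder_config` list.
#' @export
decoder_config <- function(cost = 1, n_permutations = 10000L, fdr_q = 0.05,
                           seed = 1L,
                           vote_tie_rule = c("lowest_label", "decision_sum"),
                           permutation_scheme = c("global", "within_block")) {
  stopifnot(cost > 0, n_permutations >= 1, fdr_q > 0, fdr_q < 1)
  structure(
    list(cost = cost, n_permutations = as.integer(n_permutations),
         fdr_q = fdr_q, seed = as.integer(seed),
         vote_tie_rule = match.arg(vote_tie_rule),
         permutation_scheme = match.arg(permutation_scheme)),
    class = "decoder_config"
  )
}

tie_rule_code <- function(rule) match(rule, c("lowest_label", "decision_sum")) - 1L

check_loso_feasible <- function(labels) {
  counts <- table(labels)
  if (length(counts) < 2) stop("need at least 2 classes")
  if (any(counts < 2)) {
    stop("class ", names(counts)[counts < 2][1],
         " has a single sample: leaving it out would drop the class from training")
  }
}

#' Leave-one-sample-out decoding accuracy
#'
#' Runs one-against-one linear SVM decoding under leave-one-sample-out
#' cross-validation: each sample in turn is held out, the pairwise
#' classifiers are trained on the remaining samples, and the held-out
#' sample is assigned the majority-vote class. The pooled accuracy is the
#' fraction of correctly predicted samples.
#'
#' @param samples A [sample_matrix][extract_roi_samples()] (demean first
#'   with [demean_by_run()]; a non-demeaned matrix is accepted but a
#'   message reminds you).
#' @param config A [decoder_config()].
#' @return A `decoding_result`: pooled `accuracy`, `chance` (1 / number of
#'   classes), a `predictions` tibble (subject, run, class, predicted,
#'   correct), and the configuration used.
#' @export
loso_cross_validate <- function(samples, config = decoder_config()) {
  stopifnot(inherits(samples, "sample_matrix"))
  check_loso_feasible(samples$info$class)
  gram <- tcrossprod(samples$values)
  pred <- cpp_loso_ovo(gram, as.integer(samples$info$class), config$cost,
                       tie_rule_code(config$vote_tie_rule))
  predictions <- dplyr::mutate(samples$info, predicted = pred,
                               correct = .data$class == pred)
  structure(
    list(
      accuracy = mean(predictions$correct),
      chance = 1 / dplyr::n_distinct(samples$info$class),
      n_samples = nrow(samples$values),
      n_voxels = ncol(samples$values),
      roi = samples$roi,
      predictions = predictions,
      config = config
    ),
    class = "decoding_result"
  )
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s: accuracy %.1f%% (chance %.1f%%), %d samples x %d voxels\n",
              x$roi, 100 * x$accuracy, 100 * x$chance, x$n_samples, x$n_voxels))
  invisible(x)
}

# one permuted label vector per column, per the configured scheme
permuted_labels <- function(info, n_perm, scheme) {
  labels <- as.integer(info$class)
  if (scheme == "global") {
    return(vapply(seq_len(n_perm), function(i) sample(labels),
                  integer(length(labels))))
  }
  block <- as.integer(interaction(info$subject, info$run, drop = TRUE))
  vapply(seq_len(n_perm), function(i) {
    out <- labels
    for (b in unique(block)) {
      rows <- which(block == b)
      out[rows] <- labels[rows][sample(length(rows))]
    }
    out
  }, integer(length(labels)))
}

#' Permutation test of decoding accuracy
#'
#' Repeats the full leave-one-sample-out procedure `n_permutations` times
#' with randomly permuted labels, pools the permuted accuracies into a null
#' distribution, and reports `p = (1 + #\{null >= observed\}) /
#' (n_permutations + 1)` -- never exactly zero.
#'
#' @inheritParams loso_cross_validate
#' @param observed Optionally a precomputed [loso_cross_validate()] result
#'   for these samples (saves one LOSO run).
#' @return A `permutation_null`: `null` accuracies, `observed` accuracy,
#'   `p_value`, `chance`, and the configuration.
#' @export
permutation_test <- function(samples, config = decoder_config(),
                             observed = NULL) {
  stopifnot(inherits(samples, "sample_matrix"))
  check_loso_feasible(samples$info$class)
  if (is.null(observed)) observed <- loso_cross_validate(samples, config)
  stopifnot(inherits(observed, "decoding_result"))

  gram <- tcrossprod(samples$values)
  perms <- with_stage_seed(config$seed, "permutation",
    permuted_labels(samples$info, config$n_permutations,
                    config$permutation_scheme))
  null <- cpp_perm_null_ovo(gram, perms, config$cost,
                            tie_rule_code(config$vote_tie_rule))
  structure(
    list(
      null = null,
      observed = observed$accuracy,
      p_value = (1 + sum(null >= observed$accuracy)) / (length(null) + 1),
      chance = observed$chance,
      n_samples = observed$n_samples,
      roi = samples$roi,
      config = config
    ),
    class = "permutation_null"
  )
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null> %s: observed %.1f%% vs null mean %.1f%% (%d perms), p = %.4g\n",
              x$roi, 100 * x$observed, 100 * mean(x$null), length(x$null),
              x$p_value))
  invisible(x)
}

#' Benjamini-Hochberg rejection flags
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param q False-discovery level.
#' @return Logical vector: which hypotheses are rejected at FDR `q`.
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) return(logical(0))
  stopifnot(all(p_values >= 0 & p_values <= 1), q > 0, q < 1)
  p.adjust(p_values, method = "BH") <= q
}

#' Decode every region of interest of a beta dataset
#'
#' For each ROI: extract samples, demean within subject x run blocks, run
#' leave-one-sample-out decoding and its permutation test; then apply
#' Benjamini-Hochberg FDR across the ROI family (one correction per
#' run-selection x class-selection analysis family).
#'
#' @param dataset A `beta_dataset`.
#' @param masks A [phantom_masks()].
#' @param rois Named list of ROI definitions (default [default_rois()]).
#' @param config A [decoder_config()].
#' @param runs,classes Optional run/class selections (e.g. `classes = 2:4`
#'   for the re-analysis excluding the simple sequence; `runs = 1:3` for
#'   the early-learning re-analysis).
#' @return Tibble with one row per ROI: accuracy, chance, p_permutation,
#'   fdr_significant, n_samples, n_voxels.
#' @export
decode_rois <- function(dataset, masks, rois = default_rois(),
                        config = decoder_config(), runs = NULL,
                        classes = NULL) {
  res <- purrr::imap_dfr(rois, function(roi, nm) {
    sm <- extract_roi_samples(dataset, masks, roi, runs = runs,
                              classes = classes) |> demean_by_run()
    pt <- permutation_test(sm, config)
    tibble::tibble(
      roi = nm, accuracy = pt$observed, chance = pt$chance,
      p_permutation = pt$p_value, n_samples = pt$n_samples,
      n_voxels = ncol(sm$values)
    )
  })
  res$fdr_significant <- fdr_correct(res$p_permutation, config$fdr_q)
  res
}
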