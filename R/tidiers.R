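#' Tidy a decoding result
#'
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return One-row tibble: roi, accuracy, chance, n_samples, n_voxels.
#' @export
tidy.decoding_result <- function(x, ...) {
  tibble::tibble(roi = x$roi, accuracy = x$accuracy, chance = x$chance,
                 n_samples = x$n_samples, n_voxels = x$n_voxels)
}

#' @rdname tidy.decoding_result
#' @export
glance.decoding_result <- function(x, ...) tidy.decoding_result(x)

#' Tidy a permutation null
#'
#' @param x A `permutation_null`.
#' @param ... Unused.
#' @return One-row tibble: roi, observed accuracy, null mean/sd, p-value,
#'   permutation count.
#' @export
tidy.permutation_null <- function(x, ...) {
  tibble::tibble(roi = x$roi, observed = x$observed,
                 null_mean = mean(x$null), null_sd = sd(x$null),
                 p_value = x$p_value, n_permutations = length(x$null),
                 chance = x$chance)
}

#' @rdname tidy.permutation_null
#' @export
glance.permutation_null <- function(x, ...) tidy.permutation_null(x)

#' Tidy an elimination trace
#'
#' @param x An `elimination_trace`.
#' @param ... Unused.
#' @return The accuracy-versus-voxel-count curve tibble.
#' @export
tidy.elimination_trace <- function(x, ...) x$curve

#' Tidy a searchlight result
#'
#' @param x A `searchlight_map` or `searchlight_significance`.
#' @param ... Unused.
#' @return The per-centre-voxel map tibble.
#' @export
tidy.searchlight_map <- function(x, ...) x$map

#' @rdname tidy.searchlight_map
#' @export
tidy.searchlight_significance <- function(x, ...) x$map

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Accuracy-versus-voxel-count plot for a backward elimination trace
#'
#' @param object An `elimination_trace`.
#' @param ... Unused.
#' @return A ggplot: pooled accuracy against the number of voxels left in
#'   the model, FDR-significant counts highlighted, chance level dashed.
#' @export
autoplot.elimination_trace <- function(object, ...) {
  curve <- object$curve
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$m, y = 100 * .data$accuracy)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$fdr_significant), size = 1.6) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "#2980b9"),
                                 name = "FDR q < 0.05") +
    ggplot2::labs(x = "voxels in model", y = "accuracy (%)",
                  title = paste("Backward voxel elimination:", object$roi)) +
    ggplot2::theme_minimal()
}

#' Null-distribution plot for a permutation test
#'
#' @param object A `permutation_null`.
#' @param ... Unused.
#' @return A ggplot: histogram of null accuracies with the observed
#'   accuracy and chance level marked.
#' @export
autoplot.permutation_null <- function(object, ...) {
  df <- tibble::tibble(accuracy = 100 * object$null)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = 100 * object$observed,
                        colour = "#c0392b", linewidth = 1) +
    ggplot2::geom_vline(xintercept = 100 * object$chance, linetype = "dashed") +
    ggplot2::labs(x = "null accuracy (%)", y = "permutations",
                  title = sprintf("%s: observed %.1f%%, p = %.3g", object$roi,
                                  100 * object$observed, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Behavioural learning-curve plot
#'
#' @param performance A [summarize_performance()] tibble.
#' @return A ggplot of group-mean movement time and accuracy per run and
#'   sequence class.
#' @export
plot_performance <- function(performance) {
  agg <- performance |>
    dplyr::group_by(.data$run, .data$class) |>
    dplyr::summarise(accuracy = mean(.data$accuracy),
                     mean_mt_s = mean(.data$mean_mt_s, na.rm = TRUE),
                     .groups = "drop") |>
    tidyr::pivot_longer(c("accuracy", "mean_mt_s"), names_to = "measure")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$run, y = .data$value,
                                    colour = factor(.data$class))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "run", colour = "sequence") +
    ggplot2::theme_minimal()
}

#' Searchlight accuracy slice plot
#'
#' @param x A `searchlight_map` or `searchlight_significance`.
#' @param k Axial slice(s) to show (default: all slices with centres).
#' @return A ggplot tile map of centre-voxel accuracies, significant
#'   centres outlined when available.
#' @export
plot_searchlight <- function(x, k = NULL) {
  map <- if (inherits(x, "searchlight_map")) x$map else x$map
  if (!is.null(k)) map <- dplyr::filter(map, .data$k %in% !!k)
  gg <- ggplot2::ggplot(map, ggplot2::aes(x = .data$i, y = .data$j,
                                          fill = 100 * .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~k) +
    ggplot2::scale_fill_viridis_c(name = "accuracy (%)") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
  if ("fdr_significant" %in% names(map)) {
    gg <- gg + ggplot2::geom_tile(data = dplyr::filter(map, .data$fdr_significant),
                                  fill = NA, colour = "#c0392b", linewidth = 0.4)
  }
  gg
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
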