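#' Searchlight configuration
#'
#' @param radius_mm Sphere radius in mm (default 5). Distances are
#'   centre-to-centre Euclidean distances in mm, with voxels at exactly the
#'   radius included (`<=`); on a 2 mm grid a 5 mm sphere holds 81 voxels
#'   deep inside a mask.
#' @param n_perm_per_voxel Label permutations run per centre voxel; all
#'   permuted accuracies are pooled into one null distribution (default 10).
#' @param fdr_q FDR level across centre voxels.
#' @param seed Integer seed; each voxel's permutations are seeded from it
#'   and the voxel index, so pooling is over independent draws and any
#'   voxel's run is reproducible in isolation.
#' @return A `searchlight_config` list.
#' @export
searchlight_config <- function(radius_mm = 5, n_perm_per_voxel = 10L,
                               fdr_q = 0.05, seed = 1L) {
  stopifnot(radius_mm > 0, n_perm_per_voxel >= 1, fdr_q > 0, fdr_q < 1)
  structure(
    list(radius_mm = radius_mm, n_perm_per_voxel = as.integer(n_perm_per_voxel),
         fdr_q = fdr_q, seed = as.integer(seed)),
    class = "searchlight_config"
  )
}

#' In-mask voxels within a sphere around a centre voxel
#'
#' @param center Grid coordinate `c(i, j, k)` of the centre (must be inside
#'   the mask).
#' @param mask Logical/numeric 3D array (nonzero = in mask).
#' @param radius_mm Sphere radius in mm.
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @return Integer vector of linear voxel indices (ascending scan order),
#'   always including the centre.
#' @export
sphere_indices <- function(center, mask, radius_mm, voxel_size_mm) {
  stopifnot(length(center) == 3)
  dims <- dim(mask)
  if (mask[center[1], center[2], center[3]] == 0) {
    stop("sphere centre is outside the mask")
  }
  r_vox <- radius_mm / voxel_size_mm
  span <- floor(r_vox)
  off <- expand.grid(dx = -span:span, dy = -span:span, dz = -span:span)
  off <- off[off$dx^2 + off$dy^2 + off$dz^2 <= r_vox^2, ]
  pts <- cbind(center[1] + off$dx, center[2] + off$dy, center[3] + off$dz)
  keep <- pts[, 1] >= 1 & pts[, 1] <= dims[1] &
    pts[, 2] >= 1 & pts[, 2] <= dims[2] &
    pts[, 3] >= 1 & pts[, 3] <= dims[3]
  pts <- pts[keep, , drop = FALSE]
  idx <- pts[, 1] + dims[1] * (pts[, 2] - 1) + dims[1] * dims[2] * (pts[, 3] - 1)
  sort(idx[mask[idx] != 0])
}

#' Searchlight decoding map
#'
#' Runs leave-one-sample-out one-against-one decoding within a sphere
#' around every ROI voxel and assigns the pooled accuracy to the sphere's
#' centre. Spheres are intersected with the ROI; demeaning is inherited
#' from the input samples (run-wise demeaning is voxelwise, so demeaning
#' the whole ROI or each sphere separately is identical).
#'
#' @param samples A demeaned `sample_matrix` covering the ROI.
#' @param config A [searchlight_config()].
#' @param decoder A [decoder_config()] (cost / tie rule).
#' @return A `searchlight_map`: tibble with one row per centre voxel
#'   (voxel, i, j, k, sphere_size, accuracy) plus metadata.
#' @export
searchlight_map <- function(samples, config = searchlight_config(),
                            decoder = decoder_config()) {
  stopifnot(inherits(samples, "sample_matrix"))
  check_loso_feasible(samples$info$class)
  mask <- array(FALSE, samples$grid_shape)
  mask[samples$voxels$voxel] <- TRUE
  labels <- as.integer(samples$info$class)
  tie <- tie_rule_code(decoder$vote_tie_rule)

  rows <- purrr::map_dfr(seq_len(nrow(samples$voxels)), function(v) {
    ctr <- c(samples$voxels$i[v], samples$voxels$j[v], samples$voxels$k[v])
    sph <- sphere_indices(ctr, mask, config$radius_mm, samples$voxel_size_mm)
    cols <- match(sph, samples$voxels$voxel)
    gram <- tcrossprod(samples$values[, cols, drop = FALSE])
    pred <- cpp_loso_ovo(gram, labels, decoder$cost, tie)
    tibble::tibble(voxel = samples$voxels$voxel[v],
                   i = ctr[1], j = ctr[2], k = ctr[3],
                   sphere_size = length(sph), accuracy = mean(pred == labels))
  })
  structure(
    list(map = rows, roi = samples$roi, grid_shape = samples$grid_shape,
         chance = 1 / dplyr::n_distinct(labels), config = config),
    class = "searchlight_map"
  )
}

#' @export
print.searchlight_map <- function(x, ...) {
  cat(sprintf("<searchlight_map> %s: %d centres, accuracy %.1f-%.1f%% (chance %.1f%%)\n",
              x$roi, nrow(x$map), 100 * min(x$map$accuracy),
              100 * max(x$map$accuracy), 100 * x$chance))
  invisible(x)
}

#' Pooled permutation null and FDR thresholding for a searchlight map
#'
#' For every centre voxel the searchlight decoding is repeated
#' `n_perm_per_voxel` times with permuted labels; all permuted accuracies
#' are pooled into a single null distribution. Each voxel's p-value is
#' `(1 + #\{pooled null >= accuracy\}) / (n_pooled + 1)`, followed by
#' Benjamini-Hochberg FDR across all centre voxels.
#'
#' @param samples The same demeaned `sample_matrix` the map was built from.
#' @param slmap A [searchlight_map()] result.
#' @param config A [searchlight_config()].
#' @param decoder A [decoder_config()] (its `permutation_scheme` is
#'   honoured here too).
#' @return A `searchlight_significance`: the map tibble extended with
#'   p_value and fdr_significant, the pooled `null` vector, and
#'   `accuracy_threshold` (the smallest accuracy that survived FDR, `NA`
#'   when none did).
#' @export
searchlight_significance <- function(samples, slmap,
                                     config = searchlight_config(),
                                     decoder = decoder_config()) {
  stopifnot(inherits(samples, "sample_matrix"),
            inherits(slmap, "searchlight_map"))
  mask <- array(FALSE, samples$grid_shape)
  mask[samples$voxels$voxel] <- TRUE
  labels <- as.integer(samples$info$class)
  tie <- tie_rule_code(decoder$vote_tie_rule)

  null <- unlist(purrr::map(seq_len(nrow(samples$voxels)), function(v) {
    ctr <- c(samples$voxels$i[v], samples$voxels$j[v], samples$voxels$k[v])
    sph <- sphere_indices(ctr, mask, config$radius_mm, samples$voxel_size_mm)
    cols <- match(sph, samples$voxels$voxel)
    gram <- tcrossprod(samples$values[, cols, drop = FALSE])
    perms <- with_stage_seed(config$seed, "searchlight",
      permuted_labels(samples$info, config$n_perm_per_voxel,
                      decoder$permutation_scheme),
      extra = samples$voxels$voxel[v])
    cpp_perm_null_ovo(gram, perms, decoder$cost, tie)
  }))

  map <- slmap$map
  map$p_value <- vapply(map$accuracy, function(a) {
    (1 + sum(null >= a)) / (length(null) + 1)
  }, numeric(1))
  map$fdr_significant <- fdr_correct(map$p_value, config$fdr_q)
  thr <- if (any(map$fdr_significant)) {
    min(map$accuracy[map$fdr_significant])
  } else NA_real_

  structure(
    list(map = map, null = null, accuracy_threshold = thr,
         chance = slmap$chance, roi = slmap$roi,
         grid_shape = slmap$grid_shape, config = config),
    class = "searchlight_significance"
  )
}

#' @export
print.searchlight_significance <- function(x, ...) {
  cat(sprintf("<searchlight_significance> %s: %d/%d centres FDR-significant (pooled null n = %d)%s\n",
              x$roi, sum(x$map$fdr_significant), nrow(x$map), length(x$null),
              if (is.na(x$accuracy_threshold)) "" else
                sprintf("; accuracy threshold %.1f%%", 100 * x$accuracy_threshold)))
  invisible(x)
}

#' Territory-wise counts of significant searchlight voxels
#'
#' For every nucleus x territory: the number N of FDR-significant centre
#' voxels and the percentage of the nucleus's significant voxels they
#' represent. Significant voxels without a territory label are counted
#' under `"unlabeled"` with a warning.
#'
#' @param sig A [searchlight_significance()] result (or any tibble with
#'   `voxel` and `fdr_significant` columns).
#' @param masks A [phantom_masks()] supplying `nucleus_labels` and
#'   `territory_labels`.
#' @return Tibble: nucleus, territory, n, percent (percentages sum to 100
#'   within each nucleus that has significant voxels).
#' @export
quantify_by_atlas <- function(sig, masks) {
  map <- if (inherits(sig, "searchlight_significance")) sig$map else sig
  stopifnot(all(c("voxel", "fdr_significant") %in% names(map)))
  terr_levels <- names(masks$territory_names)
  nuc_levels <- names(masks$nucleus_names)

  sig_vox <- map$voxel[map$fdr_significant]
  nuc <- masks$nucleus_labels[sig_vox]
  terr <- masks$territory_labels[sig_vox]
  if (any(terr == 0 & nuc > 0)) {
    warning(sum(terr == 0 & nuc > 0),
            " significant voxel(s) without territory label counted as 'unlabeled'")
    terr_levels <- c(terr_levels, "unlabeled")
  }

  grid <- tidyr::expand_grid(nucleus = nuc_levels, territory = terr_levels)
  counts <- tibble::tibble(
    nucleus = factor(nuc_levels[nuc], levels = nuc_levels),
    territory = ifelse(terr == 0, "unlabeled",
                       names(masks$territory_names)[terr])
  ) |>
    dplyr::count(.data$nucleus, .data$territory, .drop = FALSE, name = "n") |>
    dplyr::mutate(nucleus = as.character(.data$nucleus))
  out <- dplyr::left_join(grid, counts, by = c("nucleus", "territory")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::group_by(.data$nucleus) |>
    dplyr::mutate(percent = if (sum(.data$n) > 0) 100 * .data$n / sum(.data$n)
                  else 0) |>
    dplyr::ungroup()
  out
}
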