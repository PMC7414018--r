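#' Phantom striatal masks with territory parcellation
#'
#' Builds a deterministic phantom of the four striatal nuclei (left/right
#' putamen and caudate nucleus) as disjoint ellipsoids on a regular 3D grid,
#' and partitions each nucleus into 7 territory sectors (limbic, executive,
#' rostral-motor, caudal-motor, parietal, occipital, temporal) along its
#' long (anterior-posterior) axis with a dorsoventral split, mimicking the
#' layout of a connectivity-based striatal parcellation. The phantom is a
#' stand-in geometry for testing: any reproducible 7-way partition serves
#' the territory quantification stage.
#'
#' @param grid_shape Integer vector of 3 positive grid dimensions.
#' @param voxel_size_mm Isotropic voxel size in mm (default 2).
#' @param seed Integer seed; jitters nucleus centres by up to one voxel so
#'   distinct seeds give distinct (but always valid) phantoms.
#' @return An object of class `phantom_masks`: grid metadata, a
#'   `nucleus_labels` integer array (0 = background, 1..4 = nuclei), a
#'   `territory_labels` integer array (0 = background, 1..7), and name
#'   lookup vectors.
#' @examples
#' masks <- phantom_masks(seed = 1)
#' table(masks$nucleus_labels[masks$nucleus_labels > 0])
#' @export
phantom_masks <- function(grid_shape = c(40L, 48L, 40L), voxel_size_mm = 2,
                          seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
            voxel_size_mm > 0)
  grid_shape <- as.integer(grid_shape)

  mid <- (grid_shape + 1) / 2
  # semi-axes in voxels; putamen is the larger, more lateral structure
  vx <- voxel_size_mm
  shapes <- list(
    left_putamen  = list(center = mid + c(-26, 0, -2) / vx, semi = c(8, 16, 10) / vx),
    right_putamen = list(center = mid + c(+26, 0, -2) / vx, semi = c(8, 16, 10) / vx),
    left_caudate  = list(center = mid + c(-12, 8, 12) / vx, semi = c(5, 14, 8) / vx),
    right_caudate = list(center = mid + c(+12, 8, 12) / vx, semi = c(5, 14, 8) / vx)
  )
  # centre jitter of +/- 1 mm keeps the phantom valid at any voxel size
  jitter <- with_stage_seed(seed, "masks",
    matrix(sample(c(-1, 0, 1), 12, replace = TRUE), nrow = 4)) / vx

  nucleus_labels <- array(0L, grid_shape)
  ijk <- as.matrix(expand.grid(i = seq_len(grid_shape[1]),
                               j = seq_len(grid_shape[2]),
                               k = seq_len(grid_shape[3])))
  for (nuc in seq_along(shapes)) {
    nm <- names(shapes)[nuc]
    ctr <- shapes[[nuc]]$center + jitter[nuc, ]
    semi <- shapes[[nuc]]$semi
    d2 <- ((ijk[, 1] - ctr[1]) / semi[1])^2 +
      ((ijk[, 2] - ctr[2]) / semi[2])^2 +
      ((ijk[, 3] - ctr[3]) / semi[3])^2
    inside <- d2 <= 1
    out_of_grid <- inside &
      (ijk[, 1] < 1 | ijk[, 1] > grid_shape[1] |
       ijk[, 2] < 1 | ijk[, 2] > grid_shape[2] |
       ijk[, 3] < 1 | ijk[, 3] > grid_shape[3])
    # expand.grid never leaves the grid; check instead that the ellipsoid
    # bounding box fits, so truncated nuclei are refused explicitly
    if (any(ctr - semi < 1) || any(ctr + semi > grid_shape)) {
      stop(sprintf("grid %s too small to hold nucleus '%s'",
                   paste(grid_shape, collapse = "x"), nm))
    }
    if (any(nucleus_labels[inside] != 0L)) {
      stop(sprintf("nucleus '%s' overlaps an earlier nucleus; enlarge the grid", nm))
    }
    nucleus_labels[inside] <- nuc
    stopifnot(!any(out_of_grid))
  }

  territory_labels <- array(0L, grid_shape)
  for (nuc in 1:4) {
    vox <- which(nucleus_labels == nuc)
    sub <- ijk[vox, , drop = FALSE]
    territory_labels[vox] <- assign_territories(sub)
  }

  affine <- diag(c(voxel_size_mm, voxel_size_mm, voxel_size_mm, 1))
  affine[1:3, 4] <- -voxel_size_mm * (grid_shape - 1) / 2

  structure(
    list(
      grid_shape = grid_shape,
      voxel_size_mm = voxel_size_mm,
      affine = affine,
      nucleus_labels = nucleus_labels,
      territory_labels = territory_labels,
      nucleus_names = c(left_putamen = 1L, right_putamen = 2L,
                        left_caudate = 3L, right_caudate = 4L),
      territory_names = c(limbic = 1L, executive = 2L, rostral_motor = 3L,
                          caudal_motor = 4L, parietal = 5L, occipital = 6L,
                          temporal = 7L),
      seed = as.integer(seed)
    ),
    class = "phantom_masks"
  )
}

# 7 sectors: 4 long-axis (anterior-posterior) slabs of equal voxel count,
# the 3 posterior slabs split at their dorsoventral median
assign_territories <- function(sub) {
  n <- nrow(sub)
  slab <- cut(rank(sub[, 2], ties.method = "first"),
              breaks = round(seq(0, n, length.out = 5)),
              labels = FALSE)
  terr <- integer(n)
  terr[slab == 1] <- 1L # limbic: anterior tip
  map <- rbind(c(2L, 7L), c(3L, 6L), c(4L, 5L)) # dorsal, ventral per slab
  for (s in 2:4) {
    idx <- which(slab == s)
    dorsal <- rank(sub[idx, 3], ties.method = "first") > length(idx) / 2
    terr[idx] <- ifelse(dorsal, map[s - 1, 1], map[s - 1, 2])
  }
  terr
}

#' @export
print.phantom_masks <- function(x, ...) {
  counts <- table(factor(x$nucleus_labels[x$nucleus_labels > 0], levels = 1:4,
                         labels = names(x$nucleus_names)))
  cat(sprintf("<phantom_masks> grid %s, %g mm voxels\n",
              paste(x$grid_shape, collapse = "x"), x$voxel_size_mm))
  print(counts)
  invisible(x)
}

#' Voxel indices of a named region of interest
#'
#' @param masks A [phantom_masks] object (or any list with `nucleus_labels`
#'   and `nucleus_names`).
#' @param roi Character vector of nucleus names; several names yield the
#'   union (e.g. putamen + caudate of one hemisphere).
#' @return Sorted integer vector of linear voxel indices (ascending, x
#'   fastest -- the package's fixed scan order).
#' @export
roi_voxels <- function(masks, roi) {
  codes <- masks$nucleus_names[roi]
  if (anyNA(codes)) {
    stop("unknown ROI name(s): ",
         paste(roi[is.na(codes)], collapse = ", "))
  }
  vox <- which(masks$nucleus_labels %in% codes)
  if (length(vox) == 0) stop("empty ROI: ", paste(roi, collapse = "+"))
  sort(vox)
}

#' Default six regions of interest
#'
#' Left/right putamen, left/right caudate nucleus, and the two
#' hemisphere-wise combinations (putamen + caudate).
#' @return Named list of character vectors usable as `roi` arguments.
#' @export
default_rois <- function() {
  list(
    left_putamen = "left_putamen",
    left_caudate = "left_caudate",
    left_striatum = c("left_putamen", "left_caudate"),
    right_putamen = "right_putamen",
    right_caudate = "right_caudate",
    right_striatum = c("right_putamen", "right_caudate")
  )
}
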