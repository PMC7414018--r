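#' Write phantom masks as NIfTI volumes
#'
#' Writes `nucleus_labels.nii.gz`, `territory_labels.nii.gz`, and one
#' binary mask per nucleus (`mask_<name>.nii.gz`), all with the phantom's
#' voxel size and affine.
#'
#' @param masks A [phantom_masks()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of file paths, invisibly.
#' @export
write_masks_nifti <- function(masks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    nucleus_labels = file.path(dir, "nucleus_labels.nii.gz"),
    territory_labels = file.path(dir, "territory_labels.nii.gz")
  )
  write_volume_nifti(masks$nucleus_labels, paths[["nucleus_labels"]], masks)
  write_volume_nifti(masks$territory_labels, paths[["territory_labels"]], masks)
  for (nm in names(masks$nucleus_names)) {
    f <- file.path(dir, sprintf("mask_%s.nii.gz", nm))
    write_volume_nifti(
      array(as.integer(masks$nucleus_labels == masks$nucleus_names[[nm]]),
            masks$grid_shape), f, masks)
    paths[nm] <- f
  }
  invisible(paths)
}

write_volume_nifti <- function(vol, path, meta) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(meta$voxel_size_mm, 3)
  img <- RNifti::`sform<-`(img, structure(meta$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a beta dataset as per-volume NIfTI files plus sidecar
#'
#' One gzipped NIfTI per (subject, run, class) named
#' `sub-<s>_run-<r>_seq-<c>_beta.nii.gz` (zeros outside the mask), plus
#' `dataset.json` holding the generator parameters and the ground-truth
#' informative voxel indices.
#'
#' @param dataset A `beta_dataset`.
#' @param dir Output directory.
#' @return Tibble mapping (subject, run, class) to file paths, invisibly.
#' @export
write_beta_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "beta_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- dataset$index
  files$file <- file.path(dir, sprintf("sub-%02d_run-%d_seq-%d_beta.nii.gz",
                                       files$subject, files$run, files$class))
  for (r in seq_len(nrow(files))) {
    vol <- array(0, dataset$grid_shape)
    vol[dataset$voxels$voxel] <- dataset$betas[files$row[r], ]
    write_volume_nifti(vol, files$file[r], dataset)
  }
  sidecar <- list(
    grid_shape = dataset$grid_shape,
    voxel_size_mm = dataset$voxel_size_mm,
    informative_voxels = dataset$truth$informative_voxels,
    pattern_spec = unclass(dataset$truth$spec),
    design = unclass(dataset$truth$design)
  )
  jsonlite::write_json(sidecar, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' Read a beta dataset from NIfTI volumes
#'
#' The counterpart of [write_beta_dataset()] and the entry point for real
#' data: reads one volume per (subject, run, class), checks that all
#' volumes share grid shape, voxel size and affine (to a tolerance of
#' 1e-4, absorbing float jitter in NIfTI headers), and keeps the in-mask
#' values.
#'
#' @param files Tibble/data frame with columns subject, run, class, file.
#' @param mask Logical/numeric 3D array selecting the voxels to retain.
#' @param design Optional [synthetic_design()] recorded as metadata (sets
#'   the default analysis runs downstream).
#' @return A `beta_dataset`.
#' @export
read_beta_dataset <- function(files, mask, design = NULL) {
  stopifnot(all(c("subject", "run", "class", "file") %in% names(files)),
            nrow(files) >= 1)
  mask_vox <- sort(which(mask != 0))
  ref <- NULL
  betas <- matrix(NA_real_, nrow(files), length(mask_vox))
  for (r in seq_len(nrow(files))) {
    img <- RNifti::readNifti(files$file[r])
    hdr <- list(dim = dim(img), pixdim = RNifti::pixdim(img),
                affine = unclass(RNifti::xform(img)))
    if (is.null(ref)) {
      ref <- hdr
      if (!identical(dim(img), dim(mask))) {
        stop("volume grid ", paste(dim(img), collapse = "x"),
             " does not match mask grid ", paste(dim(mask), collapse = "x"),
             " in ", files$file[r])
      }
    } else if (!identical(hdr$dim, ref$dim) ||
               max(abs(hdr$pixdim - ref$pixdim)) > 1e-4 ||
               max(abs(hdr$affine - ref$affine)) > 1e-4) {
      stop("grid/affine mismatch in ", files$file[r])
    }
    betas[r, ] <- as.array(img)[mask_vox]
  }
  coords <- arrayInd(mask_vox, dim(mask))
  index <- tibble::tibble(subject = as.integer(files$subject),
                          run = as.integer(files$run),
                          class = as.integer(files$class),
                          row = seq_len(nrow(files)))
  structure(
    list(index = index, betas = betas,
         voxels = tibble::tibble(voxel = mask_vox, i = coords[, 1],
                                 j = coords[, 2], k = coords[, 3]),
         grid_shape = dim(mask), voxel_size_mm = ref$pixdim[1],
         affine = ref$affine,
         truth = list(informative_voxels = integer(0), design = design)),
    class = "beta_dataset"
  )
}

#' Write a searchlight accuracy / significance map as NIfTI
#'
#' @param sig A `searchlight_map` or `searchlight_significance`.
#' @param dir Output directory.
#' @param voxel_size_mm Voxel size for the header.
#' @return Paths of the accuracy (and, when available, significance-mask)
#'   volumes, invisibly.
#' @export
write_searchlight_nifti <- function(sig, dir, voxel_size_mm = 2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(voxel_size_mm = voxel_size_mm,
               affine = diag(c(rep(voxel_size_mm, 3), 1)))
  acc <- array(0, sig$grid_shape)
  acc[sig$map$voxel] <- sig$map$accuracy
  paths <- c(accuracy = file.path(dir, "searchlight_accuracy.nii.gz"))
  write_volume_nifti(acc, paths[["accuracy"]], meta)
  if ("fdr_significant" %in% names(sig$map)) {
    m <- array(0L, sig$grid_shape)
    m[sig$map$voxel] <- as.integer(sig$map$fdr_significant)
    paths["significance"] <- file.path(dir, "searchlight_significant.nii.gz")
    write_volume_nifti(m, paths[["significance"]], meta)
  }
  invisible(paths)
}
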