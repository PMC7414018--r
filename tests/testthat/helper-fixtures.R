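# Small fixtures shared across tests; everything is generated in code.

# coarse 4 mm phantom: same mm geometry as the default, ~90 + ~40 voxel nuclei
small_masks <- function(seed = 1) {
  phantom_masks(grid_shape = c(20L, 24L, 20L), voxel_size_mm = 4, seed = seed)
}

# sample_matrix with one-of-each-class subject x run blocks of iid noise,
# demeaned like the pipeline does; optional class signal on chosen columns
toy_samples <- function(n_subjects = 4, n_runs = 3, n_classes = 4,
                        n_voxels = 24, seed = 1, signal = 0,
                        signal_cols = integer(0), demean = TRUE) {
  set.seed(seed)
  info <- tidyr::expand_grid(subject = seq_len(n_subjects),
                             run = seq_len(n_runs),
                             class = seq_len(n_classes))
  values <- matrix(rnorm(nrow(info) * n_voxels), nrow(info), n_voxels)
  if (signal > 0 && length(signal_cols)) {
    pat <- matrix(rnorm(n_classes * length(signal_cols), 0, signal),
                  n_classes, length(signal_cols))
    pat <- sweep(pat, 2, colMeans(pat)) # mean-balanced across classes
    values[, signal_cols] <- values[, signal_cols] + pat[info$class, ]
  }
  sm <- structure(
    list(values = values, info = info,
         voxels = tibble::tibble(voxel = seq_len(n_voxels),
                                 i = seq_len(n_voxels), j = 1L, k = 1L),
         roi = "toy", voxel_size_mm = 2,
         grid_shape = c(n_voxels, 1L, 1L), demeaned = FALSE),
    class = "sample_matrix")
  if (demean) demean_by_run(sm) else sm
}

# brute-force Benjamini-Hochberg by definition (independent of p.adjust)
bh_brute_force <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(below)) reject[ord[seq_len(max(below))]] <- TRUE
  reject
}
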