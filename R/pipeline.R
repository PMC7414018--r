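#' End-to-end pipeline configuration
#'
#' Bundles the configuration of every stage of the phantom experiment (or,
#' in `mode = "real"`, of an analysis starting from existing beta volumes).
#' All stage seeds derive from the single global `seed` through fixed
#' offsets, so results are reproducible and stages independent.
#'
#' @param mode `"synthetic"` (default) or `"real"`.
#' @param output_dir Where stage outputs are written.
#' @param grid_shape,voxel_size_mm Phantom geometry (synthetic mode).
#' @param design A [synthetic_design()]; its seed is overridden by `seed`.
#' @param pattern A [pattern_spec()].
#' @param learning A [learning_params()].
#' @param rois Named ROI list (default the six standard ROIs).
#' @param runs,classes Optional run/class selections for the decoding
#'   family (e.g. `runs = 1:3` for the early-learning re-analysis,
#'   `classes = 2:4` to exclude the simple sequence).
#' @param decoder A [decoder_config()] (500 permutations by default here:
#'   the desk-scale setting; raise to 10000 for full fidelity).
#' @param searchlight A [searchlight_config()].
#' @param rfe_roi ROI for the backward-elimination stage.
#' @param rfe_max_voxels Random (seeded) voxel subsample size for the
#'   elimination stage, keeping its cost desk-scale; `Inf` uses all.
#' @param searchlight_roi ROI for the searchlight stage.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "behavior", "decode", "rfe", "searchlight")`.
#' @param beta_files,mask,masks Real mode inputs: a file table for
#'   [read_beta_dataset()], its mask, and a mask/atlas object.
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "real"),
                            output_dir = tempfile("striamvpa_run_"),
                            grid_shape = c(40L, 48L, 40L), voxel_size_mm = 2,
                            design = synthetic_design(),
                            pattern = pattern_spec(),
                            learning = learning_params(),
                            rois = default_rois(),
                            runs = NULL, classes = NULL,
                            decoder = decoder_config(n_permutations = 500L),
                            searchlight = searchlight_config(),
                            rfe_roi = "left_putamen",
                            rfe_max_voxels = 40L,
                            searchlight_roi = "left_putamen",
                            stages = c("simulate", "behavior", "decode",
                                       "rfe", "searchlight"),
                            beta_files = NULL, mask = NULL, masks = NULL,
                            seed = 1L) {
  mode <- match.arg(mode)
  stages <- match.arg(stages, several.ok = TRUE)
  if (mode == "real") {
    if (is.null(beta_files) || is.null(mask)) {
      stop("real mode needs `beta_files` and `mask`")
    }
    if (!all(file.exists(beta_files$file))) {
      stop("missing beta file(s): ",
           paste(utils::head(beta_files$file[!file.exists(beta_files$file)], 3),
                 collapse = ", "))
    }
  }
  design$seed <- as.integer(seed)
  decoder$seed <- as.integer(seed)
  searchlight$seed <- as.integer(seed)
  structure(
    list(mode = mode, output_dir = output_dir, grid_shape = grid_shape,
         voxel_size_mm = voxel_size_mm, design = design, pattern = pattern,
         learning = learning, rois = rois, runs = runs, classes = classes,
         decoder = decoder, searchlight = searchlight, rfe_roi = rfe_roi,
         rfe_max_voxels = rfe_max_voxels,
         searchlight_roi = searchlight_roi, stages = stages,
         beta_files = beta_files, mask = mask, masks = masks,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the configured pipeline
#'
#' Executes the requested stages in order (simulate, behavior, decode,
#' backward elimination, searchlight), writes each stage's tables as TSV
#' under `output_dir`, and returns a manifest of results and paths. A
#' stage failure aborts with the stage name; completed outputs remain on
#' disk.
#'
#' @param config A [pipeline_config()].
#' @return A `run_manifest`: per-stage results, output paths, timings, and
#'   the configuration.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config, outputs = list(), timing = list())
  res <- list()

  run_stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(code), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$timing[[name]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  if (config$mode == "synthetic") {
    if ("simulate" %in% config$stages) {
      res$masks <- run_stage("simulate", {
        phantom_masks(config$grid_shape, config$voxel_size_mm, config$seed)
      })
      res$dataset <- simulate_betas(config$design, res$masks, config$pattern)
      res$press_log <- simulate_press_log(config$design, config$learning)
      log_path <- file.path(config$output_dir, "press_log.tsv")
      write_press_log(res$press_log, log_path)
      manifest$outputs$press_log <- log_path
    }
  } else {
    res$masks <- config$masks
    res$dataset <- run_stage("assemble", {
      read_beta_dataset(config$beta_files, config$mask, config$design)
    })
  }

  if ("behavior" %in% config$stages && !is.null(res$press_log)) {
    res$performance <- run_stage("behavior", summarize_performance(res$press_log))
    perf_path <- file.path(config$output_dir, "performance.tsv")
    write.table(res$performance, perf_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest$outputs$performance <- perf_path
  }

  if ("decode" %in% config$stages) {
    res$roi_results <- run_stage("decode", {
      decode_rois(res$dataset, res$masks, config$rois, config$decoder,
                  runs = config$runs, classes = config$classes)
    })
    p <- file.path(config$output_dir, "roi_decoding.tsv")
    write.table(res$roi_results, p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs$roi_decoding <- p
  }

  if ("rfe" %in% config$stages) {
    res$rfe <- run_stage("rfe", {
      sm <- extract_roi_samples(res$dataset, res$masks, config$rfe_roi,
                                runs = config$runs, classes = config$classes) |>
        demean_by_run()
      if (is.finite(config$rfe_max_voxels) &&
          ncol(sm$values) > config$rfe_max_voxels) {
        keep <- with_stage_seed(config$seed, "rfe", extra = 1L,
          sort(sample(ncol(sm$values), config$rfe_max_voxels)))
        sm <- select_voxels(sm, keep)
      }
      backward_elimination(sm, config$decoder)
    })
    p <- file.path(config$output_dir, "rfe_curve.tsv")
    write.table(res$rfe$curve, p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs$rfe_curve <- p
    res$top_voxels <- top_selected_voxels(res$rfe,
                                          k = min(10, nrow(res$rfe$curve)))
    p2 <- file.path(config$output_dir, "rfe_top_voxels.tsv")
    write.table(res$top_voxels, p2, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs$rfe_top_voxels <- p2
  }

  if ("searchlight" %in% config$stages) {
    res$searchlight <- run_stage("searchlight", {
      sm <- extract_roi_samples(res$dataset, res$masks, config$searchlight_roi,
                                runs = config$runs, classes = config$classes) |>
        demean_by_run()
      map <- searchlight_map(sm, config$searchlight, config$decoder)
      searchlight_significance(sm, map, config$searchlight, config$decoder)
    })
    res$territory_table <- quantify_by_atlas(res$searchlight, res$masks)
    p <- file.path(config$output_dir, "searchlight_map.tsv")
    write.table(res$searchlight$map, p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest$outputs$searchlight_map <- p
    p2 <- file.path(config$output_dir, "territory_table.tsv")
    write.table(res$territory_table, p2, sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest$outputs$territory_table <- p2
  }

  manifest$results <- res
  class(manifest) <- "run_manifest"
  manifest
}

#' Write a plain-text report of a pipeline run
#'
#' One human-readable summary: behavioural performance, per-ROI decoding
#' with permutation p-values and FDR flags, the elimination curve, and the
#' searchlight territory table. Sections whose stage did not run are
#' marked absent. Regeneration is idempotent.
#'
#' @param manifest A [run_pipeline()] manifest.
#' @param path Output file (default `report.txt` in the run's output dir).
#' @return `path`, invisibly.
#' @export
write_report <- function(manifest,
                         path = file.path(manifest$config$output_dir,
                                          "report.txt")) {
  stopifnot(inherits(manifest, "run_manifest"))
  res <- manifest$results
  lines <- c("striamvpa pipeline report",
             sprintf("mode: %s   seed: %d", manifest$config$mode,
                     manifest$config$seed), "")
  section <- function(title, obj, fmt) {
    if (is.null(obj)) {
      c(sprintf("## %s", title), "(stage not run)", "")
    } else {
      c(sprintf("## %s", title), fmt(obj), "")
    }
  }
  fmt_tbl <- function(x) utils::capture.output(print(as.data.frame(x),
                                                     digits = 4))
  lines <- c(
    lines,
    section("Behavioural performance", res$performance, function(perf) {
      agg <- perf |>
        dplyr::group_by(.data$run, .data$class) |>
        dplyr::summarise(accuracy = mean(.data$accuracy),
                         mean_mt_s = mean(.data$mean_mt_s, na.rm = TRUE),
                         .groups = "drop")
      fmt_tbl(agg)
    }),
    section("ROI decoding", res$roi_results, fmt_tbl),
    section("Backward voxel elimination", res$rfe, function(tr) {
      sig <- tr$curve$m[tr$curve$fdr_significant]
      c(sprintf("voxels: %d; FDR-significant down to m = %s",
                nrow(tr$curve), if (length(sig)) min(sig) else "none"),
        fmt_tbl(utils::head(tr$curve[order(tr$curve$m), ], 12)))
    }),
    section("Searchlight territories", res$territory_table, fmt_tbl)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> mode %s, seed %d\n", x$config$mode,
              x$config$seed))
  for (nm in names(x$timing)) {
    cat(sprintf("  %-12s %6.1f s\n", nm, x$timing[[nm]]))
  }
  invisible(x)
}
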