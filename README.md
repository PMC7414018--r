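# striamvpa

Multivoxel pattern analysis of sequence-specific activity in the human
striatum.

## What this package is for

After people practise discrete five-press finger sequences, average
per-voxel activity in the striatum looks the same whichever sequence is
executed — yet the *distributed* activity pattern across striatal voxels
can still identify the sequence. `striamvpa` implements the complete
decoding pipeline for testing this on volumetric beta images (per
subject, run and sequence) and region-of-interest masks, plus a phantom
generator so the whole pipeline is testable without any imaging data.

The statistical core:

- **One-against-one linear SVM decoding.** For K sequence classes, one
  soft-margin linear classifier per unordered pair (K(K−1)/2 = 6 for
  K = 4), cost C = 1, trained on Gram matrices by an SMO solver (verified
  against libsvm). A sample is assigned the majority-vote class across
  pairwise decisions sign(wᵀx + b).
- **Leave-one-sample-out cross-validation.** Each of the n samples
  (192 = 16 subjects × 3 runs × 4 sequences) is held out once; pooled
  accuracy is the fraction predicted correctly. Before any training,
  every subject × run block is demeaned voxelwise across its classes.
- **Permutation inference.** The full LOSO procedure is re-run under
  permuted labels; p = (1 + #{null ≥ observed}) / (N + 1). ROI families
  are corrected with Benjamini–Hochberg FDR at q = 0.05.
- **Sensitivity and sparsity.** Voxel sensitivity = mean over pairs of
  the squared weight; cross-validated backward elimination removes the
  least sensitive voxel per fold down to one, mapping accuracy against
  the number of voxels kept.
- **Searchlight.** Local decoding in 5 mm spheres (81 voxels on a 2 mm
  grid) around every ROI voxel, a pooled permutation null (10 permuted
  runs per voxel), FDR across centres, and counts of significant voxels
  per atlas territory.

## Worked example

A complete phantom experiment on a coarse grid, small enough to run in
about a minute:

```r
library(striamvpa)

masks <- phantom_masks(grid_shape = c(20, 24, 20), voxel_size_mm = 4, seed = 1)
design <- synthetic_design(n_subjects = 8, seed = 1)
dataset <- simulate_betas(design, masks,
                          pattern_spec(n_informative_voxels = 10,
                                       pattern_sd = 1.5,
                                       smoothing_fwhm_mm = 0))

samples <- extract_roi_samples(dataset, masks, "left_putamen") |>
  demean_by_run()
samples
#> <sample_matrix> left_putamen: 96 samples x 86 voxels (8 subjects, runs 4,5,6, classes 1,2,3,4), demeaned

result <- loso_cross_validate(samples)
result
#> <decoding_result> left_putamen: accuracy 74.0% (chance 25.0%), 96 samples x 86 voxels

null <- permutation_test(samples,
                         decoder_config(n_permutations = 200, seed = 1),
                         observed = result)
null
#> <permutation_null> left_putamen: observed 74.0% vs null mean 23.9% (200 perms), p = 0.004975
```

The decoder recovers the planted 10-voxel pattern far above the 25% chance
level, and no permuted labelling comes close, so the permutation p-value
is at its floor of 1/201. Behavioural scoring works the same way:

```r
log <- simulate_press_log(design)
summarize_performance(log) |> head(3)
#> # A tibble: 3 x 6
#>   subject   run class n_trials accuracy mean_mt_s
#>     <int> <int> <int>    <int>    <dbl>     <dbl>
#> 1       1     1     1       12    0.75       1.29
#> 2       1     1     2       12    1          1.44
#> 3       1     1     3       12    0.667      1.43
```

`run_pipeline(pipeline_config(...))` chains every stage (simulation,
behaviour, ROI decoding with FDR across the six striatal ROIs, backward
elimination, searchlight with territory quantification) and
`write_report()` renders one plain-text summary.

A caution worth knowing before interpreting absolute accuracies: because
the voxelwise demeaning ties the samples of a block together, the LOSO
accuracy of *signal-free* data sits above 1/K when the voxel count is
comparable to the sample count, while the default global-permutation null
stays at chance. `decoder_config(permutation_scheme = "within_block")`
gives the exactly exchangeable null for this design; the vignette
explains the mechanism and when each scheme is appropriate.

## Package layout

- `R/synth-*.R` — phantom masks/atlas, beta generator, press logs
- `R/behavior.R` — trial scoring (strict 2.5 s movement-time cutoff)
- `R/assembly.R` — group masks, ROI sample matrices, run-wise demeaning
- `R/svm.R`, `R/decoder.R`, `src/svm.cpp` — pairwise SVMs, LOSO,
  permutation tests, FDR
- `R/sensitivity.R` — weight/sensitivity maps, backward elimination
- `R/searchlight.R` — spheres, pooled null, territory quantification
- `R/pipeline.R` — end-to-end orchestration and reporting
- `vignettes/striatal-sequence-decoding.Rmd` — the methods vignette
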