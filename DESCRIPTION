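Package: striamvpa
Title: Multivoxel Pattern Decoding of Finger Sequences from Striatal fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate pattern analysis of sequence-specific activity in
    the human striatum. Assembles per-subject, per-run beta images into
    region-of-interest sample matrices, removes run-wise voxel means, and
    decodes discrete finger sequences with one-against-one linear
    support-vector classifiers under leave-one-sample-out cross-validation.
    Inference uses label-permutation null distributions with
    Benjamini-Hochberg false-discovery-rate control across regions.
    Includes classifier weight and sensitivity maps, recursive
    backward voxel elimination to probe pattern sparsity, searchlight
    decoding with a pooled permutation null, territory-wise quantification
    against a striatal parcellation, and a synthetic phantom generator that
    produces beta datasets whose class information is carried by
    mean-balanced multivoxel patterns (decodable multivariately, invisible
    to per-voxel averages) together with button-press trial logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    dplyr,
    generics,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
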