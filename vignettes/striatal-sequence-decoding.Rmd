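---
title: "Decoding discrete finger sequences from striatal activity patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding discrete finger sequences from striatal activity patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the analysis

When people execute well-practised five-element finger sequences, does the
human striatum carry sequence-specific information? Average per-voxel
activity typically does not distinguish one learned sequence from another,
so the question is multivariate: can the *joint* pattern of activity across
striatal voxels identify which sequence was performed?

`striamvpa` implements the full decoding pipeline for this question over
volumetric beta images (per-subject, per-run, per-sequence GLM amplitude
estimates) and region-of-interest masks:

1. **Assembly.** Individual binary masks are combined into a group mask
   (a voxel is kept when at least 50% of subjects have it). For each ROI a
   sample matrix is extracted: one row per (subject, run, sequence), one
   column per in-ROI voxel in a fixed scan order (ascending linear grid
   index, x fastest). Within every subject x run block, each voxel's mean
   across the sequences of that run is subtracted once, before any
   training, removing scalar session offsets exactly.
2. **Decoding.** One soft-margin linear SVM (cost C = 1) per unordered
   pair of sequence classes; a test sample receives one vote per pairwise
   model and is assigned the majority class (vote ties go to the lowest
   class label by default; a decision-value rule is available). Accuracy
   is estimated by leave-one-sample-out cross-validation: 192 folds for
   16 subjects x 3 runs x 4 sequences.
3. **Inference.** The whole cross-validation is repeated with permuted
   labels; `p = (1 + #{null >= observed}) / (n_perm + 1)`. Across the six
   ROIs (left/right putamen, caudate, and the hemisphere-wise
   combinations) p-values are corrected by Benjamini-Hochberg FDR at
   q = 0.05, one correction per run-selection x class-selection family.
4. **Sensitivity and sparsity.** A voxel's sensitivity is the mean squared
   linear weight across the pairwise classifiers. Backward elimination
   removes, within each cross-validation fold, the least sensitive voxel
   (ties to the lowest index), one at a time down to a single voxel,
   recording pooled accuracy at every voxel count; per-count significance
   uses permuted-label elimination runs and BH-FDR across counts.
5. **Searchlight.** Every ROI voxel centres a sphere (default radius 5 mm,
   centre-to-centre distance, boundary included: 81 voxels on a 2 mm grid
   deep inside a mask; spheres are clipped to the ROI). Local LOSO accuracy
   is assigned to the centre. The null pools a small number of permuted
   runs per voxel (default 10) into one distribution; per-voxel p-values
   are BH-corrected over all centres, and significant voxels are counted
   per atlas territory (7 sectors per nucleus).

The re-analyses reachable by configuration mirror the study design:
`classes = 2:4` drops the simple ascending sequence (chance 1/3,
144 samples), `runs = 1:3` analyses the early learning phase.

## The phantom generator

The study's imaging data are not deposited, so the package ships a
synthetic mode that generates everything the pipeline consumes. The
phantom is explicit about what it does and does not emulate.

Masks are four disjoint ellipsoids (left/right putamen and caudate) on a
configurable grid (default 40 x 48 x 40 at 2 mm; roughly 690 and 280
voxels per nucleus), each partitioned geometrically into 7 territory
sectors (anterior slab plus three posterior slabs split dorsoventrally),
standing in for a connectivity-based parcellation. Any reproducible 7-way
partition serves the territory-quantification stage; no anatomical claim
is attached.

Beta values follow

    beta(s, r, c, v) = baseline(v) + a_s + b_sr + P(s, c, v) + eps

with scalar subject offsets `a_s`, scalar run offsets `b_sr`, i.i.d.
Gaussian noise `eps` (optionally smoothed, see below), and a class pattern
`P` confined to `n_informative_voxels` voxels. `P` blends a shared and a
subject-specific component (`subject_consistency` in [0, 1]) and is then
centred across classes per voxel and subject, so the class mean is
*exactly* zero at every voxel: decodable multivariately, invisible to
per-voxel class averages by construction rather than only in expectation.
Press logs emulate the behavioural task: 12 trials per sequence per run
(4 blocks x 3 executions), five presses each, movement time following a
saturating learning curve `MT_r = MT_inf + (MT_0 - MT_inf) exp(-r / tau)`,
with a speed advantage for the simple sequence and a configurable error
rate realised as permuted press orders.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `n_subjects`, `n_runs`, `n_classes` | 16, 6, 4 | the study design; analysis runs default to 4-6 |
| `noise_sd` | 1 | scale unit; all amplitudes are relative to it |
| `pattern_sd` (tau) | 0.3 | calibrated once so the default configuration's left-putamen accuracy lands in the 35-45% band reported for striatal ROIs; a phantom convention, not an effect-size claim |
| `subject_consistency` | 0.5 | between-subject decoding plausibly rides on a partly shared pattern |
| `subject_offset_sd`, `run_offset_sd` | 0.5, 0.25 | session effects larger than run effects; both removed exactly by demeaning |
| `smoothing_fwhm_mm` | 5 | the upstream preprocessing smooths with a 5 mm kernel, so phantom noise is spatially correlated at that scale; the kernel is energy-normalised to preserve the marginal SD and is applied to the noise only, keeping the class-mean balance of `P` exact |
| trials, presses | 12/run/sequence, 5 | the task structure |
| `mt` curve | 1.8 s to 1.15 s, tau 1.2 runs | saturates by run 4, matching a plateau over the late runs |

Scalar (not per-voxel) offsets are deliberate: they are removed exactly by
the demeaning stage, which makes that stage's correctness testable to
machine precision against an offset-free twin generated from the same
seed.

## Statistical behaviour of the published procedure

Two properties of the procedure deserve explicit documentation because
they shape what the package's tests can and cannot claim.

**Demeaning before cross-validation couples the folds.** After run-wise
demeaning, the four samples of a block sum to zero, so every held-out
sample equals the negative sum of three training samples. On signal-free
i.i.d.-noise phantoms this *raises* leave-one-sample-out accuracy above
1/K — substantially when the voxel count approaches the sample count
(e.g. ~48% at 200 voxels and 192 samples for unsmoothed noise; less with
smoothed, spatially correlated noise). We verified this elevation
independently with a reference SVM implementation; it is a property of the
procedure, not of the solver.

**The two permutation schemes answer different questions.** Globally
permuting the label vector (the default, and the literal reading of the
published procedure) destroys the one-label-per-block structure, so its
null centres at chance (25% / 33%) and does *not* absorb the elevation
above. Permuting labels within each subject x run block preserves the
structure and is exactly exchangeable for this design; its null tracks the
elevated baseline and yields calibrated p-values on signal-free data.
Consequently the package's type-I calibration and exchangeability tests
use `permutation_scheme = "within_block"`, while the global scheme remains
the default for procedural fidelity. Both are exposed in
`decoder_config()`.

Relatedly, a one-way ANOVA computed *on demeaned data* is anticonservative
(demeaning shrinks the residual variance without adjusting the error df),
so the package's univariate dissociation check uses a randomized-block
ANOVA (`value ~ block + class` on the undemeaned matrix), which is exact
under the null and equivalent to demeaning with correct df accounting.

## Numerical choices

- The pairwise SVMs are solved by sequential minimal optimisation with
  second-order working-set selection on a precomputed Gram matrix,
  stopping tolerance 1e-3 (the reference engine's default), cost C = 1
  fixed, no hyperparameter search. Tests verify weight vectors, biases and
  one-vs-one predictions against libsvm (via e1071) to that tolerance.
  Fold models are warm-started from the full-data pair solution; removing
  a non-support-vector leaves the model exactly unchanged, which the
  implementation exploits.
- Vote ties default to the lowest class label; `decision_sum` picks the
  tied class with the largest summed signed decision value. The
  lowest-label rule is reproducible but deliberately not equivariant under
  class relabelling on exact ties.
- Sensitivity ties during elimination go to the lowest voxel index; one
  voxel is removed per iteration, never batches.
- Sphere membership uses centre-to-centre distance `<= radius`; at 5 mm on
  a 2 mm grid this includes the boundary shell (81 voxels, verified by a
  brute-force offset oracle). Demeaning is voxelwise, so whole-ROI and
  per-sphere demeaning coincide (asserted by a test, not assumed).
- Every random draw derives from one global seed plus fixed per-stage
  offsets (masks 101, betas 202, press logs 303, ROI permutations 404,
  searchlight 505 plus the centre's voxel index, elimination 606), so each
  stage is reproducible in isolation and searchlight permutation draws are
  independent across centres.
- p-values use the add-one estimator `(1 + #{null >= obs}) / (N + 1)` and
  can never be zero.

## Problem sizes used by the test suite

The full-fidelity settings (10,000 permutations per ROI, whole-nucleus
elimination) are the package defaults for analyses, but the shipped tests
run at desk scale, chosen once for statistical meaning rather than
runtime drama: null-calibration checks use the full 192-sample design on
a 200-voxel ROI with 500 permutations; the type-I study uses 100
signal-free replicates of an 8-subject, 3-run design on 48 voxels with
200 within-block permutations; the elimination-recovery study plants 5
informative voxels among 16 in a 6-subject design with 60 permuted
elimination runs; searchlight checks run on a coarse 4 mm phantom. The
pipeline wrapper defaults to 500 permutations; raise
`decoder_config(n_permutations = 10000)` for full fidelity.

## Known limitations

The phantom's noise is Gaussian and (optionally) smoothed but otherwise
unstructured: no physiological confounds, no motion residuals, no
between-voxel covariance beyond the smoothing kernel, no anatomical
variability between subjects, and GLM-level betas are emitted directly
(no time series, HRF or design-matrix effects). Passing the shipped tests
therefore demonstrates that the machinery is correct and calibrated under
the stated assumptions — it does not validate effect sizes, spatial
claims or territory attributions on real data. The atlas stand-in is
geometric; territory labels carry no anatomical meaning. For the
three-class re-analysis, demeaning uses the included classes only (the
alternative — demeaning over all four before dropping one — is available
by extracting all classes, demeaning, then subsetting rows).
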