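---
title: "Methods: diagnostic pipelines for multi-site resting-state fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnostic pipelines for multi-site resting-state fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcdiag)
```

## The problem

Group-level brain differences between clinical populations do not
automatically translate into accurate diagnosis of individuals. With a large
multi-site pediatric cohort — healthy controls and two ADHD subtypes
(combined, ADHD-C; inattentive, ADHD-I), scanned at several institutions with
different scanners, durations and repetition times — a mean difference that
is overwhelmingly significant at the group level can still leave the two
groups' individual values almost completely overlapping. `fcdiag` implements
the full comparison machinery for this question: personal-characteristic
classification pipelines, seven resting-state fMRI feature-extraction stacks,
group spatial ICA with per-participant back-reconstruction, group-difference
cluster feature selection, and a counterbalanced cross-validation harness —
together with a synthetic-data module so every stage is testable end to end
without access to restricted imaging data.

The package's simplest illustration of the group-versus-individual gap is
`simulate_two_gaussian_groups()`: two unit-variance Gaussians separated so
that a two-sample t test on 1000 + 1000 samples yields t near 7.1
(p around 1e-12) are classified by their nearest group mean at only about
56 % accuracy — the closed-form ceiling is `pnorm(delta / 2)`.

## Diagnostic tasks and evaluation

Two tasks are supported: binary (control vs ADHD, collapsing subtype) and
three-way (control / ADHD-C / ADHD-I). Evaluation uses 10-fold
cross-validation over fold assignments that are *approximately
counterbalanced* for diagnosis, gender, age, handedness, IQ, medication and
site (`make_counterbalanced_folds()`). The assignment is greedy: participants
are visited in a seeded random order and placed in the eligible fold (sizes
constrained to differ by at most one; 66 or 67 for n = 668) minimizing the
sum over strata and categories of the absolute deviation from proportional
allocation. Continuous strata are tercile-binned for costing; quantile ties
collapse bins. The greedy cost is checked in the tests against the best of
1000 random assignments.

Accuracy is reported in percent as mean ± sd over the 10 test folds, with
training-fold accuracy alongside (a pipeline that cannot even fit its
training data carries no signal; one that fits it perfectly and still tests
at chance is overfitting). Pipelines are compared by one-tailed paired t
tests on the 10 paired fold accuracies (df = 9). The chance baseline is the
majority-class share — 64.2 % for the 429/141/98 training composition and
55.0 % for the 94/51/26 holdout composition; ties resolve control < ADHD-C <
ADHD-I. The competition rule scores 1 point per exact diagnosis and 0.5 for
ADHD with the wrong subtype.

Classifier families are the standard five — logistic (multinomial, small
ridge `decay = 1e-4`), and linear / quadratic / cubic / RBF-kernel SVMs with
complexity constant 1 (`coef0 = 1` for the polynomial kernels, gamma
`1/n_features` for RBF). These are deliberately thin wrappers over
`nnet::multinom` and `e1071::svm` with internal rescaling disabled: the
pipeline's own 0–1 scaling is authoritative, and every hyperparameter is
exposed.

## Personal-characteristic features

Two fixed selections are provided. `PCs1` (7 features): site, gender, age,
handedness, Verbal IQ, Performance IQ, Full-4 IQ, with handedness passed
through as a continuous value. `PCs2` (9 features) adds the IQ-instrument
indicator and Full-2 IQ, and recodes the one site's continuous Edinburgh
handedness scores (range −100 to 100) into the categorical scheme: positive
to 1 (right), negative to 0 (left). A score of exactly 0 is not covered by
that rule; it maps to 1 with a warning. Missing values are filled by mean
(continuous) or mode (categorical, alphabetical tie-break) imputation;
categorical fields are one-hot encoded over the levels observed in the
fitting rows; every column is then min–max scaled to [0, 1]. Constant
columns map to 0 (a deterministic stand-in for the undefined 0/0), and
held-out values outside the fitted range are clipped into [0, 1].

By default all fitted statistics — imputation values, one-hot level sets,
scaling bounds — are computed on the training folds only, and the
test-acceptance suite audits that these are bit-identical to statistics
recomputed on tables from which the held-out rows were physically removed.
`global_stats = TRUE` reproduces whole-dataset fitting for comparison with
toolkits that standardize at import time.

## fMRI preprocessing

Scans arrive as 4D arrays on a common 3 mm isotropic grid (the reference
full-resolution grid is 57 × 67 × 50). Motion correction, co-registration,
warping and spatial smoothing are assumed done upstream and are out of
scope. The package implements:

* **Temporal standardization** (`standardize_time()`): truncate to the
  *first* 185 s and linearly interpolate to 2 Hz, anchored at the first
  volume taken as time 0, giving exactly 370 volumes at 0.5 s. A
  full-resolution standardized scan holds 57 × 67 × 50 × 370 = 70,651,500
  values. Scans shorter than the target are refused — extrapolation would
  fabricate data.
* **Spatial window averaging** (`swa()`): block means with an integer factor
  r; output dims are floor(dim/r) with the remainder voxels absorbed into
  the final window, so no data are dropped while reproducing the printed
  grids (r = 3: 19 × 22 × 16 = 6,688 voxels; r = 8: 7 × 8 × 6 = 336).
  Nominal voxel size scales by r.
* **Masking** (`build_mask()`): a voxel is in-brain iff its across-scan mean
  intensity reaches `threshold_frac` (default 0.5) of the global mean of
  nonzero voxels; reduced-grid masks are derived by per-window majority vote
  (`swa(mask, r)`), and the rule is recorded in the mask's provenance. The
  reference masks have 97,216 / 3,558 / 186 voxels at r = 1 / 3 / 8.
* **Flattening** (`mask_and_flatten()`): one declared order everywhere —
  x fastest, then y, then z (R's native array order); the inverse zero-fills
  excluded voxels.
* **Intensity normalization**: per-voxel percent signal change
  (`pscs_tc()`, making every timecourse mean-zero — hence never combined
  with the temporal-average feature) and per-scan percent signal change
  (`pscs_s()`, dividing by the in-mask scan-wide mean so that a
  site-specific global gain cancels exactly).

## Feature extraction

Per voxel, the extractors produce η feature values: temporal average
(η = 1), projections onto a pooled timecourse PCA basis (η = 1 or 5),
modulus and phase of the DFT harmonics in the 0.001–0.1 Hz band (η = 36),
ALFF — the mean band modulus (η = 1) — and, from the connectivity analysis
below, component weighting maps (η = 1 for the default-mode map, 20 for all
components). On the standardized grid the band holds exactly harmonics
k = 1..18 (frequencies k/185 Hz); the DFT is the unnormalized forward
transform (moduli not divided by N), validated in the tests by Parseval's
identity. The timecourse PCA treats every in-mask voxel timecourse of every
training participant as an observation, centres columns, and uses the
eigendecomposition of the 370 × 370 covariance; component signs are fixed by
making the largest-magnitude loading positive, and the basis is fitted
inside each training split when its projections feed a classifier.
Masking + flattening + concatenation in k order reproduce the reference
feature lengths: 3,558 and 186 (T Avg / ALFF / FC_DMN at r = 3 / 8), 930
(five PCA components at r = 8), 6,696 (FFT at r = 8), 3,720 (20 component
maps at r = 8).

## Group spatial ICA and back-reconstruction

The functional-connectivity analysis follows the standard two-stage group
spatial ICA. Each participant's masked, timecourse-normalized data (time ×
voxels) is reduced to 25 components by a temporal PCA; scan-level scaling is
unsuitable here because it does not remove between-voxel mean differences.
The reductions are concatenated, a second PCA retains 20 components, and
symmetric FastICA (tanh nonlinearity, tolerance 1e-6, at most 1000
iterations, seeded random start) unmixes them into independent spatial
maps. Whitening centres the component-by-voxel signals across voxels, and
the resulting affine unmixing (matrix plus offset) is retained. Component
sign is fixed so each group map's largest-magnitude voxel is positive.

Per-participant maps use the GICA3 back-reconstruction: with M subjects,
subject i's maps are `M * unmix %*% (G_i' Y_i) + offset`, where `G_i` is
subject i's block of the group PCA basis and `Y_i` its reduction. Because
the blocks sum to the full group projection, the across-subject mean of the
subject maps equals the group map *exactly* — the scheme's defining
property, asserted to 1e-6 relative error in the acceptance suite (it holds
to machine precision). A single-subject "group" degenerates to its own
decomposition. Masked-out voxels are zero-filled when maps are expanded to
volumes.

Two policies deserve explanation:

* **Non-convergence.** When the model order exceeds the number of
  non-Gaussian signals — routine when 20 components are extracted from data
  containing a handful of true networks — the Gaussian residual components
  have no FastICA fixed point, and the symmetric iteration cannot meet the
  tolerance even though the structured components lock in within tens of
  iterations. The decomposition therefore warns and returns the final
  iterate (with `converged = FALSE` and the iteration count) by default;
  `ica_config(on_nonconvergence = "error")` makes it abort instead.
* **Model order vs effect recovery.** The group-difference recovery test
  matches the model order to the generator's source count. With a spare
  component, the kurtosis-seeking ICA isolates the small injected effect
  block as its own highly sparse component; the patients' default-mode
  loading then splits degenerately across two spatially overlapping,
  temporally identical directions and per-subject back-reconstruction of
  the default-mode map becomes unstable. This is a genuine property of ICA
  on such data, not an implementation artifact; matching the model order is
  the standard remedy and is what the test encodes.

The default-mode component is identified by maximal absolute spatial
correlation with a template over in-mask voxels (an automated, reproducible
surrogate for visual inspection; in tests the template is the generator's
ground-truth map). Correlations below a floor (default 0.2) raise a "no DMN
found" error rather than silently returning noise.

## Group statistics and cluster feature selection

Massively univariate statistics are pooled-variance two-sample t maps
(patients vs controls, df = n_A + n_B − 2; 666 for 239 vs 429) and
one-sample localizer maps against zero (df = n − 1); zero-variance voxels
yield t = 0 with a warning. Maps are thresholded voxelwise (|t| > θ_t,
strictly), then cluster-size thresholded: connected components
(26-neighbour default, 6/18 available) smaller than θ_cs mm³ are zeroed.
Positive and negative suprathreshold voxels form separate components —
contrasts are two-tailed and mixing signs within a cluster would corrupt
cluster means. The reference operating point |t| ≥ 2.582 (p < 0.01
two-tailed at df = 666) with a 63-voxel (1,701 mm³ at 3 mm) minimum
corresponds to a family-wise α of 0.05; the package recomputes such
minima by Monte-Carlo simulation (`monte_carlo_cluster_threshold()`):
Gaussian white-noise group draws are smoothed to a stated FWHM (separable
truncated kernel, edge-renormalized), variance-normalized, turned into null
t-fields, and the smallest cluster size whose exceedance probability is at
most α is returned. The acceptance suite verifies that the calibrated
threshold keeps the empirical family-wise false-positive rate within
binomial error of α over 200 null cohorts, and that doubling smoothness
never lowers the threshold.

Cluster extraction is peak-based: local |t| maxima among suprathreshold
voxels (no strictly larger neighbour), merging of peaks closer than d_min mm
(keeping the higher |t|; ties to the lower linear index), nearest-peak
assignment of all suprathreshold voxels (Euclidean mm; distance ties to the
lower-index peak), discarding of clusters below v_min mm³, ordering by
statistical mass (the sum of |t| over member voxels), and retention of the
n_clusters most massive (∞ keeps all). The five-number parameter vector is
accepted in bracket syntax, e.g. `"[2.582, 1701, inf, 30, 540]"`. Cluster
features are the per-cluster means of the participant's corresponding
feature volume, concatenated in (map, cluster) order — 20 maps × 10
clusters gives the reference 200 features.

The *robust* variant recomputes, for cross-validation iteration i, nine
sub-iteration map sets leaving out fold i and one additional fold j; after
thresholding, only voxels surviving in the main set *and all nine*
sub-iteration sets are retained — implemented, and tested against, a
voxelwise logical AND across the ten sets applied to the main set's values.
All statistical selection happens on training folds only.

## The synthetic-data module

The generator is first-class, tested code, and defines the study conditions
for every downstream check.

**Participant tables.** `training_cohort_spec()` encodes the 668-participant
composition (429 controls, 141 ADHD-C, 98 ADHD-I) with the published
marginals: per-group site mixes over seven active sites, ages (12.4 ± 3.3 /
11.4 ± 3.1 / 12.1 ± 2.5 years), female fractions (47.6 / 17.0 / 26.5 %),
handedness and medication proportions, per-group IQ distributions, and
per-site IQ-battery availability (one site provides no IQ and reports
continuous Edinburgh handedness, simulated uniform on [−100, 100] since only
the score's range convention is published; one site additionally provides
the two-subtest full-scale score). `holdout_cohort_spec()` does the same for
the 94/51/26 holdout composition. Printed percentages are renormalized to
sum to one. Fields are drawn independently given group and site — the
published tables are marginal summaries, so joint structure such as
age-by-IQ correlation is deliberately not modelled. Missing values are
`NA` in memory and empty fields in CSV, so imputation is observable in
tests; additional per-site per-field missingness is configurable.

**Scans.** 4D scans are linear mixtures: smooth random multi-blob source
maps (one designated default-mode-like), per-subject source weights around
1 (sd 0.15), smooth band-limited timecourses, Gaussian noise, a per-site
multiplicative gain, and a constant baseline intensity (default 100) inside
the gain. The baseline is a deliberate addition to the bare mixing model:
percent-signal-change scaling divides by temporal means, which are near
zero for a pure zero-mean mixture, and real fMRI has a large baseline;
fixtures that need the literal pure mixture set `baseline = 0`. Per-subject
timecourses are QR-orthogonalized across sources because distinct
resting-state networks have approximately uncorrelated dynamics — without
this, a single subject's data cannot separate the sources and per-subject
back-reconstruction is meaningless. The group difference is injected
additively on the default-mode source map inside a stated voxel block for
patients only, giving the statistics modules a clean recovery target
recorded in the `ground_truth` object. Scan generation is seed-deterministic
(bit-identical under a repeated seed) and does not model scanner physics,
motion, or physiological noise — so passing tests demonstrate correctness
of the machinery under the stated statistical model, not robustness to real
acquisition artifacts.

## Problem sizes and numerical choices

The test and acceptance suites run at desk scale, chosen as the smallest
sizes at which each property is sharply testable: grids of 10 × 10 × 8 to
15 × 15 × 12 voxels, cohorts of 12 subjects, 185 s scans at TR 2 s, 200
Monte-Carlo null simulations and 200 null cohorts for the false-positive
audit, and 150–200 replicates of the two-Gaussian simulation. Eigen-based
PCA, seeded FastICA and explicit tie-break rules (documented above) make
every pipeline deterministic given its seed; generators save and restore the
global RNG state so library calls do not perturb user code.

## Limitations

Real-data headline accuracies are not reproducible from this package alone:
they require the original restricted multi-site dataset and its exact
curation. What the package reproduces are the structural constants of the
pipelines, the published baselines, the group-vs-individual simulation, and
the behavioural properties (GICA3 identity, source and effect recovery,
false-positive calibration, leakage discipline) on synthetic cohorts whose
generator encodes the published marginal structure. The cluster extractor
and mask construction follow declared, configurable conventions where the
original appendix-level details are not public.
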