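---
title: "Voxel-wise network centrality in a masked fMRI network: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise network centrality: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

voxcent implements voxel-wise functional-network centrality analysis of
resting-state fMRI within a binary network mask, together with the group
inference and clinical-regression machinery that such analyses are embedded
in, and a fully seeded synthetic-data generator that gives every stage a
ground truth. This vignette is the package's account of the underlying
science: the models, the tunable parameters and their defaults, the
numerical choices, and what the validation experiments do and do not show.

## The centrality model

Each subject contributes a 4D acquisition restricted to an `N`-voxel mask.
After preprocessing, the `N x T` voxel-by-time matrix is row-standardized so
that the Pearson correlation between voxels `i` and `j` is the dot product
of their rows divided by `T - 1`.

**Degree centrality (DC).** For voxel `i`,

    DC(i) = sum_{j != i} r_ij * [r_ij > r0]

the weighted sum of supra-threshold positive correlations (a binary variant
counts rather than sums). The threshold `r0` removes weak, noise-dominated
correlations; the conventional primary value is 0.25 inside an exploration
set 0.10-0.40 in steps of 0.05. Two choices deserve comment:

* *Self-correlation is excluded.* Including `j = i` adds the constant 1 to
  every voxel; excluding it makes uncorrelated data score near zero, which
  is the behavior a "connection strength" reading requires.
* *Blockwise evaluation.* The `N x N` correlation matrix is never formed;
  row blocks of the correlation matrix are produced by one matrix product
  each and reduced immediately. Results are bit-stable across block sizes,
  which the tests check, because each voxel's sum is always accumulated in
  the same (column) order.

**Eigenvector centrality (EC).** EC weights each voxel's connections by the
centrality of its neighbors: it is the principal eigenvector of a
connectivity matrix. The raw correlation matrix `C` may be indefinite with
mixed-sign entries, under which the Perron-Frobenius guarantee of a unique
nonnegative principal eigenvector fails. Following the fast-ECM
construction, voxcent therefore uses

    A = (C + 1) / 2

whose entries lie in [0, 1]. The eigenvector is computed matrix-free by
power iteration:

    A v = ( Z (Z' v) / (T - 1) + 1 * sum(v) ) / 2

where `Z` is the standardized data matrix, so memory stays `O(N T)`.
Iteration starts from the uniform vector `1/sqrt(N)` (deterministic — no
seed enters the computation), and stops when successive unit-norm iterates
differ by less than `tol = 1e-12` in Euclidean norm, or at `max_iter = 1000`
with a warning and a flagged partial result. The returned vector is
nonnegative with unit Euclidean norm; the Rayleigh quotient provides the
principal-eigenvalue estimate.

**Normalization for group analysis.** Individual maps are made comparable
across subjects before entering group models:

* DC: divide by the subject's in-mask mean (`k/k0`), then z-standardize
  over the mask. Literal Fisher `atanh` conversion is also implemented, but
  mean-normalized DC values routinely exceed 1, where `atanh` is undefined;
  `convert_for_group()` therefore refuses out-of-range input with a pointer
  to z-standardization, which is the default conversion.
* EC: rank-Gaussian normalization (midranks, Blom positions
  `(rank - 3/8)/(N + 1/4)`, then the normal quantile), followed by
  z-standardization. A global-mean (`u/u0`) path is retained as an
  alternative; each map records its normalization provenance as an ordered
  list.

## Preprocessing

The pipeline assumes realignment, slice-timing correction and spatial
normalization were done upstream, and applies, in order: discard the first
10 volumes (scanner stabilization); Gaussian smoothing (FWHM 6 mm);
band-pass 0.01-0.08 Hz; nuisance regression on white-matter and CSF signals
plus six motion parameters. Smoothing before filtering is a documented
package decision — the two operations commute only approximately, and the
REST-family tools this order mirrors list them in the same breath.

* *Smoothing* is separable convolution with a Gaussian of
  `sigma = FWHM / (2 sqrt(2 ln 2))` per axis in mm, renormalized by the
  smoothed support. With a mask, support renormalization prevents both
  intensity dilution at the mask edge and bleeding across the boundary.
  The discrete kernel samples the exact Gaussian, so the value one 3-mm
  voxel from an interior impulse is `exp(-9 / (2 sigma^2)) = 0.500` of the
  peak at FWHM 6 mm — a closed-form oracle the tests assert.
* *Band-pass* is an ideal (rectangular) frequency-domain filter after
  linear detrending, the dialect of the REST family: spectrum bins with
  folded frequency inside [0.01, 0.08] Hz are kept, all others (including
  DC) zeroed. Detrending and filtering together are not a projection, so
  the matrix records that detrending happened; a second call skips it and
  reduces to the ideal filter, which is a projection — making the operation
  idempotent exactly rather than approximately.
* *Motion QC* follows the translation-based convention: mean head motion is
  the average Euclidean norm of volume-to-volume translation differences;
  rotations are summarized separately; scans reaching 2 mm translation or
  2 degrees rotation are flagged for exclusion. "Mean head motion" admits
  several formulas in the literature; the translation reading is our
  documented interpretation, not an assertion about any particular study.

## Group inference and cluster correction

Converted maps enter ordinary voxel-wise GLMs with a common design:
two-sample contrasts with age (centered) and 0/1 gender as covariates,
paired t tests on within-pair differences, and a partial-F ANCOVA for
three-group comparisons. All of these reduce to textbook closed forms that
the tests verify against base R (`t.test`, `aov`, `anova`, `lm`).

Cluster-level correction is Monte-Carlo, in the AlphaSim style. Voxel
adjacency comes from a millimetre radius `rmm`: all offsets with
center-to-center distance at most `rmm`. For 3-mm voxels, `rmm = 5` gives
18-connectivity. Each null iteration fills the mask bounding box with white
Gaussian noise, smooths it to the nominal applied FWHM, restricts to the
mask, re-standardizes the in-mask values (so kernel-edge variance loss
cannot deflate the threshold — AlphaSim implementations differ here, and
this is our documented resolution), thresholds at the one-tailed normal
quantile for the voxel-wise `p`, and records the largest cluster. The
critical size `k` at corrected level `alpha` is the smallest size whose
family-wise occurrence frequency is at most `alpha`. Increases and
decreases are analyzed as separate one-tailed families at the same
voxel-wise `p`, each corrected at `alpha` — so a study-wise false-positive
rate near `2 * alpha` (less integer discreteness of `k`) is the expected
behavior when both tails are searched.

Two caveats are inherent to the nominal-FWHM convention. First, the null
model is only calibrated when the simulated smoothness matches the actual
map smoothness; residual-based smoothness estimation is deliberately out of
scope. The calibration experiment therefore runs on spatially independent
null maps against an FWHM-0 null, where the match is exact. Second, maps
with long-range structure (e.g. community-correlated noise) violate the
stationary-smoothness assumption and can produce supra-nominal rates — a
known property of cluster-extent correction, not of this implementation.

## Clinical measures and regression

Brain parenchymal fraction is `(GM + WM) / (GM + WM + CSF)` volume;
probability volumes are integrated as probability mass times voxel volume
rather than thresholded, with the hard-mask path retained and tested as
equivalent on binary input. Lesion load is voxel count times voxel volume
in ml.

Cluster-level regression models the cluster-mean centrality as response and
the clinical metric as predictor, adjusting for age and gender; the metric
coefficient is reported with its t, partial correlation
(`r^2 = t^2/(t^2 + dof)`, sign from the slope) and a Bonferroni-corrected p
over a declared family. The family defaults to (clusters) x (metrics) and
is written into the output so users can re-scope it; regression runs on
cluster means, not voxel-wise, to keep that family interpretable.

## The synthetic-data generator

Voxel time courses are weighted sums of unit-variance community latent
signals plus AR(1) noise with stationary initialization (variance
`sd^2/(1 - phi^2)`, so early volumes are typical). This latent-factor
construction generates data in `O(N T)` and has closed-form population
correlations: voxels sharing one community with weight `w` correlate at
`w^2/(w^2 + sd^2)`, so tests have analytic targets. Hub voxels load on
every community latent; group or phase effects are planted as additive
loading shifts at designated voxels, which raises those voxels'
correlations with their community and hence their true centrality.
Defaults (three contiguous communities, weight 1, noise SD 1 — hence
within-community `r = 0.5` — AR(1) 0.3, TR 2 s) are chosen once as a
plausible resting-state regime.

Study-level simulation reproduces a two-phase patient cohort: single-session
controls and remitting patients plus paired subjects scanned in both the
relapsing and the remitting phase. Paired sessions share the subject's
latent connectivity scale (SD 0.1 around 1), so within-pair differences
cancel subject-level variance the way a paired design should. Clinical
covariates follow the ranges typical of a relapsing-remitting MS cohort —
EDSS around 2-3.5 in 0.5 steps clipped to [0, 10], BPF near 0.83 in
patients versus 0.86 in controls, lesion loads near 19 ml — and can be
linearly coupled to the subject connectivity scale. Because the regression
operation models centrality as response, the slope-recovery experiment
generates truth in exactly that direction (centrality linear in the metric
plus noise); the cohort simulator's covariates are drawn in the opposite
direction and serve realism, not slope identification.

What the generator does *not* emulate: hemodynamic response shapes,
physiological (cardiac/respiratory) noise, scanner drift beyond a linear
trend, registration error, or lesion-shape realism. Passing tests on this
generator therefore validate the *computational* chain — that the
implementation measures what the formulas define, with calibrated error
rates under the stated model — not that any particular biological claim
holds in real patients.

## Validation experiments and problem sizes

The package ships its calibration evidence as seeded experiments
(`fwe_calibration()`, `power_recovery()`, `slope_recovery()`), run by the
test suite and the acceptance script at these sizes, chosen to complete in
minutes on a single CPU while keeping Monte-Carlo error useful:

* **Oracle equivalence.** Blockwise DC matches dense-matrix brute force to
  1e-10 per voxel, and matrix-free EC matches a dense eigen-solver of
  `(C + 1)/2` to cosine similarity above `1 - 1e-8`, on 20 random fixtures
  of up to 100 voxels, plus a hand-solved 3-voxel case with eigenvector
  `(1, 1, 0)/sqrt(2)` and eigenvalue 2.
* **Threshold robustness.** On community-structured data (1,000-voxel mask,
  T = 120), DC maps at `r0 = 0.2` and `0.3` have Spearman correlation above
  0.9 — the centrality pattern is not an artifact of the threshold choice.
* **Family-wise calibration.** 200 null studies (8 + 8 subjects, T = 60,
  global-null data) yield a study-wise rate of any surviving cluster within
  [0.01, 0.12], the binomial band around the expected two-tailed rate, with
  the Monte-Carlo null at 200 iterations.
* **Power.** A planted 30-voxel loading shift of 0.8 (realized within-pair
  standardized effect d well above 1.5) in an 11-pair two-phase design is
  recovered — a surviving cluster overlapping the planted voxels — in at
  least 90% of 100 seeds.
* **Regression recovery.** The cluster-level regression recovers a known
  slope at n = 34 with under 5% bias over 200 replicates, and its null
  false-positive rate at nominal 0.05 falls in [0.02, 0.09] over 500
  replicates.
* **End-to-end determinism.** The demo configuration (1,000-voxel mask,
  T = 120, 8 + 8 single-session subjects plus 6 pairs) runs in well under
  15 minutes on one CPU, and re-running from its manifest reproduces every
  output file bit-identically.

## Degenerate inputs and numerical edges

Zero-variance voxel rows are flagged, excluded from centrality with value 0
and reported in a QC attribute. Rank-deficient nuisance or group designs
drop collinear columns with a warning, never silently. Fisher conversion of
out-of-range values, zero-mean maps under global-mean normalization,
all-zero difference voxels in paired tests, and empty clusters all raise
explicit, message-bearing conditions. Cluster labels are ordered
deterministically (descending size, ties by smallest member voxel linear
index), voxel ordering is everywhere the ascending column-major linear
index (1-based, first axis fastest), and every stochastic function takes a
seed and restores the caller's RNG state.

## Known limitations

Registration, slice timing and segmentation are out of scope — inputs are
assumed aligned on a common grid. The AlphaSim-style null uses the nominal
applied FWHM rather than estimated smoothness. Permutation-based voxel
inference, FDR correction and random-field closed forms are not provided.
The EC normalization order (rank-Gaussian before z-standardization, with
global-mean as an alternative) and the smooth-then-filter order are
package decisions where the field's conventions genuinely vary; both are
recorded in map provenance and here.
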