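# voxcent

Voxel-wise degree and eigenvector centrality analysis of masked resting-state
fMRI networks, with group inference, Monte-Carlo cluster-size correction, and
clinical regression — plus a seeded synthetic-data generator so that every
stage of the pipeline can be validated against known ground truth.

## Who this is for

Researchers analyzing resting-state fMRI at the connectome level within a
network mask (for example a sensorimotor-network template): the package
measures, for every voxel, how strongly and how centrally it is embedded in
the masked functional network, compares those maps between groups or disease
phases, and relates the resulting clusters to clinical variables such as
disability scores, brain atrophy and lesion load.

## The model

After preprocessing (volume discarding, FWHM-6 mm Gaussian smoothing, ideal
0.01–0.08 Hz band-pass, nuisance regression), each subject's masked data form
an N × T matrix whose row correlations define a weighted voxel graph.

**Degree centrality** — direct connection strength:

    DC(i) = Σ_{j≠i} r_ij · [r_ij > r0],      r0 = 0.25 (set 0.10 … 0.40)

computed blockwise so the N × N correlation matrix is never stored.

**Eigenvector centrality** — connections weighted by neighbor centrality:
the principal eigenvector of the shifted correlation matrix A = (C + 1)/2
(nonnegative, hence a unique Perron eigenvector), obtained matrix-free by
power iteration with A·v = (Z(Zᵀv)/(T−1) + 1·Σv)/2.

Maps are normalized per subject (DC: global-mean division then
z-standardization; EC: rank-Gaussian then z-standardization), compared with
voxel-wise GLMs (two-sample with age/gender covariates, paired t, ANCOVA),
and corrected by AlphaSim-style Monte-Carlo simulation (voxel p = 0.01,
rmm = 5 mm adjacency, 1,000 iterations, corrected α = 0.05). Surviving
clusters feed a Bonferroni-corrected regression of cluster-mean centrality
on clinical metrics (EDSS, BPF, TWMLL), controlling for age and gender.

## Worked example

A complete desk-scale study — synthetic two-phase cohort, preprocessing,
centrality, corrected group statistics, clinical regression — from one seed:

```r
library(voxcent)
res <- run_study(default_config(), "demo_run")
subset(res$cluster_table, surviving)
```

```
            metric contrast label tail size peak_stat peak_index ... surviving
dc_paired.1     dc   paired     1  pos   12  6.986962         84      TRUE
```

The paired relapsing-vs-remitting contrast recovers the planted 30-voxel
connectivity effect as a surviving cluster (12 voxels at the Monte-Carlo
critical size k = 10, peak t = 6.99 at 10 degrees of freedom): during the
simulated relapsing phase those voxels' community coupling was shifted, and
the paired analysis finds exactly that region. The clinical regression on
the surviving cluster then reports, per metric:

```r
res$clinical
```

```
  family_size   cluster   metric n        slope           t   partial_r p_uncorrected p_bonferroni
1           3 cluster_1     edss 6 -0.005535664 -0.05467865 -0.03863478     0.9613652    1.0000000
2           3 cluster_1      bpf 6 20.377133636  1.77395430  0.78193198     0.2180680    0.6542041
3           3 cluster_1 twmll_ml 6 -0.018953326 -0.94283414 -0.55471042     0.4452896    1.0000000
```

slope and partial correlation of cluster-mean centrality on each clinical
metric (age- and gender-adjusted), with the Bonferroni family (3 tests)
declared in the output. With the default generator the covariates are only
weakly coupled to centrality, so none of the six-subject regressions reaches
significance — as they should not.

Every run writes NIfTI maps, TSV tables and a `manifest.json` (config, seed,
per-file checksums); `run_from_manifest()` re-executes the manifest and
verifies bit-identical outputs.

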