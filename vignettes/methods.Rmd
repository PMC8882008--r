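---
title: "Methods: brain-behaviour PLS correlation for amyloid PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-behaviour PLS correlation for amyloid PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petpls)
```

## The problem

Global ("mean cortical") measures of beta-amyloid burden correlate only
weakly with cognitive performance, both in established Alzheimer's disease
and in mild cognitive impairment. The question this package addresses is
the *regional* one: which spatial patterns of amyloid deposition (or of
grey-matter loss) covary with which cognitive deficits across a cohort
spanning healthy ageing and multi-domain amnestic MCI? Voxel-wise
univariate testing answers this poorly — tens of thousands of correlated
comparisons — so the core method here is partial least squares correlation
(PLS-C), a multivariate decomposition that treats the whole image and the
whole behavioural battery as two blocks and finds their dominant modes of
covariation in a single step.

`petpls` implements the complete chain: DVR parametric imaging from
dynamic PET, volume IO/smoothing/masking, PLS-C, permutation and bootstrap
inference, cluster-level reporting with stereotaxic coordinates, the
accompanying univariate group statistics, and a synthetic-data generator
that makes every stage testable without access to subject data.

## Kinetic modelling: from dynamic PET to DVR

Dynamic scans are re-binned into 30 frames over 90 minutes (four 15 s,
four 30 s, three 1 min, two 2 min, five 4 min, twelve 5 min;
`default_frame_schedule()`). The regional outcome is the distribution
volume ratio, DVR = 1 + binding potential, estimated without arterial
sampling by multilinear reference tissue modelling against cerebellar
grey matter:

* **MRTM** (three parameters) regresses
  $C_T(T) = b_1\int_0^T C_R + b_2\int_0^T C_T + b_3 C_R(T)$ over frames at
  or after $t^*$; it supplies the reference clearance
  $k_2' = b_1/b_3$ and $\mathrm{DVR} = -b_1/b_2$.
* **MRTM2** (two parameters) fixes $k_2'$ — estimated once from a
  high-binding region — and fits
  $C_T(T) = b_1[\int_0^T C_R + C_R(T)/k_2'] + b_2\int_0^T C_T$ per voxel,
  again with $\mathrm{DVR} = -b_1/b_2$. This is the voxel-wise model
  behind `dvr_map_from_dynamic()`, solved in closed form (2×2 normal
  equations) across all voxels at once.

Because no operational equations are printed in typical study reports,
correctness is *defined* here by recovery on the simplified reference
tissue model (SRTM): `generate_target_tac()` produces curves
$C_T = R_1 C_R + (k_2 - R_1 k_{2a})\,[C_R \otimes e^{-k_{2a}t}]$ with
known DVR, and the test suite demands that the fits invert this forward
model (noiseless grid DVR 1.0–2.4 within 2%; in practice the error is
below 0.2%).

Numerical choices, and why:

* Integrals are cumulative trapezoids over frame mid-times anchored at
  $(0, 0)$ — standard for frame-binned data. At the earliest 15 s frames
  the *relative* error of any such scheme is curvature-limited (the
  integral itself is tiny); this is irrelevant to the fits, which use
  frames at or after $t^*$.
* $t^*$ defaults to 20 min — the usual choice for this tracer class —
  and is configurable.
* The SRTM convolution runs on a 0.05 min grid (so every frame boundary
  of the standard schedule is a grid point) with an exact
  trapezoid-exponential recursion; the delivery term reuses the reference
  frame means directly so that $R_1 = 1,\ \mathrm{DVR} = 1$ collapses to
  the reference curve exactly.
* Degenerate voxel fits (design condition number > 1e10, or a singular
  2×2 system) are flagged NaN and counted, never clamped; summaries
  exclude and report them.
* Mean cortical DVR is classified against the validated cut-offs
  DVR ≤ 1.08 (low accumulator) and DVR ≥ 1.20 (high accumulator), both
  boundaries inclusive; cohort percentages are reported to one decimal.

## The imaging block

`build_datamat()` flattens each subject's 3D map over an analysis mask
into one row of the $n \times v$ imaging block, in fixed raster order
(x fastest). The analysis mask is the intersection of the supplied mask
and per-subject finite-value masks, so NaN voxels from degenerate kinetic
fits cannot silently enter the statistics. The inverse operation
(`datamat_to_map()`) is exact on the mask, which the tests assert for
arbitrary vectors. Grey-matter masks use an absolute probability
threshold of 0.2. Smoothing (`smooth_gaussian()`) is separable Gaussian
convolution with $\sigma_{axis} = \mathrm{FWHM} /
(\mathrm{voxel}_{axis}\sqrt{8\ln 2})$ and zero padding — the convention of
SPM-style pipelines; 10 mm FWHM is the study default, matching PET
resolution.

## PLS-C

Both blocks are column-wise z-scored ($n-1$ denominator), giving the
cross-block matrix $R = Z_Y^\top Z_X/(n-1)$ whose entries are Pearson
correlations. Its SVD $R = U S V^\top$ yields latent variables: columns
of $U$ are behavioural saliences, columns of $V$ topographic (voxel)
saliences, and latent variable $l$ explains $100\, s_l^2 / \sum s^2$
percent of the cross-block covariance. Subject (brain) scores are
$Z_X V$; each behaviour's Pearson correlation with each latent variable's
brain scores is the quantity reported in behaviour profiles. The
correlation-scaled variant (both blocks z-scored) is used because the
reported profiles are Pearson R values.

Determinism choices: each latent variable's global sign is fixed so its
largest-magnitude behaviour salience is positive (sign is otherwise
arbitrary in an SVD); latent variables with $s_l < 10^{-12} s_1$ are
dropped as rank-deficient. With the default orientation a pattern in
which memory loadings are negative simply appears with memory positive
and age/APOE4 negative — one of the two equivalent orientations.

## Resampling inference

**Permutation test** (`permutation_test()`): each of `n_perm` (default
100) iterations permutes the subject rows of the behaviour block and
refits; the p-value of latent variable $l$ is the fraction of
permutations whose $l$-th largest singular value strictly exceeds the
observed one. A latent variable is deemed significant below 0.05. The
plain proportion is used (an add-one smoothed estimator is available but
off by default), and permuted singular values are compared rank-for-rank
— the common toolbox convention. No Procrustes rotation is applied in the
permutation step.

**Bootstrap** (`bootstrap_saliences()`): `n_boot` (default 1000)
resamples of subjects with replacement, identical rows in both blocks.
Each resampled SVD is aligned to the original fit by an orthogonal
Procrustes rotation computed on the behaviour saliences (SVD axes are
only defined up to reflection/rotation); the same rotation is applied to
voxel saliences and brain scores. The voxel salience SE is the standard
deviation across aligned resamples, and the bootstrap salience ratio
BSR = salience / SE is a pseudo-z thresholded at 2.58 (two-sided normal
99%) by default. Because saliences are estimated in one mathematical step
on the whole brain, BSR thresholding does not require a multiple
comparisons correction. Behaviour correlations are recomputed per
resample; their SD is the reported SE and their 2.5/97.5 percentiles the
95% CI, with "CI excludes zero" the significance rule for drawing
per-behaviour correlation maps. Resamples that produce a constant column
are redrawn (at most 100 attempts); rank-deficient resamples are padded
with zero saliences before alignment.

Calibration is tested, not assumed: with independent blocks the
type-I rate of the LV1 p-value over 500 replicate datasets must lie in
[0.02, 0.09], and at $n = 5$ the sampled p must agree with exhaustive
enumeration of all 120 permutations.

## Cluster reporting

`extract_clusters()` groups supra-threshold voxels (|value| ≥ threshold
two-sided; NaN is sub-threshold) by 26-neighbour connectivity (6/18
available), never merging opposite signs, and keeps clusters of at least
50 voxels — the extent threshold is inclusive (≥ 50), matching the
SPM-style convention, since "exceeding 50 contiguous voxels" is ambiguous
by one voxel. Peaks are maximum-|value| voxels with raster-order
tie-breaks. Coordinates stay at full precision internally; rounding to
the nearest mm happens only in `make_cluster_table()`. MNI→Talairach
mapping uses the Lancaster pooled affine for SPM-normalised images by
default; published coordinate tables in this literature scatter by a few
mm across the transforms in circulation, so agreement is only expected
within ~5 mm per axis, and the matrix is configurable.

## Group statistics

Two-group one-way ANOVA is the pooled-variance form ($F = t^2$ of the
pooled t, df $(1, n_1+n_2-2)$), with `anova_from_summary()` the
algebraically identical computation from printed means/SDs/sizes — so a
published cohort table row can be re-tested directly; the package ships
one such reference table (`mci_cohort_reference()`), from which the CVLT
delayed-recall row reproduces its published F statistic within 0.2%
(rounding of the printed inputs bounds the agreement). Chi-square for 2×2
tables is Pearson's, Yates correction off by default (flag provided).
Simple regression is OLS with R and a two-sided t-based p; a constant
response returns slope 0, R 0 by convention. `voxelwise_ttest()` is the
simplified voxel-wise comparison: pooled two-sample t per voxel, kept at
an uncorrected one-sided height threshold of p ≤ 1e-4 per direction, with
a 50-voxel extent filter via the cluster module. Random-field-theory
family-wise correction is deliberately out of scope.

## The synthetic-data generator

`generate_pls_dataset()` emulates the joint structure the analysis is
designed to detect — nothing more. Each subject draws a latent score
$z \sim N(0,1)$; the image is $\text{effect} \cdot z \cdot$ pattern on a
signal region plus iid $N(0, \sigma)$ noise; behaviour column $j$ is
$\lambda_j z + N(0,1)$. The population cross-block correlation matrix is
therefore exactly rank 1, with known voxel and behaviour saliences
(returned as ground truth), so recovery, power and calibration are all
checkable. Gaussian latent scores and noise are the minimal assumptions
under which PLS-C is well behaved; the generator makes no claim to
realistic neuroanatomy, spatially correlated scanner noise, or
partial-volume effects — passing tests show the *statistics* behave as
designed, not that the pipeline was validated on real tissue contrast.

Default scenario (fixed once, used by the analysis scripts and the
acceptance checks): 60 subjects, a 20³ grid of 8 mm voxels — a
deliberately scaled-down grid that still spans a head-sized field of
view, so the 10 mm smoothing kernel keeps a realistic size relative to
voxel size — a 6×6×6-voxel signal cube with constant unit pattern,
effect size 1.5 against unit noise, and ten behaviour variables whose
loadings carry the signs and magnitudes typical of amyloid-cognition
studies (age, male sex, APOE4 positive around 0.25; memory and semantic
fluency negative around 0.33–0.46; education and phonemic fluency zero).
Sex is coded female = 0 / male = 1 so that "male sex" correlations carry
the conventional sign. The TAC generator uses a bi-exponential reference
shape (amp 100, rates 0.03 and 0.5 per min: zero at injection, peak near
6 min, slow washout) as a plausible cerebellar-grey stand-in.

Resampling sizes follow the study design (100 permutations, 1000
bootstrap iterations); the end-to-end demonstration and the planted-BSR
checks run at 200 bootstrap iterations, the scaled size prescribed for
desk-scale validation, and the calibration suite states its replicate
counts (500 null datasets; 200 for the p-uniformity check) in the tests
themselves.

## Known limitations

* Spatial normalisation/registration is out of scope; all volumes are
  assumed to share a space and affine already.
* The voxel-wise group comparison is uncorrected-height + extent only —
  intentionally simpler than random-field cluster-level inference.
* Bootstrap SEs with fewer than ~10 subjects are unreliable (the package
  warns); percentile CIs inherit the usual small-n bootstrap caveats.
* Brodmann/anatomical labelling requires a user-supplied lookup; no atlas
  is bundled.
* The synthetic generator's white-noise assumption makes cluster-extent
  false-positive behaviour more benign than on smoothed real data; extent
  thresholds there should be calibrated against their own null.
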