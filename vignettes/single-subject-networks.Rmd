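---
title: "Single-subject gray matter networks: methods and design notes"
author: "sgmnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-subject gray matter networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgmnet)
```

# The method

`sgmnet` implements an end-to-end analysis of individual structural brain
organization from gray matter MRI: each subject's segmented, spatially
normalized gray matter map is turned into a similarity network whose
small-world properties can be related to age, sex and predicted brain
age.

## Network construction

1. **Nodes.** The smoothed gray matter volume is tiled with
   non-overlapping cubes of 3 x 3 x 3 voxels (`extractCubes()`). A cube
   becomes a node when all of its 27 voxels lie inside the brain mask
   with positive intensity (the inclusion fraction is configurable;
   1.0 is the default because partially-brain cubes mix tissue with
   background and distort correlations). Nodes are ordered
   lexicographically by grid position so every downstream output is
   bit-for-bit reproducible.

2. **Edges.** The similarity of two nodes is the *maximum* Pearson
   correlation between the 27 intensities of one cube and any symmetry
   transform of the other (`maxRotatedSimilarity()`), accommodating the
   locally varying orientation of cortical folds. The transform set
   (`symmetryTransforms()`) is, by default, the full symmetry group of
   the cube realized exactly on the 3 x 3 x 3 lattice: 48 combinations
   of axis permutations and reflections (24 proper rotations plus their
   mirror images), each an exact, invertible permutation of the 27
   positions. Rotations by odd multiples of 45 degrees cannot be
   realized exactly on this lattice; an approximate, trilinear
   interpolation dialect (`"interp45"`) is available for comparison,
   but it is not invertible (corner values are clamped) and is not the
   default. Because the lattice set is closed under inversion, the
   maximized similarity is symmetric in its two arguments, which the
   implementation exploits: rows are standardized once and each
   transform contributes one matrix product, so a 400-node similarity
   matrix costs 48 small matrix multiplications.

3. **Thresholding.** The similarity matrix is binarized by keeping node
   pairs whose similarity is significantly higher than chance at an FDR
   of `q = 0.05` (`fdrBinarize()`). The null model matters here more
   than anywhere else in the pipeline. Taking the maximum over 48
   transforms inflates chance-level similarity substantially: for
   independent cubes of 27 voxels the *maximum rotated* correlation
   centers near 0.4, not 0. The default null is therefore a Monte-Carlo
   *scramble* null: cube contents are permuted within the cube
   (destroying spatial pattern while keeping the intensity marginals),
   the rotation-maximized similarity is computed for `nNull = 2000`
   random scrambled pairs, and a normal fit on the Fisher-z scale
   supplies continuous one-sided p-values, which Benjamini-Hochberg
   then corrects across all pairs. The classical correlation t test
   (`nullMethod = "t"`, df = 27 - 2) is also provided; it ignores the
   maximum-selection inflation, so on rotation-maximized matrices it
   declares nearly every pair significant and yields near-complete
   graphs -- we keep it for plain-correlation work and for didactic
   comparison, not as the default. Either way the rule reduces to a
   single correlation cutoff per matrix (reported by `rThreshold()`),
   so the graph is a superlevel set of the similarity: raising `q`
   can only add edges, and every retained similarity exceeds every
   discarded one. A pooled variant (`pooledFDRThreshold()`) computes
   one cutoff across subjects for designs that want a common threshold
   for all participants.

## Small-world properties

`clusteringCoefficient()` (mean of the per-node triangle density,
nodes of degree < 2 contributing 0) and `characteristicPathLength()`
(mean breadth-first shortest path over pairs in the largest connected
component) are normalized by their means over `nRandom = 5`
degree-preserving randomized reference graphs
(`randomizeNetwork()`, Maslov-Sneppen double-edge swaps, 10 attempted
swaps per edge):

* normalized clustering: gamma = C / C_rand,
* normalized path length: lambda = L / L_rand,
* small-world coefficient: sigma = gamma / lambda.

A network is called *small-world* when gamma > 1, lambda is close to 1
and sigma > 1. Averaging path length within the largest component is a
choice, not a law; an efficiency-style harmonic mean over all pairs is
available (`pathMethod = "harmonic"`). Nodes with degree below 2 could
alternatively be excluded from the clustering mean; including them as
zeros follows the common single-subject-network convention and makes
the mean sensitive to fragmentation, which we consider a feature.

## Brain age

`fitBrainAgeCV()` predicts chronological age from the 4-mm-smoothed
voxel intensities by principal-component reduction (100 components at
cohort scale) followed by support-vector regression with a linear
kernel (libsvm nu-SVR, C = 1, nu = 0.5 -- the library defaults; an
epsilon-SVR fallback is provided because "C = 1, v = 0.5" admits both
readings). Under 10-fold cross-validation the PCA basis and the SVR are
fitted on the training folds only; fitting the basis globally is
available behind `globalBasis = TRUE` for replicating pipelines that
are ambiguous on this point, but it leaks test data and is off by
default. Accuracy is summarized by MAE, RMSE and the correlation
between predicted and chronological age on the pooled held-out
predictions; `brainPAD()` is predicted minus chronological age.
Features enter unstandardized (gray matter densities are commensurate
across voxels); z-scoring is a flag. Fold assignment is derived from a
hash of subject ids so that results do not depend on the order in which
subjects are listed.

## Statistics

The statistical stage (`runFullAnalysis()`) mirrors the analysis such a
cohort study reports:

* **Demographics:** Mann-Whitney U comparisons of women and men
  (`mannWhitneyU()`), exact by enumeration of rank assignments when the
  combined sample is at most 12 (the enumeration is tie-robust, which
  the classical exact distribution is not), normal approximation with
  tie and continuity correction otherwise. Alpha is 0.05, Bonferroni
  0.05/3 for the three network properties.
* **Age x sex models:** within the age strata below and at-or-above
  70 years (the boundary belongs to the upper stratum), a Gaussian
  identity-link linear model `property ~ age + sex + age:sex + n_nodes
  + scanner` (`fitInteractionGLM()`). "Generalized linear model" is
  read as this Gaussian fit because the responses are continuous
  ratios. Standardized coefficients are obtained by refitting with
  every variable -- including the interaction product -- z-scored;
  with a z-scored interaction column the standardized coefficients can
  legitimately exceed 1 in collinear strata. When the interaction is
  not significant at 0.05, main effects are tested in the reduced
  model. Node count and scanner enter as nuisance covariates (men have
  systematically more nodes; scanner is a two-level indicator).
* **Sex contrasts:** covariate-adjusted means per sex by ANCOVA
  (`ancovaSexContrast()`, estimated marginal means at covariate means).
* **Correlations:** partial correlations of each property with
  chronological and predicted brain age controlling sex, node count and
  scanner (`partialCorrelation()`; alpha 0.05/2), and a comparison of
  the two dependent overlapping correlations
  (`compareDependentCorrelations()`): the Hittner-style Fisher-z
  statistic by default, Steiger's variant behind a flag, since tools
  commonly used for this comparison implement several closely related
  procedures. The effective sample size passed to the comparison is
  the stratum size minus the number of partialled covariates.
* **Trajectories:** penalized-spline age curves per sex
  (`fitAgeTrajectory()`, `mgcv`), covariates entering linearly,
  predictions at covariate means with pointwise intervals.

# The synthetic cohort generator

No imaging data ship with the package; every analysis is exercised on
synthetic volumes (`simulateVolume()`, `simulateCohort()`) designed to
reproduce the *statistical shape* the pipeline assumes.

## Why a latent-motif model

The obvious generator -- white noise plus a spatially smooth Gaussian
component -- fails in an instructive way. Pearson correlation between
two smooth 27-voxel patches, *maximized over 48 orientations*,
saturates around 0.9 regardless of whether the patches are neighbors or
lie in opposite corners of the volume: generic smooth patches are
mutually alignable, so the distance information carried by plain
correlation (which decays cleanly with distance) is erased by the
rotation maximum. Any calibrated threshold then yields a complete graph
or an empty one, never a sparse small-world one. Real gray matter does
not behave like an isotropic Gaussian field: local tissue configuration
is *sharp* and *recurrent* -- neighboring regions contain the same
fine-scale anatomical motif, while imperfectly rotation-aligned foreign
motifs decorrelate quickly.

`simulateVolume()` therefore builds volumes from `nMotifs = 40` latent
tissue motifs: white 27-vectors mixed by spatially smooth, sharply
peaked weight fields over the cube grid (Gaussian fields of standard
deviation `motifScale = 1.2` cubes passed through `exp(3 z)` and
normalized). Each cube's pattern is `s * motifMixture +
sqrt(1 - s^2) * noise`, where `s` is the subject's *covariance
strength*; `s = 0` degenerates to pure i.i.d. voxel noise. Because
motifs are white at the voxel scale, unrelated cube pairs sit exactly
on the scramble null of the maximum rotated similarity, while cubes
sharing dominant motifs rise above it. At the default geometry
(30^3 voxels of 6 mm, 8 mm FWHM smoothing, covariance strength
0.7-0.9) the resulting networks have 300-400 nodes, densities of
4-7%, gamma about 1.9-3.0, lambda about 1.10-1.15 and sigma about
1.7-2.7, with the largest component holding essentially all nodes --
the regime reported for real single-subject gray matter networks,
whose normalized clustering sits near 1.7 and normalized path length
near 1.11. The 6 mm voxel size is deliberate: the network-stage
smoothing of 8 mm FWHM is then mild at cube scale (sigma = 0.57
voxels), preserving the within-cube degrees of freedom on which the
null calibration relies; at 1.5-2 mm voxels an 8 mm kernel leaves
cubes so smooth that every pair aligns.

## Cohort structure

`cohortSpec()` fixes the study conditions: 812 subjects by default
(407 women, 405 men -- counts are exact), ages uniform over 25.8-85.1
years, two scanner labels assigned alternately, and a per-subject
covariance strength

```
s_i = 0.95 - 0.004 age_i + 0.02 F_i - 0.008 max(0, age_i - 70) F_i + e_i
```

with `e_i ~ N(0, 0.02^2)`, clipped into [0, 1] with a warning if ever
needed. The linear decline encodes age-related network deterioration
(gamma falls with falling covariance strength), the positive female
offset a female advantage, and the changepoint at 70 years a steeper
female decline late in life. `simulatePropertyTable()` generates the
same effect structure directly at the level of per-subject network
properties (gamma declining 0.0035/year from 1.85, lambda 0.0006/year
from 1.13, sigma = gamma/lambda, sex-specific node counts near
6378/7092, predicted age = age + N(0, 5^2)); its late-life interaction
slopes (-0.0035 and -0.0007 per year) are chosen so that the female
advantage closes, rather than reverses, over the 70-85 year span --
the qualitative pattern the statistical stage is meant to detect:
sex differences present below 70, absent above, and an age-by-sex
interaction concentrated in the older stratum.

## What the generator does not emulate

Scanner hardware differences beyond a categorical label, motion and
susceptibility artifacts, T1 contrast, tissue segmentation errors,
registration distortions, cortical topology (the mask is an ellipsoid,
motifs are not sheet-like), and any genuine biological coupling between
brain age and network properties (predicted age is chronological age
plus noise unless the features are supplied). Passing tests therefore
demonstrate that the algorithms are correct and the statistics
calibrated under the assumed generative structure -- not that the
pipeline is robust to real-world preprocessing failure modes.

# Numerical choices

* **Smoothing** is separable discrete Gaussian convolution with kernel
  sigma = FWHM/2.3548 per axis (truncated at 4 sigma) and
  mass-conserving boundary handling: the kernel is renormalized at the
  edges so each input voxel redistributes total weight 1; total
  intensity is conserved to machine precision and the operator is
  linear.
* **Zero-variance cubes** (possible in flat mask regions) get
  similarity 0 against everything and are flagged rather than dropped.
* **Similarity matrices** are symmetrized by the entrywise maximum with
  their transpose (the transform set makes them symmetric
  mathematically; floating-point summation order does not), and clamped
  to [-1, 1].
* **Fisher-z fits** of the scramble null use plain moments; 2000 null
  draws put the standard error of the fitted mean near 0.002 z-units,
  negligible against the effect sizes thresholded.
* **Ties and degeneracies:** exact Mann-Whitney enumeration measures
  extremeness by |U - E[U]|, which is well defined under ties;
  constant-age targets skip the SVR and predict the constant; constant
  covariate columns make the design rank-deficient and raise an error
  naming the column.
* **Seeds:** every stochastic step (volumes, cohort, scramble null,
  rewiring, folds) derives its seed from one master seed through a
  fixed affine congruence (`childSeed()`), so pipelines are
  reproducible end to end and subject order never matters.

# Problem sizes used by the test-suite

The package's own validation runs at desk scale, chosen to finish in
minutes while leaving the conclusions unambiguous: 20 subjects of
30^3 voxels for the small-world property checks; at least 100 seeded
instances per brute-force oracle comparison (clustering, path length,
BH edge sets, rotation-maximized similarity, partial correlation);
Erdos-Renyi self-normalization at n = 200; brain-age recovery with 120
subjects, 500 voxels and 20 components; 10^4 null replicates for the
type-I-error calibration of the interaction and dependent-correlation
tests; and 20 replicate cohorts of 400 subjects for the
stratum-pattern recovery. The full-scale defaults (812 subjects, 100
components) are what `cohortSpec()` and `brainAgeModel()` encode.

# Known limitations

* The scramble null calibrates "similarity above chance pairing"; it
  does not correct for spatial autocorrelation induced by smoothing
  beyond what within-cube scrambling removes, so heavier smoothing at
  small voxel sizes biases the graph denser.
* gamma and sigma magnitudes depend on the motif geometry; the
  generator targets the small-world regime, not the exact printed
  values of any particular cohort.
* The interpolated 45-degree dialect clamps out-of-cube coordinates and
  is therefore only an approximation of continuous rotation.
* Brain-age bias correction (regression-to-the-mean adjustment of
  brain-PAD) is deliberately out of scope.
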