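---
title: "Methods: group comparison and classification of resting-state functional connectivity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group comparison and classification of resting-state functional connectivity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`rsfcnet` implements a complete group-comparison pipeline for resting-state
functional brain networks, of the kind used to contrast patients in a major
depressive episode with healthy controls. The pipeline starts from
parcellated BOLD time series (one matrix of regions x timepoints per
subject, regions in ascending atlas order) and proceeds through five
stages:

1. **Connectivity.** For each subject, the functional connectivity matrix
   $R$ holds the Pearson correlation $r_{ij}$ between the parcel-averaged
   series $x_i(t)$ and $x_j(t)$. No detrending, band-pass filtering,
   nuisance regression or scrubbing is applied between parcel averaging
   and correlation: the correlation is computed on the averaged series as
   given. A region with zero temporal variance is a hard error naming the
   region — a silent `NaN` would poison every downstream stage.
2. **Network measures.** Three weighted node measures per subject:
   node strength $Ns_i = \sum_j w_{ij}$; eigenvector centrality
   $\theta$, the unit-norm eigenvector of the weight matrix at its
   largest eigenvalue $\lambda$; and the weighted clustering coefficient
   $$C_i = \frac{\sum_{j \ne i}\sum_{k \ne i, k \ne j} w_{ij} w_{jk} w_{ki}}
                {l_i (l_i - 1)}, \qquad l_i = \sum_j w_{ij},$$
   with the network mean of each measure defined as the arithmetic mean
   over nodes.
3. **Edge-wise inference.** Per-edge general-linear-model contrast t
   (positive = stronger in controls), Freedman–Lane permutation p-values,
   Benjamini–Hochberg FDR across all edges, and a 0/1 significance mask.
4. **Node-cluster inference.** A cluster-based permutation test over the
   anatomical (atlas-index) ordering of nodes, yielding signed clusters
   of neighboring nodes where a measure differs between groups.
5. **Specific networks and classification.** The subgraph induced by
   significant-cluster nodes restricted to FDR-significant edges, exported
   in BrainNet Viewer formats; and a pseudo-inverse linear discriminant
   classifier over five feature-vector variants with repeated stratified
   k-fold cross-validation.

A seeded synthetic-cohort generator stands in for real scans, which are
not publicly available for the motivating study; every stage is exercised
end-to-end on cohorts with known, recoverable planted effects.

# Design choices where the published description is open

Several operational details are not pinned down by the descriptions such
pipelines usually receive. The choices below are this package's normative
definitions; each is tested against an independent oracle or simulation.

**Weight policy.** Correlation matrices contain negative entries, but the
clustering coefficient's triple products and the Perron–Frobenius argument
behind eigenvector centrality presuppose nonnegative weights. The default
policy takes absolute values (`absolute`); `positive_only` and `raw` are
retained for sensitivity analyses, and `raw` is rejected by the clustering
coefficient when negatives are present. The diagonal is always zeroed
before any measure — otherwise every node strength is inflated by exactly
the self-correlation of 1.

**Clustering-coefficient summation.** The restored double sum runs over
ordered pairs $(j, k)$ with $j \ne k$, both different from $i$; on 0/1
graphs this reduces to twice the node's triangle count over
$k_i(k_i - 1)$, which the tests verify by direct triangle counting. Nodes
with $l_i \le 1$ (non-positive denominator) are assigned $C_i = 0$.

**Network mean.** The network-level summary of each node measure is the
mean over nodes (dividing by $N$); the plain sum is recoverable by
multiplying by $N$.

**Degenerate spectra.** A leading eigenvalue with numerical multiplicity
above one (relative tolerance `1e-10`), or an all-zero weight matrix,
raises an error: silent tie-breaking would make centrality irreproducible
across linear-algebra backends.

**Edge-wise test.** The normative definition is: fit
`edge ~ intercept + covariates + group` per upper-triangle edge; compute
the group-contrast t; obtain p-values by Freedman–Lane permutation
(permute the residuals of the covariates-only model, refit the full
model), with the add-one estimator
$p = (1 + \#\{|t^\*| \ge |t|\})/(1 + n_\mathrm{perm})$; control FDR by
Benjamini–Hochberg across all edges. With no covariates the procedure is
algebraically identical to permuting group labels, and a vectorized
two-sample path is used; the test suite verifies the two paths agree.
The defaults are $\alpha = 10^{-4}$ and 100{,}000 permutations (the
motivating study's settings); examples and tests use smaller values, and
the permutation count must respect the estimator's floor: no permutation
p-value can fall below $1/(n_\mathrm{perm}+1)$, so BH significance at
level $\alpha$ over $m$ edges requires roughly
$n_\mathrm{perm} \gtrsim m/\alpha$.

**Covariate coding.** Subject tables may carry a diagnosis column
(e.g. unipolar vs bipolar depression); `read_subject_table()` emits one
dummy column per diagnosis level. Those dummies sum to the patient
indicator, so entering all of them together with the group contrast
makes the design rank-deficient; `build_design()` rejects such designs,
and the intended usage is to pass a full-rank subset (e.g. the bipolar
dummy alone, coding the within-patient contrast).

**Cluster test.** "Neighborhood of the anatomical parcellations" is
operationalized as adjacency of consecutive atlas indices: supra-threshold
nodes ($|t|$ above the two-sided critical value at the forming level,
default 0.05) are segmented into maximal sign-homogeneous contiguous runs
of atlas indices. The cluster statistic is the mass (sum of member t
values); the null distribution is the maximum $|$mass$|$ per label
permutation, pooled over both signs, which controls family-wise error
across positive and negative clusters jointly. The test suite includes a
deliberate regression check that scrambling the atlas ordering destroys
planted contiguous clusters — the ordering is semantics, not cosmetics.

**Specific networks and hubs.** A specific network joins the nodes of one
sign's significant clusters with the FDR-significant edges internal to
that node set. "Hub" is operationalized as within-network degree, ties
broken by atlas index. BrainNet Viewer export writes the `.node` file
(x, y, z, color code — 1 positive / 2 negative —, size = degree, label)
and the `.edge` dense symmetric matrix over member nodes.

**Classifier.** Two-class LDA with the pooled within-class covariance
inverted by Moore–Penrose pseudo-inverse (the "pseudolinear" contract):
rank-deficient feature sets — 13,695 edge features from 90 subjects,
duplicated columns — are tolerated because the discriminant acts in the
span of the within-class variation. The pseudo-inverse is computed from
the economy SVD of the class-centered data matrix (singular values below
`1e-8` of the largest are dropped), never forming the feature-by-feature
covariance. Priors default to empirical class proportions; the positive
class for sensitivity/precision/ROC is `"depression"` — a documented
convention, not a claim about the motivating study. "k-fold repeated
1000 times" is read as 1000 independent repetitions of stratified
10-fold cross-validation with reshuffled folds (LDA has no
hyperparameters, so no inner tuning loop exists); accuracy is summarized
as mean ± SD across repeats, while sensitivity, specificity and
precision come from the confusion matrix pooled over all out-of-fold
predictions, and the ROC/AUC from the pooled out-of-fold discriminant
scores with trapezoidal integration.

**Feature selection without leakage.** For the significant-connections
variant the edge mask is, by default, recomputed inside every training
fold (`fc_mask_selector()`), so selection never sees the held-out fold.
Fold-internal selection uses analytic t p-values with BH rather than
permutations: selection does not need permutation exactness, and the
permutation floor would make every fold-internal BH threshold unreachable
at practical permutation counts. Passing a fixed whole-sample mask to
`build_features("significant_fc", ...)` instead reproduces the simpler
design in which the mask is computed once on all subjects — that variant
leaks test-set information into feature selection and its accuracy should
be read as optimistic.

# The synthetic cohort generator

The generator defines the study conditions under which everything is
tested: 166 regions, 192 timepoints (TR = 2 s scale), 49 controls and 41
patients by default.

- **Baseline dependence.** A low-rank factor model (default rank 8) with
  a positive-dominant leading factor plus region-specific noise, rescaled
  to a correlation matrix — giving the positive-dominant, diffusely
  correlated structure typical of parcel-averaged BOLD.
- **Planted effects.** Within contiguous atlas-index blocks, patient
  off-diagonal correlations are attenuated by $(1-\delta)$ (hypo) or
  moved to $\min(1, r(1+\delta))$ (hyper), then the matrix is projected
  to the nearest PSD correlation matrix (eigenvalue clipping, diagonal
  rescaling). The defaults plant two hypo blocks (occipital-like nodes
  47–54, vermis-like 109–113) and one hyper block (orbitofrontal-like
  21–28), each at $\delta = 0.5$ — positioned and signed after the
  spatial pattern typically reported for depression, with a magnitude
  large enough to be recoverable by the pipeline at the default cohort
  size.
- **Projection spillover.** The PSD repair is global: raising a block's
  internal correlations can shave the block nodes' correlations with the
  rest of the brain. Hyper blocks therefore partially self-cancel in
  node strength (the within-block gain is offset by cross-block loss),
  while hypo blocks are recovered robustly. This is a documented property
  of the generator, visible in the worked example.
- **Temporal model.** Innovations with the group covariance are smoothed
  by a lag-1 autoregression (default coefficient 0.3), scaled to preserve
  unit marginal variance; because all regions share the same AR
  coefficient, the stationary cross-correlation equals the innovation
  correlation. No haemodynamic convolution is applied — every downstream
  statistic is correlation-based and unaffected by shared linear
  filtering at this level of realism.
- **Between-subject variability.** Each subject's covariance is a Wishart
  perturbation of the group matrix (default 500 degrees of freedom,
  rescaled to a correlation matrix; a 0.1% identity shrinkage keeps the
  Wishart scale strictly positive-definite after PSD projection). The
  magnitude is calibrated only to make the permutation tests
  non-degenerate — no per-subject variance statistics exist to match.
- **Determinism.** Every draw derives its seed from the spec seed and a
  stage/subject key, so an identical spec regenerates a bit-identical
  cohort and two pipeline runs with one global seed produce
  hash-identical artifact trees.

What the generator does **not** emulate: voxel-level structure, motion
and physiological artefacts, haemodynamic response variability, scanner
drift, non-Gaussian and non-stationary dynamics, and realistic anatomical
covariance beyond the factor model. Passing tests on these cohorts
demonstrates that the statistics recover the effects they are designed to
recover under Gaussian, stationary conditions — not that the pipeline is
robust to real-scanner confounds.

# Numerical choices and degenerate inputs

- Permutation p-values always use the add-one estimator, so they lie in
  $(0, 1]$ and never underflow the achievable resolution.
- PSD projection clips negative eigenvalues at zero and rescales the
  diagonal to exactly 1; symmetry is enforced by averaging with the
  transpose.
- Matrix files are written with 17 significant digits so write/read
  round-trips are exact at double precision; ragged or non-numeric files
  fail with the offending line number.
- Constant series, zero pooled variances, empty parcels, confounded
  designs, degenerate eigenvalues and missing coordinates are all hard
  errors with named causes; nothing degrades silently.
- Cross-validation folds are stratified per class; a training fold that
  loses a class entirely stops with an error suggesting a smaller k. An
  empty fold-internal feature selection falls back to a priors-only
  classifier rather than failing.

# Problem sizes used by the test suite

The package's own validation runs at sizes chosen to exercise every code
path while completing quickly: oracle comparisons on 5–8-node graphs
(50 replicates); type-I-error calibration of the cluster test on 400 null
cohorts of 30 nodes with 20 + 20 subjects at 2,000 permutations; planted
recovery at 40 + 40 subjects (6-node shift of 1.5 pooled SD; a single
planted edge at standardized difference 2.0 among 190 null edges, tested
at 40,000 permutations so the BH threshold is reachable); chance-level
and separable classification checks on 90-subject cohorts with 100
repeats of 10-fold cross-validation; and a full-pipeline determinism run
on a 20-region cohort. Full-scale analyses (166 regions, 100,000
permutations, 1000 repeats) use the same code paths with larger
parameters.

# Known limitations

- The cluster test's 1-D adjacency follows the atlas index ordering;
  regions that are spatial neighbors but not index neighbors are not
  pooled. A centroid-distance adjacency would generalize this but is not
  implemented.
- The one-sample normality check uses plug-in parameters and is
  conservative about rejecting normality (the Lilliefors caveat).
- The edge-wise test assumes exchangeable subjects under the null within
  the Freedman–Lane scheme; site, scanner or batch structure would need
  additional covariates.
- Reported classification accuracies on synthetic cohorts depend
  strongly on the planted effect size delta and the jitter degrees of
  freedom; they are benchmarks of the machinery, not forecasts of
  clinical performance.
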