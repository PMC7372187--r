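---
title: "Reference-guided multimodal fusion: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-guided multimodal fusion: models, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refusion)
```

This vignette is the package's own account of the statistics it
implements: the fusion model and its assumptions, the tunable parameters
and their defaults, the synthetic cohort the validation suite relies on,
the numerical choices that were genuinely open, and what the passing tests
do and do not establish about real data.

## The fusion model

The data are $K$ subject-by-feature matrices $X_k$ (functional
connectivity edges, FA voxels, GMV voxels, ...) over the same $n$
subjects, plus one per-subject reference $r$ — a methylation
$\beta$-value at a CpG site in the motivating use case. After
preparation (below), each $X_k$ is whitened by PCA to $Y_k$ and assigned
an orthonormal weight matrix $W_k$, giving canonical variates
$D_k = Y_k W_k$. The weights maximize

$$J \;=\; \sum_{i<j}\sum_{c=1}^{M}\operatorname{corr}(D_i[,c],
D_j[,c])^2 \;+\; \lambda \sum_{k}\sum_{c=1}^{M}
\operatorname{corr}(D_k[,c], r)^2 .$$

Both terms use *squared* correlations. The wording "maximize the
correlations" does not pin down a power; the squared form is smooth,
invariant to component sign, and reduces exactly to classical CCA when
$K=2$, $M=1$, $\lambda=0$ — an equivalence the test suite checks against
an independent generalized-eigenvalue oracle to $10^{-6}$. Correlation
(not covariance) is used for the inter-set term as well; with whitened
inputs and unit-norm weights the two coincide anyway, so this choice
costs nothing and keeps the objective interpretable.

After the canonical stage, the component maps (regressions of the
prepared data on the variates) are concatenated across modalities and
rotated to independence by joint ICA; subject loadings are then
recomputed against the final joint maps, because all downstream tests
(group differences, reference and clinical correlations) are on the
final joint components, not the raw canonical variates.

### Optimization

The weights are found stage-wise, as is usual for multiset CCA:
component 1 is obtained by alternating, across modalities, a closed-form
eigen-update of its quadratic form (unconstrained); component $c$ is
obtained the same way inside the orthogonal complement of components
$1..c{-}1$ of the same modality. Each update solves its subproblem
exactly, so the running objective is non-decreasing by construction, and
the variates within a modality are exactly uncorrelated. Stages
initialize from the $\lambda = 0$ pairwise-CCA solution (an SVD of the
cross-covariances), which for two modalities is already the global
optimum of the unregularized problem.

Two alternatives were tried and rejected during development. Updating
each column inside the complement of *all* other columns is degenerate
in the standard square configuration (whitening rank equal to $M$): the
feasible set collapses to the current column and nothing can move.
Unconstrained per-column updates followed by symmetric orthogonalization
of each $W_k$ per sweep are not monotone: from a good initializer all
columns are attracted toward the dominant direction and the polar
projection scrambles the pairing, lowering $J$. Stage-wise deflation has
neither defect.

Convergence is declared when a stage's objective changes by less than
`tol` ($10^{-6}$ by default) between sweeps; non-convergence within
`max_iter` is reported with a warning and a `converged = FALSE` flag,
never silently. Components are returned sorted by their contribution to
$J$, descending, so "component 1" is always the strongest joint
component under the configured $\lambda$.

### Whitening rank versus number of components

`whiten(features, M)` retains the top $M$ principal directions and
returns operators mapping back to the rank-$M$ approximation. The
pipeline default makes the whitening rank equal to the number of
extracted components (square $W_k$), the standard setup in published
fusion toolboxes. The two are deliberately decoupled
(`fuse_cohort(whiten_rank = ...)`): searching weights in a larger PCA
subspace lets the reference pull in directions beyond the top-$M$
subspace, and full-rank whitening is what makes the classical-CCA
equivalence exact rather than approximate.

## Preparation

Features are conditioned in the order the workflow prescribes:

1. **Covariate regression** — each feature column is replaced by its OLS
   residual on an intercept, age, and sex (coded 0/1); mean framewise
   displacement is added for FC only, since head motion contaminates
   connectivity estimates specifically. Rank-deficient covariate designs
   are an error naming the collinear columns.
2. **Normalization** — columns are centered and the whole matrix is
   divided by one scalar so the pooled SD over all entries is 1.
   "Normalize" is ambiguous between this and per-feature z-scoring; the
   single-scalar form is used because its purpose is equal *modality*
   contribution to the fusion, and per-feature scaling would distort the
   relative variance structure (hence the spatial maps) within a
   modality.

FC features are built as region-by-region Pearson correlations,
Fisher-z transformed by default with $|r|$ clipped to $1 - 10^{-7}$ so
`atanh` stays finite on self-correlated (duplicated) regions; raw
correlations are available via `fisher_z = FALSE`. The strict upper
triangle is vectorized in row-major order, giving $R(R-1)/2$ features.

## Model order

`estimate_order_mdl()` implements the classical Wax–Kailath MDL on the
sample-covariance eigenvalues,

$$\mathrm{MDL}(m) = -N(p-m)\log\frac{g_m}{a_m} +
\tfrac12 m(2p-m)\log N,$$

with $g_m, a_m$ the geometric/arithmetic means of the trailing
eigenvalues and $p = \min(N-1, \text{features})$. Which "advanced" MDL
correction a given fusion study used is typically unknowable from its
text; the classical criterion is reproducible and standard, and the
effective sample size $N$ is exposed (`n_eff`) so a subsampling
correction for spatially smoothed data can be applied externally.
`fuse_cohort(n_components = "auto")` takes the maximum MDL estimate
across modalities (so no modality is under-modeled) and a fixed integer
overrides the estimate entirely — the common practice of fixing, say, 20
components is one line.

## Choosing the reference weight

`select_lambda_cv()` runs subject-wise $k$-fold cross-validation over a
$\lambda$ grid: weights are fit on the training folds, and the criterion
is the mean over folds and modalities of the absolute correlation
between the held-out *top* variate and the held-out reference. Ties
within $10^{-12}$ go to the smaller $\lambda$, so a reference carrying
no signal defaults to the least-regularized model. The per-fold refit
covers the canonical weights, not the whitening, which is computed once
on the full cohort; the criterion is a ranking device and this keeps it
cheap and deterministic.

One property discovered during validation is worth stating: when the
data contain a *single* latent shared across modalities and the
reference correlates with that same latent, the criterion is essentially
flat in $\lambda$ — the unregularized fit already finds the only joint
component there is, and regularization has nothing to add. $\lambda$
earns its keep when joint structure is plural: with a strong shared
latent carrying no reference signal and a weaker reference-correlated
one, only $\lambda > 0$ ranks the reference component first, and the
cross-validated criterion detects this reliably. The test suite encodes
exactly that scenario.

## Joint ICA

The concatenated maps are row-centered, whitened in component space, and
unmixed by natural-gradient infomax with the logistic nonlinearity
(learning rate $0.01/\log M$, halved on divergence; stopping when the
weight change drops below `tol`, with a generous iteration budget since
each step is a small $M \times \Sigma p_k$ multiply). A symmetric
FastICA with the log-cosh contrast is available as
`ica_algorithm = "fastica-logcosh"`. Both are seeded and deterministic.
Final maps are scaled to unit SD with a deterministic sign, and subject
loadings are the least-squares projection
$A_k = X_k S_k^{\top}(S_k S_k^{\top})^{-1}$.

ICA separates only non-Gaussian sources: with Gaussian maps the run
still converges numerically but the rotation is arbitrary, which is a
documented limitation rather than an error.

## Statistics and selection

For every (component, modality) pair: a two-sample t-test on the
loadings (Welch by default — real cohorts rarely have equal group
variances; pooled available), and a Pearson correlation with the
reference; each family of $M \times K$ p-values is Benjamini–Hochberg
corrected. A pair is **selected** when both $q$-values fall below
$\alpha$ (0.05 default); a component selected in all modalities is the
joint component. This two-condition rule mirrors how such components are
characterized: group-discriminating *and* reference-correlated. The
partial correlation regresses both the loading and the reference on the
group indicator before correlating (p from the t-transform with $n-3$
df), separating within-group covariation from a pure group-mean effect.

Component signs are aligned so the control-group mean loading is at
least the patient mean in every (component, modality); maps flip with
their loadings, so positive map values always read control > patient.
Maps are z-scored to zero mean/unit SD and thresholded at $|Z|>2$ for
voxel modalities and $|Z|>3$ for the (much denser) FC edge maps.

Locus-wise differential methylation uses the same Welch test, vectorized
over loci, with BH correction across *all* loci; $\beta$-values are
tested on their raw $[0,1]$ scale by default (the convention for
reporting group means like 0.34 vs 0.28), with the logit M-value
transform available for variance stabilization.

## The synthetic cohort

`generate_multimodal()` builds each modality as
`loadings %*% sources + noise`:

* **Sources** are sparse Laplacian rows (`source_sparsity` fraction of
  nonzero double-exponential entries, unit RMS per row) — super-Gaussian
  by construction, so the ICA stage is identifiable.
* **One shared latent** drives the target loading column in every
  modality (plus `loading_noise_sd` of modality-specific noise);
  non-target loadings are independent standard normals. Patients' latent
  values are shifted down by `group_effect_d` SD.
* **The reference** is the latent mixed with independent noise at
  correlation `rho_ref`, mapped onto the $\beta$ scale as
  $0.31 + 0.06\,z$ (clipped to $(0,1)$). Its distribution across
  subjects is a modeling convenience — nothing is claimed about the
  distribution of real methylation values.
* **Clinical scores** correlate with the latent at configured levels;
  age of onset exists for patients only.

Defaults were fixed once at values a fusion study of this kind reports:
`rho_ref = -0.4` (hypermethylation with lower loadings),
`group_effect_d = 0.8`, onset/MMSE/HSCT correlations 0.6/0.35/0.3,
`noise_sd = 0.5`, 100+100 subjects, 500 features per modality, 5
sources. `generate_methylation()` draws $\beta$ from Beta distributions
parameterized by mean/SD via method of moments (respecting the $[0,1]$
support), with patient mean 0.34 vs control 0.28 (SD 0.06) at target
loci.

What the generator does **not** emulate: spatial autocorrelation of
brain maps, site/batch effects, realistic MRI physics, or non-Gaussian
reference distributions. Passing recovery tests therefore show the
pipeline is correct and identifiable under its stated model — not that
real cohort effect sizes are attainable.

## Validation suite sizes and observed calibration

The simulation suites run at sizes chosen to make their statistical
targets sharp while keeping the whole suite quick: parameter recovery at
the generator defaults (200 subjects, $3\times500$ features, 20 seeded
runs); null calibration of component selection on 200 reduced cohorts
(50 subjects, $3\times100$ features, $M=3$); locus-test calibration on
1,000 loci (a scaled-down stand-in for array-wide scans, whose only
relevant property here is the number of tests).

Two empirical notes from building the suite. First, with group means
0.34 vs 0.28 (SD 0.06) at $n = 33/40$, a planted locus among 1,000 nulls
is top-ranked by $q$ about 70% of the time and lands in the top 10 about
96% of the time — a useful reminder that a single locus of this effect
size does not dominate an array-wide scan with certainty. Second, under
the fully null generator the joint-selection rate over 200 runs is far
below $\alpha$: requiring *both* FDR-corrected conditions is
conservative by design.

## Known limitations

* One reference signal; no kernel/nonlinear variants.
* The stage-wise optimizer finds strong local optima with a good
  initializer but carries no global guarantee for $K > 2$ — no algorithm
  for this objective does.
* Sign/permutation indeterminacy is inherent to ICA; all comparisons to
  ground truth or across replication runs use absolute spatial
  correlations and greedy matching.
* Anatomical labeling of surviving features is out of scope; maps are
  returned in feature space (with optional NIfTI export through a mask).
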