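---
title: "Brain age, network lesions, and gene expression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain age, network lesions, and gene expression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netbrainage)
```

## The analysis

`netbrainage` implements a three-stage analysis of structural brain aging:

1. **Brain-age prediction.** Chronological age is regressed on regional
   gray-matter volumes (GMV; one mean value per atlas ROI) with Gaussian
   process regression (GPR) under repeated 10-fold cross-validation. The
   per-subject brain-predicted age difference (brain-PAD) is the mean
   out-of-fold prediction minus chronological age.
2. **Computational lesion analysis.** Each brain network's ROIs are removed
   in turn and the cross-validated prediction is re-run on the remaining
   features. A network's importance is the degradation it causes, scored
   with Steiger's Z test for two dependent correlations sharing one
   variable: the age–prediction correlation of the full model versus the
   lesioned model, given the correlation between the two prediction
   vectors.
3. **Transcriptomic annotation.** The decisive network is annotated with
   genes whose spatial expression is elevated (or depressed) inside it,
   using a multi-donor expression atlas: samples are mapped into the
   network through 6-mm sphere ROIs, expression is normalized per donor by
   the median rule, genes are tested by label permutation with
   family-wise-error control, and the resulting gene list is summarized by
   hypergeometric over-representation analysis against GMT gene sets.

Every stage runs on synthetic data with known ground truth, so the whole
chain is testable without any external download.

## The GPR model

The default covariance is linear + bias with white observation noise,

$$k(x, x') = \sigma_f^2\, x^\top x' + \sigma_b^2, \qquad
  y \sim \mathcal{N}(0,\, K + \sigma_n^2 I),$$

a standard choice for regional-volume brain-age models, where the feature
count (68–246 ROIs) is comparable to the subject count and the age signal
is approximately linear. A `linear+rbf` option adds an isotropic
squared-exponential component sharing $\sigma_f$, for mild nonlinearity.
Hyperparameters are optimized on the log scale by Polak–Ribière conjugate
gradients with analytic gradients of the log marginal likelihood
(relative tolerance $10^{-7}$, at most 50 iterations — in practice the
three-parameter problem converges to four significant figures well inside
that budget). Initial values are $\sigma_f = \sigma_b = 1$ and
$\sigma_n = 0.1\,\mathrm{sd}(y)$.

Two algebraically identical evaluations of the marginal likelihood are
implemented: the usual kernel-space (dual) form, and a weight-space
(primal) form used automatically for the linear kernel whenever
$p + 1 < n$, which costs $O((p+1)^3)$ per evaluation after one pass over
the data. The test suite asserts their equality and checks predictive
means against an independent dense solve at $10^{-8}$.

Numerical safeguards: features are z-scored and targets centred with
*training-fold* statistics only (no leakage); if the Cholesky
factorization of $K + \sigma_n^2 I$ fails, a jitter of
$10^{-8}\,\mathrm{tr}(K)/n$ is added, with one retry at ten times that
(the plain factorization is tried first so well-posed problems are solved
exactly); log-hyperparameters are confined to
$|\theta| \le 25$; constant targets short-circuit to a degenerate model
predicting the training mean.

## Cross-validation and metrics

Folds are contiguous blocks of a seeded permutation, sizes differing by at
most one; the repeat index advances the seed, so partitions are
reproducible and can be shared bit-for-bit between the full and every
lesioned run — the comparison then isolates the lesion. Lesioned models
re-optimize their hyperparameters (re-training is what "lesioned model"
means here); the fold partition, not the hyperparameters, is what must be
held fixed.

Headline MAE and Pearson $r$ are computed on the per-subject mean
out-of-fold prediction across repeats; per-repeat metrics are retained,
and the lesion stage reports a secondary per-repeat-averaged Z alongside
the primary Z on averaged predictions, since either averaging order is
defensible.

## Steiger's Z

For correlations $r_1 = \mathrm{cor}(a, p_1)$, $r_2 = \mathrm{cor}(a, p_2)$
sharing the variable $a$, with $r_{12} = \mathrm{cor}(p_1, p_2)$ and
$z_i = \operatorname{artanh} r_i$:

$$\bar r = \tfrac{r_1 + r_2}{2},\quad
  \bar\psi = r_{12}(1 - 2\bar r^2) - \tfrac{1}{2}\bar r^2
             (1 - 2\bar r^2 - r_{12}^2),\quad
  c = \frac{\bar\psi}{(1 - \bar r^2)^2},$$

$$Z = (z_1 - z_2)\,\frac{\sqrt{n - 3}}{\sqrt{2 - 2c}},\qquad
  p = 2\,(1 - \Phi(|Z|)).$$

This is the 1980 form for dependent correlations with the mean-correlation
substitution, the variant used by standard correlation-comparison
packages. The sign convention puts the full model first, so positive Z
means the lesion *degraded* performance. No correction across the 17
networks is applied; the per-network p-values are reported uncorrected.
The null calibration of this test (type-I error at $\alpha = 0.05$ over
1,000 simulated cohorts of $n = 200$) is asserted in the acceptance suite.

## The synthetic cohort generator

The generator encodes linear atrophy with a latent brain-age offset:

$$\mathrm{gmv}_{ij} = b_{0j} + b_{1j}\,(\mathrm{age}_i + d_i
  + \beta_{\mathrm{sex}}\,\mathrm{sex}_i) + \varepsilon_{ij},$$

with ROI slopes $b_{1j}$ drawn around their network's mean slope,
ROI noise $\varepsilon$ Gaussian per network, and
$d_i \sim \mathcal N(0, \sigma_d^2)$ a per-subject offset shared by all
ROIs. The offset is the accuracy-limiting ingredient: a perfect predictor
recovers $\mathrm{age} + d$, so the population ceiling on the
age–prediction correlation is
$\mathrm{sd(age)}/\sqrt{\mathrm{sd(age)}^2 + \sigma_d^2}$. Defaults —
ages uniform on 19–80 years ($n = 492$), $\sigma_d = 9$ years, network
slopes $-0.25$ volume units/year, ROI noise sd 3 — place that ceiling at
0.89; one calibration run of the cross-validated predictor at these frozen
defaults landed at $r = 0.898$, inside the 0.85–0.95 design band asserted
by the tests. Sex is coded 0 = male / 1 = female (ratio 308:187 by
default, both exposed as parameters since the source cohort's reported
counts are internally inconsistent), with no sex effect on GMV by default.
TIV is drawn independently of age and GMV residuals. Setting every noise
source to zero makes GMV an exact affine function of age, the noiseless
limit in which cross-validated $r \ge 0.999$ and MAE $\le 0.5$ years are
asserted.

What the generator does **not** emulate: spatially correlated noise
between neighbouring ROIs, scanner/site effects, non-linear atrophy
trajectories, and realistic cortical geometry (parcels are Voronoi cells
in an ellipsoid). Passing tests therefore demonstrate the *statistical
machinery*, not performance on real morphometry.

## The expression generator and annotation stage

Donors contribute spatially uniform samples inside the brain mask
(363–946 samples per donor at full scale; desk-scale runs use 40–80).
Baseline log-expression is Gaussian with mean 1 and sd 0.25 (log-normal
expression: strictly positive, multiplicative noise); signal genes gain
$+\delta$ (default 0.5) on the log scale in samples whose 6-mm sphere maps
to the target network under the same admission rule used by the analysis —
strictly more than 50% of the sphere's voxels inside the mask, assignment
to the cluster holding the largest voxel share, ties to the lowest id with
a warning.

Per-donor median normalization, $(x - m)/m$ with $m$ the donor's
per-gene median, is applied to all of a donor's samples before any
cluster subsetting. The permutation test resamples cluster labels over
all admitted samples pooled across donors (the exchangeability reading of
"randomly selected sample sets of the same size"), reusing one set of
permutations across genes; p-values use the add-one estimator, two-sided
by default since no direction is prescribed. FWE control is single-step
max-statistic over the centred absolute statistics (Bonferroni via flag),
with adjusted p floored at the raw p. Probe collapsing (keep the
highest-mean probe per gene) is provided as a utility but the main path
assumes gene-level input.

## Enrichment

The over-representation stage is a deliberate local stand-in for web-based
enrichment services: exact hypergeometric upper-tail p per GMT term,
Benjamini–Hochberg adjustment across terms. The universe defaults to the
genes measured in the expression dataset — the background actually tested —
rather than the union of GMT terms. Term-similarity clustering and
multi-database merging are out of scope.

## Problem sizes and determinism

Desk-scale defaults (68 ROIs, 250 subjects, 5 CV repeats, 999
permutations, 150–200 genes) are sized so the full demo and the test
suite run interactively on one core; paper-scale settings (246 ROIs, 492
subjects, 100 repeats, 5,000 permutations) are one flag away and use the
identical code path. Every generator and every stochastic stage is a pure
function of its parameters and an explicit integer seed; the pipeline
refuses a configuration without one. Known degenerate inputs — constant
targets, empty networks, samples outside the grid, zero donor medians,
correlations of magnitude one — are either handled with a documented
convention or rejected loudly; silent coercion is avoided throughout.

## Limitations

* The GPR kernel the original brain-age literature used is under-specified
  in most reports; the linear+bias default is a reasonable reconstruction,
  and the kernel kind is recorded in output metadata rather than asserted
  as *the* original.
* Brain-PAD is not bias-corrected for regression toward the mean; the
  covariate tests control for age and age² instead.
* The annotation stage's permutation scheme (what is resampled, its
  sidedness, the FWE flavour) follows one defensible reading of
  common practice; alternatives are exposed as flags, not silently mixed.
* Absolute gene counts from real donor atlases (thousands of significant
  genes) are not reproducible from synthetic data; the planted-truth
  recovery rates are the meaningful check here.
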