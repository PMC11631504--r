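---
title: "Regularization-grid construction and nested cross-validation for genomic prediction"
author: "penGrids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularization-grid construction and nested cross-validation for genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penGrids)
```

## The problem

Genomic selection predicts the genetic merit of candidate lines from
genome-wide marker dosages. With hundreds of lines and thousands to tens of
thousands of markers (p ≫ n), ridge regression is a workhorse: it shrinks
all marker effects toward zero, with the amount of shrinkage governed by
the regularization parameter λ. Prediction accuracy depends strongly on how
λ is chosen, and λ is almost always chosen by cross-validation over a
*grid* of candidate values. This package implements and compares two ways
of building that grid, embedded in a leakage-free nested cross-validation
protocol, together with a REML GBLUP comparator and a trait simulator so
that every claim can be checked without external data.

## The model

All penalized fits minimize the per-observation elastic-net objective

$$\frac{1}{2n}\sum_{i=1}^{n}\left(y_i - \beta_0 - x_i^\top\beta\right)^2 +
\lambda\left[\frac{1-\alpha}{2}\lVert\beta\rVert_2^2 +
\alpha\lVert\beta\rVert_1\right],$$

with mixing parameter α = 0 for ridge and α = 1 for the lasso. The
textbook penalized residual sum of squares (no 1/n factor) gives the same
solutions with its penalty equal to nλ; the per-observation convention is
adopted throughout because both grid constructions presuppose it — the
conventional path reproduces the internal recipe of `glmnet`, and the
variance-ratio grid equates λ to a per-observation variance-component
ratio. `fitPath()` documents and tests this mapping explicitly.

Training data are standardized with the *population* (divisor n, not
n − 1) convention for both markers and response. This matters: the
conventional grid's λ\_max formula is only exact under it, and after this
standardization the mean squared row norm of the marker matrix equals p
exactly, which is what gives the variance-ratio grid its closed form.

## The two grids

**Conventional path** (`conventionalGrid()`). From standardized training
data: per-column cross-products with the standardized response, scaled by
1000/n; λ\_max is their maximum; λ\_min.ratio is 0.01 when p > n and
10⁻⁴ otherwise; 100 values are placed log-equally between λ\_max and
λ\_min = λ\_max · λ\_min.ratio. The factor 1000 is reproduced literally:
it is the α = 0.001 surrogate that `glmnet` uses internally because the
true ridge λ\_max is infinite. The maximum is taken over the signed
cross-products; on standardized data these are the marker–trait
correlations, and the signed and absolute maxima coincide except in
adversarial cases where every correlation is negative.

**Variance-ratio grid** (`varianceRatioGrid()`). From a mixed-model view,
the optimal λ is the variance ratio σ²/σ²\_β. For a proportion R² of
phenotypic variance s²\_y explained by the genotypic effects,
σ² = (1 − R²)s²\_y and σ²\_β = R²s²\_y/m with
m = (1/n)Σᵢ xᵢᵀxᵢ, so

$$\lambda_l = \frac{(1-R^2_l)\,s_y^2}{R^2_l\,s_y^2 / m}
            = m\,\frac{1-R^2_l}{R^2_l},$$

where the R²\_l are 100 log-spaced proportions from 10⁻⁵ to 0.9999. The
phenotypic variance cancels exactly — the implementation evaluates the
cancelled form, accepts s²\_y anyway, and invariance of the grid to
rescaling the phenotype is part of the tested contract. After
standardization m = p exactly, so λ\_l = p(1 − R²\_l)/R²\_l. The m-term is
computed from the standardized training matrix; since s²\_y cancels, this
choice affects only the overall scale and keeps the derivation consistent
with the standardized-variance decomposition.

Two structural facts, both verified empirically by the test suite:

- the log-λ support of the conventional path is (essentially always)
  contained in the much wider support of the variance-ratio grid;
- the variance-ratio grid is log-uniform over most of its range but coarse
  at its small-λ end: the last R² step (0.89 → 0.9999) spans about three
  decades of λ. This is an inherent feature of mapping log-spaced R² to λ,
  and it is why the grid's advantage depends on where the cross-validation
  optimum falls (see *Known limitations*).

## The nested protocol

`innerCV()` tunes λ on an outer-training set: the grid is built **once**
from the full outer-training set (matching `cv.glmnet`'s behavior, and
stated as the compatibility target), while within each of the k = 10 inner
folds the standardization is refit on the inner-training block only, so no
validation information reaches any fitted quantity. Validation predictions
are back-transformed and squared errors are recorded per λ both as raw
sums and per-observation means; the selection criterion averages the
per-observation means so unequal folds weigh correctly, and exact ties go
to the largest λ (the more regularized model — `glmnet`'s convention; the
per-observation mean and the raw sum give the same minimizer for a fixed
fold layout). `refitFull()` then refits at the selected λ on the whole
outer-training set.

`outerEvaluate()` wraps this in 10-fold outer cross-validation. All
compared methods — both grids and the GBLUP comparator — consume identical
outer folds and identical inner seeds, so comparisons are paired per fold.
Metrics are computed on the observed phenotype scale: predictions are
back-transformed before Pearson correlation and NRMSE are taken, because
NRMSE's denominator (the mean of observed test values) is only meaningful
on the original scale. NRMSE is implemented as √MSE divided by the mean of
the observed test values; the un-rooted variant (MSE over the mean) is
exposed as a switch because the two readings differ only by the root and
cross-checks on real data may need either. Folds with a constant test
response yield an undefined correlation; these are marked missing, counted
and excluded from averages rather than aborting the run.

Reported summary tables use the sample (n − 1) SD convention consistently;
per-dataset SDs across a single trait are 0 by definition. Percent gains
are computed on fold-mean correlations per trait and then averaged.

## The GBLUP comparator

`vanRadenG()` builds G = ZZᵀ/c with Z the dosage matrix centered at twice
the allele frequencies and c = 2Σpⱼ(1 − pⱼ) (VanRaden method 1, stated
explicitly since it is usually only cited). Monomorphic markers contribute
zero to Z and are excluded from c. In cross-validation the frequencies are
estimated from the training partition by default (leakage control), with a
whole-data mode available since that is common practice.

`remlFit()` estimates the mixed model y = μ + g + ε, g ~ N(0, σ²\_g G), by
spectral profile REML: one eigendecomposition of the training block of G,
then a 1-D bounded search over log δ, δ = σ²/σ²\_g, on [10⁻⁹, 10⁹]. A
41-point coarse scan verifies the optimizer is bracketed away from the
search boundary (recorded in the fit; a boundary peak usually means a
degenerate variance component, as with an identity G). BLUPs for
unphenotyped lines are G\_test,train(G\_train,train + δI)⁻¹(y − μ̂).

GBLUP and marker ridge are the same model in different coordinates: with
G = ZZᵀ/c, GBLUP predictions at variance ratio δ equal ridge-on-Z
predictions at λ = δ·c/n under the per-observation objective. The test
suite asserts this identity to 10⁻⁶ on simulated instances; it is the
strongest available check that the two model families are implemented
coherently. A frequentist REML comparator is used rather than an MCMC one;
published comparisons show the two GBLUP variants agree to a few decimals,
so one comparator suffices.

## The simulator

`simulateGenotypes()` draws per-marker allele frequencies uniformly from
the MAF range (default 0.05–0.5) and generates two haplotypes per line as
first-order Markov chains whose transition probabilities preserve the
marginal frequencies while inducing a target adjacent-marker correlation
(`ldRho`, default 0). `simulatePhenotype()` draws Gaussian effects for a
random QTL subset and calibrates the error variance against the *sample*
variance of the genetic values, so the realized genetic variance share
equals the target h² exactly on the generated sample — chosen to keep
stochastic recovery tests sharp at small n. The default intercept of 10
keeps the trait mean well away from zero so the mean-normalized error
metric is well behaved. The null (h² = 0) construction zeroes all effects
and uses unit error variance.

`makeBenchmarkSuite()` fixes three scenarios used throughout the tests and
the acceptance script: *small* (n = 100, p = 500, h² = 0.3, 50 QTL),
*medium* (n = 300, p = 2000, h² = 0.5, 200 QTL) and *null* (n = 100,
p = 500, h² = 0). The QTL counts (10% of markers) make the traits
polygenic without being infinitesimal; sizes were chosen as desk-scale
stand-ins for real marker panels, which have n in the hundreds and p from
two thousand to tens of thousands. What the simulator does **not** emulate:
linkage-disequilibrium blocks unless requested (`ldRho` defaults to 0),
population structure, dominance/epistasis, and genotype missingness.
Passing tests therefore demonstrate correctness of the machinery and the
qualitative behavior of the grids under idealized sampling, not
quantitative reproduction of accuracies on real panels.

## Numerical choices

- Ridge paths are solved in closed form from one spectral decomposition
  per training set — of XᵀX/n when p ≤ n, of XXᵀ/n otherwise, which is the
  cheap side in the p ≫ n regime; zero eigencomponents at λ = 0 are
  dropped, giving the minimum-norm solution.
- Coordinate descent (α > 0, or on request for ridge) uses cyclical
  soft-thresholding updates with warm starts down the descending path,
  tolerance 10⁻⁷ on the maximum coefficient change, and a 10⁵-sweep cap;
  non-convergence warns and returns the best iterate with its convergence
  record. Cold starts are available and tested to agree within tolerance.
- The intercept is never penalized; it is obtained by centering, and on
  standardized data it is analytically zero (asserted to 10⁻¹⁰).
- Degenerate inputs fail loudly and early: all-constant marker matrices,
  constant phenotypes, nonpositive λ\_max (response orthogonal to every
  marker), zero mean squared row norm, non-PSD relationship matrices
  beyond −10⁻⁸ (ridge-stabilized by 10⁻⁶ with a warning).
- Zero-variance marker columns inside a fold are dropped with a warning
  and an index map rather than erroring, since cross-validation
  subsampling of real marker data routinely produces monomorphic columns.
  Missing genotypes are mean-imputed at the I/O boundary only, keeping the
  statistical core deterministic.
- Every function that uses randomness takes an explicit seed, derives any
  sub-seeds deterministically from it, and restores the caller's RNG
  state. Two runs from the same configuration are byte-identical.

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on simulated data:
solver oracles on 50 random instances up to 60 × 120; ridge–GBLUP
equivalence on instances up to ~100 lines × 150 markers; REML recovery on
10 replicates of 300 × 1000; the nested benchmark on the small and medium
scenarios (up to 300 × 2000) over 5 seeds. These sizes keep a full run in
the low minutes on one core while staying in the p ≫ n regime the methods
target.

## Known limitations

- The variance-ratio grid's coarse small-λ end means that when the
  cross-validation optimum falls inside the conventional path's (narrow
  but fine) range, the conventional path can resolve it better and the
  wider grid brings no benefit — we observe exactly this on small
  simulated panels with independent markers and moderate heritability,
  where the per-fold tuned-λ ratio of the two methods has no consistent
  sign. The wider grid pays off when the optimum lies *below* the
  conventional floor λ\_min = 0.01·λ\_max, the typical situation on dense
  real panels; users can also simply raise `nPoints`.
- The conventional generator always uses the ridge-style recipe above
  regardless of α; `glmnet`'s deviance-based early path termination is
  documented but deliberately not implemented — all grid values are always
  evaluated.
- Gaussian responses only; no observation weights or sparse storage.
- The one-standard-error selection rule and repeated cross-validation are
  out of scope.

## A worked example

```{r example, eval = FALSE}
suite <- makeBenchmarkSuite(seed = 1)
sc <- suite$medium
report <- outerEvaluate(sc$X, sc$y,
                        methods = c("conventional", "variance_ratio",
                                    "gblup"),
                        kOuter = 10, kInner = 10, seed = 1)
aggregateReports(list(report))$perTrait
lambdaRatioDiagnostic(report)
```

The same computation, plus REML heritability recovery and the exact grid
constants, is what `scripts/acceptance.R` reruns from scratch and writes
to JSON.
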