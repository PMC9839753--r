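---
title: "Discovering latent behavioral domains with phenofactor"
author: "phenofactor authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering latent behavioral domains with phenofactor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenofactor)
```

## The problem

Large behavioral batteries — the kind collected alongside neuroimaging in
population studies — yield dozens of questionnaire scores, task accuracies
and reaction times per subject. Before such a table can serve as a
prediction target or be related to brain measures, it needs a small set of
*robust, interpretable* summary dimensions. `phenofactor` implements a
complete workflow for finding them: exploratory factor analysis (EFA) with
principled dimensionality selection, a consensus clustering of the
variables as a discrete cross-check, a factor hierarchy that shows how
broad domains split as dimensionality grows, and confirmatory factor
analysis (CFA) on held-out subjects.

## The factor model

Each observed variable is modeled as a weighted sum of a few latent
factors plus variable-specific noise,

$$x_{i,v} \approx \sum_{f=1}^{k} l_{v,f}\,F_{f,i} + \epsilon_{i,v},$$

so that the covariance of standardized variables decomposes as
$\Sigma = L L' + U^2$ with a loading matrix $L$ and a diagonal uniqueness
matrix $U^2$. Fitting maximizes the Gaussian likelihood, which
`fitMlFactors()` does by minimizing the discrepancy

$$E = \tfrac{1}{2}\,\mathrm{tr}\big(((S - \Sigma)\Sigma^{-1})^2\big)$$

between the sample matrix $S$ and the model-implied $\Sigma$. The
optimizer works in two stages: a profile-likelihood pass over the
uniquenesses (conditionally optimal loadings come from the leading
eigenpairs of $U^{-1} S U^{-1}$, and the profiled deviance reduces to a
closed form over the trailing eigenvalues with an analytic gradient),
followed by a joint quasi-Newton polish of $(L, U^2)$ directly on $E$ with
its analytic gradient. The contract is the achieved discrepancy value, not
the optimization path; the test suite verifies the optimum against an
independent general-purpose minimizer started from the same point.

Numerical choices worth knowing:

* **Heywood guard.** Uniquenesses are floored at 0.005 (with a warning)
  rather than allowed to collapse to zero.
* **Single-indicator factors.** A factor carried by exactly one variable
  is not identified separately from that variable's uniqueness (only
  $l^2 + \psi$ enters $\Sigma$); such factor variance is folded back into
  the uniqueness, which is why a perfectly diagonal input yields loadings
  of exactly zero.
* **Sign and order conventions.** Factors are ordered by explained
  variance $EV_f = \sum_v l_{v,f}^2$ and signed so the largest-magnitude
  loading is positive; signs of loadings are otherwise arbitrary.
* **Rotation.** `varimaxRotate()` applies varimax (via `stats::varimax`)
  without Kaiser row normalization by default; a flag enables it.
  Rotation never changes communalities or the reconstructed $\Sigma$.

Subject-level factor scores use Bartlett's weighted least-squares
estimator $\hat F = X U^{-2} L (L' U^{-2} L)^{-1}$, which is conditionally
unbiased and univocal.

## Choosing the dimensionality

Three complementary criteria are computed for every candidate $k$:

1. **Parallel analysis** (`parallelAnalysis()`) bounds the search: shared
   variance per factor in the data is compared to the mean over 20
   pure-noise matrices of identical dimensions; the crossover index is the
   largest number of leading factors that still beat noise. The default
   comparison uses correlation eigenvalues; a `method = "ml"` option uses
   per-factor sums of squared ML loadings instead, since either reading is
   defensible and they agree on strong structure.
2. **Interpretability** (`interpretabilityCounts()`): every factor should
   have at least 3 variables with absolute loadings above 0.4 (absolute,
   because loading signs are arbitrary under orthogonal rotation).
3. **Robustness** (`robustnessSubsampling()`): factors are re-extracted on
   80% subject subsamples (1000 iterations by default), aligned to the
   full-data solution at the same $k$ with the Hungarian algorithm on a
   $1 - |r|$ cost, and summarized by the mean absolute pairwise
   correlation of each factor's loading vector across subsamples. The
   full-data solution is the alignment reference — some fixed reference is
   needed and it is the natural one. Surplus factors beyond the true
   dimensionality show visibly lower stability, which is the signature the
   diagnostic is designed to reveal.

`evaluateDimensionality()` assembles the three into a per-$k$ report and
flags candidates passing the interpretability and robustness thresholds;
model fit (percent variance explained) should then be as high as those
constraints allow. The final choice is deliberately left to the analyst.

## The factor hierarchy

`buildHierarchy()` fits solutions for $k = 1 \dots k_{max}$, computes
Bartlett scores at every level, and correlates scores between consecutive
levels. The absolute correlations are "flows" of variance from a parent
factor to its children — the data behind a Sankey diagram. On synthetic
data built so one broad domain carries two sub-domains, the broad factor's
two strongest outgoing edges lead exactly to its two children, which is
the qualitative pattern the diagnostic should expose.

## Consensus clustering

As a discrete counterpart to EFA, `consensusCluster()` subsamples 80% of
the *variables* 1000 times, K-means-clusters each subsample (variables
represented by their vectors over subjects; 10 restarts keeping the best
inertia), and records for each variable pair the **consensus index**: the
fraction of times the pair co-clustered out of the times it was co-drawn.
Diagnostics per $K$:

* the CDF of the off-diagonal indices and its **AUC** — computed here as
  the exact integral of the right-continuous empirical CDF over $[0, 1]$,
  so a perfectly binary half/half index distribution gives 0.5; the AUC
  levels off once $K$ reaches the true cluster count;
* **cluster consensus**: mean within-cluster index (singletons are
  defined as 1, with a warning);
* the **consensus score** $CS = \overline{ci}_{>1/K} -
  \overline{ci}_{\le 1/K}$: indices are split at the chance level $1/K$
  — indices exactly at chance go to the lower bin, the package's fixed
  convention — and the two bin means are differenced; an empty bin
  contributes 0. Near 0 when indices scatter around chance, 1 for
  perfect consensus. $CS$ peaks at the planted cluster count on
  block-structured data.

Final labels come from K-means on the rows of the consensus matrix (each
variable's consensus profile). Agreement between two labelings — e.g.
discovery vs replication halves — is quantified by the adjusted Rand
index and adjusted mutual information, both implemented from their
contingency-table definitions with hypergeometric chance correction and
verified against exhaustive oracles for all partitions of up to 6 items.

## Confirmatory factor analysis

`patternFromEfa()` turns a rotated EFA solution into a CFA pattern:
variables with $|l| > 0.45$ become indicators (free loadings), everything
else is fixed to zero, factor variances are fixed to 1, and factor
covariances are free by default (standard practice when variances carry
the scale; an orthogonal flag exists). `fitCfa()` minimizes
$F_{ML} = \mathrm{tr}(S\Sigma^{-1}) - \ln|S\Sigma^{-1}| - p$ with analytic
gradients; $\chi^2 = (n-1) F_{ML}$ (an $n$ multiplier is available), the
baseline is the independence model with closed-form
$\chi^2_B = -(n-1)\ln|R|$, and `fitIndices()` adds CFI, TLI, RMSEA (with
its 90% CI from inverting the noncentral $\chi^2$ CDF at 0.95/0.05 over
noncentralities in $[0, 10\chi^2]$), and SRMR over the $p(p+1)/2$ unique
standardized residuals. RMSEA carries the parsimony correction
$\max(\chi^2 - df, 0)$. Non-convergence is reported in the `converged`
slot rather than raised, since a non-converging model is itself a
finding. Input is analyzed as a correlation matrix — the data are z-scored
upstream.

## Preprocessing

The preprocessing stages mirror what a careful analyst does to a raw
battery, in this order: screening (numeric, under 10% missing, not a
composite, not an adjusted duplicate, at least one $|r| > 0.1$ with
another candidate — computed pairwise-complete *before* imputation, since
screening precedes completion in the workflow), a family-preserving split
(greedy by descending family size onto the smaller half with seeded
tie-breaks, so siblings never straddle discovery and replication),
chained-equation imputation (single completed dataset; 10 sweeps of
per-variable Bayesian regression draws — coefficient and residual-variance
posteriors plus prediction noise), confound regression on age and gender
(OLS residuals, exactly orthogonal to the predictors), sign-flip inversion
of error measures (a sign flip preserves the correlation magnitudes EFA
consumes and is an involution; reciprocal inversion is available), and
z-scoring (n−1 denominator).

A note on stochastic imputation: posterior-predictive draws add
legitimate noise, so imputation beats column-mean imputation in RMSE when
the masked variable is predictable enough ($R^2 > 0.5$ against the other
variables); the package's validation uses strongly correlated synthetic
variables, which is also the regime of real questionnaire batteries where
imputation matters.

## What the synthetic generator does and does not emulate

`generateFactorData()` draws i.i.d. standard-normal factor scores
(orthogonal in the population), Gaussian uniqueness noise, integer ages
uniform on 22–37, Bernoulli(0.5) gender, linear confound effects, MCAR
missingness strictly below 10% per variable, and singleton/sibling family
structures. This covers exactly the assumptions of the model being fitted,
which is the point: every downstream stage can be validated by parameter
recovery. It does **not** emulate ordinal response scales, floor/ceiling
effects, non-Gaussian heavy tails, missingness that depends on the data,
or genuinely hierarchical factor structures beyond the planted-split
designs used in the tests — so green tests certify the machinery, not the
adequacy of the linear-Gaussian model for any particular real battery.

## Problem sizes used in validation

The shipped checks run planted-recovery studies at 600 subjects and 40
variables (4 factors, block loadings 0.6–0.8), robustness with 100
subsamples, consensus with 200 iterations over $K = 2..8$ on 30 variables
in 3 blocks (within-block $r = 0.9$), and 50 Monte-Carlo CFA replicates at
$n = 600$; these sizes give stable Monte-Carlo margins for every
assertion while keeping a full run in the minutes range. The resampling
defaults exposed to users (1000 iterations) are the ones a real analysis
should use.

## Known limitations

* Orthogonal (varimax) rotation only; oblique rotations are out of scope.
* ML estimation assumes continuous, roughly Gaussian variables; ordinal
  CFA estimators (WLSMV and friends) are not provided.
* Multiple imputations are not pooled; one completed dataset per subset
  is analyzed, with the seed logged for auditability.
* The consensus machinery clusters variables, not subjects.

## A worked example

```{r example, eval = FALSE}
spec <- syntheticSpec(320, nFactors = 3, varsPerFactor = 6,
                      loading = 0.75, missingRate = 0.03, seed = 5)
tab <- generateFactorData(spec)$table
cfg <- pipelineConfig(seed = 2, robustnessIterations = 200,
                      consensusIterations = 200)
report <- runFullStudy(tab, cfg, outDir = "study-artifacts")
report
```

See the README for the output this prints and how to reproduce the
package's validation numbers.
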