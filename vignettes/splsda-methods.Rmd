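---
title: "Sparse PLS discriminant analysis: model, tuning and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse PLS discriminant analysis: model, tuning and diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splsda)
```

## The model

Given an $n \times p$ matrix $X$ of expression values or 0/1/2 genotype
counts, and $n$ samples partitioned into $K$ classes, the class membership
is recoded as an $n \times K$ dummy indicator block $Y$ (row $i$ has a
single 1 in the column of its class). PLS regression run against this
dummy block — PLS-DA — builds latent variables $\xi_h = X_h u_h$ that
maximize the covariance between a linear combination of features and the
class coding. The sparse variant constrains each $X$-side weight vector
$u_h$ with an $\ell_1$ penalty, so each dimension selects a small set of
discriminative features.

Each dimension solves a penalized rank-one approximation of the
cross-product matrix $M_h = X_h^\top Y_h$. Writing the soft-thresholding
operator $P_\lambda(x) = \mathrm{sign}(x)(|x| - \lambda)_+$, the fitting
loop alternates

$$u \leftarrow P_\lambda(M_h v) / \|P_\lambda(M_h v)\|_2, \qquad
  v \leftarrow M_h^\top u / \|M_h^\top u\|_2,$$

initialized at the dominant right singular vector of $M_h$. Only $u$ is
penalized: the dummy response block is left untouched, because the goal
is to select features, not classes. Rather than tuning $\lambda$
directly, the user states `keepX`, the number of features to retain on
each dimension; $\lambda$ is set internally to the $(\text{keepX}+1)$-th
largest entry of $|M_h v|$, which on tie-free data yields exactly `keepX`
nonzero weights. After convergence the latent score $\xi_h = X_h u_h$ and
the regression loadings $c_h = X_h^\top \xi_h / \xi_h^\top \xi_h$,
$d_h = Y_h^\top \xi_h / \xi_h^\top \xi_h$ are computed, and both blocks
are deflated in regression mode:
$X_{h+1} = X_h - \xi_h c_h^\top$, $Y_{h+1} = Y_h - \xi_h d_h^\top$.

Regression-mode deflation of both blocks was chosen because (i) it
guarantees that the latent scores are mutually orthogonal across
dimensions, and (ii) it supports the regression prediction formula. For a
new sample the normative prediction path repeats the training projection:
standardize with the *training* means and scales, then for
$h = 1 \dots H$ project onto $u_h$ and deflate with the training loading
$c_h$, accumulating $\hat Y = \bar y + \sum_h \xi_{new,h} d_h^\top$. The
closed form $\beta = U (C^\top U)^{-1} D^\top$ is provided as a
convenience and agrees with the sequential path to machine precision
(this equivalence is asserted in the test suite at $10^{-10}$); the
sequential path is normative because it remains defined even when
$C^\top U$ is singular. The literature prints this coefficient identity
with inconsistently assigned letters, so the package treats the
projection/deflation recursion — which is unambiguous — as the contract.

The predicted class under the default **max** rule is the column of the
largest predicted dummy value per row. **centroid** and **mahalanobis**
rules assign the nearest training-class centroid in latent-score space,
under the Euclidean or pooled within-class covariance metric. Argmax ties
break to the lowest class index for determinism.

## Parameters that matter

* `ncomp` ($H$) — number of latent dimensions. Default guidance is
  $H = K - 1$: with a $K$-column dummy response of rank $K - 1$ after
  centering, the cross-validated error typically stabilizes there.
  `choose_ncomp()` returns $K - 1$ without data, and with a CV result
  applies a one-sd elbow rule, never exceeding $K - 1$ unless the curve
  strictly improves beyond it (covering data where two classes are nearly
  indistinguishable and $K - 2$ suffices).
* `keepX` — features kept per dimension (unitless count, 1..p). A scalar
  is broadcast. Default is $p$, i.e. classical PLS-DA. Tuned by
  `cv_error()` over a grid, and corroborated by stability analysis.
* `scale` — unit-variance scaling of $X$ columns, on by default (the
  usual convention when features are on heterogeneous scales; genotype
  counts tolerate it too). Centering always happens. Both modes are
  supported because published PLS analyses differ on this point.
* Convergence: iteration stops when $\max_j |\Delta u_j| < 10^{-6}$, cap
  500 iterations (a warning is raised if hit). Initialization is the
  deterministic dominant singular vector, so refits are reproducible.
* Sign convention: the largest-magnitude entry of each $u_h$ is made
  positive (the sign of a singular pair is arbitrary).

## Tuning by cross-validation

`cv_error()` implements stratified $k$-fold cross-validation repeated
$r$ times (the conventional design is 10-fold averaged 10 times; the
examples in this package use 5-fold × 2–3 repeats, which keeps the full
suite fast at these sample sizes while leaving 10 × 10 available for real
analyses). Stratification keeps every class in every fold — necessary
when a class has only a handful of samples. Standardization and the model
are refit inside every training split, so no information leaks from
held-out samples. Errors are aggregated per fold and then averaged; the
reported sd is across the $k \times r$ fold errors. A fold draw that
would empty a class from some training split is redrawn with a derived
sub-seed and logged.

## Stability analysis

`stability_frequencies()` adapts the bolasso idea to per-dimension
selection: draw $B$ bootstrap samples of size $n$ (or half-samples of
size $\lfloor n/2 \rfloor$), refit the model on each with a fixed keepX,
and record the fraction of resamples in which each feature carries a
nonzero weight on the dimension under study. The procedure is sequential:
settle keepX for dimension 1, then condition on it (the *size*, not the
identities — each resample refits the entire model) while analysing
dimension 2, and so on. `stable_selection()` keeps either the top-$m$
features or all features above a frequency threshold ($t = 1$ is the
strict intersection rule). Frequencies on the later dimensions tend to
drop as the class structure is exhausted; this is exposed as a
diagnostic, not an automatic stopping rule, since no quantitative
criterion is well established.

Note one subtlety checked by the tests: under pure noise the *mean*
frequency across features equals keepX/$p$ exactly (every resample
selects exactly keepX features), but individual noise features can be
selected far more often than keepX/$p$, because every resample re-uses
the same data realization. Stability frequencies rank features within a
dataset; they are not p-values.

## The synthetic generators

`simulate_expression()` builds $K$ classes of Gaussian samples. The $q$
informative features are split into $K$ contiguous blocks; class $k$'s
mean is $\delta$ (in noise-sd units) on its own block and 0 elsewhere, so
the class mean patterns are orthogonal and discriminating all $K$ classes
genuinely requires about $K - 1$ latent dimensions. Within the
informative block an equicorrelation $\rho$ is induced by a shared
per-sample factor. The remaining $p - q$ features are independent noise.
Defaults: $K = 3$, 20 samples per class, $p = 500$, $q = 15$,
$\delta = 1.5$, $\rho = 0.5$, noise sd 1 — a moderately hard problem
where univariate ranking is unreliable but the multivariate signal is
recoverable (median support recovery across replicate datasets is above
90% at `keepX = 15` on two dimensions).

`simulate_snp()` draws genotypes as Binomial(2, $f$) counts of the mutant
allele, with $f$ = `base_maf` everywhere except class $k$'s informative
block, where $f$ = `base_maf + maf_shift` (clipped to [0.01, 0.99]).
For the package's SNP study condition the examples use $q = 400$ of
$p = 500$ SNPs informative with 50 samples per class: population-scale
genotype panels are characterized by many weakly informative markers
rather than a few strong ones, and with allele-frequency shifts of 0.15
a handful of informative SNPs carries too little information for *any*
classifier at these sample sizes (an oracle LDA restricted to the true
support still errs at ~37% under the expression-style defaults). The
K = 4 stabilization example likewise uses $\delta = 3$ with 4 informative
features per class, a construction where $K - 1$ dimensions demonstrably
suffice, so the CV curve's flattening at $K - 1$ is a property of the
method and not an artifact of residual signal.

What the generators do *not* emulate: intensity-dependent microarray
noise, batch effects, linkage disequilibrium between SNPs, or unbalanced
class priors. Passing tests on this synthetic family therefore shows
correct mechanics and calibration, not robustness to those real-data
phenomena; class-prior weighting in particular is out of scope.

## Numerical choices and degenerate inputs

* Ties in the soft-threshold boundary that would zero the whole weight
  vector trigger a hard fallback — keep the keepX largest entries
  unshrunk, lowest index first — with a warning. On continuous data this
  path has probability zero.
* A zero cross-product matrix ("no covariance left") is an error on the
  first dimension and an early stop with a warning on later ones, so
  `ncomp` beyond the informative rank degrades gracefully.
* Constant columns are an error when scaling is enabled (the offending
  feature ids are listed); missing values are rejected outright rather
  than imputed, because imputation policy is a study-level decision.
* The MAF filter keeps a SNP iff $\min(f, 1-f) >$ threshold, strictly:
  a MAF of exactly 0.05 is dropped at the 0.05 threshold.
* Model files are JSON with 17 significant digits, so every float
  round-trips exactly; plot tables regenerated from a reloaded model are
  identical to those from the fitted one.

## Worked example

```{r example}
sim <- simulate_expression(synthetic_spec(seed = 1))
fit <- splsda(sim$X, sim$labels, ncomp = choose_ncomp(sim$labels),
              keepX = 15)
fit

cv <- cv_error(sim$X, sim$labels, ncomp = 3, keepX_grid = c(5, 15, 50),
               k = 5, repeats = 2, seed = 2)
subset(cv$table, keepX == 15)

st <- stability_frequencies(sim$X, sim$labels, dimension = 1,
                            keepX_h = 15, B = 50, seed = 3)
head(sort(st$frequencies, decreasing = TRUE), 8)
```

The CV table reproduces the characteristic pattern: error drops sharply
from one to two dimensions ($K - 1 = 2$ here) and is flat afterwards, for
any keepX. The stability head shows planted features selected in a large
fraction of bootstrap resamples while noise features appear sporadically.

## Known limitations

Unbalanced classes are not reweighted (deliberately out of scope);
the maximum-distance rule can favor large classes. The keepX grid search
is marginal, not nested — the reported CV error at the chosen setting is
an optimistic estimate of generalization error. Only $X$-side selection
is implemented; symmetric two-block (canonical-mode) sparse PLS and
missing-data NIPALS are out of scope.
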