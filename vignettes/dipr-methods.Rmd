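---
title: "Differentially penalized regression: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differentially penalized regression: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipr)
```

## The prediction problem

Genomic prediction regresses a quantitative trait measured on n lines on a
large panel of m covariates with m >> n — here genome-wide dominant
presence/absence markers (scored 1/0) and seed metabolite profiles (NMR
bucket intensities).  Ordinary least squares is unusable in this regime;
ridge regression fits

$$ y = Xb + e, \qquad \hat b = (X'X + I\lambda)^{-1} X'y , $$

which minimizes $\sum_i (y_i - \sum_j b_j x_{ij})^2 + \lambda \sum_j b_j^2$.
Throughout the package the covariate columns are standardized to mean zero
and unit sample variance, the trait is centered (its mean is stored and
added back to predictions), and the intercept is unpenalized — realized by
centering rather than by an explicit intercept column, which leaves the
penalized fit unchanged.

## Why one penalty is not enough, and the DiPR reformulation

When two covariate sets of different predictive value (or simply different
size) are pooled under a single $\lambda$, the stronger set is shrunk too
much and the weaker too little, and the pooled model can be *worse* than the
better single set.  DiPR gives each block its own penalty,

$$ \min_b \; \lVert y - X_1 b_1 - X_2 b_2 \rVert^2
   + \lambda_a \lVert b_1 \rVert^2 + \lambda_b \lVert b_2 \rVert^2 , $$

and exploits the identity that this equals a *single*-penalty ridge on
rescaled blocks.  Writing $\lambda_a = \lambda / w$ and
$\lambda_b = \lambda / (1 - w)$ with $w \in [0, 1]$, a standard ridge on
$[\,c_1(w) X_1 \mid c_2(w) X_2\,]$ with penalty $\lambda$ recovers the
two-penalty solution via $b_1 = c_1 \tilde b_1$, $b_2 = c_2 \tilde b_2$.
Two conventions for the scale factors are implemented:

* **`sqrt-w`** (default): $c_1 = \sqrt{w}$, $c_2 = \sqrt{1 - w}$.  The
  single-penalty fit on the scaled matrix then minimizes the two-penalty
  objective *exactly* with penalties $\lambda / w$ and $\lambda / (1-w)$
  (substitute $\tilde b_1 = b_1 / \sqrt{w}$ into the penalty term).
* **`linear-w`**: $c_1 = w$, $c_2 = 1 - w$, the literal "regression on
  $wx$ with coefficient $b/w$" description; implied penalties
  $\lambda / w^2$ and $\lambda / (1-w)^2$.

The two conventions trace the same family of penalty *ratios* under a
reparametrization of $(w, \lambda)$, so grid searches explore equivalent
model families; the tests verify that matched penalty pairs give identical
predictions.  `sqrt-w` is the default because its penalty mapping is the
exact algebraic identity.  Special cases: $w = 1$ (or 0) drops block two
(one) entirely and reduces to single-block ridge; $w = 0.5$ reduces to
pooled ridge at penalty $2\lambda$ (`sqrt-w`) or $4\lambda$ (`linear-w`).

## Hyperparameter search and the nested drop-one protocol

Both $w$ and $\lambda$ are chosen by maximizing the leave-one-out
cross-validation correlation (CVC) over an exhaustive grid — $\lambda$ is
re-searched at every $w$, a full 2-D scan.  Because the default $w$ grid
(0 to 1 in steps of 0.05) contains 0, 0.5 and 1, the best cell can never
have a lower inner CVC than single-block or pooled ridge on the same folds.

Honest accuracy is then estimated with nested drop-one CV: each sample is
set aside in turn, the covariates are restandardized and the entire inner
search rerun on the remaining n − 1 samples, the model refit at the
selected $(w, \lambda)$ predicts the held-out sample, and the n collated
out-of-fold predictions are correlated with the observations.  At this
outer level the inner guarantee no longer holds — nested DiPR *can* fail to
beat the best single block — and an undefined correlation (e.g. a constant
trait) is reported as the status `"failed"`, not as an error.  The reported
average weight is the mean of the per-fold selections.  Refitting at the
selected hyperparameters (rather than averaging inner-fold models) was
chosen as the natural reading of using "the regression equation" from the
training set; per-fold averaging of $w$ likewise.

## Exact fast leave-one-out

With centered columns the ones vector is a null eigenvector of the centered
kernel $K = X_c X_c'$, so the hat matrix of ridge-with-intercept decomposes
as $H = \mathbf{1}\mathbf{1}'/n + X_c (X_c'X_c + I\lambda)^{-1} X_c'$ and
the classical shortcut $\hat y_{(-i)} = y_i - e_i / (1 - h_{ii})$ is
*algebraically exact* against n explicit refits (which recenter the
response per fold; column recentering is absorbed by the intercept).  What
the shortcut does not include is per-fold re-*scaling* of columns — that
would break exactness — so inner-loop standardization is fixed per outer
training fold, while the outer loop does restandardize (see below).

Computationally everything runs in the dual: per (fold, w) the combined
kernel $c_1^2 K_1 + c_2^2 K_2$ is eigendecomposed once and every $\lambda$
costs only $O(n^2)$, so one trait's full nested CV at n = 151 with ~1400
covariates and the default 21 × 25 grid takes on the order of a minute on
one CPU.  Eigenvalues are clamped at zero; for $\lambda > 0$ the leverages
satisfy $h_{ii} < 1$ strictly, so no division guard is needed.

## Preprocessing

Markers pass quality control once on the full data, before any
cross-validation: features with minor allele frequency below 0.01 (computed
over non-missing calls) are removed, then a greedy left-to-right scan drops
any marker whose squared Pearson correlation with a retained earlier marker
exceeds 0.95 (keeping the earlier column — an arbitrary but deterministic
tie-break; the retained partner is recorded).  Both filters are
unsupervised with respect to the trait, so applying them outside the CV
loop leaks nothing.  After standardization, missing marker calls become
zero — the column mean — and constant columns are zeroed and flagged.

Two points the pipeline leaves configurable because reasonable analysts
differ:

* `standardization_mode`: `"training-fold"` (default; statistics recomputed
  within each outer fold, no leakage) or `"full-data"` (fixed once — the
  variant an analysis that standardizes before CV would produce).
* `sd_denom`: sample (n − 1, default) versus population SD.
* The trait is centered but never variance-scaled; a CVC is scale-free, so
  scaling would only obscure the returned predictions.

## Grids and tie-breaks

* $w$: 0 to 1 in steps of 0.05 (21 values).  A finer step buys little: the
  CVC surface is flat near its optimum.
* $\lambda$: 25 points, log-uniform on $[10^{-3} m, \; 10^{3} m]$ where m
  is the number of columns the model sees.  Scaling by m keeps per-column
  shrinkage comparable between single-block and pooled searches.
* Ties: larger $\lambda$ first (the more shrunken model), then $w$ nearest
  0.5, then the smaller $w$.  Any deterministic rule would do; this one is
  fixed and documented.
* Undefined CVCs (zero-variance observed or predicted vector) are treated
  as $-\infty$ in searches and as the value `"failed"` in reports.

## The synthetic generator

Real marker/metabolite/trait data for a diversity panel cannot ship with
the package, so a seeded generator emulates the structure the methods
target, with defaults fixed at the panel's dimensions: n = 151 lines,
843 binary markers, 620 metabolite features.  Markers are independent
Bernoulli with presence frequency uniform in (0.05, 0.5) and 2% missing
calls (typical for dominant marker assays).  Metabolite features
exponentiate a latent Gaussian with AR(1) correlation 0.6 across adjacent
features, giving positive, right-skewed, locally correlated intensities
like binned NMR spectra.  The trait adds three mutually orthogonalized
components — 30 causal markers, 20 causal metabolite features, Gaussian
noise — each rescaled so the realized variance shares equal the requested
`signal_share1` and `h2` (defaults 0.5 and 0.5) exactly; total trait
variance is 1 around a baseline of 50.

What the generator does *not* emulate: linkage disequilibrium and pedigree
structure among markers, genotype-by-environment variation, metabolite
blocks that are biologically coupled to the markers (the two blocks are
generated independently, so their Mantel correlation is near zero by
construction), and NMR artifacts.  Passing tests on synthetic data
therefore demonstrate the *algorithms* — recovery of the signal-share
weighting, calibration, exactness identities — not field performance on
real panels.

## Problem sizes used by the test suite

The suite checks the closed form against a generic numerical minimizer on
dozens of small random instances, the LOO shortcut against explicit
refits, the boundary and convention identities at every default grid
penalty, weight recovery on 500 simulated datasets (n = 150, 200 + 200
covariates, 5 signal shares × 100 replicates, with a 10-point $\lambda$
grid), Mantel type-I calibration over 500 replicates at 199 permutations,
and one full nested CV at the panel scale (n = 151, 843 + 620 covariates,
21 × 25 grid).  These sizes were chosen so the whole suite runs in a few
minutes while each property is still measured at the scale where it is
informative.

## Known limitations

* Exactly two covariate blocks.  The reformulation extends to more blocks,
  but the multidimensional weight search grows combinatorially and is out
  of scope.
* Ridge (L2) only; no lasso variant, no mixed-model/kinship formulation.
* The Mantel comparison defaults to plain Euclidean distances between
  standardized profiles; cophenetic distances from average-linkage (UPGMA)
  trees are available via `upgma_cophenetic()` for analyses that want the
  "distance through the dendrogram" convention, since published practice
  varies between the two.
* Leave-one-out is the only CV scheme: it is deterministic (no fold RNG)
  and exact under the shortcut, but for very large n a k-fold variant
  would be cheaper than the n outer refits.
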