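---
title: "Poisson GLM-PCA by alternating Poisson regression: model, algorithm, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poisson GLM-PCA by alternating Poisson regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poispca)
```

## The model

Principal components analysis is poorly matched to sparse count data such
as single-cell RNA-seq gene-by-cell matrices: the implicit Gaussian error
model is wrong for small counts, and the mean–variance relationship of
counts is ignored.  GLM-PCA replaces the Gaussian model with an
exponential-family likelihood.  `poispca` implements the Poisson variant:
for an $n \times m$ count matrix $Y$ (rows $i$ are genes, columns $j$ are
cells),

$$
y_{ij} \sim \mathrm{Pois}(\lambda_{ij}), \qquad
\log \lambda_{ij} = h_{ij}, \qquad
H = U D V^\top + X B^\top + G Z^\top ,
$$

where $U$ ($n \times K$) and $V$ ($m \times K$) are gene and cell factors,
$D = \mathrm{diag}(d)$ holds non-negative scales, $X$ ($n \times p$) are
*known* gene-level covariates with *estimated* per-cell coefficients $B$
($m \times p$), and $Z$ ($m \times q$) are known cell-level covariates
with estimated per-gene coefficients $G$ ($n \times q$).  The defaults
$X = \mathbf{1}$ and $Z = \mathbf{1}$ give every cell an intercept (a log
size factor, absorbing sequencing depth) and every gene an intercept (its
baseline log expression).  The model is symmetric in rows and columns:
transposing $Y$ swaps $(U, X, B)$ with $(V, Z, G)$.

No orthogonality is imposed during fitting; after (or at any point during)
optimization, a PCA-like representation is recovered from the SVD of the
fitted $U V^\top$, giving orthonormal loadings, scales sorted
non-increasing, and cell scores $V D$ that play the role of principal
components.

## The fitting algorithm

Maximizing the Poisson log-likelihood

$$
\ell(U, V, B, G)
 = \sum_{ij}\left[ y_{ij} h_{ij} - e^{h_{ij}} \right] - \sum_{ij} \log y_{ij}!
$$

jointly over all parameters is a high-dimensional non-convex problem, but
it has a special structure: with the gene-side quantities $(U, G)$ fixed,
the parameters of different cells decouple, and each cell's parameters
$(V_{j\cdot}, B_{j\cdot})$ solve an ordinary Poisson GLM with log link —
response $y_{\cdot j}$, design $[\,U \mid X\,]$, offset $G Z_{j\cdot}^\top$.
Symmetrically for genes with cells fixed.  The fitter therefore alternates:

1. **Cell pass** — for each cell $j$ independently, update
   $(V_{j\cdot}, B_{j\cdot})$ by a fixed number of cyclic coordinate
   descent (CCD) cycles on its GLM, warm-started at the current values.
2. **Gene pass** — mirror image for each gene $i$, updating
   $(U_{i\cdot}, G_{i\cdot})$.
3. **Orthogonalization** — replace $(U, d, V)$ by the compact SVD of
   $U D V^\top$ (computed from the QR factors of $U$ and $V$ and a
   $K \times K$ SVD, never forming the $n \times m$ product), then fold
   $\sqrt{d}$ back into each factor so the optimizer continues to work
   with $d = \mathbf{1}$.

Each 1-d CCD update is a Newton step $\Delta_k = -g_k / c_k$ with gradient
$g_k = \sum_i D_{ik}(\mu_i - y_i)$ and curvature
$c_k = \sum_i D_{ik}^2 \mu_i$, safeguarded in three ways: the step is
clipped to $|\Delta| \le 8$ (one wild step could overflow $e^\eta$), it is
halved until the GLM objective does not increase (at most 20 halvings;
otherwise the coordinate keeps its value), and $\eta$ is clamped at 40
inside every exponential.  Because each coordinate update is
non-increasing in the negative log-likelihood, each GLM update is, each
pass is, and orthogonalization preserves $H$ exactly — so the outer trace
of log-likelihoods is non-decreasing by construction, not merely in
practice.  This monotonicity is the algorithm's central guarantee and is
asserted exactly in the test suite.

Full-vector IRLS is deliberately not used for the inner problems: its cost
grows quickly with $K$ (each update solves a $(K{+}p)$-dimensional least
squares per gene or cell), whereas a CCD cycle is $O(N(K{+}p))$.  IRLS
appears in the tests only, as an independent oracle (`stats::glm.fit`)
that the CCD solver must match to $10^{-6}$ in optimal log-likelihood.

Orthogonalizing every iteration is not cosmetic: it keeps the factor
basis well conditioned, which is what lets inexact coordinate-wise inner
solves make rapid progress.

### Sparsity and memory

All computations respect the sparsity of $Y$:

* The data term $\sum y_{ij} h_{ij}$ and the constant $\sum \log y_{ij}!$
  are accumulated over stored nonzeros only.
* The $\sum e^{h_{ij}}$ term is evaluated in column blocks of
  configurable width (default 128), so peak extra memory is
  $O(n \cdot \text{block\_width})$, never $O(nm)$.
* Each GLM touches its response only through cached cross-products
  $s_k = \sum_i D_{ik} y_i$ over the nonzero positions.

A profiling test on a $2000 \times 5000$ sparse fixture asserts that no
allocation approaches the dense $n \times m$ size.

Cell (and gene) sub-problems share no mutable state, so the passes are
embarrassingly parallel; `workers = w` forks the per-column loop, and
results are bitwise identical for any worker count because no randomness
or shared accumulation is involved.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `K` | — | Rank of the latent term; must satisfy $K \le \min(n, m)$. |
| `max_iters` | 100 | Outer iteration cap. |
| `tol` | $10^{-4}$ | Stop when the log-likelihood improves by less (absolute, nats). Any stopping rule here is somewhat arbitrary, so it is exposed rather than hard-wired; `Inf` runs no iterations. |
| `inner_cycles` | 4 | CCD cycles per GLM per outer iteration.  Inner solves are deliberately inexact — the outer loop revisits them — and monotonicity holds for any value. |
| `block_width` | 128 | Columns per block in likelihood evaluation; changes results only at summation-order rounding ($<10^{-10}$ relative). |
| `orthogonalize_every` | 1 | Orthogonalize each iteration; larger values trade conditioning for a little time. |
| `step_cap`, halvings, clamp | 8, 20, 40 | Safeguards of the 1-d Newton update (internal); chosen so that a single update can never overflow `exp` while leaving ordinary steps untouched. |
| `seed` | 1 | Controls the normal(0, 0.1) factor initialization; fits are deterministic given it. |

Coordinates are visited in fixed ascending order and initialization uses a
seeded generator, so runs are exactly reproducible across platforms and
worker counts.  Per-gene intercepts are initialized at
$\log\{(\text{row sum} + 1)/(m + 1)\}$, a lightly smoothed log mean, so
the first iterations start from a sensible baseline rather than zero.

## The synthetic-data generator

`simulate_counts()` draws from exactly the model above: gene baseline
log-means uniform on $[\log 0.01, \log 3]$ (most genes well below one
count per cell, as in UMI data), cell log size factors normal(0, 0.3)
(about a $\pm 2\times$ depth range), factor entries normal(0, 0.5), and
Poisson draws column by column with per-column seeds derived from the
master seed (reproducible and column-order independent).  At
$n = 1000, m = 500$ these defaults give a zero fraction around 0.70 and
pooled marginals that look overdispersed even though each entry is
Poisson — the overdispersion is exactly the low-rank heterogeneity.

What the generator does *not* emulate: technical batch effects, gene
length or capture-efficiency biases, zero inflation beyond the Poisson
model, or biological structure that is not low-rank (discrete clusters
enter only insofar as they admit a rank-$K$ log-mean representation).
Passing recovery tests on these simulations therefore demonstrates that
the optimizer recovers the generative structure when the model is
correct; it does not validate the Poisson low-rank model itself on real
data.

One consequence of honest Poisson sampling at these settings: a dataset
occasionally contains a gene with no nonzero counts.  Its log-mean MLE is
$-\infty$, so continued fitting drifts that intercept downward without
bound (harmlessly for the likelihood, badly for truth-recovery
correlations).  This is a property of the model, not the optimizer;
`poispca_init()` warns when empty genes are present, and the standard
practice of filtering all-zero genes before dimensionality reduction is
recommended.

## Numerical choices and degenerate inputs

* Duplicate triplets in input are summed; explicit zeros dropped.
* An all-zero design column in a GLM is skipped silently (its coefficient
  is not identifiable); non-finite or non-positive curvature (possible
  only via overflow) skips the coordinate with a warning.
* Rank-deficient covariate matrices and $K > \min(n,m)$ are rejected at
  initialization.
* Rank-deficient factor products yield trailing zero entries of $d$; the
  SVD-based orthogonalization handles them without special cases.
* Sign convention: after orthogonalization the largest-magnitude entry of
  each $U$ column is made positive, making output reproducible across
  LAPACK implementations.
* The log-likelihood reported everywhere includes the
  $-\sum \log y_{ij}!$ constant (computed once from the nonzeros), so
  values are true Poisson log-likelihoods comparable across tools.

## Scope of the validation suite

The test suite validates the fitting guarantees at desk scale, with sizes
chosen to keep the full suite around a minute: monotone likelihood on 25
simulated fits ($200 \times 300$, $K \in \{1,3,5\}$); CCD-vs-IRLS
agreement on 100 random GLMs ($N = 60$, $J \le 6$); closed-form intercept
optima; a $6 \times 6$ full-rank fit reaching the saturated model;
orthogonalization against a dense SVD on 50 random factor pairs;
truth recovery on $500 \times 400$ rank-2 simulations (5 seeds, 200
iteration budget); blocked-likelihood exactness and the allocation audit;
and worker-count invariance.  `scripts/acceptance.R` re-runs the same
computations end to end and writes the measured quantities as JSON.

## Known limitations

* Poisson likelihood only; no negative-binomial or zero-inflated variant.
* No deviance residuals and no projection of unseen cells onto a fitted
  basis.
* No automatic rank selection; choose $K$ and inspect `glance()` /
  per-cell log-likelihoods.
* The optimizer finds a local maximum; different seeds can reach
  different (usually nearby) solutions, as for any non-convex
  factorization.
* No acceleration (extrapolation) of the fixed-point iteration; the
  per-iteration cost is low but many iterations may be needed for tight
  tolerances on large data.
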