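# poispca

Poisson GLM-PCA for sparse count matrices, fitted by alternating Poisson
regression.

## What problem this solves

Dimensionality reduction is the first step of almost every single-cell
RNA-seq analysis, but ordinary PCA assumes Gaussian errors, which fit
sparse counts badly.  GLM-PCA replaces the Gaussian model with a count
likelihood.  `poispca` implements the Poisson variant: for a genes × cells
count matrix **Y** (n × m),

    y_ij ~ Pois(λ_ij),   log λ_ij = h_ij,
    H = U diag(d) Vᵀ + X Bᵀ + G Zᵀ

with gene factors **U** (n × K), cell factors **V** (m × K), scales d,
known gene covariates **X** with estimated per-cell coefficients **B**,
and known cell covariates **Z** with estimated per-gene coefficients
**G**.  The defaults X = 1 and Z = 1 give per-cell intercepts (log size
factors) and per-gene intercepts (baseline log expression).

Fitting maximizes the Poisson log-likelihood by **alternating Poisson
regression**: with the gene side fixed, each cell's parameters solve an
independent Poisson GLM (and vice versa), so the fitter alternates full
cell-wise and gene-wise passes, each sub-problem solved by cyclic
coordinate descent with safeguarded 1-d Newton updates, and
re-orthogonalizes the factors every iteration.  Every update is
guaranteed non-increasing in the negative log-likelihood, so the fit
trace is monotone by construction.  All computations use the sparse
representation of Y: no dense n × m array is ever allocated, and the
per-cell/per-gene fits parallelize across workers with bitwise-identical
results.

The package is for anyone reducing count matrices — bulk or single-cell
RNA-seq practitioners, or methods developers who need a transparent,
testable GLM-PCA reference with a simulation generator and ground-truth
scoring built in.

## Worked example

```r
library(poispca)

sim <- simulate_counts(n = 1000, m = 500, K = 3, seed = 42)
sim
#> Simulated Poisson GLM-PCA data: 1000 genes x 500 cells, K = 3, seed = 42
#>   nonzeros: 144243 (71.2% zero)

fit <- poispca(sim$Y, K = 3, seed = 42, max_iters = 50)
fit
#> Poisson GLM-PCA fit: 1000 genes x 500 cells, K = 3
#>   log-likelihood -333075.705419 after 10 outer iteration(s) (converged)
#>   scales d: 255.1, 231.2, 218.2

glance(fit)
#> # A tibble: 1 × 7
#>   n_genes n_cells     K   loglik iterations converged elapsed_seconds
#>     <int>   <int> <int>    <dbl>      <int> <lgl>               <dbl>
#> 1    1000     500     3 -333076.         10 TRUE                 5.05

head(tidy(fit, "cells"), 3)   # cell scores d_k * V_jk, the "PCs"
#> # A tibble: 3 × 3
#>   cell    component score
#>   <chr>       <int> <dbl>
#> 1 cell001         1  2.60
#> 2 cell002         1 -4.65
#> 3 cell003         1  1.25

recovery_score(sim, fit)      # correlation of true vs fitted log-means
#> [1] 0.9699
```

The simulation drew a 71%-zero count matrix from a known rank-3 model;
the fit converged in 10 monotone iterations (the trace is in
`fit$trace`), and the fitted log-mean matrix correlates 0.97 with the
generative truth.  `autoplot(fit)` scatterplots two components of the
cell scores; `to_pca(fit)` returns the orthonormal (U, d, V) triplet;
`per_cell_loglik(sim$Y, fit)` gives the per-cell fit diagnostic;
`export_factors(fit, "out/run")` writes the model as diff-able TSV.

A two-phase command line mirrors the library (`exec/poispca` in the
installed package):

```sh
poispca init --counts counts.mtx -K 10 --seed 1 --output-prefix run
poispca fit  --prefix run --max-iters 100 --workers 4
```

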