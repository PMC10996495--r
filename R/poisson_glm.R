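# Inner kernel: a single Poisson GLM with log link and offset, solved by
# cyclic coordinate descent (CCD) with safeguarded 1-d Newton updates.
# This is the sub-problem the alternating fitter solves once per gene and
# once per cell; it is internal (no exported surface).
#
# A problem is a list with fields
#   yi     0-based positions of nonzero responses
#   yx     nonzero response values
#   N      response length
#   D      N x J design matrix
#   offset length-N offset
#   beta   length-J current coefficients
# Minimizing f(beta) = sum_i [exp(eta_i) - y_i eta_i], eta = offset + D beta,
# is equivalent to maximizing the Poisson log-likelihood up to the constant
# sum log y!.

glm_problem <- function(y, D, offset = NULL, beta = NULL) {
  D <- as.matrix(D)
  storage.mode(D) <- "double"
  N <- nrow(D)
  if (is.list(y)) {
    yi <- as.integer(y$idx) - 1L
    yx <- as.double(y$val)
    stopifnot(y$N == N)
  } else {
    stopifnot(length(y) == N)
    nz <- which(y != 0)
    yi <- nz - 1L
    yx <- as.double(y[nz])
  }
  if (is.null(offset)) offset <- numeric(N)
  if (is.null(beta)) beta <- numeric(ncol(D))
  stopifnot(length(offset) == N, length(beta) == ncol(D),
            all(is.finite(D)), all(is.finite(offset)), all(is.finite(beta)),
            all(yx >= 0), all(yx == round(yx)))
  list(yi = yi, yx = yx, N = N, D = D,
       offset = as.double(offset), beta = as.double(beta))
}

# One full CCD cycle over coordinates 1..J.  Returns the updated problem
# plus the achieved objective decrease (always >= 0 by step-halving).
ccd_cycle <- function(problem, step_cap = 8, max_halvings = 20L,
                      eta_clamp = 40) {
  res <- ccd_fit_cpp(problem$yi, problem$yx, problem$D, problem$offset,
                     problem$beta, 1L, 0, step_cap, as.integer(max_halvings),
                     eta_clamp)
  warn_kernel(res)
  problem$beta <- res$beta
  list(problem = problem, eta = res$eta, decrease = res$decrease,
       objective = res$objective, max_change = res$max_change)
}

# Run CCD cycles until the max coefficient change drops below tol or
# max_cycles is reached.  Inner fits need not be exact: the outer
# alternating loop revisits every sub-problem.
fit_glm <- function(problem, max_cycles = 100L, tol = 1e-4, step_cap = 8,
                    max_halvings = 20L, eta_clamp = 40) {
  if (ncol(problem$D) == 0L)
    return(list(beta = problem$beta, objective = glm_objective(problem),
                cycles = 0L, decrease = 0))
  res <- ccd_fit_cpp(problem$yi, problem$yx, problem$D, problem$offset,
                     problem$beta, as.integer(max_cycles), tol, step_cap,
                     as.integer(max_halvings), eta_clamp)
  warn_kernel(res)
  list(beta = res$beta, objective = res$objective, cycles = res$cycles,
       decrease = res$decrease)
}

# f(beta) evaluated directly in R (used for J = 0 and in tests)
glm_objective <- function(problem, beta = problem$beta) {
  eta <- problem$offset +
    if (length(beta)) as.vector(problem$D %*% beta) else 0
  sum(exp(pmin(eta, 40))) - sum(problem$yx * eta[problem$yi + 1L])
}

warn_kernel <- function(res) {
  if (res$n_skipped > 0L)
    warning(sprintf("CCD skipped %d coordinate update(s) with non-positive or non-finite curvature",
                    res$n_skipped), call. = FALSE)
  if (res$n_clamped > 0L)
    warning(sprintf("CCD clamped %d linear-predictor value(s) at the exp overflow guard",
                    res$n_clamped), call. = FALSE)
  invisible(res)
}
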