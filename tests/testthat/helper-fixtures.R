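# Fixtures built in code: random factor models, dense oracles, and random
# Poisson GLM instances.  All deterministic given a seed.

rand_model <- function(n, m, K, p = 1L, q = 1L, seed = 1L, scale = 0.3) {
  set.seed(seed)
  poispca:::new_factor_model(
    U = matrix(rnorm(n * K, 0, scale), n, K),
    V = matrix(rnorm(m * K, 0, scale), m, K),
    d = if (K > 0) sort(abs(rnorm(K, 2, 1)), decreasing = TRUE) else numeric(0),
    X = if (p > 0) cbind(1, matrix(rnorm(n * (p - 1L), 0, scale), n, p - 1L))
        else matrix(0, n, 0L),
    B = matrix(rnorm(m * p, 0, scale), m, p),
    Z = if (q > 0) cbind(1, matrix(rnorm(m * (q - 1L), 0, scale), m, q - 1L))
        else matrix(0, m, 0L),
    G = matrix(rnorm(n * q, 0, scale), n, q))
}

# brute-force dense H = U diag(d) V' + X B' + G Z'
dense_H <- function(model) {
  H <- matrix(0, model$n, model$m)
  if (model$K > 0)
    H <- H + model$U %*% diag(model$d, model$K) %*% t(model$V)
  if (ncol(model$X) > 0) H <- H + model$X %*% t(model$B)
  if (ncol(model$Z) > 0) H <- H + model$G %*% t(model$Z)
  H
}

# draw counts from a model (dense; for small oracle instances only)
rand_counts <- function(model, seed = 1L) {
  set.seed(seed)
  H <- dense_H(model)
  matrix(rpois(length(H), exp(H)), nrow(H), ncol(H))
}

# dense-oracle Poisson log-likelihood
dense_loglik <- function(Y, model, include_constant = TRUE) {
  Y <- as.matrix(Y)
  H <- dense_H(model)
  sum(Y * H - exp(H)) - if (include_constant) sum(lgamma(Y + 1)) else 0
}

dense_loglik_per_cell <- function(Y, model, include_constant = TRUE) {
  Y <- as.matrix(Y)
  H <- dense_H(model)
  colSums(Y * H - exp(H)) -
    if (include_constant) colSums(lgamma(Y + 1)) else 0
}

# random well-conditioned Poisson GLM instance with offset
rand_glm_problem <- function(N, J, seed = 1L) {
  set.seed(seed)
  D <- cbind(1, matrix(rnorm(N * (J - 1L), 0, 0.5), N, J - 1L))
  beta_true <- rnorm(J, 0, 0.4)
  offset <- rnorm(N, 0, 0.3)
  y <- rpois(N, exp(pmin(offset + as.vector(D %*% beta_true), 5)))
  poispca:::glm_problem(y, D, offset)
}

# Poisson log-likelihood (with constant) of a GLM problem at coefficients b
glm_loglik <- function(problem, b) {
  eta <- problem$offset + if (length(b)) as.vector(problem$D %*% b) else 0
  y <- numeric(problem$N)
  y[problem$yi + 1L] <- problem$yx
  sum(stats::dpois(y, exp(eta), log = TRUE))
}

# independent IRLS oracle via stats::glm
irls_loglik <- function(problem) {
  y <- numeric(problem$N)
  y[problem$yi + 1L] <- problem$yx
  fit <- suppressWarnings(
    stats::glm.fit(problem$D, y, family = stats::poisson(),
                   offset = problem$offset))
  glm_loglik(problem, fit$coefficients)
}

expect_monotone_loglik <- function(trace, label = "trace") {
  ll <- trace$loglik
  if (length(ll) > 1L) {
    drops <- diff(ll) + 1e-8 * abs(ll[-1L])
    expect_true(all(drops >= 0), label = sprintf(
      "%s log-likelihood non-decreasing (worst drop %.3e)",
      label, min(diff(ll))))
  }
  invisible(trace)
}
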