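# The outer alternating Poisson regression loop.

test_that("initialization is deterministic and validates its configuration", {
  sim <- simulate_counts(30, 20, 2, seed = 4)
  m1 <- poispca_init(sim$Y, 3, seed = 11)
  m2 <- poispca_init(sim$Y, 3, seed = 11)
  expect_identical(m1, m2)
  expect_false(identical(m1$U, poispca_init(sim$Y, 3, seed = 12)$U))

  # K = 0: covariates-only model
  m0 <- poispca_init(sim$Y, 0)
  expect_equal(dim(m0$U), c(30L, 0L))
  expect_equal(m0$G[, 1], unname(log((Matrix::rowSums(sim$Y) + 1) / 21)))

  expect_error(poispca_init(sim$Y, 21), class = "poispca_config_error")
  expect_error(poispca_init(sim$Y, 2, gene_covariates = cbind(1, 1)[rep(1, 30), ]),
               class = "poispca_config_error")
})

test_that("intercept-only updates recover closed-form Poisson means", {
  sim <- simulate_counts(40, 15, 0, seed = 6)
  Y <- sim$Y

  # cell pass, K = 0, X = ones, G fixed at 0: B_j -> log(colMeans)
  m <- poispca_init(Y, 0, gene_intercept = FALSE)
  m$G <- matrix(0, 40, 0); m$Z <- matrix(0, 15, 0)  # drop gene side entirely
  up <- poispca:::update_cells(Y, m, inner_cycles = 60)
  expect_equal(up$B[, 1], unname(log(Matrix::colMeans(Y))), tolerance = 1e-8)

  # gene pass, K = 0, Z = ones, B fixed at 0: G_i -> log(rowMeans)
  m2 <- poispca_init(Y, 0, cell_intercept = FALSE)
  pos <- which(Matrix::rowSums(Y) > 0)  # zero rows have MLE at -inf
  up2 <- poispca:::update_genes(Y, m2, inner_cycles = 60)
  expect_equal(up2$G[pos, 1], unname(log(Matrix::rowMeans(Y))[pos]), tolerance = 1e-8)

  # constant-row data, gene-intercept-only model: fitted lambda equals the row value
  Yc <- matrix(rep(c(2, 5, 1), each = 1, times = 8), 3, 8, byrow = FALSE)
  fc <- poispca_fit(Yc, poispca_init(Yc, 0, cell_intercept = FALSE),
                    max_iters = 5, tol = 1e-10, inner_cycles = 50)
  lam <- exp(sapply(1:8, function(j) predict_column(fc$model, j)))
  expect_equal(lam, matrix(c(2, 5, 1), 3, 8), tolerance = 1e-7,
               ignore_attr = TRUE)
})

test_that("a single-column matrix reduces the cell pass to one GLM fit", {
  sim <- simulate_counts(25, 1, 1, seed = 8)
  m <- poispca_init(sim$Y, 1, seed = 2)
  up <- poispca:::update_cells(sim$Y, m, inner_cycles = 9)
  pr <- poispca:::glm_problem(as.vector(sim$Y[, 1]), cbind(m$U, m$X),
                              offset = as.vector(m$G %*% m$Z[1, ]),
                              beta = c(m$V[1, ], m$B[1, ]))
  ref <- poispca:::fit_glm(pr, max_cycles = 9, tol = 0)
  expect_equal(c(up$V[1, ], up$B[1, ]), ref$beta, tolerance = 1e-14,
               ignore_attr = TRUE)
})

test_that("updates are invariant to the number of workers", {
  sim <- simulate_counts(40, 30, 2, seed = 9)
  m <- poispca_init(sim$Y, 2, seed = 3)
  u1 <- poispca:::update_cells(sim$Y, m, inner_cycles = 3, workers = 1)
  u4 <- poispca:::update_cells(sim$Y, m, inner_cycles = 3, workers = 4)
  expect_identical(u1$V, u4$V)
  expect_identical(u1$B, u4$B)
  g1 <- poispca:::update_genes(sim$Y, u1, inner_cycles = 3, workers = 1)
  g4 <- poispca:::update_genes(sim$Y, u1, inner_cycles = 3, workers = 4)
  expect_identical(g1$U, g4$U)
  expect_identical(g1$G, g4$G)
})

test_that("orthogonalize matches the dense SVD oracle and preserves H", {
  # K = 1 normalization
  m1 <- rand_model(2, 2, K = 1, p = 0, q = 0, seed = 1)
  m1$U[, 1] <- c(2, 0); m1$V[, 1] <- c(0, 3); m1$d <- 1
  o1 <- orthogonalize(m1)
  expect_equal(o1$d, 6)
  expect_equal(abs(o1$U[, 1]), c(1, 0))
  expect_equal(abs(o1$V[, 1]), c(0, 1))

  for (seed in 1:6) {
    m <- rand_model(10, 8, K = 4, p = 0, q = 0, seed = seed, scale = 1)
    o <- orthogonalize(m)
    P <- m$U %*% diag(m$d, 4) %*% t(m$V)
    expect_equal(o$d, svd(P)$d[1:4], tolerance = 1e-12)
    expect_lt(max(abs(o$U %*% diag(o$d, 4) %*% t(o$V) - P)), 1e-10)
    expect_lt(max(abs(crossprod(o$U) - diag(4))), 1e-8)
    expect_lt(max(abs(crossprod(o$V) - diag(4))), 1e-8)
    expect_true(all(diff(o$d) <= 0) && all(o$d >= 0))
    # already-orthogonal input is a fixed point
    o2 <- orthogonalize(o)
    expect_equal(o2$U, o$U, tolerance = 1e-10)
    expect_equal(o2$d, o$d, tolerance = 1e-12)
  }
})

test_that("the outer loop monotonically improves the log-likelihood", {
  sim <- simulate_counts(60, 45, 2, seed = 13)
  fit <- poispca_fit(sim$Y, poispca_init(sim$Y, 2, seed = 13),
                     max_iters = 12, tol = 1e-9)
  expect_monotone_loglik(fit$trace)
  expect_s3_class(fit$trace, "tbl_df")
  expect_true(all(c("iteration", "loglik", "elapsed_seconds",
                    "max_coef_change") %in% names(fit$trace)))

  # fitting further never lowers the log-likelihood
  more <- poispca_fit(sim$Y, fit, max_iters = 3, tol = 1e-12)
  expect_gte(more$loglik, fit$loglik - 1e-8 * abs(fit$loglik))
  expect_monotone_loglik(more$trace)

  # infinite tolerance performs no iterations
  same <- poispca_fit(sim$Y, fit, max_iters = 5, tol = Inf)
  expect_identical(same$model, fit$model)
  expect_identical(nrow(same$trace), nrow(fit$trace))

  expect_error(poispca_fit(simulate_counts(10, 10, 1, seed = 1)$Y, fit),
               class = "poispca_config_error")
})

test_that("fitting the transpose gives the transposed model", {
  sim <- simulate_counts(30, 22, 2, seed = 17)
  f1 <- poispca_fit(sim$Y, poispca_init(sim$Y, 2, seed = 5),
                    max_iters = 6, tol = 1e-9)

  # same starting point mapped through the transpose symmetry
  m0 <- poispca_init(sim$Y, 2, seed = 5)
  mt <- poispca:::new_factor_model(U = m0$V, V = m0$U, d = m0$d,
                                   X = m0$Z, B = m0$G, Z = m0$X, G = m0$B)
  Yt <- Matrix::t(sim$Y)
  # gene/cell pass order swaps under transposition, so run the passes manually
  work <- mt
  for (it in 1:6) {
    work <- poispca:::update_genes(Yt, work, inner_cycles = 4)
    work <- poispca:::update_cells(Yt, work, inner_cycles = 4)
    work <- poispca:::fold_d(orthogonalize(work))
  }
  h1 <- matrix(poispca:::dense_h(f1$model), 30, 22)
  h2 <- matrix(poispca:::dense_h(work), 22, 30)
  expect_equal(h1, t(h2), tolerance = 1e-6)
})
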