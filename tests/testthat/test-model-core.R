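test_that("predict_column reproduces each linear-predictor term", {
  # intercept-only: h_.j is the cell intercept everywhere
  m0 <- rand_model(4, 3, K = 1, p = 1, q = 1, seed = 1)
  m0$U[] <- 0; m0$V[] <- 0; m0$d <- 0; m0$G[] <- 0
  m0$B[2, 1] <- 2
  expect_equal(predict_column(m0, 2), rep(2, 4))

  # rank-1 product, no covariates
  m1 <- rand_model(2, 3, K = 1, p = 0, q = 0, seed = 1)
  m1$U[, 1] <- c(1, 2); m1$V[, 1] <- c(0, 0, 3); m1$d <- 1
  expect_equal(predict_column(m1, 3), c(3, 6))

  # random model with all terms vs brute-force dense H
  m2 <- rand_model(4, 3, K = 2, p = 2, q = 2, seed = 7)
  H <- dense_H(m2)
  for (j in 1:3)
    expect_equal(predict_column(m2, j), H[, j])

  expect_error(predict_column(m2, 0), class = "poispca_config_error")
  expect_error(predict_column(m2, 4), class = "poispca_config_error")
})

test_that("log_likelihood matches hand-computed and dense-oracle values", {
  # 1x1 zero matrix, h = 0
  m <- rand_model(1, 1, K = 0, p = 0, q = 1, seed = 1)
  m$G[] <- 0
  expect_equal(log_likelihood(Matrix::sparseMatrix(i = integer(0),
                                                   j = integer(0), x = numeric(0),
                                                   dims = c(1, 1)), m), -1)
  # y = 1, h = 0: 1*0 - 1 - log(1!)
  expect_equal(log_likelihood(matrix(1), m), -1)
  # y = 2, h = log 2: 2 log 2 - 2 - log 2!
  m2 <- m; m2$G[] <- log(2)
  expect_equal(log_likelihood(matrix(2), m2), 2 * log(2) - 2 - log(2))

  # random sparse 20x30 vs dense evaluation, with and without the constant
  mod <- rand_model(20, 30, K = 3, p = 2, q = 2, seed = 11)
  Y <- rand_counts(mod, seed = 12)
  expect_equal(log_likelihood(Y, mod), dense_loglik(Y, mod), tolerance = 1e-12)
  expect_equal(log_likelihood(Y, mod, include_constant = FALSE),
               dense_loglik(Y, mod, include_constant = FALSE),
               tolerance = 1e-12)
})

test_that("blocked evaluation is invariant to block width and flags bad cells", {
  for (seed in 1:5) {
    n <- sample(5:60, 1); m <- sample(5:100, 1)
    mod <- rand_model(n, m, K = sample(0:3, 1), p = 1, q = 1, seed = seed)
    Y <- rand_counts(mod, seed = seed + 100)
    ref <- dense_loglik(Y, mod)
    expect_equal(log_likelihood(Y, mod), ref,
                 tolerance = 1e-9 * max(1, abs(ref)))
    lls <- vapply(c(1L, 7L, 128L, 4096L), function(w)
      log_likelihood(Y, mod, block_width = w), numeric(1))
    expect_true(max(abs(lls - lls[1])) <= 1e-10 * max(1, abs(lls[1])))
  }

  mod <- rand_model(5, 8, K = 1, p = 1, q = 1, seed = 3)
  mod$B[4, 1] <- NaN
  err <- tryCatch(log_likelihood(matrix(0, 5, 8), mod), error = identity)
  expect_s3_class(err, "poispca_numeric_error")
  expect_match(conditionMessage(err), "cell 4")
})

test_that("per-cell log-likelihood decomposes the total", {
  # one cell: the single element is the total
  mod1 <- rand_model(6, 1, K = 1, p = 1, q = 1, seed = 2)
  Y1 <- rand_counts(mod1, seed = 3)
  expect_equal(per_cell_loglik(Y1, mod1), log_likelihood(Y1, mod1))

  # all-zero counts with h = 0: each of m cells contributes -n
  n <- 5
  mz <- rand_model(n, 3, K = 0, p = 0, q = 1, seed = 1)
  mz$G[] <- 0
  expect_equal(per_cell_loglik(matrix(0, n, 3), mz), rep(-n, 3))

  # random instance: per-column dense oracle, and the sum matches the total
  mod <- rand_model(15, 25, K = 2, p = 1, q = 2, seed = 9)
  Y <- rand_counts(mod, seed = 10)
  pc <- per_cell_loglik(Y, mod, block_width = 4L)
  expect_equal(pc, dense_loglik_per_cell(Y, mod), tolerance = 1e-12)
  tot <- log_likelihood(Y, mod)
  expect_equal(sum(pc), tot, tolerance = 1e-9 * abs(tot))
})

test_that("log-likelihood is invariant under orthogonalization", {
  mod <- rand_model(12, 18, K = 3, p = 1, q = 1, seed = 21)
  Y <- rand_counts(mod, seed = 22)
  expect_equal(log_likelihood(Y, orthogonalize(mod)),
               log_likelihood(Y, mod), tolerance = 1e-10)
})
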