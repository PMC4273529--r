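test_that("exact linear systems are fitted exactly", {
  # single collinear column
  f1 <- fit_pls(matrix(c(0, 1, 2)), c(0, 2, 4), 1)
  expect_equal(f1$fitted, c(0, 2, 4), tolerance = 1e-12)
  expect_equal(f1$r2, 1, tolerance = 1e-12)
  # noise-free y = 2 x1 + 3 x2 recovered with 2 components
  set.seed(3)
  X <- cbind(x1 = rnorm(12), x2 = rnorm(12))
  y <- 2 * X[, 1] + 3 * X[, 2]
  f2 <- fit_pls(X, y, 2)
  expect_equal(unname(f2$coefficients), c(2, 3), tolerance = 1e-8)
  expect_equal(f2$r2, 1, tolerance = 1e-10)
})

test_that("NIPALS agrees with the Krylov-subspace PLS1 identity", {
  set.seed(11)
  X <- matrix(rnorm(20 * 50), 20, 50)
  y <- drop(X[, 1:5] %*% runif(5)) + rnorm(20, sd = 0.3)
  for (c_try in 1:4) {
    got <- fit_pls(X, y, c_try)
    want <- krylov_pls(X, y, c_try)
    expect_equal(got$fitted, want$fitted, tolerance = 1e-6)
    expect_equal(unname(got$coefficients), want$coefficients,
                 tolerance = 1e-6)
  }
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_pls(X, rep(1, 10), 1), "constant")
  expect_error(fit_pls(X, rnorm(10), 3), "rank")
  expect_error(fit_pls(X, rnorm(9), 1), "length")
  expect_error(fit_pls(X[1:3, ], rnorm(3), 2), "observations")
})

test_that("duplicate columns leave full-rank predictions unchanged", {
  # at the full component count the PLS fit reaches the least-squares
  # projection onto the column space, which a duplicated column preserves
  set.seed(5)
  X <- matrix(rnorm(15 * 4), 15, 4)
  y <- drop(X %*% c(1, -1, 0.5, 2)) + rnorm(15, sd = 0.1)
  f1 <- fit_pls(X, y, 4)
  f2 <- fit_pls(cbind(X, X[, 2]), y, 4)
  expect_equal(f1$fitted, f2$fitted, tolerance = 1e-8)
  Xnew <- matrix(rnorm(3 * 4), 3, 4)
  expect_equal(predict(f1, Xnew), predict(f2, cbind(Xnew, Xnew[, 2])),
               tolerance = 1e-8)
})

test_that("leave-one-out matches an explicit refit loop", {
  set.seed(21)
  sizes <- list(c(5, 1), c(8, 3), c(12, 6), c(30, 10))
  for (sz in sizes) {
    n <- sz[1]; p <- sz[2]
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X %*% rnorm(p)) + rnorm(n, sd = 0.2)
    c_use <- min(2L, p)
    got <- loo_cv(X, y, c_use)
    # independent loop with the Krylov-identity fitter
    preds <- vapply(seq_len(n), function(i) {
      fit <- krylov_pls(X[-i, , drop = FALSE], y[-i], c_use)
      sum(X[i, ] * fit$coefficients) + fit$intercept
    }, numeric(1))
    expect_equal(got$predictions, preds, tolerance = 1e-6)
    press <- sum((y - preds)^2)
    expect_equal(got$q2, 1 - press / sum((y - mean(y))^2), tolerance = 1e-6)
    expect_equal(got$sep, sqrt(press / (n - c_use - 1)), tolerance = 1e-6)
  }
  # 5-point univariate case against a literal hand loop
  x <- matrix(c(0, 1, 2, 3, 5)); y5 <- c(0.1, 0.9, 2.2, 2.8, 5.2)
  got5 <- loo_cv(x, y5, 1)
  hand <- vapply(1:5, function(i) {
    f <- fit_pls(x[-i, , drop = FALSE], y5[-i], 1)
    predict(f, x[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(got5$predictions, hand, tolerance = 1e-12)
})

test_that("cross-validated q2 behaves as a predictivity measure", {
  set.seed(9)
  # rank-3 predictors with y in their span: noise-free data at the true
  # dimension predicts perfectly
  T3 <- matrix(rnorm(20 * 3), 20, 3)
  X <- T3 %*% matrix(runif(18, -1, 1), 3, 6)
  y <- drop(T3 %*% c(2, -1, 1))
  expect_equal(loo_cv(X, y, 3)$q2, 1, tolerance = 1e-8)
  # y permuted against informative X: no predictivity (100 repetitions)
  qs <- vapply(1:100, function(i) loo_cv(X, sample(y), 2)$q2, numeric(1))
  expect_gt(mean(qs <= 0.3), 0.9)
  expect_error(loo_cv(X, y, 19), "n - 1")
  expect_error(loo_cv(X[1:2, ], y[1:2], 1), "3 observations")
})

test_that("component selection maximises q2 with ties toward fewer", {
  set.seed(31)
  # one-factor noise-free data
  t1 <- rnorm(15)
  X1 <- outer(t1, runif(4))
  y1 <- 2 * t1
  sel1 <- select_components(X1, y1, 3)
  expect_identical(sel1$ncomp_opt, 1L)
  expect_identical(select_components(X1, y1, 1)$ncomp_opt, 1L)
  # rank-1 data truncates the component table at the rank
  expect_identical(nrow(sel1$table), 1L)
  # the reported optimum attains the maximum of the table
  expect_equal(sel1$table$q2[sel1$table$ncomp == sel1$ncomp_opt],
               max(sel1$table$q2))
})

test_that("two-component latent structure is identified in most replicates", {
  set.seed(41)
  hits <- 0L
  n_rep <- 50L
  for (r in seq_len(n_rep)) {
    T2 <- matrix(rnorm(30 * 2), 30, 2)
    P <- matrix(runif(10 * 2, -1, 1), 10, 2)
    X <- T2 %*% t(P) + matrix(rnorm(300, sd = 0.05), 30, 10)
    y <- drop(T2 %*% c(1.5, -1)) + rnorm(30, sd = 0.02)
    if (select_components(X, y, 4)$ncomp_opt == 2L) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("broom methods expose the fit as tidy tables", {
  set.seed(2)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("b1", "b2", "b3")))
  y <- rnorm(10)
  f <- fit_pls(X, y, 2)
  td <- tidy(f)
  expect_identical(td$term, c("(Intercept)", "b1", "b2", "b3"))
  gl <- glance(f)
  expect_identical(names(gl), c("n", "ncomp", "r2", "see", "q2", "sep"))
  expect_identical(gl$n, 10L)
})
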