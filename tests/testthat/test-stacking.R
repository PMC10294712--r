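test_that("make_folds balances, stratifies, and respects groups", {
  f <- make_folds(20, V = 10, seed = 1)
  expect_equal(unname(sort(table(f))), rep(2L, 10), ignore_attr = TRUE)
  # stratification: each fold of size 2 gets one of each class
  y <- rep(c(0, 1), 10)
  fs <- make_folds(20, V = 10, seed = 2, strata = y)
  expect_true(all(tapply(y, fs, sum) == 1))
  # grouped rows (early/late pairs) never split across folds
  groups <- rep(1:10, each = 2)
  fg <- make_folds(20, V = 5, seed = 3, groups = groups,
                   strata = rep(c(0, 1), each = 10))
  expect_true(all(tapply(fg, groups, function(x) length(unique(x))) == 1))
  expect_identical(make_folds(33, V = 7, seed = 9),
                   make_folds(33, V = 7, seed = 9))
  expect_error(make_folds(5, V = 10), "exceeds")
})

test_that("constant learner's out-of-fold column is the training prevalence", {
  n <- 20
  y <- rep(c(0, 1), 10)
  X <- matrix(0, n, 2)
  folds <- make_folds(n, V = 5, seed = 1, strata = y)
  Z <- cv_predictions(X, y, "constant", folds)
  for (v in 1:5) {
    expect_equal(unique(Z[folds == v, "constant"]), mean(y[folds != v]))
  }
})

test_that("a perfectly separating feature yields out-of-fold accuracy 1", {
  vm <- toy_matrix(n = 30)
  folds <- make_folds(30, V = 10, seed = 2, strata = vm$y)
  Z <- cv_predictions(vm$X[, 1, drop = FALSE], vm$y, "glm", folds)
  expect_equal(dim(Z), c(30, 1))
  expect_true(all(Z >= 0 & Z <= 1))
  expect_equal(mean((Z[, 1] >= 0.5) == (vm$y == 1)), 1)
})

test_that("a failing learner is dropped with a warning, not a crash", {
  register_learner("broken",
                   fit = function(X, y, seed, hyper) stop("boom"),
                   predict = function(model, X) rep(0.5, nrow(X)))
  vm <- toy_matrix(n = 20)
  folds <- make_folds(20, V = 5, seed = 1, strata = vm$y)
  expect_warning(Z <- cv_predictions(vm$X, vm$y, c("glm", "broken"), folds),
                 "broken")
  expect_equal(colnames(Z), "glm")
})

test_that("nnls_solve matches the frozen reference solution", {
  # expected values computed once with an independent active-set solver
  # (scipy.optimize.nnls) and frozen
  A <- matrix(c(1.0, 0.8, 0.3, 0.9, 0.1, 0.5,
                0.2, 0.9, 0.7, 0.4, 0.8, 0.5,
                0.5, 0.1, 0.6, 0.2, 0.9, 0.5), ncol = 3)
  b <- c(1.2, 0.4, -0.3, 0.8, 0.6, 0.3)
  sol <- nnls_solve(A, b)
  expect_equal(sol$x, c(0.74974824, 0, 0.20367573), tolerance = 1e-6)
  expect_equal(sqrt(sol$rss), 0.8624262, tolerance = 1e-6)
})

test_that("nnls weights pick the exact column and ignore its complement", {
  y <- rep(c(0, 1), 8)
  Z <- cbind(a = y, b = 1 - y)
  expect_equal(nnls_weights(Z, y), c(1, 0), ignore_attr = TRUE)
  # single learner gets weight 1
  expect_equal(nnls_weights(Z[, 1, drop = FALSE], y), 1)
})

test_that("nnls solution beats every single-learner vertex (cone optimality)", {
  set.seed(17)
  for (rep in 1:10) {
    n <- 25; L <- 4
    y <- rbinom(n, 1, 0.5)
    Z <- matrix(runif(n * L), n, L)
    sol <- nnls_solve(Z, y)
    rss_vertex <- apply(Z, 2, function(col) sum((y - col)^2))
    expect_true(all(sol$rss <= rss_vertex + 1e-9))
    expect_true(all(sol$x >= 0))
  }
})

test_that("duplicated columns leave the ensemble prediction invariant", {
  y <- rep(c(0, 1), 10)
  set.seed(4)
  z <- pmin(pmax(y * 0.8 + runif(20, 0, 0.2), 0), 1)
  Z1 <- cbind(z, 1 - z)
  Z2 <- cbind(z, z, 1 - z)
  a1 <- nnls_weights(Z1, y)
  a2 <- nnls_weights(Z2, y)
  expect_equal(drop(Z1 %*% a1), drop(Z2 %*% a2), tolerance = 1e-8)
})

test_that("degenerate all-zero NNLS falls back to the best learner", {
  y <- c(1, 1, 1, 0)
  Z <- cbind(a = c(0, 0, 0, 0), b = c(0, 0, 0, 1))  # both anti-predictive
  a <- nnls_weights(Z, y, cv_risk = c(0.9, 0.99))
  expect_equal(a, c(1, 0), ignore_attr = TRUE)
})

test_that("fit_superlearner produces a convex combination and sane predictions", {
  vm <- toy_matrix(n = 40)
  fit <- fit_superlearner(vm$X, vm$y, library = c("glm", "lasso", "knn",
                                                  "constant"),
                          V = 10, seed = 5)
  expect_true(all(fit$weights >= 0))
  expect_equal(sum(fit$weights), 1)
  expect_true(all(is.finite(fit$cv_risk)))
  # noise-free-ish separable toy: training classification is perfect
  expect_equal(mean(classify(predict(fit, vm$X)) == vm$y), 1)
  # constant library predicts the prevalence everywhere
  fitc <- fit_superlearner(vm$X, vm$y, library = "constant", V = 5, seed = 1)
  expect_equal(unique(predict(fitc, vm$X)), mean(vm$y))
  # determinism
  fit2 <- fit_superlearner(vm$X, vm$y, library = c("glm", "lasso", "knn",
                                                   "constant"),
                           V = 10, seed = 5)
  expect_identical(fit$weights, fit2$weights)
  expect_identical(fit$oof, fit2$oof)
  expect_error(fit_superlearner(vm$X, rep(1, 40)), "single class")
})

test_that("rf and ridge learners fit and predict probabilities", {
  vm <- toy_matrix(n = 40)
  for (lib in c("rf", "ridge")) {
    fit <- fit_superlearner(vm$X, vm$y, library = lib, V = 5, seed = 3)
    p <- predict(fit, vm$X)
    expect_true(all(p >= 0 & p <= 1))
    expect_gt(mean(classify(p) == vm$y), 0.85)
  }
})

test_that("out-of-fold discipline: a row's fold content does not leak into it", {
  vm <- toy_matrix(n = 30)
  folds <- make_folds(30, V = 5, seed = 8, strata = vm$y)
  Z <- cv_predictions(vm$X, vm$y, "glm", folds, seed = 2)
  # flip the outcome of every row in fold 1: fold-1 predictions are computed
  # by models trained on folds 2..5, so they cannot change
  y2 <- vm$y
  y2[folds == 1] <- 1 - y2[folds == 1]
  Z2 <- cv_predictions(vm$X, y2, "glm", folds, seed = 2)
  expect_equal(Z[folds == 1, 1], Z2[folds == 1, 1])
  # but other folds' predictions do change (the models saw the flip)
  expect_false(isTRUE(all.equal(Z[folds != 1, 1], Z2[folds != 1, 1])))
})
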