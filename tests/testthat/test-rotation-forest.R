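sep_toy <- function(n = 60, p = 6, seed = 2) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  y <- as.integer(x[, 1] > 0)
  x[, 1] <- x[, 1] + ifelse(y == 1, 3, -3)   # wide margin: separable
  list(x = x, y = y)
}

test_that("rotation forest fits a separable toy exactly", {
  toy <- sep_toy()
  fit <- rotation_forest(toy$x, toy$y, n_trees = 10, seed = 1)
  expect_s3_class(fit, "rotation_forest")
  expect_equal(mean(predict(fit, toy$x) == toy$y), 1.0)
})

test_that("rotation blocks are orthonormal and off-block entries exactly zero", {
  toy <- sep_toy()
  fit <- rotation_forest(toy$x, toy$y, n_trees = 5, seed = 3)
  for (i in seq_along(fit$trees)) {
    for (B in fit$blocks[[i]])
      expect_lt(max(abs(crossprod(B) - diag(ncol(B)))), 1e-8)
    R <- rotation_matrix(fit, i)
    mask <- matrix(FALSE, fit$p, fit$p)
    for (g in fit$partitions[[i]]) mask[g, g] <- TRUE
    expect_true(all(R[!mask] == 0))
    # partition covers all features exactly once
    expect_setequal(unlist(fit$partitions[[i]]), seq_len(fit$p))
  }
})

test_that("prediction is the average of per-tree distributions", {
  toy <- sep_toy()
  fit1 <- rotation_forest(toy$x, toy$y, n_trees = 1, seed = 5)
  # with L = 1 the ensemble score equals the single tree's estimate
  xr <- toy$x %*% rotation_matrix(fit1, 1)
  df <- data.frame(xr)
  colnames(df) <- paste0("R", seq_len(ncol(xr)))
  manual <- predict(fit1$trees[[1]], df, type = "prob")
  expect_equal(unname(predict(fit1, toy$x, type = "prob")), unname(manual))

  fit <- rotation_forest(toy$x, toy$y, n_trees = 7, seed = 5)
  probs <- predict(fit, toy$x, type = "prob")
  expect_equal(unname(rowSums(probs)), rep(1, nrow(toy$x)))
  # class labels agree with arg-max of the confidences
  expect_equal(predict(fit, toy$x),
               colnames(probs)[max.col(probs, ties.method = "first")])
})

test_that("fits are deterministic in the seed and sensitive to it", {
  toy <- sep_toy(n = 80)
  f1 <- rotation_forest(toy$x, toy$y, n_trees = 6, seed = 7)
  f2 <- rotation_forest(toy$x, toy$y, n_trees = 6, seed = 7)
  newx <- matrix(rnorm(20 * 6), 20, 6)
  expect_identical(predict(f1, newx, type = "prob"),
                   predict(f2, newx, type = "prob"))
  f3 <- rotation_forest(toy$x, toy$y, n_trees = 6, seed = 8)
  expect_false(identical(rotation_matrix(f1, 1), rotation_matrix(f3, 1)))
})

test_that("degenerate inputs are handled per the model contract", {
  toy <- sep_toy()
  expect_error(rotation_forest(toy$x, rep(1, nrow(toy$x))), "2 classes")
  fit <- rotation_forest(toy$x, toy$y, n_trees = 3, seed = 1)
  expect_error(predict(fit, toy$x[, 1:4]), "expects")
  # zero-variance subset falls back to an identity block
  xz <- cbind(toy$x[, 1:3], 0, 0, 0)
  fz <- rotation_forest(xz, toy$y, n_trees = 3, subset_size = 3, seed = 2)
  expect_equal(mean(predict(fz, xz) == toy$y), 1.0)
  for (i in 1:3)
    expect_lt(max(abs(crossprod(rotation_matrix(fz, i)) - diag(6))), 1e-8)
})

test_that("rotation improves over a single unrotated tree on planted data", {
  # pair-level planted signal, small scale: mean 10-fold accuracy of the
  # forest vs an axis tree, majority of seeds
  wins <- 0
  for (s in 1:5) {
    set.seed(s)
    n <- 200
    x <- matrix(rnorm(n * 8), n, 8)
    eta <- rowSums(x[, 1:3]) * 1.5
    y <- stats::rbinom(n, 1, stats::plogis(eta))
    if (length(unique(y)) < 2) next
    fold <- stratified_folds(y, 5, s)
    acc_rf <- acc_tree <- 0
    for (f in 1:5) {
      tr <- fold != f
      fit <- rotation_forest(x[tr, ], y[tr], n_trees = 15, seed = s)
      acc_rf <- acc_rf + mean(predict(fit, x[!tr, ]) == y[!tr])
      tree <- rpart::rpart(y ~ ., data = data.frame(y = factor(y[tr]), x[tr, ]),
                           method = "class")
      acc_tree <- acc_tree +
        mean(predict(tree, data.frame(x[!tr, ]), type = "class") == y[!tr])
    }
    if (acc_rf >= acc_tree) wins <- wins + 1
  }
  expect_gte(wins, 3)
})
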