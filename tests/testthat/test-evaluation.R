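test_that("confusion counts and the metric identities hold", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(cc, c(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")

  perfect <- classification_metrics(c(TP = 50, FP = 0, TN = 50, FN = 0))
  expect_equal(unname(perfect[c("Acc", "MCC")]), c(1, 1))

  m <- classification_metrics(c(TP = 40, FP = 5, TN = 45, FN = 10))
  expect_equal(m[["Acc"]], 0.85)
  expect_equal(m[["Sen"]], 0.8)
  expect_equal(m[["Sp"]], 0.9)
  expect_equal(m[["Pre"]], 8 / 9)
  expect_equal(m[["MCC"]], 1750 / sqrt(55 * 45 * 50 * 50))

  deg <- classification_metrics(c(TP = 0, FP = 0, TN = 10, FN = 5))
  expect_equal(deg[["Pre"]], 0)
  expect_true("Pre" %in% attr(deg, "degenerate"))
})

test_that("metrics of self-prediction are perfect for any non-degenerate labels", {
  set.seed(1)
  for (i in 1:20) {
    y <- sample(0:1, 30, replace = TRUE)
    if (length(unique(y)) < 2) next
    m <- classification_metrics(confusion(y, y))
    expect_equal(unname(m[c("Acc", "MCC")]), c(1, 1))
  }
})

test_that("AUC matches limits, the hand example, and the pairwise oracle", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1))$auc, 0.75)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")

  set.seed(23)
  for (i in 1:50) {
    y <- c(rep(1, 8), rep(0, 9))
    s <- sample(seq(0, 1, by = 0.1), 17, replace = TRUE)  # many ties
    expect_equal(roc_auc(y, s)$auc, ora_auc(y, s))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(3)
  y <- sample(0:1, 40, replace = TRUE, prob = c(0.6, 0.4))
  s <- rnorm(40)
  a0 <- roc_auc(y, s)$auc
  expect_equal(roc_auc(y, exp(s))$auc, a0)
  expect_equal(roc_auc(y, 5 * s - 2)$auc, a0)
  expect_equal(roc_auc(y, stats::plogis(s))$auc, a0)
})

test_that("AUC and ROC agree with an established reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  y <- sample(0:1, 60, replace = TRUE)
  s <- rnorm(60) + y
  mine <- roc_auc(y, s)
  ref <- suppressMessages(pROC::roc(y, s, direction = "<"))
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)))
  expect_true(all(diff(mine$roc_points$fpr) >= 0))
  expect_true(all(diff(mine$roc_points$tpr) >= 0))
})

test_that("stratified folds partition rows and balance classes", {
  set.seed(2)
  y <- c(rep(1, 33), rep(0, 67))
  fold <- stratified_folds(y, 10, seed = 4)
  expect_equal(sort(unique(fold)), 1:10)
  expect_length(fold, 100)
  for (f in 1:10) {
    frac <- mean(y[fold == f])
    expect_lt(abs(frac - 0.33), 1 / 10 + 1e-9)
  }
  expect_identical(fold, stratified_folds(y, 10, seed = 4))
  expect_false(identical(fold, stratified_folds(y, 10, seed = 5)))
})

test_that("independent split is stratified, disjoint and exhaustive", {
  set.seed(6)
  X <- matrix(rnorm(100 * 4), 100, 4,
              dimnames = list(sprintf("D%02d|P%02d", 1:100, 1:100), NULL))
  colnames(X) <- paste0("f", 1:4)
  y <- rep(c(0L, 1L), each = 50)
  pairs <- list(X = X, y = y,
                pair_ids = data.frame(drug_id = as.character(1:100),
                                      protein_id = as.character(1:100)))
  class(pairs) <- "dti_pairs"
  sp <- independent_split(pairs, 0.9, seed = 7)
  expect_equal(nrow(sp$train$X), 90)
  expect_equal(nrow(sp$independent$X), 10)
  expect_setequal(c(rownames(sp$train$X), rownames(sp$independent$X)),
                  rownames(X))
  expect_equal(sum(sp$independent$y), 5)
  sp2 <- independent_split(pairs, 0.9, seed = 7)
  expect_identical(rownames(sp$independent$X), rownames(sp2$independent$X))
})

test_that("k-fold cross-validation nests fitting inside training folds", {
  set.seed(12)
  n <- 120
  X <- matrix(rnorm(n * 6), n, 6)
  colnames(X) <- paste0("f", 1:6)
  y <- as.integer(X[, 1] + X[, 2] > 0)
  rownames(X) <- sprintf("D%03d|P%03d", 1:n, 1:n)
  pairs <- structure(list(X = X, y = y,
                          pair_ids = data.frame(drug_id = as.character(1:n),
                                                protein_id = as.character(1:n))),
                     class = "dti_pairs")
  rep <- kfold_cv(pairs, k = 5, seed = 3, rf = list(n_trees = 8))
  expect_s3_class(rep, "dti_eval")
  expect_equal(nrow(rep$per_fold), 5)
  expect_length(rep$fold, n)
  expect_true(all(c("Acc", "Sen", "Sp", "Pre", "MCC", "AUC") %in%
                    names(rep$fold_mean)))
  expect_gt(rep$auc, 0.8)                 # clean linear signal
  expect_error(kfold_cv(pairs, k = 80, seed = 1), "at least k")
})
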