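test_that("entropy, discretization and SU behave on canonical cases", {
  expect_equal(shannon_entropy(c(0, 1)), 1)
  expect_equal(shannon_entropy(c(1, 1, 1)), 0)
  expect_equal(shannon_entropy(c(0, 0, 1, 1, 1, 1)),
               -(1/3) * log2(1/3) - (2/3) * log2(2/3))

  expect_equal(discretize(c(0, 1, 2, 3), bins = 2), c(1L, 1L, 2L, 2L))
  expect_equal(discretize(rep(4.2, 10), bins = 5), rep(1L, 10))
  expect_equal(discretize(c(0, 1, 0, 1), bins = 5), c(1L, 2L, 1L, 2L))

  expect_equal(symmetric_uncertainty(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
  expect_equal(symmetric_uncertainty(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_equal(symmetric_uncertainty(c(0, 0, 0, 1), c(0, 0, 1, 1)),
               ora_su(c(0, 0, 0, 1), c(0, 0, 1, 1)))
  expect_error(symmetric_uncertainty(c(0, 1), c(0, 1, 1)), "equal length")
})

test_that("SU is symmetric and bounded on random discrete pairs", {
  set.seed(13)
  for (i in 1:200) {
    f <- sample(0:3, 30, replace = TRUE)
    c <- sample(0:2, 30, replace = TRUE)
    su <- symmetric_uncertainty(f, c)
    expect_gte(su, 0)
    expect_lte(su, 1)
    expect_equal(su, symmetric_uncertainty(c, f))
    expect_equal(su, ora_su(f, c))
  }
})

test_that("SU ranking orders by weight with index tie-breaks", {
  set.seed(31)
  y <- rep(0:1, each = 25)
  X <- cbind(noise1 = rnorm(50), dup = rnorm(50), label = as.numeric(y))
  X <- cbind(X, dup2 = X[, "dup"])
  rk <- rank_features(X, y)
  expect_equal(rk$ranking[1], 3L)          # column equal to y ranks first
  expect_equal(rk$su[["label"]], 1)
  # identical columns: smaller index first
  expect_lt(which(rk$ranking == 2), which(rk$ranking == 4))

  perm <- c(3, 1, 4, 2)
  rk2 <- rank_features(X[, perm], y)
  expect_equal(rk$su[perm], rk2$su, ignore_attr = TRUE)
})

test_that("IWSSR keeps a perfect feature and traces monotone accepted scores", {
  set.seed(17)
  n <- 200
  y <- rep(0:1, each = n / 2)
  X <- cbind(matrix(rnorm(n * 5), n, 5), perfect = as.numeric(y))
  colnames(X) <- c(paste0("noise", 1:5), "perfect")
  sel <- iwssr_select(X, y, seed = 3)
  expect_true("perfect" %in% sel$feature_names)
  expect_equal(sel$best_score, 1.0)
  expect_false(anyDuplicated(sel$selected) > 0)
  expect_lte(length(sel$selected), ncol(X))
  acc <- sel$trace$score[sel$trace$action != "reject"]
  expect_true(all(diff(acc) > 0))
})

test_that("the replacement step swaps out a weaker feature (exhaustive-oracle check)", {
  # score-table evaluator isolates the search mechanics: ranked order c, a, b;
  # the pair {a, b} is jointly best and c must be swapped out on the way
  scores <- list("1" = 0.60, "2" = 0.65, "3" = 0.50,
                 "1,2" = 0.66, "1,3" = 0.62, "2,3" = 0.95,
                 "1,2,3" = 0.90)
  evalr <- function(S) scores[[paste(sort(S), collapse = ",")]]
  X <- matrix(0, 4, 3)  # shape carrier only; ranking supplied explicitly
  colnames(X) <- c("c", "a", "b")
  rk <- structure(list(su = c(c = 0.9, a = 0.5, b = 0.1), ranking = 1:3),
                  class = "su_ranking")
  sel <- iwssr_select(X, c(0, 0, 1, 1), evaluator = evalr, ranking = rk)

  # exhaustive search over all non-empty subsets
  subsets <- unlist(lapply(1:3, function(k)
    combn(3, k, simplify = FALSE)), recursive = FALSE)
  best <- subsets[[which.max(vapply(subsets, evalr, numeric(1)))]]
  expect_setequal(sel$selected, best)
  expect_false(1L %in% sel$selected)       # the weak high-SU feature is gone
  expect_equal(sel$best_score, 0.95)
  expect_equal(sel$trace$action, c("add", "swap", "add"))
})

test_that("the default tree evaluator is deterministic given its seed", {
  set.seed(5)
  X <- matrix(rnorm(300), 100, 3)
  y <- as.integer(X[, 1] > 0)
  ev <- make_tree_evaluator(X, y, seed = 11)
  expect_equal(ev(1L), ev(1L))
  expect_gte(ev(1L), 0.9)
  expect_lte(ev(3L), ev(1L))
})
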