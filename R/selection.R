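#' Shannon entropy (base 2) of a discrete vector
#'
#' @param x Discrete (integer/factor/character) vector.
#' @return Entropy in bits; `0 * log(0)` terms contribute 0.
#' @export
shannon_entropy <- function(x) {
  stopifnot(length(x) > 0)
  p <- tabulate(as.integer(factor(x)))
  p <- p[p > 0] / length(x)
  -sum(p * log2(p))
}

#' Equal-width discretization of a numeric feature
#'
#' Features with at most `bins` distinct values pass through unchanged (their
#' values are recoded to consecutive integers); otherwise values are cut into
#' `bins` equal-width intervals between the minimum and maximum. Constant
#' features map to a single bin.
#'
#' @param x Numeric vector.
#' @param bins Number of bins (>= 2).
#' @return Integer vector of bin codes.
#' @export
discretize <- function(x, bins = 5L) {
  stopifnot(bins >= 2)
  u <- sort(unique(x))
  if (length(u) <= bins) return(match(x, u))
  if (u[1] == u[length(u)]) return(rep(1L, length(x)))
  brk <- seq(u[1], u[length(u)], length.out = bins + 1L)
  as.integer(cut(x, breaks = brk, include.lowest = TRUE))
}

#' Symmetric uncertainty between a discrete feature and a class vector
#'
#' `SU(F, C) = 2 * (H(F) - H(F|C)) / (H(F) + H(C))`, a normalized mutual
#' information in `[0, 1]`; defined as 0 when the denominator is 0 (both
#' variables constant).
#'
#' @param feature,classes Equal-length discrete vectors.
#' @return A number in `[0, 1]`.
#' @export
symmetric_uncertainty <- function(feature, classes) {
  if (length(feature) != length(classes))
    stop("feature and classes must have equal length")
  hf <- shannon_entropy(feature)
  hc <- shannon_entropy(classes)
  if (hf + hc == 0) return(0)
  joint <- shannon_entropy(paste(feature, classes, sep = "\r"))
  h_f_given_c <- joint - hc
  su <- 2 * (hf - h_f_given_c) / (hf + hc)
  min(max(su, 0), 1)
}

#' Rank features by symmetric uncertainty with the class label
#'
#' Each column is discretized ([discretize()]) and scored with
#' [symmetric_uncertainty()]; the ranking is by descending SU, ties broken by
#' ascending column index.
#'
#' @param X Numeric feature matrix.
#' @param y Class labels.
#' @param bins Discretization bins.
#' @return Object of class `su_ranking`: `su` (per-column values, named if
#'   `X` has column names) and `ranking` (column indices, best first).
#' @export
rank_features <- function(X, y, bins = 5L) {
  stopifnot(is.matrix(X), ncol(X) >= 1, nrow(X) == length(y))
  su <- apply(X, 2L, function(col)
    symmetric_uncertainty(discretize(col, bins), y))
  structure(list(su = su, ranking = order(-su, seq_along(su))),
            class = "su_ranking")
}

#' @export
print.su_ranking <- function(x, n = 10L, ...) {
  cat("Symmetric-uncertainty feature ranking (", length(x$su),
      " features)\n", sep = "")
  top <- x$ranking[seq_len(min(n, length(x$ranking)))]
  lab <- if (!is.null(names(x$su))) names(x$su)[top] else paste0("col", top)
  cat(sprintf("  %-30s %.4f\n", lab, x$su[top]), sep = "")
  invisible(x)
}

#' Default wrapper evaluator: stratified k-fold decision-tree accuracy
#'
#' Builds a deterministic subset evaluator for [iwssr_select()]: given column
#' indices it returns the stratified `k`-fold cross-validated accuracy of a
#' depth-limited CART tree on those columns. The fold assignment is drawn
#' once from `seed`, so the evaluator is a pure function of the subset.
#'
#' @param X Feature matrix.
#' @param y Binary labels.
#' @param k Folds.
#' @param maxdepth Tree depth limit.
#' @param seed Fold-assignment seed.
#' @return `function(subset_indices) -> accuracy in [0, 1]`.
#' @export
make_tree_evaluator <- function(X, y, k = 5L, maxdepth = 5L, seed = 1L) {
  stopifnot(nrow(X) == length(y))
  fold <- stratified_folds(y, k, seed)
  yf <- factor(y)
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, cp = 0, xval = 0,
                               minsplit = 4, minbucket = 2)
  function(subset) {
    stopifnot(length(subset) >= 1)
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- fold != f
      df_tr <- data.frame(X[tr, subset, drop = FALSE])
      df_te <- data.frame(X[!tr, subset, drop = FALSE])
      colnames(df_tr) <- colnames(df_te) <- paste0("V", seq_along(subset))
      fit <- rpart::rpart(y ~ ., data = cbind(y = yf[tr], df_tr),
                          method = "class", control = ctrl)
      pred <- predict(fit, df_te, type = "class")
      correct <- correct + sum(pred == yf[!tr])
    }
    correct / length(y)
  }
}

#' Incremental wrapper subset selection with replacement (IWSSR)
#'
#' Scans an SU-ranked feature list. The subset starts with the top-ranked
#' feature. For every next-ranked candidate `f` the search proceeds in two
#' levels: level 1 tries replacing each selected feature `s` with `f`
#' (subsets `(S \ {s}) + {f}`); if the best replacement strictly improves the
#' running best score it is adopted. Otherwise level 2 tries the plain
#' addition `S + {f}`. The best candidate of the two levels is accepted only
#' on strict improvement, so accepted scores are strictly increasing. Ties
#' within level 1 resolve toward the smaller replacement position.
#'
#' @param X Feature matrix.
#' @param y Binary labels.
#' @param evaluator `function(subset_indices) -> accuracy`; defaults to
#'   [make_tree_evaluator()] on `(X, y)`.
#' @param ranking An `su_ranking` (computed from `X`, `y` if `NULL`).
#' @param bins Discretization bins for the ranking.
#' @param max_rank Scan only the top `max_rank` ranked features (`NULL` =
#'   full ranking). A practical cap for very wide matrices.
#' @param seed Seed for the default evaluator's fold assignment.
#' @return Object of class `iwssr`: `selected` (column indices, in
#'   acceptance order), `feature_names`, `best_score`, and a `trace` data
#'   frame of per-candidate actions (`add`, `swap`, `reject`) and scores.
#' @export
iwssr_select <- function(X, y, evaluator = NULL, ranking = NULL, bins = 5L,
                         max_rank = NULL, seed = 1L) {
  stopifnot(is.matrix(X), ncol(X) >= 2, nrow(X) == length(y))
  if (is.null(ranking)) ranking <- rank_features(X, y, bins)
  if (is.null(evaluator)) evaluator <- make_tree_evaluator(X, y, seed = seed)
  rk <- ranking$ranking
  if (!is.null(max_rank)) rk <- rk[seq_len(min(max_rank, length(rk)))]

  S <- rk[1L]
  best <- evaluator(S)
  trace <- list(list(feature = rk[1L], action = "add", score = best))

  for (f in rk[-1L]) {
    # level 1: swap f against each selected feature
    swap_scores <- vapply(seq_along(S), function(i)
      evaluator(c(S[-i], f)), numeric(1))
    i_best <- which.max(swap_scores)      # ties -> smaller position
    level1_improves <- length(swap_scores) > 0 && swap_scores[i_best] > best
    if (level1_improves) {
      S <- c(S[-i_best], f)
      best <- swap_scores[i_best]
      trace[[length(trace) + 1L]] <-
        list(feature = f, action = "swap", score = best)
      next
    }
    # level 2: plain addition to the unchanged subset
    add_score <- evaluator(c(S, f))
    if (add_score > best) {
      S <- c(S, f)
      best <- add_score
      trace[[length(trace) + 1L]] <-
        list(feature = f, action = "add", score = best)
    } else {
      sc <- max(c(swap_scores, add_score))
      trace[[length(trace) + 1L]] <-
        list(feature = f, action = "reject", score = sc)
    }
  }
  trace <- do.call(rbind, lapply(trace, as.data.frame))
  nms <- if (!is.null(colnames(X))) colnames(X)[S] else paste0("col", S)
  structure(list(selected = S, feature_names = nms, best_score = best,
                 trace = trace, su = ranking$su[S]),
            class = "iwssr")
}

#' @export
print.iwssr <- function(x, ...) {
  cat("IWSSR feature selection\n")
  cat("  selected:  ", length(x$selected), " features\n", sep = "")
  cat("  best score:", round(x$best_score, 4), "\n")
  cat("  features:  ", paste(utils::head(x$feature_names, 8), collapse = ", "),
      if (length(x$feature_names) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}
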