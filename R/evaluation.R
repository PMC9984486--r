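#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred Equal-length 0/1 vectors; the positive class is 1.
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stop("labels must be binary 0/1")
  c(TP = sum(y_true == 1 & y_pred == 1),
    FP = sum(y_true == 0 & y_pred == 1),
    TN = sum(y_true == 0 & y_pred == 0),
    FN = sum(y_true == 1 & y_pred == 0))
}

#' Binary classification metrics
#'
#' Accuracy `(TN + TP) / total`, sensitivity `TP / (TP + FN)`, specificity
#' `TN / (TN + FP)`, precision `TP / (TP + FP)` and the Matthews correlation
#' coefficient
#' `(TN*TP - FN*FP) / sqrt((TN+FN)(TP+FP)(TN+FP)(TP+FN))`.
#' A metric whose denominator is 0 is reported as 0 and flagged in the
#' `degenerate` attribute (degenerate folds should not abort a
#' cross-validation run).
#'
#' @param counts Named vector from [confusion()].
#' @return Named numeric vector `Acc, Sen, Sp, Pre, MCC` with attribute
#'   `degenerate` (character vector of zero-denominator metrics).
#' @export
classification_metrics <- function(counts) {
  tp <- as.double(counts[["TP"]]); fp <- as.double(counts[["FP"]])
  tn <- as.double(counts[["TN"]]); fn <- as.double(counts[["FN"]])
  total <- tp + fp + tn + fn
  stopifnot(total > 0)
  degenerate <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { degenerate <<- c(degenerate, name); 0 } else num / den
  }
  out <- c(Acc = (tn + tp) / total,
           Sen = safe(tp, fn + tp, "Sen"),
           Sp = safe(tn, tn + fp, "Sp"),
           Pre = safe(tp, fp + tp, "Pre"),
           MCC = safe(tn * tp - fn * fp,
                      sqrt((tn + fn) * (tp + fp) * (tn + fp) * (tp + fn)),
                      "MCC"))
  attr(out, "degenerate") <- degenerate
  out
}

#' ROC curve and area under the curve
#'
#' AUC is the normalized Mann-Whitney U statistic: the fraction of
#' positive-negative score pairs ordered correctly, ties counting one half.
#' ROC points sweep all score thresholds from high to low.
#'
#' @param y_true 0/1 labels (both classes present).
#' @param scores Numeric scores, higher = more positive.
#' @return List with `auc` and `roc_points` (data frame `fpr`, `tpr`,
#'   monotone non-decreasing in both coordinates, from (0,0) to (1,1)).
#' @export
roc_auc <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores), all(y_true %in% c(0, 1)))
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)                      # midranks handle ties as 1/2
  auc <- (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  ys <- y_true[ord]; ss <- scores[ord]
  keep <- !duplicated(ss, fromLast = TRUE)  # last index of each threshold
  tpr <- c(0, cumsum(ys)[keep] / n1)
  fpr <- c(0, cumsum(1 - ys)[keep] / n0)
  list(auc = auc, roc_points = data.frame(fpr = fpr, tpr = tpr))
}

#' Seeded stratified fold assignment
#'
#' @param y Class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, with per-class counts
#'   balanced to within one.
#' @export
stratified_folds <- function(y, k = 10L, seed = 1L) {
  stopifnot(k >= 2)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Stratified k-fold cross-validation of the selection + classification stage
#'
#' Folds are stratified and seeded. Inside each training fold (only), the
#' optional feature-selection stage is run and a Rotation Forest is fitted;
#' predictions on the held-out fold are pooled. The report carries pooled
#' metrics, per-fold metric vectors, and their mean and standard deviation
#' (the error-bar protocol).
#'
#' @param pairs A `dti_pairs` object (or list with `X`, `y`).
#' @param k Number of folds (every class must have at least `k` members).
#' @param seed Integer seed (folds, selection evaluator, forest).
#' @param selection `NULL` to skip feature selection, or a list of options
#'   for [iwssr_select()] (`bins`, `max_rank`).
#' @param rf List of options for [rotation_forest()] (`n_trees`,
#'   `subset_size`, `bootstrap_fraction`).
#' @return Object of class `dti_eval` (see [evaluate_predictions()]), plus
#'   `per_fold`, `fold_mean`, `fold_std`, `fold` assignment and per-fold
#'   selected feature counts.
#' @export
kfold_cv <- function(pairs, k = 10L, seed = 1L, selection = NULL,
                     rf = list()) {
  X <- pairs$X; y <- pairs$y
  if (any(table(y) < k))
    stop("every class needs at least k = ", k, " members")
  fold <- stratified_folds(y, k, seed)
  scores <- numeric(length(y))
  per_fold <- matrix(NA_real_, k, 6,
                     dimnames = list(NULL,
                       c("Acc", "Sen", "Sp", "Pre", "MCC", "AUC")))
  n_selected <- integer(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    cols <- seq_len(ncol(X))
    if (!is.null(selection)) {
      sel <- iwssr_select(X[tr, , drop = FALSE], y[tr],
                          bins = selection$bins %||% 5L,
                          max_rank = selection$max_rank,
                          seed = seed + f)
      cols <- sel$selected
    }
    n_selected[f] <- length(cols)
    rf_opts <- rf
    if (!is.null(rf_opts$subset_size))
      rf_opts$subset_size <- min(rf_opts$subset_size, length(cols))
    fit <- do.call(rotation_forest,
                   c(list(x = X[tr, cols, drop = FALSE], y = y[tr],
                          seed = seed + f), rf_opts))
    pr <- predict(fit, X[!tr, cols, drop = FALSE], type = "prob")
    sc <- pr[, "1"]
    scores[!tr] <- sc
    pred <- as.integer(sc > 0.5)
    m <- classification_metrics(confusion(y[!tr], pred))
    auc_f <- if (length(unique(y[!tr])) == 2) roc_auc(y[!tr], sc)$auc
             else NA_real_
    per_fold[f, ] <- c(m, AUC = auc_f)
  }
  rep <- evaluate_predictions(y, scores)
  rep$per_fold <- as.data.frame(per_fold)
  rep$fold_mean <- colMeans(per_fold, na.rm = TRUE)
  rep$fold_std <- apply(per_fold, 2, stats::sd, na.rm = TRUE)
  rep$fold <- fold
  rep$n_selected <- n_selected
  rep
}

#' Metrics report from pooled scores
#'
#' @param y_true 0/1 labels.
#' @param scores Positive-class scores.
#' @param threshold Decision threshold.
#' @return Object of class `dti_eval`: `metrics` (Acc/Sen/Sp/Pre/MCC),
#'   `auc`, `roc_points`, `counts`.
#' @export
evaluate_predictions <- function(y_true, scores, threshold = 0.5) {
  pred <- as.integer(scores > threshold)
  counts <- confusion(y_true, pred)
  ra <- roc_auc(y_true, scores)
  structure(list(metrics = classification_metrics(counts), auc = ra$auc,
                 roc_points = ra$roc_points, counts = counts),
            class = "dti_eval")
}

#' @export
print.dti_eval <- function(x, ...) {
  cat("DTI evaluation report\n")
  m <- x$metrics
  cat(sprintf("  Acc %.4f  Sen %.4f  Sp %.4f  Pre %.4f  MCC %.4f  AUC %.4f\n",
              m[["Acc"]], m[["Sen"]], m[["Sp"]], m[["Pre"]], m[["MCC"]],
              x$auc))
  if (!is.null(x$fold_mean)) {
    cat("  per-fold mean (sd):\n")
    for (nm in names(x$fold_mean))
      cat(sprintf("    %-4s %.4f (%.4f)\n", nm, x$fold_mean[[nm]],
                  x$fold_std[[nm]]))
  }
  invisible(x)
}

#' Stratified train / independent split
#'
#' Draws a seeded, stratified, disjoint and exhaustive split: by default 90%
#' of the rows for training + testing and 10% as an independent evaluation
#' set.
#'
#' @param pairs A `dti_pairs` object (at least 10 rows).
#' @param train_fraction Fraction assigned to the training portion.
#' @param seed Integer seed.
#' @return List of two `dti_pairs`: `train` and `independent`.
#' @export
independent_split <- function(pairs, train_fraction = 0.9, seed = 1L) {
  y <- pairs$y
  stopifnot(length(y) >= 10, train_fraction > 0, train_fraction < 1)
  test_idx <- integer(0)
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      n_te <- round((1 - train_fraction) * length(idx))
      test_idx <- c(test_idx, sample(idx, n_te))
    }
  })
  take <- function(i) new_dti_pairs(X = pairs$X[i, , drop = FALSE],
                                    y = pairs$y[i],
                                    pair_ids = pairs$pair_ids[i, , drop = FALSE],
                                    mode = pairs$mode)
  list(train = take(setdiff(seq_along(y), test_idx)),
       independent = take(sort(test_idx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
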