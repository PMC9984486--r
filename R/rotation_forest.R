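#' Fit a Rotation Forest classifier
#'
#' An ensemble of CART trees in which each tree sees the data through its own
#' sparse block-diagonal rotation matrix. Per tree: the feature indices are
#' randomly partitioned into `K = ceiling(p / subset_size)` disjoint subsets;
#' for each subset a 75% sample of the training rows (without replacement by
#' default) is drawn and principal component analysis is run on the sampled
#' rows restricted to that subset; all component axes form the subset's
#' diagonal block of the rotation matrix `R_i` (entries outside the blocks
#' are exactly zero). The tree is then grown on `X %*% R_i`. A zero-variance
#' subset gets an identity block so `R_i` stays invertible.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Class labels (coerced to factor; at least 2 classes).
#' @param n_trees Number of trees `L`.
#' @param subset_size Features per rotation subset `(n/K)`.
#' @param bootstrap_fraction Fraction of rows sampled per subset before PCA.
#' @param replace Sample rows with replacement (default `FALSE`, the
#'   original 75% non-replacement scheme).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param control `rpart.control` for the base trees (default: fully grown,
#'   `cp = 0`, `minsplit = 2`).
#' @return Object of class `rotation_forest` with per-tree feature
#'   partitions, rotation blocks and fitted trees.
#' @seealso [predict.rotation_forest()], [rotation_matrix()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60 * 6), 60, 6)
#' y <- as.integer(x[, 1] + x[, 2] > 0)
#' fit <- rotation_forest(x, y, n_trees = 5, seed = 1)
#' mean(predict(fit, x) == y)
#' @export
rotation_forest <- function(x, y, n_trees = 35L, subset_size = 3L,
                            bootstrap_fraction = 0.75, replace = FALSE,
                            seed = 1L, control = NULL) {
  stopifnot(is.matrix(x), nrow(x) >= 2, n_trees >= 1,
            subset_size >= 1, subset_size <= ncol(x),
            bootstrap_fraction > 0, bootstrap_fraction <= 1)
  y <- factor(y)
  if (nlevels(y) < 2) stop("y must contain at least 2 classes")
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  p <- ncol(x)
  n <- nrow(x)
  if (is.null(control))
    control <- rpart::rpart.control(minsplit = 2, minbucket = 1, cp = 0,
                                    xval = 0, maxdepth = 30)
  trees <- vector("list", n_trees)
  partitions <- vector("list", n_trees)
  blocks <- vector("list", n_trees)
  n_draw <- ceiling(bootstrap_fraction * n)
  with_seed(seed, {
    for (i in seq_len(n_trees)) {
      perm <- sample.int(p)
      K <- ceiling(p / subset_size)
      part <- split(perm, rep(seq_len(K), each = subset_size,
                              length.out = p))
      blk <- lapply(part, function(idx) {
        rows <- sample.int(n, n_draw, replace = replace)
        sub <- x[rows, idx, drop = FALSE]
        .pca_block(sub)
      })
      xr <- .apply_rotation(x, part, blk)
      df <- data.frame(xr)
      colnames(df) <- paste0("R", seq_len(p))
      fit <- rpart::rpart(y ~ ., data = cbind(y = y, df), method = "class",
                          control = control)
      trees[[i]] <- fit
      partitions[[i]] <- part
      blocks[[i]] <- blk
    }
  })
  structure(list(trees = trees, partitions = partitions, blocks = blocks,
                 classes = levels(y), p = p,
                 config = list(n_trees = n_trees, subset_size = subset_size,
                               bootstrap_fraction = bootstrap_fraction,
                               replace = replace, seed = seed),
                 feature_names = colnames(x)),
            class = "rotation_forest")
}

# full-rank orthonormal PCA block for one feature subset; identity when the
# subset has no variance, basis completion when PCA is rank-deficient
.pca_block <- function(sub) {
  m <- ncol(sub)
  sds <- apply(sub, 2, stats::sd)
  if (all(sds < .Machine$double.eps^0.5)) return(diag(m))
  pr <- stats::prcomp(sub, center = TRUE, scale. = FALSE)
  B <- pr$rotation
  if (ncol(B) < m) {
    full <- qr.Q(qr(cbind(B, diag(m))))[, seq_len(m), drop = FALSE]
    B <- full
  }
  B
}

.apply_rotation <- function(x, partition, blocks) {
  out <- matrix(0, nrow(x), ncol(x))
  for (j in seq_along(partition)) {
    idx <- partition[[j]]
    out[, idx] <- x[, idx, drop = FALSE] %*% blocks[[j]]
  }
  out
}

#' Materialize the dense rotation matrix of one tree
#'
#' @param object A fitted [rotation_forest()].
#' @param i Tree index.
#' @return The `p x p` block-diagonal rotation matrix `R_i` (zeros outside
#'   the diagonal blocks are exact).
#' @export
rotation_matrix <- function(object, i = 1L) {
  stopifnot(inherits(object, "rotation_forest"))
  p <- object$p
  R <- matrix(0, p, p)
  part <- object$partitions[[i]]
  blk <- object$blocks[[i]]
  for (j in seq_along(part)) R[part[[j]], part[[j]]] <- blk[[j]]
  R
}

#' Predict from a Rotation Forest
#'
#' Class confidences are the average of the per-tree class-probability
#' estimates on the rotated inputs (`lambda_j = (1/L) sum_i d_ij`); per
#' sample they sum to 1. `type = "class"` takes the arg-max, ties resolving
#' to the smaller class label; for two classes this equals thresholding the
#' positive-class confidence at `threshold`.
#'
#' @param object A fitted [rotation_forest()].
#' @param newdata Numeric matrix with the training column count.
#' @param type `"class"` (labels) or `"prob"` (confidence matrix).
#' @param threshold Positive-class decision threshold (binary case).
#' @param ... Unused.
#' @return Labels (character, training levels) or a samples x classes
#'   confidence matrix.
#' @export
predict.rotation_forest <- function(object, newdata, type = c("class", "prob"),
                                    threshold = 0.5, ...) {
  type <- match.arg(type)
  stopifnot(is.matrix(newdata))
  if (ncol(newdata) != object$p)
    stop("newdata has ", ncol(newdata), " columns; model expects ", object$p)
  L <- length(object$trees)
  acc <- matrix(0, nrow(newdata), length(object$classes),
                dimnames = list(rownames(newdata), object$classes))
  for (i in seq_len(L)) {
    xr <- .apply_rotation(newdata, object$partitions[[i]], object$blocks[[i]])
    df <- data.frame(xr)
    colnames(df) <- paste0("R", seq_len(object$p))
    pr <- predict(object$trees[[i]], df, type = "prob")
    acc <- acc + pr[, object$classes, drop = FALSE]
  }
  probs <- acc / L
  if (type == "prob") return(probs)
  if (length(object$classes) == 2) {
    pos <- object$classes[2]
    lab <- ifelse(probs[, pos] > threshold, pos, object$classes[1])
    return(unname(lab))
  }
  unname(object$classes[max.col(probs, ties.method = "first")])
}

#' @export
print.rotation_forest <- function(x, ...) {
  cat("Rotation Forest classifier\n")
  cat("  trees:       ", x$config$n_trees, "\n")
  cat("  features:    ", x$p, " (subsets of ", x$config$subset_size, ")\n",
      sep = "")
  cat("  row sample:  ", round(100 * x$config$bootstrap_fraction), "% ",
      if (x$config$replace) "with" else "without", " replacement\n", sep = "")
  cat("  classes:     ", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.rotation_forest <- function(object, ...) {
  depths <- vapply(object$trees, function(t)
    max(floor(log2(as.numeric(rownames(t$frame))))), numeric(1))
  out <- list(config = object$config, classes = object$classes,
              p = object$p, tree_depths = depths)
  class(out) <- "summary.rotation_forest"
  out
}

#' @export
print.summary.rotation_forest <- function(x, ...) {
  cat("Rotation Forest (", x$config$n_trees, " trees, ", x$p,
      " features)\n", sep = "")
  cat("  tree depth: median ", stats::median(x$tree_depths), ", range ",
      min(x$tree_depths), "-", max(x$tree_depths), "\n", sep = "")
  invisible(x)
}
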