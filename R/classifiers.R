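# Nearest-neighbour variant classifiers.
#
# All three decision rules share the same first step: for a query x, sort
# each class's training points by ascending Euclidean distance (exact ties
# broken by training-set row index) and keep the first k (truncated to the
# class size).  They differ in how the per-class score is formed:
#   lmknn  - distance from x to the mean of the k nearest neighbours
#   pnn    - sum over j = 1..k of (1/j) * d(x, j-th neighbour)
#   lmpnn  - sum over j = 1..k of (1/j) * d(x, mean of first j neighbours)
# The query is assigned to the class with the smallest score; score ties go
# to the class earlier in the level order of `labels`.

#' Names of the available nearest-neighbour classifiers
#'
#' @return Character vector `c("lmknn", "pnn", "lmpnn")`.
#' @export
fall_classifiers <- function() c("lmknn", "pnn", "lmpnn")

as_label_factor <- function(labels) {
  if (is.factor(labels)) factor(labels) else factor(labels, levels = unique(labels))
}

as_train_matrix <- function(train) {
  if (is.data.frame(train)) {
    train <- as.matrix(dplyr::select(train, dplyr::where(is.numeric)))
  }
  if (!is.matrix(train) || !is.numeric(train)) {
    stop_param("`train` must be a numeric matrix or data frame of feature columns")
  }
  train
}

# Per-class scores for all three rules at every k = 1..k_max (columns);
# k beyond a class's size reuses the truncated-k score.
knn_class_scores <- function(x, train, labels, k_max) {
  classes <- levels(labels)
  n_class <- length(classes)
  lmknn <- pnn <- lmpnn <- matrix(NA_real_, n_class, k_max)
  for (ci in seq_len(n_class)) {
    idx <- which(labels == classes[ci])
    if (length(idx) == 0L) {
      stop_param(sprintf("class '%s' has no training members", classes[ci]))
    }
    sub <- train[idx, , drop = FALSE]
    d <- sqrt(colSums((t(sub) - x)^2))
    ord <- order(d)  # stable: equal distances keep ascending row index
    kk <- min(k_max, length(idx))
    ds <- d[ord][seq_len(kk)]
    neigh <- sub[ord[seq_len(kk)], , drop = FALSE]
    cmean <- apply(neigh, 2, cumsum) / seq_len(kk)
    cmean <- matrix(cmean, nrow = kk)
    dloc <- sqrt(colSums((t(cmean) - x)^2))
    w <- 1 / seq_len(kk)
    cols <- pmin(seq_len(k_max), kk)
    lmknn[ci, ] <- dloc[cols]
    pnn[ci, ]   <- cumsum(w * ds)[cols]
    lmpnn[ci, ] <- cumsum(w * dloc)[cols]
  }
  list(classes = classes, lmknn = lmknn, pnn = pnn, lmpnn = lmpnn)
}

check_query <- function(x, train) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!is.numeric(x)) stop_param("`x` must be numeric")
  if (ncol(x) != ncol(train)) {
    stop_param(sprintf("query has %d dimensions but training data has %d",
                       ncol(x), ncol(train)))
  }
  x
}

classify_impl <- function(x, train, labels, k, method) {
  train <- as_train_matrix(train)
  labels <- as_label_factor(labels)
  if (length(labels) != nrow(train)) {
    stop_param("`labels` must have one entry per training row")
  }
  k <- check_count(k, "k", min = 1L)
  x <- check_query(x, train)
  out <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    sc <- knn_class_scores(x[i, ], train, labels, k)
    out[i] <- sc$classes[which.min(sc[[method]][, k])]
  }
  factor(out, levels = levels(labels))
}

#' Per-class nearest neighbours of a query
#'
#' @param x A numeric query vector.
#' @param train Numeric matrix or data frame of training vectors.
#' @param labels Class labels, one per training row; their factor-level
#'   order is the tie-break order of the classifiers.
#' @param k Neighbours per class (truncated to the class size).
#' @return A tibble with `class`, `rank`, `index` (training row), and
#'   `distance`, sorted by ascending distance within class; exact
#'   distance ties are broken by training-set row index.
#' @export
nearest_neighbors <- function(x, train, labels, k) {
  train <- as_train_matrix(train)
  labels <- as_label_factor(labels)
  k <- check_count(k, "k", min = 1L)
  x <- drop(check_query(x, train))
  purrr::map_dfr(levels(labels), function(cl) {
    idx <- which(labels == cl)
    d <- sqrt(colSums((t(train[idx, , drop = FALSE]) - x)^2))
    ord <- order(d)
    kk <- min(k, length(idx))
    tibble::tibble(class = cl, rank = seq_len(kk),
                   index = idx[ord][seq_len(kk)],
                   distance = d[ord][seq_len(kk)])
  })
}

#' Local mean k-nearest-neighbour classification
#'
#' Assigns each query to the class whose local mean (mean of its `k`
#' nearest training vectors) is closest in Euclidean distance.
#'
#' @inheritParams nearest_neighbors
#' @param x A query vector, or a matrix/data frame of query rows.
#' @return Predicted class factor (one per query row).
#' @export
lmknn_classify <- function(x, train, labels, k) {
  classify_impl(x, train, labels, k, "lmknn")
}

#' Pseudo nearest-neighbour classification
#'
#' Scores each class by the weighted distance sum
#' `sum_j (1/j) * d(x, x_j)` over its `k` nearest neighbours and assigns
#' the query to the class with the smallest sum.
#'
#' @inheritParams lmknn_classify
#' @return Predicted class factor.
#' @export
pnn_classify <- function(x, train, labels, k) {
  classify_impl(x, train, labels, k, "pnn")
}

#' Local mean pseudo nearest-neighbour classification
#'
#' Scores each class by `sum_j (1/j) * d(x, xbar_j)` where `xbar_j` is
#' the cumulative mean of its first `j` nearest neighbours, and assigns
#' the query to the class with the smallest sum.  At `k = 1` all three
#' rules coincide with per-class 1-NN.
#'
#' @inheritParams lmknn_classify
#' @return Predicted class factor.
#' @export
lmpnn_classify <- function(x, train, labels, k) {
  classify_impl(x, train, labels, k, "lmpnn")
}
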