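# LOOCV evaluation, exhaustive subset search, and the sensitivity-first
# selection rule.

as_group_factor <- function(labels) {
  u <- unique(as.character(labels))
  if (setequal(u, c("faller", "nonfaller"))) {
    factor(labels, levels = c("faller", "nonfaller"))
  } else {
    as_label_factor(labels)
  }
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(TP + TN) / N`, sensitivity `TP / (TP + FN)`, and
#' specificity `TN / (TN + FP)`, with the faller (positive) class in the
#' TP/FN cells.  A zero denominator yields `NA` for that metric; such
#' undefined values rank below any defined value during subset selection.
#'
#' @param tp,fn,fp,tn Non-negative counts, or `tp` may be a list/one-row
#'   data frame carrying all four.
#' @return A one-row tibble: `tp`, `fn`, `fp`, `tn`, `n`, `accuracy`,
#'   `sensitivity`, `specificity`.
#' @examples
#' classification_metrics(tp = 11, fn = 3, fp = 0, tn = 24)
#' @export
classification_metrics <- function(tp, fn = NULL, fp = NULL, tn = NULL) {
  if (is.list(tp)) {
    cm <- tp
    tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
  }
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (length(counts) != 4L || !is.numeric(counts) || anyNA(counts) ||
      any(counts < 0) || any(counts != floor(counts))) {
    stop_param("`tp`, `fn`, `fp`, `tn` must be non-negative integer counts")
  }
  n <- sum(counts)
  if (n < 1) stop_param("confusion matrix must contain at least one sample")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    tp = tp, fn = fn, fp = fp, tn = tn, n = n,
    accuracy = (tp + tn) / n,
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp)
  )
}

# Held-out predictions for every classifier and every k = 1..k_max,
# as a list of n x k_max matrices of class indices.
loocv_predictions <- function(X, y, k_max) {
  n <- nrow(X)
  if (n < 3) stop_param("LOOCV needs at least 3 samples")
  if (nlevels(y) < 2 || any(tabulate(y, nlevels(y)) == 0)) {
    stop_param("both classes must be present")
  }
  if (min(tabulate(y, nlevels(y))) < 2) {
    stop_param("a class with a single member would vanish from its training fold")
  }
  arr <- loocv_preds_cpp(X, as.integer(y), nlevels(y), k_max)
  methods <- fall_classifiers()
  preds <- lapply(seq_along(methods), function(m) {
    matrix(arr[, , m], n, k_max)
  })
  names(preds) <- methods
  preds
}

confusion_counts <- function(y, pred_idx) {
  pos <- 1L  # first level is the positive (faller) class
  list(tp = sum(pred_idx == pos & as.integer(y) == pos),
       fn = sum(pred_idx != pos & as.integer(y) == pos),
       fp = sum(pred_idx == pos & as.integer(y) != pos),
       tn = sum(pred_idx != pos & as.integer(y) != pos))
}

#' Leave-one-out cross-validated confusion matrix
#'
#' Each subject is held out in turn, the classifier is trained on the
#' rest, and the `n` held-out predictions are aggregated into one
#' confusion matrix.  The procedure contains no randomness.
#'
#' @param data A data frame with a label column and numeric feature
#'   columns.
#' @param classifier One of `"lmknn"`, `"pnn"`, `"lmpnn"`.
#' @param k Neighbours per class.
#' @param subset Optional feature subset: column names or indices into
#'   the feature columns; default uses all of them.
#' @param label_col Name of the label column (positive class = first
#'   factor level; `"faller"` is placed first when present).
#' @return A one-row tibble as from [classification_metrics()].
#' @export
loocv_confusion <- function(data, classifier = "lmpnn", k = 1, subset = NULL,
                            label_col = "group") {
  classifier <- match.arg(classifier, fall_classifiers())
  k <- check_count(k, "k", min = 1L)
  y <- as_group_factor(data[[label_col]])
  X <- as_train_matrix(dplyr::select(data, -dplyr::any_of(c(label_col, "subject_id"))))
  if (!is.null(subset)) {
    if (length(subset) == 0L) stop_param("`subset` must be nonempty")
    X <- X[, subset, drop = FALSE]
  }
  preds <- loocv_predictions(X, y, k)
  cm <- confusion_counts(y, preds[[classifier]][, k])
  classification_metrics(cm)
}

#' Enumerate every nonempty feature subset
#'
#' Deterministic order: ascending cardinality, then lexicographic by
#' feature index.  For 8 features this yields the 255 candidate subsets
#' of the exhaustive search.
#'
#' @param n_features Number of features (>= 1).
#' @return A list of integer index vectors.
#' @examples
#' length(enumerate_subsets(8))  # 255
#' @export
enumerate_subsets <- function(n_features) {
  n_features <- check_count(n_features, "n_features", min = 1L)
  unlist(lapply(seq_len(n_features), function(sz) {
    utils::combn(n_features, sz, simplify = FALSE)
  }), recursive = FALSE)
}

selection_keys <- function(evals, selection) {
  key <- function(v) ifelse(is.na(v), -1, v)
  if (selection == "sensitivity_first") {
    list(-key(evals$sensitivity), -key(evals$accuracy), -key(evals$specificity))
  } else {
    list(-key(evals$accuracy), -key(evals$sensitivity), -key(evals$specificity))
  }
}

#' Pick the best subset evaluation
#'
#' Implements the sensitivity-first rule: rank by sensitivity, then
#' accuracy, then specificity (undefined metrics rank last), breaking
#' remaining ties toward the smaller subset, the lexicographically
#' earlier subset, and the smaller `k` — a total order, so the winner is
#' unique.  All `k` values sharing the winner's subset, classifier and
#' metrics are reported in `k_values`.
#'
#' @param evals Grid tibble as produced by [full_search()] (columns
#'   `subset_id`, `size`, `classifier`, `k`, and the three metrics), all
#'   rows from one classifier.
#' @param selection `"sensitivity_first"` (default) or
#'   `"accuracy_first"`.
#' @return The winning row with an extra `k_values` column.
#' @export
select_best <- function(evals, selection = c("sensitivity_first", "accuracy_first")) {
  selection <- match.arg(selection)
  if (!is.data.frame(evals) || nrow(evals) == 0L) {
    stop_param("`evals` must be a nonempty evaluation table")
  }
  if (length(unique(evals$classifier)) > 1L) {
    stop_param("`evals` must contain a single classifier; filter first")
  }
  keys <- selection_keys(evals, selection)
  ord <- order(keys[[1]], keys[[2]], keys[[3]], evals$size, evals$subset_id, evals$k)
  best <- evals[ord[1L], ]
  same <- evals$subset_id == best$subset_id &
    vapply(seq_len(nrow(evals)), function(i) {
      identical(keys[[1]][i], keys[[1]][ord[1L]]) &&
        identical(keys[[2]][i], keys[[2]][ord[1L]]) &&
        identical(keys[[3]][i], keys[[3]][ord[1L]])
    }, logical(1))
  best$k_values <- paste(sort(unique(evals$k[same])), collapse = "/")
  best
}

#' Exhaustive feature-subset search under LOOCV
#'
#' Evaluates every nonempty subset of the feature columns, for every
#' classifier and every `k` from 1 to `k_max` (capped at the smallest
#' class size minus one), by leave-one-out cross-validation, and selects
#' per classifier the winner under the sensitivity-first rule.
#'
#' @inheritParams loocv_confusion
#' @param classifiers Classifiers to evaluate.
#' @param k_max Largest neighbourhood size to sweep.
#' @param feature_cols Feature columns to search over; defaults to the
#'   canonical GRF channels present in `data`, else all numeric columns.
#' @param selection Selection ordering, see [select_best()].
#' @return A `fall_search` object: `grid` (one row per subset x
#'   classifier x k with confusion counts and metrics), `best` (one row
#'   per classifier), and `by_k` (best accuracy and sensitivity per
#'   classifier and k).  `tidy()`, `glance()` and `autoplot()` methods
#'   are available.
#' @export
full_search <- function(data, classifiers = fall_classifiers(), k_max = 10,
                        label_col = "group", feature_cols = NULL,
                        selection = c("sensitivity_first", "accuracy_first")) {
  selection <- match.arg(selection)
  classifiers <- match.arg(classifiers, fall_classifiers(), several.ok = TRUE)
  k_max <- check_count(k_max, "k_max", min = 1L)
  if (is.null(feature_cols)) {
    feature_cols <- intersect(grf_channels()$feature, names(data))
    if (length(feature_cols) == 0L) {
      feature_cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                              c(label_col, "subject_id"))
    }
  }
  if (length(feature_cols) == 0L) stop_param("no feature columns found")
  y <- as_group_factor(data[[label_col]])
  X <- as.matrix(data[, feature_cols, drop = FALSE])
  if (!is.numeric(X) || anyNA(X)) stop_param("feature columns must be numeric with no missing values")

  k_cap <- max(1L, min(k_max, min(tabulate(y, nlevels(y))) - 1L))
  subsets <- enumerate_subsets(length(feature_cols))
  labels <- vapply(subsets, function(s) paste(feature_cols[s], collapse = "+"),
                   character(1))

  n_rows <- length(subsets) * length(classifiers) * k_cap
  col_subset_id <- integer(n_rows); col_k <- integer(n_rows)
  col_classifier <- character(n_rows)
  col_tp <- integer(n_rows); col_fn <- integer(n_rows)
  col_fp <- integer(n_rows); col_tn <- integer(n_rows)
  y_int <- as.integer(y)
  pos <- y_int == 1L
  ri <- 0L
  for (sid in seq_along(subsets)) {
    Xs <- X[, subsets[[sid]], drop = FALSE]
    preds <- loocv_predictions(Xs, y, k_cap)
    for (m in classifiers) {
      pm <- preds[[m]]
      for (k in seq_len(k_cap)) {
        ri <- ri + 1L
        pk <- pm[, k] == 1L
        col_subset_id[ri] <- sid; col_classifier[ri] <- m; col_k[ri] <- k
        col_tp[ri] <- sum(pk & pos);  col_fn[ri] <- sum(!pk & pos)
        col_fp[ri] <- sum(pk & !pos); col_tn[ri] <- sum(!pk & !pos)
      }
    }
  }
  safe_ratio <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  grid <- tibble::tibble(
    subset_id = col_subset_id,
    subset = labels[col_subset_id],
    size = lengths(subsets)[col_subset_id],
    classifier = col_classifier, k = col_k,
    tp = col_tp, fn = col_fn, fp = col_fp, tn = col_tn,
    n = col_tp + col_fn + col_fp + col_tn,
    accuracy = (col_tp + col_tn) / (col_tp + col_fn + col_fp + col_tn),
    sensitivity = safe_ratio(col_tp, col_tp + col_fn),
    specificity = safe_ratio(col_tn, col_tn + col_fp)
  )

  best <- dplyr::bind_rows(lapply(classifiers, function(m) {
    select_best(grid[grid$classifier == m, ], selection = selection)
  }))
  by_k <- grid |>
    dplyr::group_by(.data$classifier, .data$k) |>
    dplyr::summarise(
      best_accuracy = max(.data$accuracy, na.rm = TRUE),
      best_sensitivity = max(.data$sensitivity, na.rm = TRUE),
      .groups = "drop")

  structure(list(grid = grid, best = best, by_k = by_k,
                 feature_cols = feature_cols, k_max = k_cap,
                 selection = selection),
            class = "fall_search")
}

#' @export
print.fall_search <- function(x, ...) {
  cat(sprintf("<fall_search> %d subsets x %s x k = 1..%d (%s selection)\n",
              length(enumerate_subsets(length(x$feature_cols))),
              paste(unique(x$grid$classifier), collapse = "/"),
              x$k_max, x$selection))
  print(dplyr::select(x$best, "classifier", "subset", "k_values",
                      "accuracy", "sensitivity", "specificity"))
  invisible(x)
}

#' @export
tidy.fall_search <- function(x, ...) x$grid

#' @export
glance.fall_search <- function(x, ...) x$best
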