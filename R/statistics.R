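# Nonparametric group comparison and correlation stage.

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided rank-sum test with mid-ranks for ties: the exact null
#' distribution when both groups have at most 10 tie-free values, the
#' normal approximation with tie and continuity correction otherwise.
#' Group means and SDs (sample SD) are reported alongside.
#'
#' @param values_a,values_b Numeric vectors, each with at least 2 values.
#' @param exact Force (`TRUE`/`FALSE`) or auto-select (`NULL`) the exact
#'   test.
#' @return A one-row tibble: `n_a`, `n_b`, `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b`, `statistic`, `p_value`, `degenerate`.  When the pooled
#'   values are all identical the comparison is flagged degenerate and
#'   `p_value` is `NA`.
#' @export
rank_sum_compare <- function(values_a, values_b, exact = NULL) {
  if (!is.numeric(values_a) || !is.numeric(values_b) ||
      length(values_a) < 2L || length(values_b) < 2L) {
    stop_param("both groups must be numeric with at least 2 values")
  }
  if (anyNA(values_a) || anyNA(values_b)) stop_param("missing values are not supported")
  out <- tibble::tibble(
    n_a = length(values_a), n_b = length(values_b),
    mean_a = mean(values_a), sd_a = sd(values_a),
    mean_b = mean(values_b), sd_b = sd(values_b),
    statistic = NA_real_, p_value = NA_real_, degenerate = FALSE
  )
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1L) {
    out$degenerate <- TRUE
    return(out)
  }
  if (is.null(exact)) {
    exact <- length(values_a) <= 10L && length(values_b) <= 10L &&
      !any(duplicated(pooled))
  }
  wt <- suppressWarnings(
    wilcox.test(values_a, values_b, exact = exact, correct = TRUE))
  out$statistic <- unname(wt$statistic)
  out$p_value <- wt$p.value
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of the mid-rank transforms, with the two-sided
#' p-value from the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A one-row tibble: `estimate` (rho), `p_value`, `n`.  Constant
#'   input yields `NA` estimates.
#' @export
spearman_corr <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) stop_param("`x` and `y` must be numeric")
  if (length(x) != length(y)) stop_param("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3L) stop_param("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop_param("missing values are not supported")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(tibble::tibble(estimate = NA_real_, p_value = NA_real_, n = n))
  }
  r <- cor(rx, ry)
  p <- if (abs(r) >= 1) {
    0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(estimate = r, p_value = p, n = n)
}

#' Categorize a correlation magnitude
#'
#' Standard interpretive bands on `|r|`: high for `|r| >= 0.50`,
#' moderate for `0.30 <= |r| < 0.50`, weak for `0.10 <= |r| < 0.30`,
#' negligible below 0.10.  Half-open intervals give every coefficient
#' exactly one category.
#'
#' @param r Correlation coefficient(s) in `[-1, 1]`.
#' @return A factor with levels `high`, `moderate`, `weak`,
#'   `negligible`.
#' @examples
#' categorize_correlation(c(0.547, 0.493, -0.05))
#' @export
categorize_correlation <- function(r) {
  if (!is.numeric(r) || anyNA(r)) stop_param("`r` must be numeric with no missing values")
  if (any(abs(r) > 1)) stop_param("|r| must not exceed 1")
  a <- abs(r)
  out <- ifelse(a >= 0.50, "high",
         ifelse(a >= 0.30, "moderate",
         ifelse(a >= 0.10, "weak", "negligible")))
  factor(out, levels = c("high", "moderate", "weak", "negligible"))
}

#' Faller vs non-faller comparison report
#'
#' One rank-sum comparison per entropy feature (group means, SDs,
#' p-value, significance star at `alpha`) plus the pairwise Spearman
#' correlation table over the selected features with interpretive
#' categories.
#'
#' @param features Feature tibble as from [extract_features()]: a
#'   `group` column plus the entropy columns.
#' @param selected Features for the correlation stage; defaults to the
#'   features significant at `alpha` (all features if none are).
#' @param alpha Significance threshold on the rank-sum p-value (default
#'   0.1).
#' @param p_adjust Optional multiplicity correction applied to the eight
#'   rank-sum p-values (`"none"`, the default, matches the reference
#'   analysis).
#' @param label_col Name of the group column.
#' @return A `fall_group_stats` object: `comparison` (one row per
#'   feature), `correlations` (long pairwise table), `corr_matrix`
#'   (symmetric, unit diagonal), `alpha`, `selected`.
#' @export
comparison_report <- function(features, selected = NULL, alpha = 0.1,
                              p_adjust = c("none", "bonferroni", "BH"),
                              label_col = "group") {
  p_adjust <- match.arg(p_adjust)
  alpha <- check_number(alpha, "alpha", min = 0, max = 1)
  y <- as_group_factor(features[[label_col]])
  if (nlevels(y) != 2L) stop_param("`features` must contain exactly two groups")
  feat_cols <- intersect(grf_channels()$feature, names(features))
  if (length(feat_cols) == 0L) {
    feat_cols <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                         c(label_col, "subject_id"))
  }
  pos <- levels(y)[1]; neg <- levels(y)[2]

  comparison <- purrr::map_dfr(feat_cols, function(f) {
    cmp <- rank_sum_compare(features[[f]][y == pos], features[[f]][y == neg])
    tibble::tibble(
      feature = f,
      faller_mean = cmp$mean_a, faller_sd = cmp$sd_a,
      nonfaller_mean = cmp$mean_b, nonfaller_sd = cmp$sd_b,
      p_value = cmp$p_value, degenerate = cmp$degenerate
    )
  })
  if (p_adjust != "none") {
    comparison$p_value <- p.adjust(comparison$p_value, method = p_adjust)
  }
  comparison$significant <- !is.na(comparison$p_value) & comparison$p_value < alpha

  if (is.null(selected)) {
    selected <- comparison$feature[comparison$significant]
    if (length(selected) == 0L) selected <- feat_cols
  }
  selected <- intersect(feat_cols, selected)
  if (length(selected) < 2L && length(feat_cols) >= 2L) {
    selected <- feat_cols
  }

  pairs <- expand.grid(feature_a = selected, feature_b = selected,
                       stringsAsFactors = FALSE)
  correlations <- purrr::pmap_dfr(pairs, function(feature_a, feature_b) {
    if (feature_a == feature_b) {
      tibble::tibble(feature_a = feature_a, feature_b = feature_b,
                     estimate = 1, p_value = NA_real_)
    } else {
      sc <- spearman_corr(features[[feature_a]], features[[feature_b]])
      tibble::tibble(feature_a = feature_a, feature_b = feature_b,
                     estimate = sc$estimate, p_value = sc$p_value)
    }
  })
  correlations$category <- categorize_correlation(
    ifelse(is.na(correlations$estimate), 0, correlations$estimate))
  correlations$category[is.na(correlations$estimate)] <- NA
  corr_matrix <- matrix(correlations$estimate, nrow = length(selected),
                        dimnames = list(selected, selected))

  structure(list(comparison = comparison, correlations = correlations,
                 corr_matrix = corr_matrix, alpha = alpha,
                 selected = selected),
            class = "fall_group_stats")
}

#' @export
print.fall_group_stats <- function(x, ...) {
  cat(sprintf("<fall_group_stats> %d features, alpha = %g; significant: %s\n",
              nrow(x$comparison), x$alpha,
              paste(x$comparison$feature[x$comparison$significant],
                    collapse = ", ")))
  print(x$comparison)
  invisible(x)
}

#' @export
tidy.fall_group_stats <- function(x, ...) x$comparison

#' @export
glance.fall_group_stats <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$comparison),
    n_significant = sum(x$comparison$significant),
    alpha = x$alpha,
    n_selected = length(x$selected)
  )
}
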