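# ggplot2 views of the result objects.

#' Plot best classification rate against k
#'
#' Line plot of the best LOOCV accuracy reached by any feature subset,
#' per classifier, as the neighbourhood size k varies.
#'
#' @param object A `fall_search` from [full_search()].
#' @param metric `"best_accuracy"` or `"best_sensitivity"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fall_search <- function(object, metric = c("best_accuracy", "best_sensitivity"),
                                 ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object$by_k,
                  ggplot2::aes(x = .data$k, y = .data[[metric]],
                               colour = .data$classifier)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = seq_len(object$k_max)) +
    ggplot2::labs(x = "k (neighbours per class)",
                  y = if (metric == "best_accuracy") "best LOOCV accuracy"
                      else "best LOOCV sensitivity",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the group comparison of entropy features
#'
#' Group means with +/- 1 SD bars per feature; features significant at
#' the report's alpha are marked.
#'
#' @param object A `fall_group_stats` from [comparison_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fall_group_stats <- function(object, ...) {
  cmp <- object$comparison
  long <- dplyr::bind_rows(
    tibble::tibble(feature = cmp$feature, group = "faller",
                   mean = cmp$faller_mean, sd = cmp$faller_sd,
                   significant = cmp$significant),
    tibble::tibble(feature = cmp$feature, group = "nonfaller",
                   mean = cmp$nonfaller_mean, sd = cmp$nonfaller_sd,
                   significant = cmp$significant))
  long$feature <- factor(long$feature, levels = cmp$feature)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$feature, y = .data$mean,
                                     colour = .data$group)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_text(
      data = dplyr::distinct(long[long$significant, ], .data$feature),
      ggplot2::aes(x = .data$feature, y = -0.02, label = "*"),
      inherit.aes = FALSE, size = 5) +
    ggplot2::labs(x = NULL, y = "sample entropy (mean ± SD)",
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Distribution of entropy features by group
#'
#' @param features Feature tibble from [extract_features()].
#' @param label_col Group column name.
#' @return A ggplot object (boxplots per channel and group).
#' @export
plot_feature_distributions <- function(features, label_col = "group") {
  feat_cols <- intersect(grf_channels()$feature, names(features))
  long <- tidyr::pivot_longer(features, dplyr::all_of(feat_cols),
                              names_to = "feature", values_to = "entropy")
  long$feature <- factor(long$feature, levels = feat_cols)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$feature, y = .data$entropy,
                                     fill = .data[[label_col]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "sample entropy", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
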