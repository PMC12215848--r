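#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a comparison matrix into a long tibble
#'
#' @param x A `comparison_matrix` from [wilcoxon_matrix()].
#' @param ... Unused.
#' @return Tibble with columns `tool_a`, `tool_b`, `p_value` (p that `tool_a`
#'   is better than `tool_b`); the diagonal is omitted.
#' @export
tidy.comparison_matrix <- function(x, ...) {
  out <- tibble::as_tibble(as.table(x$p), .name_repair = "minimal")
  names(out) <- c("tool_a", "tool_b", "p_value")
  out[out$tool_a != out$tool_b, , drop = FALSE]
}

#' Summarise a comparison matrix
#'
#' @param x A `comparison_matrix`.
#' @param alpha Significance level for win counting.
#' @param ... Unused.
#' @return One row per tool: `wins` (significant pairwise wins at `alpha`),
#'   `losses`, and the tool's median p-value against the field.
#' @export
glance.comparison_matrix <- function(x, alpha = 0.05, ...) {
  p <- x$p
  tibble::tibble(
    tool = x$tools,
    wins = rowSums(p < alpha, na.rm = TRUE),
    losses = colSums(p < alpha, na.rm = TRUE),
    median_p = apply(p, 1L, stats::median, na.rm = TRUE)
  )
}

#' Tidy a cross-validation result
#'
#' @param x A `loop_cv` from [stratified_kfold_eval()].
#' @param ... Unused.
#' @return The per-fold tibble (`classifier`, `fold`, `macro_f1`).
#' @export
tidy.loop_cv <- function(x, ...) x$per_fold

#' Summarise a cross-validation result
#'
#' @param x A `loop_cv`.
#' @param ... Unused.
#' @return One row per classifier with `min`, `max`, `median`, `mean`
#'   macro-F1.
#' @export
glance.loop_cv <- function(x, ...) x$summary

#' Heatmap of pairwise one-sided p-values
#'
#' @param object A `comparison_matrix`.
#' @param ... Unused.
#' @return A ggplot: tools on both axes, tile fill = p that the row tool
#'   beats the column tool.
#' @export
autoplot.comparison_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tool_b, y = .data$tool_a,
                                   fill = .data$p_value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$p_value, 2)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "#1a9850", high = "#f7f7f7",
                                 limits = c(0, 1), name = "p") +
    ggplot2::labs(x = "... than this tool", y = "This tool is better ...",
                  title = "One-sided Wilcoxon signed-rank p-values") +
    ggplot2::theme_minimal()
}

#' Violin plot of per-tool metric distributions
#'
#' @param metrics Long tibble with columns `tool` and `value` (finite values
#'   only are drawn).
#' @param metric_name Axis label.
#' @return A ggplot.
#' @export
plot_metric_distributions <- function(metrics, metric_name = "value") {
  metrics <- metrics[is.finite(metrics$value), , drop = FALSE]
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data$tool, y = .data$value,
                                        fill = .data$tool)) +
    ggplot2::geom_violin(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = metric_name) +
    ggplot2::theme_minimal()
}

#' Bar chart of loop-type composition
#'
#' @param object A `loop_summary` from [summarize_records()].
#' @param ... Unused.
#' @return A ggplot of counts per loop type.
#' @export
autoplot.loop_summary <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$loop_type <- factor(df$loop_type, levels = df$loop_type)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$loop_type, y = .data$count)) +
    ggplot2::geom_col(fill = "#4575b4") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$percent, "%")),
                       vjust = -0.3, size = 3) +
    ggplot2::labs(x = "loop type", y = "count") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
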