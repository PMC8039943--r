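#' Plot signature scores by group
#'
#' Violin/box view of per-observation scores, optionally split by a cell
#' annotation (mirrors the per-cell-type score distribution figures).
#'
#' @param object an `anchor_scores` tibble.
#' @param annotation optional annotation tibble with `obs_id` and
#'   `cell_type`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot anchor_scores
#' @export
autoplot.anchor_scores <- function(object, annotation = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(annotation)) {
    df <- dplyr::inner_join(df, annotation[, c("obs_id", "cell_type")],
                            by = "obs_id")
    ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$cell_type,
                                                        .data$score, median),
                                     y = .data$score)) +
      ggplot2::geom_violin(fill = "grey85") +
      ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.4) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::labs(x = NULL, y = "anchor signature score") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
      ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "grey30") +
      ggplot2::labs(x = "anchor signature score", y = "observations") +
      ggplot2::theme_minimal()
  }
}

#' Plot jackstraw permutation results
#'
#' Histogram of permutation p-values with the selected genes highlighted
#' in a direction-vs-significance panel.
#'
#' @param object a `jackstraw_result` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot jackstraw_result
#' @export
autoplot.jackstraw_result <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$direction * .data$stat,
                                   y = -log10(.data$p_perm),
                                   color = .data$selected)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "signed |Pearson r| with score",
                  y = expression(-log[10] ~ "permutation p"),
                  color = "selected") +
    ggplot2::theme_minimal()
}

#' Forest plot of score-metagene correlations
#'
#' @param object a `metagene_cor` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot metagene_cor
#' @export
autoplot.metagene_cor <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r,
                                   y = stats::reorder(.data$cell_type,
                                                      .data$r))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Pearson r (95% CI) with signature score", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the mHG prefix profile
#'
#' Hypergeometric tail probability along the ranked list with the
#' minimizing prefix marked, one panel per prefix fraction.
#'
#' @param object an `mhg_result` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mhg_result
#' @export
autoplot.mhg_result <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff_rank,
                                   y = -log10(.data$mhg_stat))) +
    ggplot2::geom_col(width = 2) +
    ggplot2::facet_wrap(~n_max_fraction, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "minimizing prefix rank",
                  y = expression(-log[10] ~ "mHG statistic")) +
    ggplot2::theme_minimal()
}
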