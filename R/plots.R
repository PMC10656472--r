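# ggplot2 views of the result objects

#' Plot the outer AUC distribution of a nested CV run
#' @param object A `tbq_nested_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tbq_nested_cv <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$rep), y = .data$auc)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "outer repeat", y = "outer-fold AUC") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Barplot of per-class Dice (mean and standard error)
#' @param object A `tbq_dice_report` (one or many scans row-bound).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tbq_dice_report <- function(object, ...) {
  s <- dice_summary(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$class, y = .data$mean_dice)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_dice - .data$se_dice,
                   ymax = .data$mean_dice + .data$se_dice),
      width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = "Dice (mean ± SE)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Heatmap of a lesion-type x region quantification
#' @param object A `tbq_quant`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tbq_quant <- function(object, ...) {
  df <- object[object$region != "(unassigned)", ]
  df$region <- factor(df$region, levels = atlas_region_names())
  df$class <- factor(df$class, levels = unique(df$class))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$class,
                                   fill = .data$volume_mm3)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "volume (mm³)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Mean AUC per experiment and segmentation variant
#' @param object A `tbq_experiment_grid`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tbq_experiment_grid <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$experiment, y = .data$mean_auc,
                                   group = .data$variant, colour = .data$variant)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_auc - .data$sd_auc,
                   ymax = .data$mean_auc + .data$sd_auc),
      width = 0.15
    ) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = NULL, y = "outer-fold AUC (mean ± SD)", colour = NULL) +
    ggplot2::theme_minimal()
}
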