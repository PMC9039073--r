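#' Box plots of lipid concentrations by group
#'
#' The standard per-feature case/control comparison display: one panel per
#' feature, boxes by group, points overlaid.
#'
#' @param abundance Wide abundance tibble (species- or class-level).
#' @param metadata Subject metadata.
#' @param features Feature columns to plot (default: all, capped at 12).
#' @param log_scale Log-transform the y axis (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_lipid_levels <- function(abundance, metadata, features = NULL,
                              log_scale = TRUE) {
  features <- features %||% head(names(abundance)[-1], 12)
  long <- tidyr::pivot_longer(
    dplyr::left_join(
      abundance[, c("subject_id", features)],
      metadata[, c("subject_id", "group")],
      by = "subject_id"
    ),
    dplyr::all_of(features),
    names_to = "feature", values_to = "concentration"
  )
  p <- ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$group, y = .data$concentration, fill = .data$group)
  ) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 0.6, alpha = 0.5) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "concentration (arbitrary units)") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' @describeIn mccv_evaluate Box plots of the per-repetition classification
#'   metrics.
#' @param object An `mccv_report`.
#' @export
autoplot.mccv_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$metrics, c("accuracy", "tpr", "tnr", "auc"),
    names_to = "metric", values_to = "value"
  )
  long$metric <- factor(long$metric, levels = c("accuracy", "tpr", "tnr", "auc"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "per-repetition value",
      title = sprintf("Monte Carlo CV, %d repetitions", object$n_reps)
    ) +
    ggplot2::theme_bw()
}

#' @describeIn select_classes Scan curve: mean AUC against model size, with
#'   the winning size highlighted.
#' @param object A `selection_result`.
#' @export
autoplot.selection_result <- function(object, ...) {
  scan <- object$scan
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$size, y = .data$auc)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_point(
      data = scan[scan$size == object$size, , drop = FALSE],
      colour = "red", size = 3
    ) +
    ggplot2::labs(
      x = "number of selected features", y = "mean AUC",
      title = paste0("Selection scan (", object$stage, ")")
    ) +
    ggplot2::theme_bw()
}
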