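# autoplot methods for audits, sweeps and training histories.

#' Plot a budget audit
#'
#' Bar chart of audited parameter counts (millions) against their published
#' targets.
#'
#' @param object A `leaf_audit` from [audit_budgets()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.leaf_audit <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("params_m", "target_params_m"),
                            names_to = "which")
  df$which <- ifelse(df$which == "params_m", "counted", "target")
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$model, .data$value),
                                   .data$value, fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "parameters (millions)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a center-loss weight sweep
#'
#' Metric trends across the swept lambda values.
#'
#' @param object A `leaf_sweep` from [lambda_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.leaf_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("accuracy", "precision", "recall", "f1"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$lambda), .data$value,
                                   colour = .data$metric, group = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression(lambda), y = "percent", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' Loss components and validation accuracy across epochs.
#'
#' @param history The history tibble returned by [train_model()].
#' @return A ggplot object.
#' @export
plot_history <- function(history) {
  df <- tidyr::pivot_longer(history, c("loss_ce", "loss", "val_accuracy"),
                            names_to = "series")
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::theme_minimal()
}

#' @rdname tidy.leaf_metrics
#' @export
glance.leaf_model <- function(x, ...) {
  tibble::tibble(variant = x$meta$variant, num_classes = x$meta$num_classes,
                 params = x$meta$params,
                 params_m = params_millions(x$meta$params),
                 macs_224 = x$meta$macs_224, macs_g = macs_g(x$meta$macs_224))
}
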