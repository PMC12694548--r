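# Evaluation metrics: confusion matrix, accuracy, macro precision/recall/F1,
# and cross-validation aggregation.

#' Confusion matrix
#'
#' @param truth,pred Integer class vectors in `1..n_classes` (rows = truth).
#' @param n_classes Number of classes.
#' @param labels Optional class labels.
#' @return An `n_classes` x `n_classes` integer matrix.
#' @export
confusion_matrix <- function(truth, pred, n_classes = max(truth, pred),
                             labels = NULL) {
  m <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(truth)) m[truth[i], pred[i]] <- m[truth[i], pred[i]] + 1L
  if (!is.null(labels)) dimnames(m) <- list(truth = labels, pred = labels)
  m
}

#' Classification metrics report
#'
#' Computes the confusion matrix, overall accuracy (trace over total), and
#' macro-averaged precision, recall and F1 from per-class one-vs-rest
#' TP/FP/FN/TN counts. All headline metrics are percentages. Per-class
#' precision (recall) with an empty predicted (true) class is treated as 0,
#' the conservative convention.
#'
#' @param truth,pred Integer class vectors in `1..n_classes`.
#' @param n_classes Number of classes.
#' @param labels Optional class labels.
#' @return A `leaf_metrics` object.
#' @examples
#' r <- metrics_report(c(1, 1, 2, 2), c(1, 2, 2, 2), 2)
#' r$accuracy
#' @export
metrics_report <- function(truth, pred, n_classes = max(truth, pred),
                           labels = NULL) {
  if (!length(truth)) stop("cannot evaluate an empty split")
  stopifnot(length(truth) == length(pred))
  cm <- confusion_matrix(truth, pred, n_classes, labels)
  total <- sum(cm)
  tp <- as.integer(diag(cm))
  fp <- as.integer(colSums(cm) - tp)
  fn <- as.integer(rowSums(cm) - tp)
  tn <- as.integer(total - tp - fp - fn)
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  per_class <- tibble::tibble(
    class = labels %||% as.character(seq_len(n_classes)),
    tp = tp, fp = fp, fn = fn, tn = tn,
    accuracy = 100 * (tp + tn) / total,
    precision = 100 * prec, recall = 100 * rec, f1 = 100 * f1)
  structure(list(confusion = cm,
                 accuracy = 100 * sum(tp) / total,
                 precision = 100 * mean(prec),
                 recall = 100 * mean(rec),
                 f1 = 100 * mean(f1),
                 n = total, per_class = per_class),
            class = "leaf_metrics")
}

#' @export
print.leaf_metrics <- function(x, ...) {
  cat(sprintf(
    "Classification report (n = %d)\n  accuracy %.2f%%  macro precision %.2f%%  macro recall %.2f%%  macro F1 %.2f%%\n",
    x$n, x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Tidy methods for metric reports
#'
#' `tidy()` returns the per-class one-vs-rest table; `glance()` returns the
#' one-row macro summary.
#'
#' @param x A `leaf_metrics` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.leaf_metrics <- function(x, ...) x$per_class

#' @rdname tidy.leaf_metrics
#' @export
glance.leaf_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, precision = x$precision,
                 recall = x$recall, f1 = x$f1, n = x$n)
}

#' @export
autoplot.leaf_metrics <- function(object, ...) {
  cm <- object$confusion
  df <- tidyr::expand_grid(truth = seq_len(nrow(cm)), pred = seq_len(ncol(cm)))
  df$count <- as.vector(t(cm))
  lab <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  df$truth <- factor(lab[df$truth], levels = rev(lab))
  df$pred <- factor(lab[df$pred], levels = lab)
  ggplot2::ggplot(df, ggplot2::aes(.data$pred, .data$truth, fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(x = "predicted", y = "true",
                  title = sprintf("Accuracy %.2f%%", object$accuracy)) +
    ggplot2::theme_minimal()
}

#' Aggregate metrics over cross-validation folds
#'
#' @param results List of `leaf_metrics`, one per fold (>= 2).
#' @return A `leaf_fold_result` with per-fold values and mean +/- sample SD
#'   (denominator k - 1) per metric.
#' @examples
#' # folds with accuracies 90, 92, 94, 91, 93 -> mean 92, sd ~1.58
#' @export
aggregate_folds <- function(results) {
  if (length(results) < 2) stop("need at least 2 folds to aggregate")
  per_fold <- dplyr::bind_rows(lapply(seq_along(results), function(i) {
    g <- glance.leaf_metrics(results[[i]])
    g$fold <- i
    g
  }))
  agg <- tidyr::pivot_longer(per_fold, c("accuracy", "precision", "recall", "f1"),
                             names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  structure(list(per_fold = per_fold, summary = agg, k = length(results)),
            class = "leaf_fold_result")
}

#' @export
print.leaf_fold_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation\n", x$k))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %.2f +/- %.2f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' @rdname tidy.leaf_metrics
#' @export
tidy.leaf_fold_result <- function(x, ...) x$per_fold

#' @rdname tidy.leaf_metrics
#' @export
glance.leaf_fold_result <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "metric",
                     values_from = c("mean", "sd"))
}

#' Mean intra-class feature distance
#'
#' Mean Euclidean distance of each sample's feature vector to its class
#' centroid, averaged over classes; the quantity the center loss contracts.
#'
#' @param features Numeric matrix (N x d).
#' @param labels Integer class vector.
#' @return Scalar distance.
#' @export
mean_intraclass_distance <- function(features, labels) {
  mean(vapply(split(seq_along(labels), labels), function(ix) {
    f <- features[ix, , drop = FALSE]
    mu <- colMeans(f)
    mean(sqrt(rowSums((f - rep(mu, each = nrow(f)))^2)))
  }, 0))
}
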