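# Joint supervision: cross-entropy, center loss, and class-center updates.
#
# The classification loss is the batch MEAN of the per-sample negative
# log-softmax; the center loss is the batch SUM (1/2) sum_i ||f(x_i) -
# mu_{y_i}||^2, following the discriminative-feature-learning formulation.
# The balancing weight lambda therefore absorbs the scale difference between
# the two reductions.

#' Cross-entropy loss
#'
#' Mean over the batch of the negative natural-log softmax probability of the
#' true class.
#'
#' @param logits Numeric matrix (N x C) of unnormalised scores.
#' @param labels Integer vector of true classes in `1..C`.
#' @return Non-negative scalar.
#' @examples
#' cross_entropy(matrix(0, 1, 11), 1)   # log(11)
#' @export
cross_entropy <- function(logits, labels) {
  stopifnot(length(labels) == nrow(logits))
  if (any(labels < 1 | labels > ncol(logits))) {
    stop("labels must lie in 1..", ncol(logits))
  }
  z <- logits - apply(logits, 1, max)
  lse <- log(rowSums(exp(z)))
  mean(lse - z[cbind(seq_len(nrow(z)), labels)])
}

# gradient of cross_entropy w.r.t. logits: (softmax - onehot) / N
cross_entropy_grad <- function(logits, labels) {
  z <- exp(logits - apply(logits, 1, max))
  p <- z / rowSums(z)
  p[cbind(seq_len(nrow(p)), labels)] <- p[cbind(seq_len(nrow(p)), labels)] - 1
  p / nrow(p)
}

#' Center loss
#'
#' Half the summed squared distance between each sample's feature vector and
#' the center of its class: `0.5 * sum_i ||f(x_i) - mu_{y_i}||^2`. Zero iff
#' every feature sits exactly on its class center.
#'
#' @param features Numeric matrix (N x d) of sample features.
#' @param labels Integer class vector in `1..C`.
#' @param centers Class-center matrix (C x d), see [init_centers()].
#' @return Non-negative scalar.
#' @examples
#' center_loss(matrix(c(3, 4), 1), 1, matrix(0, 1, 2))   # 12.5
#' @export
center_loss <- function(features, labels, centers) {
  if (ncol(features) != ncol(centers)) {
    stop("feature dimension (", ncol(features), ") != center dimension (",
         ncol(centers), ")")
  }
  diff <- features - centers[labels, , drop = FALSE]
  0.5 * sum(diff * diff)
}

# gradient w.r.t. features: f(x_i) - mu_{y_i}
center_loss_grad <- function(features, labels, centers) {
  features - centers[labels, , drop = FALSE]
}

#' Joint loss
#'
#' `L = L_CE + lambda * L_center` with `lambda >= 0`; reduces to the
#' cross-entropy alone at `lambda = 0`.
#'
#' @param l_ce Cross-entropy component.
#' @param l_center Center-loss component.
#' @param lambda Non-negative balancing weight (shipped default 0.01).
#' @return Scalar joint loss.
#' @export
joint_loss <- function(l_ce, l_center, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0) {
    stop("lambda must be a single non-negative number")
  }
  l_ce + lambda * l_center
}

#' Initialise class centers
#'
#' @param num_classes Number of classes C.
#' @param dim Center feature dimension d (the audited joint-loss head uses 85).
#' @return A zero C x d matrix with an update-count attribute.
#' @export
init_centers <- function(num_classes, dim = CENTER_DIM) {
  m <- matrix(0, num_classes, dim)
  attr(m, "updates") <- integer(num_classes)
  m
}

#' Mini-batch class-center update
#'
#' The canonical center-loss update: each class center moves toward the mean
#' of the batch features of that class,
#' `delta_j = sum_{i: y_i = j} (mu_j - f_i) / (1 + n_j)`, then
#' `mu_j <- mu_j - alpha * delta_j`. Classes absent from the batch are
#' unchanged. Optimised by plain SGD, separate from the network optimiser.
#'
#' @param features Numeric matrix (N x d).
#' @param labels Integer class vector in `1..C`.
#' @param centers Current center matrix (C x d).
#' @param alpha Center learning rate in (0, 1].
#' @return Updated center matrix.
#' @examples
#' update_centers(matrix(4), 1, matrix(0), alpha = 0.5)   # 1
#' @export
update_centers <- function(features, labels, centers, alpha = 0.5) {
  stopifnot(alpha > 0, alpha <= 1)
  counts <- tabulate(labels, nbins = nrow(centers))
  present <- which(counts > 0)
  sums <- rowsum(features, labels)
  rows <- as.integer(rownames(sums))
  delta <- (centers[rows, , drop = FALSE] * counts[rows] - sums) / (1 + counts[rows])
  centers[rows, ] <- centers[rows, , drop = FALSE] - alpha * delta
  upd <- attr(centers, "updates")
  if (!is.null(upd)) {
    upd[present] <- upd[present] + 1L
    attr(centers, "updates") <- upd
  }
  centers
}

#' Project pooled features into the center-feature space
#'
#' Applies the learned affine 576-to-d projection of a joint-loss model to a
#' pooled feature batch; the projected features feed [center_loss()] and
#' [update_centers()] while the classifier path is untouched.
#'
#' @param model A joint-loss `leaf_model` (built as `"ICS-MS"`).
#' @param features Pooled feature matrix (N x 576).
#' @return Projected features (N x d).
#' @export
center_projection <- function(model, features) {
  if (is.null(model$center_proj)) {
    stop("model '", model$meta$variant,
         "' has no center-feature head; build the joint-loss variant")
  }
  eng_fwd(model$center_proj, features)$y
}
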