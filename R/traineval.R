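# Training loop with the dual-optimiser joint-loss contract, evaluation,
# lambda sweep and cross-validation.

#' Training configuration
#'
#' Defaults follow the reference training protocol: batch 64, 200 epochs,
#' Adam at learning rate 1e-4 on all network weights, plain SGD (rate
#' `center_alpha`) on the class centers, joint loss with `lambda = 0.01`.
#' The continuous-testing preset in this package scales the schedule down
#' (see the methods vignette) but leaves the contract unchanged.
#'
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs (no early stopping; the best-validation
#'   checkpoint is additionally recorded).
#' @param lr Adam learning rate for network weights.
#' @param lambda Center-loss weight (>= 0); 0 recovers pure cross-entropy.
#' @param center_alpha SGD rate for the class-center updates, in (0, 1].
#' @param loss `"joint"` or `"ce"`; `"ce"` skips the center machinery
#'   entirely (a lambda = 0 joint run must match it exactly).
#' @param eval_every Evaluate validation accuracy every this many epochs.
#' @param seed RNG seed covering initial shuffling, augmentation and dropout.
#' @param augment An [augment_config()] applied to the training split only,
#'   or `NULL` to disable.
#' @param image_size Square size images are resized to before entering the
#'   model (the standard pipeline uses 224; any multiple of 32 >= 32 works
#'   since pooling is global).
#' @param verbose Print one line per epoch.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 64, epochs = 200, lr = 1e-4,
                         lambda = 0.01, center_alpha = 0.5,
                         loss = c("joint", "ce"), eval_every = 1, seed = 1,
                         augment = augment_config(), image_size = 224L,
                         verbose = FALSE) {
  loss <- match.arg(loss)
  stopifnot(batch_size >= 2, epochs >= 1, lr > 0, lambda >= 0,
            center_alpha > 0, center_alpha <= 1)
  structure(list(batch_size = batch_size, epochs = epochs, lr = lr,
                 lambda = lambda, center_alpha = center_alpha, loss = loss,
                 eval_every = eval_every, seed = seed, augment = augment,
                 image_size = as.integer(image_size), verbose = verbose),
            class = "train_config")
}

# ---- Adam -------------------------------------------------------------------

adam_state <- function() {
  list(t = 0L, m = list(), v = list())
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    m <- state$m[[k]]
    v <- state$v[[k]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    params[[k]] <- params[[k]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    state$m[[k]] <- m
    state$v[[k]] <- v
  }
  list(params = params, state = state)
}

# ---- batching helpers -------------------------------------------------------

make_batches <- function(idx, batch_size) {
  n <- length(idx)
  starts <- seq(1, n, by = batch_size)
  batches <- lapply(starts, function(s) idx[s:min(s + batch_size - 1, n)])
  # merge a trailing singleton into the previous batch (batch norm needs n>1)
  last <- length(batches)
  if (last > 1 && length(batches[[last]]) == 1) {
    batches[[last - 1]] <- c(batches[[last - 1]], batches[[last]])
    batches[[last]] <- NULL
  }
  batches
}

prep_batch <- function(imgs, idx, cfg, augmenting) {
  out <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    im <- imgs[[idx[i]]]
    if (augmenting && !is.null(cfg$augment)) im <- augment_image(im, cfg$augment)
    out[[i]] <- resize_normalize(im, cfg$image_size)
  }
  images_to_batch(out)
}

# ---- training ---------------------------------------------------------------

#' Train a model
#'
#' One Adam step on all network weights per mini-batch from the joint loss
#' `L = L_CE + lambda * L_center` (center loss on the projected 576-to-d
#' center features for joint-head models), followed by the SGD class-center
#' update. Augmentation is applied to the training split only; validation
#' passes are deterministic. Aborts with a diagnostic if the loss is not
#' finite. The history logs the loss breakdown and validation accuracy per
#' epoch; the best-validation weights are kept alongside the final ones.
#'
#' @param model A `leaf_model` from [build_variant()].
#' @param manifest Manifest tibble with a `split` column (train/val rows used).
#' @param config A [train_config()].
#' @param images Optional list of image arrays aligned with the manifest
#'   (defaults to [load_images()]).
#' @return List: trained `model`, `history` tibble, `best` (epoch/accuracy/
#'   params of the best validation checkpoint), final `centers`.
#' @export
train_model <- function(model, manifest, config = train_config(),
                        images = NULL) {
  stopifnot(inherits(model, "leaf_model"), inherits(config, "train_config"))
  if (!"split" %in% names(manifest)) stop("manifest has no split column")
  if (config$loss == "joint" && config$lambda > 0 && is.null(model$center_proj)) {
    stop("lambda > 0 requires a joint-head model (variant 'ICS-MS')")
  }
  images <- images %||% load_images(manifest)
  tr <- which(manifest$split == "train")
  va <- which(manifest$split == "val")
  if (!length(tr)) stop("manifest has no training rows")
  labels <- manifest$class_id
  nc <- model$meta$num_classes
  use_centers <- config$loss == "joint" && !is.null(model$center_proj)
  centers <- if (use_centers) model$centers else NULL
  set.seed(config$seed)
  opt <- adam_state()
  params <- c(eng_params(model$features),
              prefix_names(eng_params(model$classifier), "clf"),
              if (use_centers) prefix_names(eng_params(model$center_proj), "cp"))
  history <- vector("list", config$epochs)
  best <- list(accuracy = -Inf, epoch = 0L, params = NULL)
  for (epoch in seq_len(config$epochs)) {
    order_tr <- tr[sample.int(length(tr))]
    batches <- make_batches(order_tr, config$batch_size)
    ep_ce <- ep_ctr <- 0
    for (b in batches) {
      x <- prep_batch(images, b, config, augmenting = TRUE)
      y <- labels[b]
      fwd <- model_forward(model, x, train = TRUE)
      l_ce <- cross_entropy(fwd$logits, y)
      genv <- new.env(parent = emptyenv())
      glogits <- cross_entropy_grad(fwd$logits, y)
      gfeat <- eng_bwd(model$classifier, fwd$caches$classifier, glogits,
                       genv, "clf.m")
      l_ctr <- 0
      if (use_centers) {
        pr <- eng_fwd(model$center_proj, fwd$feature, train = TRUE)
        l_ctr <- center_loss(pr$y, y, centers)
        if (config$lambda > 0) {
          gproj <- config$lambda * center_loss_grad(pr$y, y, centers)
          gfeat <- gfeat + eng_bwd(model$center_proj, pr$cache, gproj,
                                   genv, "cp.m")
        } else {
          # keep optimiser state aligned: zero grads for the center head
          tmp <- new.env(parent = emptyenv())
          invisible(eng_bwd(model$center_proj, pr$cache, pr$y * 0, tmp, "cp.m"))
          for (k in ls(tmp)) genv[[k]] <- tmp[[k]] * 0
        }
      }
      l <- joint_loss(l_ce, l_ctr, if (use_centers) config$lambda else 0)
      if (!is.finite(l)) {
        stop(sprintf(
          "non-finite loss at epoch %d (lambda = %g, lr = %g): CE = %g, center = %g",
          epoch, config$lambda, config$lr, l_ce, l_ctr))
      }
      gp <- eng_bwd(model$pool, fwd$caches$pool, gfeat, genv, "p")
      invisible(eng_bwd(model$features, fwd$caches$features, gp, genv, "m"))
      r <- adam_step(params, as.list(genv), opt, config$lr)
      params <- r$params
      opt <- r$state
      model$features <- eng_set(model$features, params)
      model$classifier <- eng_set(model$classifier, unprefix_names(params, "clf"))
      if (use_centers) {
        model$center_proj <- eng_set(model$center_proj, unprefix_names(params, "cp"))
        centers <- update_centers(pr$y, y, centers, config$center_alpha)
      }
      ep_ce <- ep_ce + l_ce * length(b)
      ep_ctr <- ep_ctr + l_ctr
    }
    n_tr <- length(tr)
    l_ce_ep <- ep_ce / n_tr
    l_ctr_ep <- ep_ctr / length(batches)
    val_acc <- NA_real_
    if (length(va) && config$eval_every > 0 && epoch %% config$eval_every == 0) {
      val_acc <- eval_accuracy(model, images, va, labels[va], config)
      if (val_acc > best$accuracy) {
        best <- list(accuracy = val_acc, epoch = epoch, params = params)
      }
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, loss_ce = l_ce_ep, loss_center = l_ctr_ep,
      loss = l_ce_ep + (if (use_centers) config$lambda else 0) * l_ctr_ep,
      val_accuracy = val_acc)
    if (config$verbose) {
      message(sprintf("epoch %3d  CE %.4f  center %.2f  val %.1f%%",
                      epoch, l_ce_ep, l_ctr_ep, val_acc))
    }
  }
  if (use_centers) model$centers <- centers
  list(model = model, history = dplyr::bind_rows(history), best = best,
       centers = centers)
}

prefix_names <- function(lst, pre) {
  names(lst) <- paste0(pre, ".", names(lst))
  lst
}

unprefix_names <- function(lst, pre) {
  sel <- startsWith(names(lst), paste0(pre, "."))
  out <- lst[sel]
  names(out) <- substring(names(out), nchar(pre) + 2)
  out
}

eval_accuracy <- function(model, images, idx, truth, config) {
  pred <- predict_classes(model, images, idx, config)
  100 * mean(pred == truth)
}

predict_classes <- function(model, images, idx, config, batch_size = 64) {
  pred <- integer(length(idx))
  feats <- NULL
  for (b in make_batches(seq_along(idx), batch_size)) {
    x <- prep_batch(images, idx[b], config, augmenting = FALSE)
    r <- predict_model(model, x)
    pred[b] <- r$class_id
    feats <- rbind(feats, r$feature)
  }
  attr(pred, "features") <- feats
  pred
}

#' Evaluate a trained model on a manifest split
#'
#' Single deterministic pass; returns the full metrics report.
#'
#' @param model Trained `leaf_model`.
#' @param manifest Manifest with a `split` column.
#' @param split Which split to evaluate (or `"all"`).
#' @param config A [train_config()] (for image size); defaults to the
#'   standard pipeline.
#' @param images Optional pre-loaded image list.
#' @return A `leaf_metrics` report.
#' @export
evaluate_model <- function(model, manifest, split = "test",
                           config = train_config(), images = NULL) {
  idx <- if (identical(split, "all")) seq_len(nrow(manifest)) else
    which(manifest$split == split)
  if (!length(idx)) stop("split '", split, "' is empty")
  images <- images %||% load_images(manifest)
  labels <- manifest$class_id
  pred <- predict_classes(model, images, idx, config)
  cls_labels <- if ("cultivar" %in% names(manifest)) {
    map <- unique(manifest[, c("class_id", "cultivar")])
    map$cultivar[order(map$class_id)]
  } else NULL
  metrics_report(labels[idx], as.integer(pred), model$meta$num_classes,
                 labels = cls_labels)
}

#' Center-loss weight sweep
#'
#' Trains one model per lambda under a shared seed and reports accuracy,
#' macro precision/recall/F1 and validation loss per weight, together with
#' the lambda maximising accuracy.
#'
#' @param manifest Manifest with train/val splits.
#' @param lambdas Candidate weights (reference sweep: 0, 0.01, 0.05, 0.1, 0.2).
#' @param config Base [train_config()]; its `lambda` field is overridden.
#' @param build Model factory, called with no arguments per lambda.
#' @param images Optional pre-loaded images.
#' @param eval_split Split evaluated for the report.
#' @return A `leaf_sweep` tibble with one row per lambda; attribute `best`
#'   holds the argmax-accuracy lambda.
#' @export
lambda_sweep <- function(manifest, lambdas = c(0, 0.01, 0.05, 0.1, 0.2),
                         config = train_config(),
                         build = function() build_variant("ICS-MS", seed = config$seed),
                         images = NULL, eval_split = "val") {
  stopifnot(length(lambdas) >= 1)
  images <- images %||% load_images(manifest)
  rows <- lapply(lambdas, function(lam) {
    cfg <- config
    cfg$lambda <- lam
    fit <- train_model(build(), manifest, cfg, images)
    rep <- evaluate_model(fit$model, manifest, eval_split, cfg, images)
    g <- glance.leaf_metrics(rep)
    tibble::tibble(lambda = lam, accuracy = g$accuracy, precision = g$precision,
                   recall = g$recall, f1 = g$f1,
                   loss = utils::tail(fit$history$loss, 1))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "best") <- out$lambda[which.max(out$accuracy)]
  class(out) <- c("leaf_sweep", class(out))
  out
}

#' k-fold cross-validation
#'
#' Trains one model per fold (fold f held out as test, the rest as training,
#' with a stratified tenth of the training rows as validation) and aggregates
#' the per-fold metric reports.
#'
#' @param manifest Manifest with a `fold` column from [make_folds()].
#' @param config A [train_config()].
#' @param build Model factory.
#' @param images Optional pre-loaded images.
#' @return A `leaf_fold_result`.
#' @export
crossval <- function(manifest, config = train_config(),
                     build = function() build_variant("ICS-MS", seed = config$seed),
                     images = NULL) {
  if (!"fold" %in% names(manifest)) stop("manifest has no fold column; run make_folds()")
  images <- images %||% load_images(manifest)
  k <- max(manifest$fold)
  reports <- lapply(seq_len(k), function(f) {
    mf <- manifest
    mf$split <- ifelse(mf$fold == f, "test", "train")
    tr_rows <- which(mf$split == "train")
    set.seed(config$seed + f)
    val_pick <- sample(tr_rows, max(2, round(0.1 * length(tr_rows))))
    mf$split[val_pick] <- "val"
    fit <- train_model(build(), mf, config, images)
    evaluate_model(fit$model, mf, "test", config, images)
  })
  aggregate_folds(reports)
}
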