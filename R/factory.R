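# Assembly of named model variants, forward passes, and (de)serialisation.

#' Build a named model variant
#'
#' Assembles one of the MobileNetV3-Small family architectures: the SE
#' baseline (`"MS"`), attention swaps (`"MS-ECA"`, `"MS-CBAM"`, `"MS-CA"`),
#' the conventional-Inception comparison (`"MS-CA-I"`), and the two fusion
#' assemblies (`"ICS-MS-CE"` cross-entropy only, `"ICS-MS"` with the joint
#' loss head: a 576-to-85 center-feature projection plus an 85-dimensional
#' class-center matrix). Weights are initialised from the current RNG state
#' (Kaiming-uniform convolutions, N(0, 0.01) linear layers), so a fixed
#' `seed` gives bit-identical models.
#'
#' @param name A name from [variant_names()].
#' @param num_classes Number of output classes (>= 2).
#' @param seed Optional integer seed for weight initialisation.
#' @return A `leaf_model`: engine modules for features, pooling and
#'   classifier, the optional center head, and a `meta` record with the
#'   audited parameter/MAC numbers.
#' @examples
#' m <- build_variant("MS", num_classes = 11, seed = 1)
#' count_parameters(m)
#' @export
build_variant <- function(name, num_classes = 11L, seed = NULL) {
  cfg <- variant_config(name, num_classes)
  if (!is.null(seed)) set.seed(seed)
  feats <- list(stem = nn_conv(3, cfg$stem_ch, 3, stride = 2),
                stem_bn = nn_bn(cfg$stem_ch), stem_act = nn_act("hswish"))
  if (cfg$micro_ics) {
    feats <- c(feats, list(ics_micro = ics_inception_block(
      ics_inception_config(cfg$stem_ch, ICS_MICRO_BRANCH, project_pool = TRUE,
                           compress_to = cfg$stem_ch))))
  }
  for (i in seq_len(nrow(cfg$rows))) {
    feats[[sprintf("bneck%02d", i)]] <- bottleneck_block(cfg$rows[i, ])
  }
  last_ch <- cfg$rows$out_ch[nrow(cfg$rows)]
  feats <- c(feats, switch(cfg$head,
    conv = list(head = nn_conv(last_ch, cfg$head_ch, 1),
                head_bn = nn_bn(cfg$head_ch), head_act = nn_act("hswish")),
    ics = list(ics_head = ics_inception_block(
      ics_inception_config(last_ch, ICS_HEAD_BRANCH))),
    inception = list(inception_head = inception_head_block(last_ch))
  ))
  classifier <- nn_seq(list(
    fc1 = nn_linear(cfg$head_ch, cfg$hidden),
    act = nn_act("hswish"),
    drop = nn_dropout(cfg$dropout),
    fc2 = nn_linear(cfg$hidden, cfg$num_classes)))
  model <- list(
    features = nn_seq(feats),
    pool = nn_gpool(),
    classifier = classifier,
    center_proj = if (cfg$joint) nn_linear(cfg$head_ch, cfg$center_dim) else NULL,
    centers = if (cfg$joint) matrix(0, cfg$num_classes, cfg$center_dim) else NULL,
    meta = list(variant = name, num_classes = cfg$num_classes,
                hidden = cfg$hidden, center_dim = cfg$center_dim,
                seed = seed,
                params = count_parameters(name, cfg$num_classes),
                macs_224 = count_macs(name, cfg$num_classes))
  )
  class(model) <- "leaf_model"
  model
}

#' Build a reference baseline for budget auditing
#'
#' The baseline zoo (ResNet50, MobileNetV2, MobileNetV3-Large, ShuffleNetV2
#' x1.0) is described as exact layer tables with the final classification
#' layer resized to `num_classes`; these models are audited (parameters,
#' MACs) but not instantiated for training.
#'
#' @param name A name from [baseline_names()].
#' @param num_classes Number of output classes.
#' @return A `leaf_model_spec` with the layer table and exact counts.
#' @examples
#' build_baseline("resnet50", 11)
#' @export
build_baseline <- function(name, num_classes = 11L) {
  if (!name %in% baseline_names()) {
    stop("unknown baseline '", name, "'; valid names: ",
         paste(baseline_names(), collapse = ", "), call. = FALSE)
  }
  layers <- arch_layers(name, num_classes)
  structure(list(name = name, num_classes = num_classes, layers = layers,
                 params = count_parameters(layers),
                 macs_224 = count_macs(layers)),
            class = "leaf_model_spec")
}

#' @export
print.leaf_model_spec <- function(x, ...) {
  cat(sprintf("<%s>  %d classes  %s M params  %.2f G MACs (audit-only)\n",
              x$name, x$num_classes, format(params_millions(x$params)),
              macs_g(x$macs_224)))
  invisible(x)
}

#' @export
print.leaf_model <- function(x, ...) {
  cat(sprintf("<leaf_model %s>  %d classes  %s M params  %.2f G MACs @224\n",
              x$meta$variant, x$meta$num_classes,
              format(params_millions(x$meta$params)), macs_g(x$meta$macs_224)))
  if (!is.null(x$center_proj)) {
    cat(sprintf("  joint-loss head: %d-d center features, %d centers\n",
                x$meta$center_dim, x$meta$num_classes))
  }
  invisible(x)
}

# full forward pass; returns logits, pooled 576-d feature, and caches
model_forward <- function(model, x, train = FALSE) {
  rf <- eng_fwd(model$features, x, train)
  rp <- eng_fwd(model$pool, rf$y, train)
  rc <- eng_fwd(model$classifier, rp$y, train)
  list(logits = rc$y, feature = rp$y,
       caches = list(features = rf$cache, pool = rp$cache, classifier = rc$cache))
}

#' Predict class scores and labels
#'
#' Deterministic inference pass. The pooled penultimate feature is returned
#' alongside the logits (it feeds the center loss during training).
#'
#' @param model A `leaf_model`.
#' @param x Image batch: array `(H, W, 3, N)` with values in `[0, 1]`
#'   (normalisation is applied internally via [resize_normalize()] upstream),
#'   or an ft matrix.
#' @return List with `logits` (N x C), `feature` (N x 576), `class_id`
#'   (1-based predicted class).
#' @export
predict_model <- function(model, x) {
  if (is.null(attr(x, "ftdim"))) x <- as_ft(x)
  r <- model_forward(model, x, train = FALSE)
  list(logits = r$logits, feature = r$feature,
       class_id = max.col(r$logits, ties.method = "first"))
}

#' Save / load a model with its audit manifest
#'
#' The serialised file embeds the variant name, class count and audited
#' parameter count; `load_model()` rebuilds the architecture, restores
#' weights and running statistics, and refuses a file whose manifest does
#' not match the rebuilt architecture.
#'
#' @param model A `leaf_model`.
#' @param path File path.
#' @return `load_model()` returns the restored `leaf_model`.
#' @export
save_model <- function(model, path) {
  payload <- list(
    meta = model$meta,
    params = list(features = eng_params(model$features),
                  classifier = eng_params(model$classifier),
                  center_proj = if (!is.null(model$center_proj)) eng_params(model$center_proj)),
    buffers = list(features = eng_buffers(model$features),
                   classifier = eng_buffers(model$classifier)),
    centers = model$centers)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- readRDS(path)
  meta <- payload$meta
  model <- build_variant(meta$variant, meta$num_classes)
  if (model$meta$params != meta$params) {
    stop("weight file manifest (", meta$params, " params) does not match ",
         "rebuilt architecture (", model$meta$params, " params)")
  }
  model$features <- eng_set(model$features, payload$params$features)
  model$features <- eng_set(model$features, payload$buffers$features, slots = buffer_slots)
  model$classifier <- eng_set(model$classifier, payload$params$classifier)
  model$classifier <- eng_set(model$classifier, payload$buffers$classifier, slots = buffer_slots)
  if (!is.null(model$center_proj)) {
    model$center_proj <- eng_set(model$center_proj, payload$params$center_proj)
    model$centers <- payload$centers
  }
  model$meta <- meta
  model
}
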