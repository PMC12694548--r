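# Architecture descriptor tables.
#
# Every variant and baseline is described twice from one source of truth:
# as a flat tibble of primitive layers (for exact parameter/MAC counting,
# see audit.R) and -- for the trainable MobileNetV3-Small family -- as an
# engine module tree (see factory.R). The stage tables below are data, not
# logic.

#' The MobileNetV3-Small stage table
#'
#' The canonical 11 inverted-residual bottleneck rows: input channels,
#' depthwise kernel size, expansion width, output channels, whether the row
#' carries an attention block, activation family, and stride. A residual
#' connection is present iff `stride == 1` and `in_ch == out_ch`.
#'
#' @return A tibble with one row per bottleneck.
#' @export
mnv3_small_rows <- function() {
  tibble::tribble(
    ~in_ch, ~kernel, ~exp_ch, ~out_ch, ~attention, ~activation, ~stride,
    16L, 3L, 16L, 16L, "se", "relu", 2L,
    16L, 3L, 72L, 24L, "none", "relu", 2L,
    24L, 3L, 88L, 24L, "none", "relu", 1L,
    24L, 5L, 96L, 40L, "se", "hswish", 2L,
    40L, 5L, 240L, 40L, "se", "hswish", 1L,
    40L, 5L, 240L, 40L, "se", "hswish", 1L,
    40L, 5L, 120L, 48L, "se", "hswish", 1L,
    48L, 5L, 144L, 48L, "se", "hswish", 1L,
    48L, 5L, 288L, 96L, "se", "hswish", 2L,
    96L, 5L, 576L, 96L, "se", "hswish", 1L,
    96L, 5L, 576L, 96L, "se", "hswish", 1L
  )
}

mnv3_large_rows <- function() {
  tibble::tribble(
    ~in_ch, ~kernel, ~exp_ch, ~out_ch, ~attention, ~activation, ~stride,
    16L, 3L, 16L, 16L, "none", "relu", 1L,
    16L, 3L, 64L, 24L, "none", "relu", 2L,
    24L, 3L, 72L, 24L, "none", "relu", 1L,
    24L, 5L, 72L, 40L, "se", "relu", 2L,
    40L, 5L, 120L, 40L, "se", "relu", 1L,
    40L, 5L, 120L, 40L, "se", "relu", 1L,
    40L, 3L, 240L, 80L, "none", "hswish", 2L,
    80L, 3L, 200L, 80L, "none", "hswish", 1L,
    80L, 3L, 184L, 80L, "none", "hswish", 1L,
    80L, 3L, 184L, 80L, "none", "hswish", 1L,
    80L, 3L, 480L, 112L, "se", "hswish", 1L,
    112L, 3L, 672L, 112L, "se", "hswish", 1L,
    112L, 5L, 672L, 160L, "se", "hswish", 2L,
    160L, 5L, 960L, 160L, "se", "hswish", 1L,
    160L, 5L, 960L, 160L, "se", "hswish", 1L
  )
}

# design constants pinned by the printed whole-model budgets (see the
# methods vignette for the derivation)
CA_REDUCTION <- 9L          # coordinate-attention bottleneck reduction
CBAM_BNECK_REDUCTION <- 4L  # CBAM-in-bottleneck channel reduction
CBAM_FUSION_REDUCTION <- 16L
ICS_MICRO_BRANCH <- 128L    # per-branch width of the stem-resolution block
ICS_HEAD_BRANCH <- 240L     # conv branch width of the 7x7 head block
ICS_HIDDEN <- 480L          # classifier hidden width in fusion variants
CENTER_DIM <- 85L           # center-feature projection dimension

#' Model variant and baseline names
#'
#' `variant_names()` lists the MobileNetV3-Small family assemblies that can be
#' built, trained and audited; `baseline_names()` lists the reference
#' architectures available for budget auditing only.
#'
#' @return Character vector of names.
#' @export
variant_names <- function() {
  c("MS", "MS-ECA", "MS-CBAM", "MS-CA", "MS-CA-I", "ICS-MS-CE", "ICS-MS")
}

#' @rdname variant_names
#' @export
baseline_names <- function() {
  c("resnet50", "mobilenet_v2", "mobilenet_v3_large", "shufflenet_v2_x1_0")
}

# resolved structural description of a variant
variant_config <- function(name, num_classes = 11L) {
  if (!name %in% variant_names()) {
    stop("unknown variant '", name, "'; valid names: ",
         paste(variant_names(), collapse = ", "), call. = FALSE)
  }
  stopifnot(num_classes >= 2)
  rows <- mnv3_small_rows()
  att <- switch(name,
    "MS" = "se", "MS-ECA" = "eca", "MS-CBAM" = "cbam",
    "ca")                                     # MS-CA and all fusion variants
  rows$attention[rows$attention == "se"] <- att
  fusion <- name %in% c("MS-CA-I", "ICS-MS-CE", "ICS-MS")
  list(
    name = name,
    num_classes = as.integer(num_classes),
    rows = rows,
    stem_ch = 16L,
    head_ch = 576L,
    hidden = if (fusion) ICS_HIDDEN else 1024L,
    head = if (!fusion) "conv" else if (name == "MS-CA-I") "inception" else "ics",
    micro_ics = name %in% c("ICS-MS-CE", "ICS-MS"),
    joint = identical(name, "ICS-MS"),
    center_dim = if (identical(name, "ICS-MS")) CENTER_DIM else 0L,
    dropout = 0.2
  )
}

# ---- flat layer descriptors -------------------------------------------------
# op is one of conv / linear / bn / conv1d; `pos` is the number of spatial
# positions the op is evaluated at (per forward pass at the given input
# size), so macs = pos * cin * cout * k^2 / groups for conv-like ops.

lrow <- function(stage, op, cin, cout, k = 1, stride = 1, groups = 1,
                 bias = FALSE, pos = 1) {
  tibble::tibble(stage = stage, op = op, cin = cin, cout = cout, k = k,
                 stride = stride, groups = groups, bias = bias, pos = pos)
}

conv_bn <- function(stage, cin, cout, k, pos, stride = 1, groups = 1, bias = FALSE) {
  dplyr::bind_rows(
    lrow(stage, "conv", cin, cout, k, stride, groups, bias, pos),
    lrow(stage, "bn", cout, cout, pos = 0)
  )
}

attention_rows <- function(kind, C, res, stage) {
  switch(kind,
    none = NULL,
    se = {
      s <- make_divisible(C %/% 4L, 8L)
      dplyr::bind_rows(
        lrow(stage, "linear", C, s, bias = TRUE),
        lrow(stage, "linear", s, C, bias = TRUE))
    },
    eca = lrow(stage, "conv1d", C, C, k = eca_kernel(C), pos = C),
    cbam = cbam_rows(C, res, stage, CBAM_BNECK_REDUCTION),
    ca = {
      mid <- max(8L, C %/% CA_REDUCTION)
      dplyr::bind_rows(
        lrow(stage, "linear", C, mid, bias = TRUE, pos = 2 * res),
        lrow(stage, "bn", mid, mid, pos = 0),
        lrow(stage, "linear", mid, C, bias = TRUE, pos = res),
        lrow(stage, "linear", mid, C, bias = TRUE, pos = res))
    },
    stop("unknown attention kind: ", kind)
  )
}

cbam_rows <- function(C, res, stage, reduction) {
  mid <- max(8L, C %/% reduction)
  dplyr::bind_rows(
    lrow(stage, "linear", C, mid, bias = TRUE, pos = 2),   # shared MLP, avg+max
    lrow(stage, "linear", mid, C, bias = TRUE, pos = 2),
    lrow(stage, "conv", 2, 1, k = 7, pos = res^2),
    lrow(stage, "bn", 1, 1, pos = 0)
  )
}

bottleneck_rows <- function(r, res_in, stage) {
  res_out <- conv_out_size(res_in, r$kernel, r$stride, r$kernel %/% 2L)
  out <- list()
  if (r$exp_ch != r$in_ch) {
    out <- c(out, list(conv_bn(stage, r$in_ch, r$exp_ch, 1, res_in^2)))
  }
  out <- c(out, list(
    conv_bn(stage, r$exp_ch, r$exp_ch, r$kernel, res_out^2,
            stride = r$stride, groups = r$exp_ch),
    attention_rows(r$attention, r$exp_ch, res_out, stage),
    conv_bn(stage, r$exp_ch, r$out_ch, 1, res_out^2)
  ))
  list(rows = dplyr::bind_rows(out), res = res_out)
}

ics_block_rows <- function(cin, branch, res, stage, project_pool, compress_to = NULL) {
  concat <- 2L * branch + if (project_pool) branch else cin
  out <- list(
    conv_bn(stage, cin, branch, 1, res^2),                  # linear 1x1 branch
    conv_bn(stage, cin, branch, 1, res^2),                  # relu6 1x1 branch
    if (project_pool) conv_bn(stage, cin, branch, 1, res^2),# maxpool + project
    cbam_rows(concat, res, stage, CBAM_FUSION_REDUCTION)
  )
  if (!is.null(compress_to)) {
    out <- c(out, list(conv_bn(stage, concat, compress_to, 1, res^2)))
  }
  dplyr::bind_rows(out)
}

inception_block_rows <- function(cin, res, stage) {
  # conventional Inception head: 1x1, 3x3 (reduced), 5x5 (reduced), pool-proj
  dplyr::bind_rows(
    conv_bn(stage, cin, 288, 1, res^2),
    conv_bn(stage, cin, 16, 1, res^2),
    conv_bn(stage, 16, 144, 3, res^2),
    conv_bn(stage, cin, 8, 1, res^2),
    conv_bn(stage, 8, 32, 5, res^2),
    conv_bn(stage, cin, 112, 1, res^2)
  )
}

mnv3_family_layers <- function(cfg, input_size = 224L) {
  res <- conv_out_size(input_size, 3L, 2L, 1L)
  out <- list(conv_bn("stem", 3, cfg$stem_ch, 3, res^2, stride = 2))
  if (cfg$micro_ics) {
    out <- c(out, list(ics_block_rows(cfg$stem_ch, ICS_MICRO_BRANCH, res,
                                      "ics_micro", project_pool = TRUE,
                                      compress_to = cfg$stem_ch)))
  }
  for (i in seq_len(nrow(cfg$rows))) {
    b <- bottleneck_rows(cfg$rows[i, ], res, sprintf("bneck%02d", i))
    out <- c(out, list(b$rows))
    res <- b$res
  }
  last_ch <- cfg$rows$out_ch[nrow(cfg$rows)]
  out <- c(out, list(switch(cfg$head,
    conv = conv_bn("head", last_ch, cfg$head_ch, 1, res^2),
    ics = ics_block_rows(last_ch, ICS_HEAD_BRANCH, res, "ics_head",
                         project_pool = FALSE),
    inception = inception_block_rows(last_ch, res, "inception_head")
  )))
  out <- c(out, list(
    lrow("classifier", "linear", cfg$head_ch, cfg$hidden, bias = TRUE),
    lrow("classifier", "linear", cfg$hidden, cfg$num_classes, bias = TRUE)
  ))
  if (cfg$joint) {
    out <- c(out, list(
      lrow("center_head", "linear", cfg$head_ch, cfg$center_dim, bias = TRUE),
      lrow("center_head", "centers", 0, 0, pos = 0) |>
        dplyr::mutate(cin = cfg$num_classes, cout = cfg$center_dim)
    ))
  }
  dplyr::bind_rows(out)
}

# ---- baseline descriptor tables ---------------------------------------------

mobilenet_v2_layers <- function(num_classes, input_size = 224L) {
  cfgs <- list(c(1, 16, 1, 1), c(6, 24, 2, 2), c(6, 32, 3, 2), c(6, 64, 4, 2),
               c(6, 96, 3, 1), c(6, 160, 3, 2), c(6, 320, 1, 1))
  res <- conv_out_size(input_size, 3L, 2L, 1L)
  out <- list(conv_bn("stem", 3, 32, 3, res^2, stride = 2))
  cin <- 32L
  for (g in cfgs) for (i in seq_len(g[3])) {
    stride <- if (i == 1) g[4] else 1L
    cexp <- cin * g[1]
    stage <- sprintf("ir_%d_%d", g[2], i)
    if (g[1] != 1) out <- c(out, list(conv_bn(stage, cin, cexp, 1, res^2)))
    res_out <- conv_out_size(res, 3L, stride, 1L)
    out <- c(out, list(
      conv_bn(stage, cexp, cexp, 3, res_out^2, stride = stride, groups = cexp),
      conv_bn(stage, cexp, g[2], 1, res_out^2)))
    cin <- g[2]; res <- res_out
  }
  dplyr::bind_rows(c(out, list(
    conv_bn("head", 320, 1280, 1, res^2),
    lrow("classifier", "linear", 1280, num_classes, bias = TRUE))))
}

mnv3_large_layers <- function(num_classes, input_size = 224L) {
  res <- conv_out_size(input_size, 3L, 2L, 1L)
  out <- list(conv_bn("stem", 3, 16, 3, res^2, stride = 2))
  rows <- mnv3_large_rows()
  for (i in seq_len(nrow(rows))) {
    b <- bottleneck_rows(rows[i, ], res, sprintf("bneck%02d", i))
    out <- c(out, list(b$rows))
    res <- b$res
  }
  dplyr::bind_rows(c(out, list(
    conv_bn("head", 160, 960, 1, res^2),
    lrow("classifier", "linear", 960, 1280, bias = TRUE),
    lrow("classifier", "linear", 1280, num_classes, bias = TRUE))))
}

resnet50_layers <- function(num_classes, input_size = 224L) {
  res <- conv_out_size(input_size, 7L, 2L, 3L)
  out <- list(conv_bn("stem", 3, 64, 7, res^2, stride = 2))
  res <- conv_out_size(res, 3L, 2L, 1L)           # maxpool
  cin <- 64L
  stages <- list(c(64, 3, 1), c(128, 4, 2), c(256, 6, 2), c(512, 3, 2))
  for (s in stages) {
    w <- s[1]; n <- s[2]
    for (i in seq_len(n)) {
      stride <- if (i == 1) s[3] else 1L
      cout <- w * 4L
      stage <- sprintf("res_%d_%d", w, i)
      res_out <- if (stride == 2) conv_out_size(res, 3L, 2L, 1L) else res
      out <- c(out, list(
        conv_bn(stage, cin, w, 1, res^2),
        conv_bn(stage, w, w, 3, res_out^2, stride = stride),
        conv_bn(stage, w, cout, 1, res_out^2)))
      if (i == 1) out <- c(out, list(conv_bn(stage, cin, cout, 1, res_out^2, stride = stride)))
      cin <- cout; res <- res_out
    }
  }
  dplyr::bind_rows(c(out, list(
    lrow("classifier", "linear", 2048, num_classes, bias = TRUE))))
}

shufflenet_v2_layers <- function(num_classes, input_size = 224L) {
  res <- conv_out_size(input_size, 3L, 2L, 1L)
  out <- list(conv_bn("stem", 3, 24, 3, res^2, stride = 2))
  res <- conv_out_size(res, 3L, 2L, 1L)           # maxpool
  cin <- 24L
  stages <- list(c(116, 4), c(232, 8), c(464, 4))
  for (s in stages) {
    cout <- s[1]; n <- s[2]; half <- cout %/% 2L
    res_out <- conv_out_size(res, 3L, 2L, 1L)
    stage <- sprintf("stage_%d", cout)
    out <- c(out, list(   # stride-2 unit, two branches
      conv_bn(stage, cin, cin, 3, res_out^2, stride = 2, groups = cin),
      conv_bn(stage, cin, half, 1, res_out^2),
      conv_bn(stage, cin, half, 1, res^2),
      conv_bn(stage, half, half, 3, res_out^2, stride = 2, groups = half),
      conv_bn(stage, half, half, 1, res_out^2)))
    res <- res_out
    for (i in seq_len(n - 1L)) {
      out <- c(out, list(
        conv_bn(stage, half, half, 1, res^2),
        conv_bn(stage, half, half, 3, res^2, groups = half),
        conv_bn(stage, half, half, 1, res^2)))
    }
    cin <- cout
  }
  dplyr::bind_rows(c(out, list(
    conv_bn("head", 464, 1024, 1, res^2),
    lrow("classifier", "linear", 1024, num_classes, bias = TRUE))))
}

#' Flat layer descriptor of a model architecture
#'
#' Expands a named variant or baseline into one row per primitive layer
#' (convolution, linear, batch norm, 1-D channel conv, class-center matrix)
#' with enough geometry to count parameters and multiply-accumulates exactly.
#'
#' @param name A name from [variant_names()] or [baseline_names()].
#' @param num_classes Number of output classes.
#' @param input_size Square input resolution used for MAC positions.
#' @return A tibble of primitive layers.
#' @export
arch_layers <- function(name, num_classes = 11L, input_size = 224L) {
  if (name %in% variant_names()) {
    return(mnv3_family_layers(variant_config(name, num_classes), input_size))
  }
  switch(name,
    resnet50 = resnet50_layers(num_classes, input_size),
    mobilenet_v2 = mobilenet_v2_layers(num_classes, input_size),
    mobilenet_v3_large = mnv3_large_layers(num_classes, input_size),
    shufflenet_v2_x1_0 = shufflenet_v2_layers(num_classes, input_size),
    stop("unknown model '", name, "'; valid names: ",
         paste(c(variant_names(), baseline_names()), collapse = ", "),
         call. = FALSE)
  )
}
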