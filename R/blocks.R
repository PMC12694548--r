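# Builders for the network building blocks: inverted-residual bottlenecks,
# the four attention mechanisms, and the multi-branch fusion stages.

#' Construct an attention block
#'
#' Builds one of the interchangeable attention gates. All blocks preserve
#' tensor shape, emit gate values strictly inside (0, 1), and reduce to the
#' identity when their gates are all ones.
#'
#' @param kind One of `"se"`, `"eca"`, `"cbam"`, `"ca"`, `"none"`.
#' @param channels Number of channels the block gates.
#' @param reduction Bottleneck reduction ratio; defaults follow the audited
#'   design (SE 4, CBAM-in-bottleneck 4, coordinate attention 9).
#' @return An engine module, or `NULL` for `"none"`.
#' @export
attention_block <- function(kind, channels, reduction = NULL) {
  switch(kind,
    none = NULL,
    se = nn_se(channels, reduction %||% 4L),
    eca = nn_eca(channels),
    cbam = nn_cbam(channels, reduction %||% CBAM_BNECK_REDUCTION),
    ca = nn_ca(channels, reduction %||% CA_REDUCTION),
    stop("unknown attention kind: ", kind)
  )
}

#' Run a block forward
#'
#' Applies any engine module (attention block, bottleneck, fusion stage) to a
#' feature batch in inference mode.
#'
#' @param block Module built by [attention_block()], [bottleneck_block()] or
#'   [ics_inception_block()].
#' @param x Feature array `(H, W, C, N)` or an internal ft matrix.
#' @param train Use training-mode batch statistics.
#' @return Output feature array of the same layout as the input.
#' @export
block_forward <- function(block, x, train = FALSE) {
  was_array <- is.null(attr(x, "ftdim"))
  if (was_array) x <- as_ft(x)
  y <- eng_fwd(block, x, train)$y
  if (was_array) ft_to_array(y) else y
}

#' One inverted-residual bottleneck specification
#'
#' @param in_ch,exp_ch,out_ch Input, expansion and output channel counts.
#' @param kernel Depthwise kernel size (3 or 5).
#' @param stride Stride (1 or 2).
#' @param attention Attention kind applied to the expanded features.
#' @param activation `"relu"` or `"hswish"`.
#' @return A one-row tibble in the layout of [mnv3_small_rows()].
#' @export
bottleneck_spec <- function(in_ch, exp_ch, out_ch, kernel = 3L, stride = 1L,
                            attention = "none", activation = "relu") {
  stopifnot(in_ch > 0, exp_ch > 0, out_ch > 0,
            kernel %in% c(3L, 5L), stride %in% c(1L, 2L))
  tibble::tibble(in_ch = as.integer(in_ch), kernel = as.integer(kernel),
                 exp_ch = as.integer(exp_ch), out_ch = as.integer(out_ch),
                 attention = attention, activation = activation,
                 stride = as.integer(stride))
}

#' Swap squeeze-and-excitation for coordinate attention
#'
#' Rewrites a bottleneck specification to carry a coordinate-attention block
#' (at the budget-pinned reduction ratio) in place of SE; all other fields are
#' unchanged. Rows without SE are returned untouched with a warning.
#'
#' @param spec One or more bottleneck rows.
#' @return The rewritten specification.
#' @examples
#' rows <- make_ca_block(mnv3_small_rows())
#' table(rows$attention)
#' @export
make_ca_block <- function(spec) {
  has_se <- spec$attention == "se"
  if (!any(has_se)) {
    warning("no SE attention present; specification returned unchanged")
    return(spec)
  }
  spec$attention[has_se] <- "ca"
  spec
}

#' Build an inverted-residual bottleneck module
#'
#' Expansion 1x1 convolution, depthwise convolution, optional attention on
#' the expanded features, and a linear 1x1 compression; wrapped in a residual
#' connection iff `stride == 1` and input and output channels match.
#'
#' @param spec A one-row specification from [bottleneck_spec()].
#' @return An engine module.
#' @export
bottleneck_block <- function(spec) {
  stopifnot(nrow(spec) == 1)
  act <- spec$activation
  mods <- list()
  if (spec$exp_ch != spec$in_ch) {
    mods <- c(mods, list(
      expand = nn_conv(spec$in_ch, spec$exp_ch, 1),
      expand_bn = nn_bn(spec$exp_ch), expand_act = nn_act(act)))
  }
  mods <- c(mods, list(
    dw = nn_dwconv(spec$exp_ch, spec$kernel, spec$stride),
    dw_bn = nn_bn(spec$exp_ch), dw_act = nn_act(act)))
  att <- attention_block(spec$attention, spec$exp_ch)
  if (!is.null(att)) mods <- c(mods, list(att = att))
  mods <- c(mods, list(
    project = nn_conv(spec$exp_ch, spec$out_ch, 1),
    project_bn = nn_bn(spec$out_ch)))
  inner <- nn_seq(mods)
  if (spec$stride == 1 && spec$in_ch == spec$out_ch) nn_res(inner) else inner
}

# ---- fusion stages ----------------------------------------------------------

#' Multi-branch fusion stage configuration
#'
#' Describes an Inception-style parallel stage built from 1x1 convolution
#' branches (one linear, one ReLU6-activated), a stride-1 max-pooling branch
#' (identity or with a 1x1 projection), dual channel/spatial attention over
#' the concatenation, and an optional linear 1x1 compression.
#'
#' @param in_channels Input channel count.
#' @param branch_channels Output width of each convolution branch.
#' @param project_pool Project the pooling branch to `branch_channels`
#'   (otherwise it passes its `in_channels` through unchanged).
#' @param apply_cbam Apply channel-then-spatial attention to the concatenation.
#' @param compress_to Optional output width of a trailing 1x1 compression.
#' @return An `ics_config` list; `concat_channels` gives the concatenated width.
#' @export
ics_inception_config <- function(in_channels, branch_channels,
                                 project_pool = FALSE, apply_cbam = TRUE,
                                 compress_to = NULL) {
  widths <- c(branch_channels, branch_channels,
              if (project_pool) branch_channels else in_channels)
  cfg <- list(in_channels = as.integer(in_channels),
              branch_channels = as.integer(branch_channels),
              branch_widths = as.integer(widths),
              project_pool = project_pool, apply_cbam = apply_cbam,
              compress_to = compress_to,
              concat_channels = as.integer(sum(widths)))
  class(cfg) <- "ics_config"
  cfg
}

#' Build a multi-branch fusion module
#'
#' @param cfg Configuration from [ics_inception_config()].
#' @return An engine module computing branch outputs on a shared input,
#'   concatenating along channels, applying dual attention, and optionally
#'   compressing.
#' @export
ics_inception_block <- function(cfg) {
  stopifnot(inherits(cfg, "ics_config"))
  if (sum(cfg$branch_widths) != cfg$concat_channels) {
    stop("branch channel sum (", sum(cfg$branch_widths),
         ") != concat_channels (", cfg$concat_channels, ")")
  }
  pool <- if (cfg$project_pool) {
    nn_seq(list(pool = nn_maxpool(3), proj = nn_conv(cfg$in_channels, cfg$branch_channels, 1),
                proj_bn = nn_bn(cfg$branch_channels)))
  } else nn_maxpool(3)
  branches <- list(
    linear = nn_seq(list(conv = nn_conv(cfg$in_channels, cfg$branch_channels, 1),
                         bn = nn_bn(cfg$branch_channels))),
    relu6 = nn_seq(list(conv = nn_conv(cfg$in_channels, cfg$branch_channels, 1),
                        bn = nn_bn(cfg$branch_channels), act = nn_act("relu6"))),
    pool = pool)
  mods <- list(branches = nn_concat(branches))
  if (cfg$apply_cbam) {
    mods <- c(mods, list(cbam = nn_cbam(cfg$concat_channels, CBAM_FUSION_REDUCTION)))
  }
  if (!is.null(cfg$compress_to)) {
    mods <- c(mods, list(compress = nn_conv(cfg$concat_channels, cfg$compress_to, 1),
                         compress_bn = nn_bn(cfg$compress_to)))
  }
  nn_seq(mods)
}

#' @rdname ics_inception_block
#' @param x Feature array `(H, W, C, N)`.
#' @param train Use training-mode batch statistics.
#' @export
ics_inception_forward <- function(cfg, x, train = FALSE) {
  block_forward(ics_inception_block(cfg), x, train)
}

# conventional Inception head used by the comparison variant
inception_head_block <- function(cin) {
  br <- function(...) nn_seq(list(...))
  nn_concat(list(
    b1 = br(conv = nn_conv(cin, 288, 1), bn = nn_bn(288), act = nn_act("relu")),
    b3 = br(red = nn_conv(cin, 16, 1), red_bn = nn_bn(16), red_act = nn_act("relu"),
            conv = nn_conv(16, 144, 3), bn = nn_bn(144), act = nn_act("relu")),
    b5 = br(red = nn_conv(cin, 8, 1), red_bn = nn_bn(8), red_act = nn_act("relu"),
            conv = nn_conv(8, 32, 5), bn = nn_bn(32), act = nn_act("relu")),
    pool = br(pool = nn_maxpool(3), proj = nn_conv(cin, 112, 1),
              bn = nn_bn(112), act = nn_act("relu"))))
}
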