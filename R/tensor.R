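# Feature tensors and spatial gather maps.
#
# A feature map batch is stored as a dense matrix with one column per channel
# and one row per (height, width, sample) position, row index
# h + (w-1)*H + (n-1)*H*W. This makes 1x1 convolutions (the bulk of the
# arithmetic in mobile architectures) single BLAS GEMM calls, and reduces
# every spatial operation to a precomputed row gather.

ft <- function(m, H, W, N) {
  attr(m, "ftdim") <- unname(c(H, W, N))
  m
}

ft_dim <- function(x) attr(x, "ftdim")

ft_like <- function(m, x) ft(m, ft_dim(x)[1], ft_dim(x)[2], ft_dim(x)[3])

#' @noRd
as_ft <- function(arr) {
  # arr: array (H, W, C, N) -> ft matrix (H*W*N, C)
  d <- dim(arr)
  m <- matrix(aperm(arr, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  ft(m, d[1], d[2], d[4])
}

ft_to_array <- function(x) {
  d <- unname(ft_dim(x))
  aperm(array(as.vector(x), c(d[1], d[2], d[3], ncol(x))), c(1, 2, 4, 3))
}

# ---- gather maps ------------------------------------------------------------
# A gather map sends an (Ho, Wo, N) output grid to rows of an (H, W, N) input,
# sampling input position ((ho-1)*stride + off_h + 1, ...). Out-of-range rows
# are zero-filled. Maps are memoised; they depend only on geometry.

.map_cache <- new.env(parent = emptyenv())

gather_map <- function(H, W, N, Ho, Wo, stride, off_h, off_w) {
  key <- paste(H, W, N, Ho, Wo, stride, off_h, off_w, sep = ",")
  hit <- .map_cache[[key]]
  if (!is.null(hit)) return(hit)
  ho <- rep.int(seq_len(Ho), Wo)
  wo <- rep.int(seq_len(Wo), rep.int(Ho, Wo))
  sh <- (ho - 1L) * stride + off_h + 1L
  sw <- (wo - 1L) * stride + off_w + 1L
  ok <- sh >= 1L & sh <= H & sw >= 1L & sw <= W
  src1 <- sh + (sw - 1L) * H                     # first sample block
  plane_out <- Ho * Wo
  plane_in <- H * W
  out_idx <- which(rep.int(ok, N)) ; src <- rep(src1[ok], N) +
    rep((seq_len(N) - 1L) * plane_in, each = sum(ok))
  map <- list(out = out_idx, src = src, n_out = plane_out * N, full = all(ok))
  assign(key, map, envir = .map_cache)
  map
}

gather <- function(m, map) {
  if (map$full) {
    out <- m[map$src, , drop = FALSE]
  } else {
    out <- matrix(0, map$n_out, ncol(m))
    out[map$out, ] <- m[map$src, , drop = FALSE]
  }
  out
}

# scatter-add the gradient of a gather (within one map, src rows are unique)
scatter_add <- function(acc, g, map) {
  if (map$full) {
    acc[map$src, ] <- acc[map$src, , drop = FALSE] + g
  } else {
    acc[map$src, ] <- acc[map$src, , drop = FALSE] + g[map$out, , drop = FALSE]
  }
  acc
}

conv_out_size <- function(H, k, stride, pad) (H + 2L * pad - k) %/% stride + 1L

# row grouping helpers for pooled statistics ---------------------------------

# group id collapsing spatial position -> one group per sample
sample_groups <- function(H, W, N) rep(seq_len(N), each = H * W)

# group ids collapsing one axis (for coordinate attention pooling)
h_groups <- function(H, W, N) {                 # keep (h, n), average over w
  rep.int(rep.int(seq_len(H), W), N) + (rep(seq_len(N), each = H * W) - 1L) * H
}
w_groups <- function(H, W, N) {                 # keep (w, n), average over h
  rep.int(rep(seq_len(W), each = H), N) + (rep(seq_len(N), each = H * W) - 1L) * W
}

group_mean <- function(m, grp, size) {
  out <- rowsum(m, grp, reorder = TRUE) / size
  rownames(out) <- NULL
  out
}

# expand per-group values back to rows
expand_rows <- function(g, grp) {
  out <- g[grp, , drop = FALSE]
  rownames(out) <- NULL
  out
}
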