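# Forward/backward implementations for the spatial and attention primitives.

# ---- standard convolution ---------------------------------------------------
# Weights are stored GEMM-ready: a (k*k*cin, cout) matrix whose rows are
# ordered channel-fastest within each kernel tap, taps enumerated kh-fastest.

conv_fwd <- function(mod, x) {
  d <- ft_dim(x)
  if (mod$k == 1 && mod$stride == 1) {
    y <- x %*% mod$w
    if (mod$has_bias) y <- y + rep(mod$b, each = nrow(y))
    return(list(y = ft_like(y, x), cache = list(x = x)))
  }
  Ho <- conv_out_size(d[1], mod$k, mod$stride, mod$pad)
  Wo <- conv_out_size(d[2], mod$k, mod$stride, mod$pad)
  k <- mod$k
  blocks <- vector("list", k * k)
  maps <- vector("list", k * k)
  t <- 0L
  for (kw in seq_len(k)) for (kh in seq_len(k)) {
    t <- t + 1L
    maps[[t]] <- gather_map(d[1], d[2], d[3], Ho, Wo, mod$stride,
                            kh - 1L - mod$pad, kw - 1L - mod$pad)
    blocks[[t]] <- gather(x, maps[[t]])
  }
  patches <- do.call(cbind, blocks)
  y <- patches %*% mod$w
  if (mod$has_bias) y <- y + rep(mod$b, each = nrow(y))
  list(y = ft(y, Ho, Wo, d[3]),
       cache = list(patches = patches, maps = maps, d = d))
}

conv_bwd <- function(mod, cache, gy, genv, path) {
  if (mod$k == 1 && mod$stride == 1) {
    genv[[paste0(path, ".w")]] <- crossprod(cache$x, gy)
    if (mod$has_bias) genv[[paste0(path, ".b")]] <- colSums(gy)
    return(ft_like(gy %*% t(mod$w), cache$x))
  }
  genv[[paste0(path, ".w")]] <- crossprod(cache$patches, gy)
  if (mod$has_bias) genv[[paste0(path, ".b")]] <- colSums(gy)
  gpatch <- gy %*% t(mod$w)
  d <- cache$d
  gx <- matrix(0, d[1] * d[2] * d[3], mod$cin)
  for (t in seq_along(cache$maps)) {
    cols <- (t - 1L) * mod$cin + seq_len(mod$cin)
    gx <- scatter_add(gx, gpatch[, cols, drop = FALSE], cache$maps[[t]])
  }
  ft(gx, d[1], d[2], d[3])
}

# ---- depthwise convolution --------------------------------------------------
# Implemented as a shift-and-add over kernel taps; weights are (k*k, C).

dwconv_fwd <- function(mod, x) {
  d <- ft_dim(x)
  Ho <- conv_out_size(d[1], mod$k, mod$stride, mod$pad)
  Wo <- conv_out_size(d[2], mod$k, mod$stride, mod$pad)
  k <- mod$k
  n_out <- Ho * Wo * d[3]
  y <- matrix(0, n_out, mod$C)
  t <- 0L
  for (kw in seq_len(k)) for (kh in seq_len(k)) {
    t <- t + 1L
    map <- gather_map(d[1], d[2], d[3], Ho, Wo, mod$stride,
                      kh - 1L - mod$pad, kw - 1L - mod$pad)
    y <- y + gather(x, map) * rep(mod$w[t, ], each = n_out)
  }
  list(y = ft(y, Ho, Wo, d[3]), cache = list(x = x, Ho = Ho, Wo = Wo))
}

dwconv_bwd <- function(mod, cache, gy, genv, path) {
  d <- ft_dim(cache$x)
  k <- mod$k
  n_out <- nrow(gy)
  gw <- matrix(0, k * k, mod$C)
  gx <- matrix(0, nrow(cache$x), mod$C)
  t <- 0L
  for (kw in seq_len(k)) for (kh in seq_len(k)) {
    t <- t + 1L
    map <- gather_map(d[1], d[2], d[3], cache$Ho, cache$Wo, mod$stride,
                      kh - 1L - mod$pad, kw - 1L - mod$pad)
    gw[t, ] <- colSums(gather(cache$x, map) * gy)
    gx <- scatter_add(gx, gy * rep(mod$w[t, ], each = n_out), map)
  }
  genv[[paste0(path, ".w")]] <- gw
  ft(gx, d[1], d[2], d[3])
}

# ---- batch normalisation ----------------------------------------------------
# Running statistics live in an environment so in-place updates survive R's
# copy-on-modify of the module tree.

bn_fwd <- function(mod, x, train) {
  n <- nrow(x)
  if (train) {
    mu <- colMeans(x)
    v <- colMeans(x * x) - mu * mu
    v[v < 0] <- 0
    invstd <- 1 / sqrt(v + mod$eps)
    st <- mod$stats
    st$rmean <- (1 - mod$momentum) * st$rmean + mod$momentum * mu
    st$rvar <- (1 - mod$momentum) * st$rvar + mod$momentum * v * n / max(n - 1, 1)
  } else {
    st <- mod$stats
    mu <- st$rmean
    invstd <- 1 / sqrt(st$rvar + mod$eps)
  }
  # fused affine: y = x * a + b; the normalised input is rebuilt in backward
  a <- mod$gamma * invstd
  y <- x * rep(a, each = n) + rep(mod$beta - mu * a, each = n)
  if (!is.null(attr(x, "ftdim"))) y <- ft_like(y, x)
  list(y = y, cache = list(x = x, mu = mu, invstd = invstd, train = train))
}

bn_bwd <- function(mod, cache, gy, genv, path) {
  n <- nrow(gy)
  xhat <- (cache$x - rep(cache$mu, each = n)) * rep(cache$invstd, each = n)
  genv[[paste0(path, ".gamma")]] <- colSums(gy * xhat)
  genv[[paste0(path, ".beta")]] <- colSums(gy)
  gxhat <- gy * rep(mod$gamma, each = n)
  if (!cache$train) {
    gx <- gxhat * rep(cache$invstd, each = n)
  } else {
    s1 <- colSums(gxhat)
    s2 <- colSums(gxhat * xhat)
    gx <- (gxhat - rep(s1 / n, each = n) - xhat * rep(s2 / n, each = n)) *
      rep(cache$invstd, each = n)
  }
  if (!is.null(attr(gy, "ftdim"))) gx <- ft_like(gx, gy)
  gx
}

# ---- max pooling ------------------------------------------------------------

maxpool_fwd <- function(mod, x) {
  d <- ft_dim(x)
  Ho <- conv_out_size(d[1], mod$k, mod$stride, mod$pad)
  Wo <- conv_out_size(d[2], mod$k, mod$stride, mod$pad)
  k <- mod$k
  n_out <- Ho * Wo * d[3]
  y <- matrix(-Inf, n_out, ncol(x))
  arg <- matrix(0L, n_out, ncol(x))
  t <- 0L
  for (kw in seq_len(k)) for (kh in seq_len(k)) {
    t <- t + 1L
    map <- gather_map(d[1], d[2], d[3], Ho, Wo, mod$stride,
                      kh - 1L - mod$pad, kw - 1L - mod$pad)
    g <- gather(x, map)
    if (!map$full) g[-map$out, ] <- -Inf
    upd <- g > y
    y[upd] <- g[upd]
    arg[upd] <- t
  }
  list(y = ft(y, Ho, Wo, d[3]),
       cache = list(arg = arg, d = d, Ho = Ho, Wo = Wo))
}

maxpool_bwd <- function(mod, cache, gy) {
  d <- cache$d
  k <- mod$k
  gx <- matrix(0, d[1] * d[2] * d[3], ncol(gy))
  t <- 0L
  for (kw in seq_len(k)) for (kh in seq_len(k)) {
    t <- t + 1L
    map <- gather_map(d[1], d[2], d[3], cache$Ho, cache$Wo, mod$stride,
                      kh - 1L - mod$pad, kw - 1L - mod$pad)
    gx <- scatter_add(gx, gy * (cache$arg == t), map)
  }
  ft(gx, d[1], d[2], d[3])
}

# ---- squeeze-and-excitation -------------------------------------------------

se_fwd <- function(mod, x, train) {
  d <- ft_dim(x)
  grp <- sample_groups(d[1], d[2], d[3])
  sq <- group_mean(x, grp, d[1] * d[2])
  r1 <- eng_fwd(mod$mods$fc1, sq, train)
  a1 <- act_fun("relu", r1$y)
  r2 <- eng_fwd(mod$mods$fc2, a1, train)
  g <- act_fun("hsigmoid", r2$y)
  y <- x * expand_rows(g, grp)
  list(y = ft_like(y, x),
       cache = list(x = x, grp = grp, hw = d[1] * d[2], c1 = r1$cache,
                    pre1 = r1$y, c2 = r2$cache, pre2 = r2$y, g = g))
}

se_bwd <- function(mod, cache, gy, genv, path) {
  grp <- cache$grp
  gx <- gy * expand_rows(cache$g, grp)
  gg <- rowsum(gy * cache$x, grp, reorder = TRUE)
  gpre2 <- act_grad("hsigmoid", cache$pre2, cache$g, gg)
  ga1 <- eng_bwd(mod$mods$fc2, cache$c2, gpre2, genv, paste(path, "fc2", sep = "."))
  gpre1 <- act_grad("relu", cache$pre1, NULL, ga1)
  gsq <- eng_bwd(mod$mods$fc1, cache$c1, gpre1, genv, paste(path, "fc1", sep = "."))
  ft_like(gx + expand_rows(gsq, grp) / cache$hw, gy)
}

# ---- efficient channel attention --------------------------------------------
# 1-D convolution of kernel k across the pooled channel descriptor.

eca_fwd <- function(mod, x, train) {
  d <- ft_dim(x)
  grp <- sample_groups(d[1], d[2], d[3])
  sq <- group_mean(x, grp, d[1] * d[2])
  C <- mod$C
  half <- (mod$k + 1L) %/% 2L
  z <- matrix(0, nrow(sq), C)
  for (j in seq_len(mod$k)) {
    off <- j - half
    src <- seq_len(C) + off
    okc <- src >= 1L & src <= C
    z[, okc] <- z[, okc, drop = FALSE] + mod$w[j] * sq[, src[okc], drop = FALSE]
  }
  g <- act_fun("sigmoid", z)
  list(y = ft_like(x * expand_rows(g, grp), x),
       cache = list(x = x, grp = grp, hw = d[1] * d[2], sq = sq, g = g))
}

eca_bwd <- function(mod, cache, gy, genv, path) {
  grp <- cache$grp
  C <- mod$C
  gx <- gy * expand_rows(cache$g, grp)
  gg <- rowsum(gy * cache$x, grp, reorder = TRUE)
  gz <- gg * cache$g * (1 - cache$g)
  half <- (mod$k + 1L) %/% 2L
  gw <- numeric(mod$k)
  gsq <- matrix(0, nrow(gz), C)
  for (j in seq_len(mod$k)) {
    off <- j - half
    src <- seq_len(C) + off
    okc <- src >= 1L & src <= C
    gw[j] <- sum(gz[, okc, drop = FALSE] * cache$sq[, src[okc], drop = FALSE])
    gsq[, src[okc]] <- gsq[, src[okc], drop = FALSE] + mod$w[j] * gz[, okc, drop = FALSE]
  }
  genv[[paste0(path, ".w")]] <- gw
  ft_like(gx + expand_rows(gsq, grp) / cache$hw, gy)
}

# ---- CBAM: channel then spatial attention -----------------------------------

row_max_by_sample <- function(x, H, W, N) {
  # per-sample, per-channel max over spatial positions; returns value matrix
  # (N, C) and the winning row offset within each sample block
  C <- ncol(x)
  hw <- H * W
  val <- matrix(0, N, C)
  argr <- matrix(0L, N, C)
  for (n in seq_len(N)) {
    sub <- x[(n - 1L) * hw + seq_len(hw), , drop = FALSE]
    am <- max.col(t(sub), ties.method = "first")
    argr[n, ] <- am
    val[n, ] <- sub[cbind(am, seq_len(C))]
  }
  list(val = val, argr = argr)
}

cbam_fwd <- function(mod, x, train) {
  d <- ft_dim(x)
  grp <- sample_groups(d[1], d[2], d[3])
  hw <- d[1] * d[2]
  avg <- group_mean(x, grp, hw)
  mx <- row_max_by_sample(x, d[1], d[2], d[3])
  mlp <- function(inp) {
    r1 <- eng_fwd(mod$mods$fc1, inp, train)
    a1 <- act_fun("relu", r1$y)
    r2 <- eng_fwd(mod$mods$fc2, a1, train)
    list(out = r2$y, c1 = r1$cache, pre1 = r1$y, c2 = r2$cache)
  }
  pa <- mlp(avg)
  pm <- mlp(mx$val)
  gc <- act_fun("sigmoid", pa$out + pm$out)
  x1 <- x * expand_rows(gc, grp)
  savg <- rowMeans(x1)
  argc <- max.col(x1, ties.method = "first")
  smax <- x1[cbind(seq_len(nrow(x1)), argc)]
  sft <- ft(cbind(savg, smax), d[1], d[2], d[3])
  rc <- eng_fwd(mod$mods$sconv, sft, train)
  rb <- eng_fwd(mod$mods$sbn, rc$y, train)
  gs <- act_fun("sigmoid", rb$y)
  y <- x1 * as.vector(gs)
  list(y = ft_like(y, x),
       cache = list(x = x, x1 = x1, grp = grp, hw = hw, d = d,
                    pa = pa, pm = pm, gc = gc, argr = mx$argr,
                    argc = argc, cc = rc$cache, cb = rb$cache,
                    pre_s = rb$y, gs = gs))
}

# run backward of a submodule into a scratch env, then accumulate into genv
bwd_accum <- function(mod, cache, gy, genv, path) {
  tmp <- new.env(parent = emptyenv())
  gx <- eng_bwd(mod, cache, gy, tmp, path)
  for (k in ls(tmp)) {
    genv[[k]] <- if (is.null(genv[[k]])) tmp[[k]] else genv[[k]] + tmp[[k]]
  }
  gx
}

cbam_bwd <- function(mod, cache, gy, genv, path) {
  d <- cache$d
  gs <- as.vector(cache$gs)
  gx1 <- gy * gs
  ggs <- rowSums(gy * cache$x1)
  gsp <- matrix(ggs * gs * (1 - gs), ncol = 1)
  gcb <- eng_bwd(mod$mods$sbn, cache$cb, gsp, genv, paste(path, "sbn", sep = "."))
  gsft <- eng_bwd(mod$mods$sconv, cache$cc, ft_like(gcb, gy), genv,
                  paste(path, "sconv", sep = "."))
  gx1 <- gx1 + gsft[, 1] / ncol(gy)                 # mean-over-channels path
  idx <- cbind(seq_len(nrow(gx1)), cache$argc)      # max-over-channels path
  gx1[idx] <- gx1[idx] + gsft[, 2]
  # channel attention
  grp <- cache$grp
  gx <- gx1 * expand_rows(cache$gc, grp)
  ggc <- rowsum(gx1 * cache$x, grp, reorder = TRUE)
  gpre <- ggc * cache$gc * (1 - cache$gc)
  mlp_bwd <- function(p, g) {
    ga1 <- bwd_accum(mod$mods$fc2, p$c2, g, genv, paste(path, "fc2", sep = "."))
    gp1 <- act_grad("relu", p$pre1, NULL, ga1)
    bwd_accum(mod$mods$fc1, p$c1, gp1, genv, paste(path, "fc1", sep = "."))
  }
  gavg <- mlp_bwd(cache$pa, gpre)
  gmx <- mlp_bwd(cache$pm, gpre)
  gx <- gx + expand_rows(gavg, grp) / cache$hw
  hw <- cache$hw
  for (n in seq_len(d[3])) {
    rows <- (n - 1L) * hw + cache$argr[n, ]
    ii <- cbind(rows, seq_len(ncol(gx)))
    gx[ii] <- gx[ii] + gmx[n, ]
  }
  ft_like(gx, gy)
}

# ---- coordinate attention ---------------------------------------------------
# Pools along each spatial axis separately, mixes through a shared bottleneck
# 1x1 conv, then emits per-axis gates so the attention map carries position.

ca_fwd <- function(mod, x, train) {
  d <- ft_dim(x)
  H <- d[1]; W <- d[2]; N <- d[3]
  hg <- h_groups(H, W, N)
  wg <- w_groups(H, W, N)
  xh <- group_mean(x, hg, W)        # (H*N, C)
  xw <- group_mean(x, wg, H)        # (W*N, C)
  cat_in <- rbind(xh, xw)
  r1 <- eng_fwd(mod$mods$conv1, cat_in, train)
  rb <- eng_fwd(mod$mods$bn1, r1$y, train)
  a <- act_fun("hswish", rb$y)
  nh <- H * N
  ah <- a[seq_len(nh), , drop = FALSE]
  aw <- a[-seq_len(nh), , drop = FALSE]
  rh <- eng_fwd(mod$mods$convh, ah, train)
  rw <- eng_fwd(mod$mods$convw, aw, train)
  gh <- act_fun("hsigmoid", rh$y)
  gw_ <- act_fun("hsigmoid", rw$y)
  Gh <- expand_rows(gh, hg)
  Gw <- expand_rows(gw_, wg)
  list(y = ft_like(x * Gh * Gw, x),
       cache = list(x = x, hg = hg, wg = wg, H = H, W = W, nh = nh,
                    c1 = r1$cache, cb = rb$cache, pre_bn = rb$y,
                    ch = rh$cache, preh = rh$y, cw = rw$cache, prew = rw$y,
                    gh = gh, gw = gw_, Gh = Gh, Gw = Gw))
}

ca_bwd <- function(mod, cache, gy, genv, path) {
  gx <- gy * cache$Gh * cache$Gw
  g_gh <- rowsum(gy * cache$x * cache$Gw, cache$hg, reorder = TRUE)
  g_gw <- rowsum(gy * cache$x * cache$Gh, cache$wg, reorder = TRUE)
  gph <- act_grad("hsigmoid", cache$preh, cache$gh, g_gh)
  gpw <- act_grad("hsigmoid", cache$prew, cache$gw, g_gw)
  gah <- eng_bwd(mod$mods$convh, cache$ch, gph, genv, paste(path, "convh", sep = "."))
  gaw <- eng_bwd(mod$mods$convw, cache$cw, gpw, genv, paste(path, "convw", sep = "."))
  ga <- rbind(gah, gaw)
  gpre <- act_grad("hswish", cache$pre_bn, NULL, ga)
  gb <- eng_bwd(mod$mods$bn1, cache$cb, gpre, genv, paste(path, "bn1", sep = "."))
  gcat <- eng_bwd(mod$mods$conv1, cache$c1, gb, genv, paste(path, "conv1", sep = "."))
  gxh <- gcat[seq_len(cache$nh), , drop = FALSE]
  gxw <- gcat[-seq_len(cache$nh), , drop = FALSE]
  gx <- gx + expand_rows(gxh, cache$hg) / cache$W +
    expand_rows(gxw, cache$wg) / cache$H
  ft_like(gx, gy)
}
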