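# Minimal reverse-mode network engine.
#
# Modules are plain lists with a `type`, weight arrays, and (for composites)
# child modules under `mods`. `eng_fwd()` returns the output plus a cache;
# `eng_bwd()` consumes the cache and writes weight gradients into a flat
# environment keyed by module path, returning the input gradient. Feature
# maps travel as ft matrices (see tensor.R); vectors after global pooling
# travel as plain (N x C) matrices.

# ---- activations ------------------------------------------------------------

act_fun <- function(kind, x) {
  switch(kind,
    relu = pmax(x, 0),
    relu6 = pmin(pmax(x, 0), 6),
    hsigmoid = pmin(pmax(x / 6 + 0.5, 0), 1),
    hswish = x * pmin(pmax(x / 6 + 0.5, 0), 1),
    sigmoid = 1 / (1 + exp(-x)),
    stop("unknown activation: ", kind)
  )
}

act_grad <- function(kind, x, y, gy) {
  switch(kind,
    relu = gy * (x > 0),
    relu6 = gy * (x > 0 & x < 6),
    hsigmoid = gy * ((x > -3 & x < 3) / 6),
    hswish = gy * (pmin(pmax(x / 6 + 0.5, 0), 1) + x * ((x > -3 & x < 3) / 6)),
    sigmoid = gy * y * (1 - y)
  )
}

#' Hard-swish and hard-sigmoid activations
#'
#' Piecewise-linear approximations of swish and sigmoid used throughout
#' mobile architectures: `hard_sigmoid(x) = clamp(x/6 + 1/2, 0, 1)`
#' (equivalently `relu6(x + 3)/6`) and `hard_swish(x) = x * hard_sigmoid(x)`.
#'
#' @param x numeric vector, matrix or array.
#' @return Object of the same shape as `x`.
#' @examples
#' hard_sigmoid(c(-3, 0, 3))   # 0, 0.5, 1
#' hard_swish(0)               # 0
#' @export
hard_swish <- function(x) act_fun("hswish", x)

#' @rdname hard_swish
#' @export
hard_sigmoid <- function(x) act_fun("hsigmoid", x)

# ---- weight init ------------------------------------------------------------

init_kaiming <- function(fan_in, n_out, n) {
  bound <- sqrt(6 / fan_in)
  matrix(stats::runif(n, -bound, bound), n / n_out, n_out)
}

# ---- primitive constructors -------------------------------------------------

nn_conv <- function(cin, cout, k = 1, stride = 1, pad = k %/% 2, bias = FALSE) {
  fan <- k * k * cin
  m <- list(type = "conv", cin = cin, cout = cout, k = k, stride = stride,
            pad = pad, has_bias = bias,
            w = init_kaiming(fan, cout, fan * cout))
  if (bias) m$b <- numeric(cout)
  m
}

nn_dwconv <- function(C, k, stride = 1) {
  list(type = "dwconv", C = C, k = k, stride = stride, pad = k %/% 2,
       w = init_kaiming(k * k, C, k * k * C))
}

nn_bn <- function(C, eps = 1e-5, momentum = 0.1) {
  st <- new.env(parent = emptyenv())
  st$rmean <- numeric(C)
  st$rvar <- rep(1, C)
  list(type = "bn", C = C, eps = eps, momentum = momentum,
       gamma = rep(1, C), beta = numeric(C), stats = st)
}

nn_act <- function(kind) list(type = "act", kind = kind)

nn_linear <- function(cin, cout, init = c("normal", "kaiming")) {
  init <- match.arg(init)
  w <- if (init == "normal") {
    matrix(stats::rnorm(cin * cout, 0, 0.01), cin, cout)
  } else init_kaiming(cin, cout, cin * cout)
  list(type = "linear", cin = cin, cout = cout, w = w, b = numeric(cout))
}

nn_dropout <- function(p = 0.2) list(type = "dropout", p = p)

nn_gpool <- function() list(type = "gpool")

nn_maxpool <- function(k = 3, stride = 1) {
  list(type = "maxpool", k = k, stride = stride, pad = k %/% 2)
}

nn_identity <- function() list(type = "identity")

nn_seq <- function(...) {
  mods <- list(...)
  if (length(mods) == 1 && is.null(mods[[1]]$type)) mods <- mods[[1]]
  if (is.null(names(mods))) names(mods) <- sprintf("s%02d", seq_along(mods))
  list(type = "seq", mods = mods)
}

nn_res <- function(inner) list(type = "res", mods = list(inner = inner))

nn_concat <- function(branches) {
  if (is.null(names(branches))) names(branches) <- sprintf("b%d", seq_along(branches))
  list(type = "concat", branches = names(branches), mods = branches)
}

# ---- attention blocks -------------------------------------------------------

nn_se <- function(cexp, reduction = 4) {
  s <- make_divisible(cexp %/% reduction, 8)
  list(type = "se", C = cexp, s = s,
       mods = list(fc1 = nn_linear(cexp, s, "kaiming"),
                   fc2 = nn_linear(s, cexp, "kaiming")))
}

eca_kernel <- function(C, gamma = 2, b = 1) {
  t <- as.integer(abs((log2(C) + b) / gamma))
  if (t %% 2 == 1) t else t + 1L
}

nn_eca <- function(C) {
  k <- eca_kernel(C)
  list(type = "eca", C = C, k = k,
       w = stats::runif(k, -sqrt(6 / k), sqrt(6 / k)))
}

nn_cbam <- function(C, reduction = 16, spatial_k = 7) {
  mid <- max(8L, C %/% reduction)
  list(type = "cbam", C = C, mid = mid,
       mods = list(fc1 = nn_linear(C, mid, "kaiming"),
                   fc2 = nn_linear(mid, C, "kaiming"),
                   sconv = nn_conv(2, 1, k = spatial_k, bias = FALSE),
                   sbn = nn_bn(1)))
}

nn_ca <- function(C, reduction = 9) {
  mid <- max(8L, C %/% reduction)
  list(type = "ca", C = C, mid = mid,
       mods = list(conv1 = nn_linear(C, mid, "kaiming"),
                   bn1 = nn_bn(mid),
                   convh = nn_linear(mid, C, "kaiming"),
                   convw = nn_linear(mid, C, "kaiming")))
}

make_divisible <- function(v, divisor = 8) {
  new_v <- max(divisor, as.integer(v + divisor / 2) %/% divisor * divisor)
  if (new_v < 0.9 * v) new_v <- new_v + divisor
  as.integer(new_v)
}

# ---- parameter walkers ------------------------------------------------------

param_slots <- function(mod) {
  switch(mod$type,
    conv = if (mod$has_bias) c("w", "b") else "w",
    dwconv = "w",
    bn = c("gamma", "beta"),
    linear = c("w", "b"),
    eca = "w",
    character(0)
  )
}

buffer_slots <- function(mod) if (mod$type == "bn") c("rmean", "rvar") else character(0)

slot_get <- function(mod, s) if (s %in% c("rmean", "rvar")) mod$stats[[s]] else mod[[s]]

eng_walk <- function(mod, path = "m", slots = param_slots) {
  out <- list()
  for (s in slots(mod)) out[[paste(path, s, sep = ".")]] <- slot_get(mod, s)
  for (nm in names(mod$mods)) {
    out <- c(out, eng_walk(mod$mods[[nm]], paste(path, nm, sep = "."), slots))
  }
  out
}

eng_params <- function(mod) eng_walk(mod)
eng_buffers <- function(mod) eng_walk(mod, slots = buffer_slots)

eng_set <- function(mod, values, path = "m", slots = param_slots) {
  for (s in slots(mod)) {
    key <- paste(path, s, sep = ".")
    if (!is.null(values[[key]])) {
      if (s %in% c("rmean", "rvar")) mod$stats[[s]] <- values[[key]] else mod[[s]] <- values[[key]]
    }
  }
  for (nm in names(mod$mods)) {
    mod$mods[[nm]] <- eng_set(mod$mods[[nm]], values, paste(path, nm, sep = "."), slots)
  }
  mod
}

n_params_of <- function(mod) sum(vapply(eng_params(mod), length, 0L))

# ---- forward ----------------------------------------------------------------

eng_fwd <- function(mod, x, train = FALSE) {
  switch(mod$type,
    identity = list(y = x, cache = NULL),
    conv = conv_fwd(mod, x),
    dwconv = dwconv_fwd(mod, x),
    bn = bn_fwd(mod, x, train),
    act = {
      y <- act_fun(mod$kind, x)
      if (!is.null(attr(x, "ftdim"))) y <- ft_like(y, x)
      list(y = y, cache = list(x = x, y = y))
    },
    linear = {
      y <- x %*% mod$w
      y <- y + rep(mod$b, each = nrow(y))
      list(y = y, cache = list(x = x))
    },
    dropout = {
      if (!train || mod$p <= 0) return(list(y = x, cache = list(mask = NULL)))
      mask <- (matrix(stats::runif(length(x)), nrow(x)) >= mod$p) / (1 - mod$p)
      list(y = x * mask, cache = list(mask = mask))
    },
    gpool = {
      d <- ft_dim(x)
      grp <- sample_groups(d[1], d[2], d[3])
      list(y = group_mean(x, grp, d[1] * d[2]), cache = list(d = d))
    },
    maxpool = maxpool_fwd(mod, x),
    seq = {
      caches <- vector("list", length(mod$mods))
      for (i in seq_along(mod$mods)) {
        r <- eng_fwd(mod$mods[[i]], x, train)
        x <- r$y
        caches[[i]] <- r$cache
      }
      list(y = x, cache = caches)
    },
    res = {
      r <- eng_fwd(mod$mods$inner, x, train)
      list(y = ft_like(x + r$y, x), cache = r$cache)
    },
    concat = {
      ys <- vector("list", length(mod$mods))
      caches <- vector("list", length(mod$mods))
      for (i in seq_along(mod$mods)) {
        r <- eng_fwd(mod$mods[[i]], x, train)
        ys[[i]] <- r$y
        caches[[i]] <- r$cache
      }
      list(y = ft_like(do.call(cbind, ys), x),
           cache = list(caches = caches, widths = vapply(ys, ncol, 0L)))
    },
    se = se_fwd(mod, x, train),
    eca = eca_fwd(mod, x, train),
    cbam = cbam_fwd(mod, x, train),
    ca = ca_fwd(mod, x, train),
    stop("unknown module type: ", mod$type)
  )
}

# ---- backward ---------------------------------------------------------------

# writes gradients into environment `genv` under `<path>.<slot>`, returns gx
eng_bwd <- function(mod, cache, gy, genv, path = "m") {
  switch(mod$type,
    identity = gy,
    conv = conv_bwd(mod, cache, gy, genv, path),
    dwconv = dwconv_bwd(mod, cache, gy, genv, path),
    bn = bn_bwd(mod, cache, gy, genv, path),
    act = {
      g <- act_grad(mod$kind, cache$x, cache$y, gy)
      if (!is.null(attr(cache$x, "ftdim"))) g <- ft_like(g, cache$x)
      g
    },
    linear = {
      genv[[paste0(path, ".w")]] <- crossprod(cache$x, gy)
      genv[[paste0(path, ".b")]] <- colSums(gy)
      gy %*% t(mod$w)
    },
    dropout = if (is.null(cache$mask)) gy else gy * cache$mask,
    gpool = {
      d <- cache$d
      grp <- sample_groups(d[1], d[2], d[3])
      ft(expand_rows(gy, grp) / (d[1] * d[2]), d[1], d[2], d[3])
    },
    maxpool = maxpool_bwd(mod, cache, gy),
    seq = {
      for (i in rev(seq_along(mod$mods))) {
        gy <- eng_bwd(mod$mods[[i]], cache[[i]], gy,
                      genv, paste(path, names(mod$mods)[i] %||% i, sep = "."))
      }
      gy
    },
    res = {
      gin <- eng_bwd(mod$mods$inner, cache, gy, genv, paste(path, "inner", sep = "."))
      ft_like(gy + gin, gy)
    },
    concat = {
      gx <- NULL
      off <- 0L
      for (i in seq_along(mod$mods)) {
        gi <- gy[, off + seq_len(cache$widths[i]), drop = FALSE]
        gi <- ft_like(gi, gy)
        g <- eng_bwd(mod$mods[[i]], cache$caches[[i]], gi,
                     genv, paste(path, names(mod$mods)[i] %||% i, sep = "."))
        gx <- if (is.null(gx)) g else gx + g
        off <- off + cache$widths[i]
      }
      ft_like(gx, gy)
    },
    se = se_bwd(mod, cache, gy, genv, path),
    eca = eca_bwd(mod, cache, gy, genv, path),
    cbam = cbam_bwd(mod, cache, gy, genv, path),
    ca = ca_bwd(mod, cache, gy, genv, path),
    stop("unknown module type: ", mod$type)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
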