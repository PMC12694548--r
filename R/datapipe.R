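# Manifest handling: stratified splitting, k-fold assignment, augmentation
# and image loading.

#' Per-class split sizes by largest-remainder apportionment
#'
#' Computes per-class train/val/test counts for the given ratios. Validation
#' and test receive `ceiling(ratio * N)` images in total, allocated across
#' classes by largest remainder (ties resolved toward larger classes); the
#' training split takes each class's remainder. On the published per-class
#' counts with ratios 0.8/0.1/0.1 this reproduces the 4839/606/606 partition
#' exactly.
#'
#' @param per_class_counts Named integer vector of class sizes.
#' @param ratios Named ratios summing to 1; the first entry is the residual
#'   (training) split.
#' @return Tibble with one row per class and one column per split.
#' @examples
#' split_sizes(c(A = 10, B = 10))
#' @export
split_sizes <- function(per_class_counts,
                        ratios = c(train = 0.8, val = 0.1, test = 0.1)) {
  if (abs(sum(ratios) - 1) > 1e-8) stop("split ratios must sum to 1")
  stopifnot(length(ratios) >= 2, all(per_class_counts >= 1))
  n_total <- sum(per_class_counts)
  out <- tibble::tibble(class = names(per_class_counts),
                        n = as.integer(per_class_counts))
  rest <- out$n
  for (s in names(ratios)[-1]) {
    tot <- as.integer(ceiling(ratios[[s]] * n_total))
    quota <- per_class_counts * ratios[[s]]
    base <- floor(quota)
    rem <- tot - sum(base)
    if (rem > 0) {
      pri <- order(quota - base, per_class_counts, decreasing = TRUE)[seq_len(rem)]
      base[pri] <- base[pri] + 1
    }
    out[[s]] <- as.integer(base)
    rest <- rest - out[[s]]
  }
  if (any(rest < 0)) stop("ratios leave a class with a negative residual split")
  out[[names(ratios)[1]]] <- rest
  out[, c("class", "n", names(ratios))]
}

#' Stratified train/val/test split
#'
#' Assigns each manifest record to a split, per class, using
#' [split_sizes()] apportionment; membership within a class is randomised by
#' `seed`, so the same seed yields an identical manifest.
#'
#' @param manifest A manifest tibble with a `cultivar` (or `class`) column.
#' @param ratios Named split ratios summing to 1 (first = training).
#' @param seed Integer seed.
#' @return The manifest with a `split` factor column.
#' @export
stratified_split <- function(manifest,
                             ratios = c(train = 0.8, val = 0.1, test = 0.1),
                             seed = 1) {
  cls_col <- if ("cultivar" %in% names(manifest)) "cultivar" else "class"
  counts <- table(manifest[[cls_col]])
  if (any(counts < 10)) stop("every class needs at least 10 records to split")
  sizes <- split_sizes(stats::setNames(as.integer(counts), names(counts)), ratios)
  set.seed(seed)
  manifest$split <- NA_character_
  for (i in seq_len(nrow(sizes))) {
    rows <- which(manifest[[cls_col]] == sizes$class[i])
    rows <- rows[sample.int(length(rows))]
    lab <- rep(names(ratios), times = as.integer(sizes[i, names(ratios)]))
    manifest$split[rows] <- lab
  }
  manifest$split <- factor(manifest$split, levels = names(ratios))
  manifest
}

#' Stratified k-fold assignment
#'
#' Assigns a fold id to every record such that, within each class, fold sizes
#' differ by at most one; every record lands in exactly one fold.
#'
#' @param manifest A manifest tibble.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return The manifest with an integer `fold` column.
#' @export
make_folds <- function(manifest, k = 5, seed = 1) {
  stopifnot(k >= 2)
  cls_col <- if ("cultivar" %in% names(manifest)) "cultivar" else "class"
  counts <- table(manifest[[cls_col]])
  if (any(counts < k)) {
    stop("class '", names(counts)[which.min(counts)], "' has fewer than k = ",
         k, " records")
  }
  set.seed(seed)
  manifest$fold <- NA_integer_
  totals <- integer(k)
  for (cl in names(counts)) {
    rows <- which(manifest[[cls_col]] == cl)
    n <- length(rows)
    base <- n %/% k
    per_fold <- rep(base, k)
    extra <- n - base * k
    if (extra > 0) {
      # give remainders to the currently smallest folds: overall fold totals
      # stay within one of each other
      spill <- order(totals, stats::runif(k))[seq_len(extra)]
      per_fold[spill] <- per_fold[spill] + 1L
    }
    totals <- totals + per_fold
    ids <- rep(seq_len(k), per_fold)
    manifest$fold[rows] <- sample(ids)
  }
  manifest
}

#' Write / read a manifest as CSV
#'
#' Round-trips all manifest columns losslessly.
#'
#' @param manifest Manifest tibble.
#' @param path CSV path.
#' @return `read_manifest()` returns the manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  df <- manifest
  if (is.factor(df$split)) df$split <- as.character(df$split)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

# ---- augmentation -----------------------------------------------------------

#' Training-set augmentation configuration
#'
#' Field-style photographic augmentation: random horizontal flip (p = 0.5),
#' random rotation in \[-15, 15\] degrees (reflect padding), independent
#' multiplicative brightness and contrast factors in \[0.9, 1.1\], and 3x3
#' Gaussian blur with probability 0.3 (sigma drawn uniformly from
#' \[0.1, 2\]). Applied to the training split only.
#'
#' @param hflip_p Horizontal-flip probability.
#' @param rotate_deg Symmetric rotation bound in degrees.
#' @param factor_range Brightness/contrast multiplicative range.
#' @param blur_p Blur probability.
#' @param blur_sigma Blur sigma range.
#' @return An `augment_config` list.
#' @export
augment_config <- function(hflip_p = 0.5, rotate_deg = 15,
                           factor_range = c(0.9, 1.1), blur_p = 0.3,
                           blur_sigma = c(0.1, 2)) {
  stopifnot(hflip_p >= 0, hflip_p <= 1, blur_p >= 0, blur_p <= 1,
            rotate_deg >= 0)
  structure(list(hflip_p = hflip_p, rotate_deg = rotate_deg,
                 factor_range = factor_range, blur_p = blur_p,
                 blur_sigma = blur_sigma), class = "augment_config")
}

# bilinear rotation with reflect padding
rotate_bilinear <- function(img, angle) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  a <- angle * pi / 180
  c1 <- (H + 1) / 2; c2 <- (W + 1) / 2
  xs <- matrix(seq_len(H), H, W) - c1
  ys <- matrix(rep(seq_len(W), each = H), H, W) - c2
  sx <- c1 + cos(a) * xs + sin(a) * ys
  sy <- c2 - sin(a) * xs + cos(a) * ys
  reflect <- function(v, n) {
    v <- abs(v - 1) %% (2 * (n - 1))
    pmin(v, 2 * (n - 1) - v) + 1
  }
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  xr0 <- reflect(x0, H); xr1 <- reflect(x0 + 1, H)
  yr0 <- reflect(y0, W); yr1 <- reflect(y0 + 1, W)
  out <- array(0, d)
  for (ch in seq_len(d[3])) {
    p <- img[, , ch]
    out[, , ch] <-
      p[cbind(c(xr0), c(yr0))] * (1 - fx) * (1 - fy) +
      p[cbind(c(xr1), c(yr0))] * fx * (1 - fy) +
      p[cbind(c(xr0), c(yr1))] * (1 - fx) * fy +
      p[cbind(c(xr1), c(yr1))] * fx * fy
  }
  out
}

gaussian_blur3 <- function(img, sigma) {
  k <- exp(-((-1:1)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_reflect <- function(m) rbind(m[2, ], m, m[nrow(m) - 1, ])
  for (ch in seq_len(dim(img)[3])) {
    p <- img[, , ch]
    pp <- pad_reflect(p)
    p <- k[1] * pp[seq_len(nrow(p)), ] + k[2] * pp[seq_len(nrow(p)) + 1, ] +
      k[3] * pp[seq_len(nrow(p)) + 2, ]
    pp <- t(pad_reflect(t(p)))
    p <- k[1] * pp[, seq_len(ncol(p))] + k[2] * pp[, seq_len(ncol(p)) + 1] +
      k[3] * pp[, seq_len(ncol(p)) + 2]
    img[, , ch] <- p
  }
  img
}

#' Augment one image
#'
#' Draws augmentation parameters from the current RNG stream and applies
#' them; the label is untouched and the output size equals the input size.
#' With no flip/blur drawn, zero rotation and unit factors the image passes
#' through unchanged.
#'
#' @param img Numeric array (H, W, 3) in `[0, 1]`.
#' @param cfg An [augment_config()].
#' @return Augmented image array.
#' @export
augment_image <- function(img, cfg = augment_config()) {
  if (stats::runif(1) < cfg$hflip_p) img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  ang <- stats::runif(1, -cfg$rotate_deg, cfg$rotate_deg)
  if (abs(ang) > 1e-12) img <- rotate_bilinear(img, ang)
  fb <- stats::runif(1, cfg$factor_range[1], cfg$factor_range[2])
  fc <- stats::runif(1, cfg$factor_range[1], cfg$factor_range[2])
  img <- img * fb
  mu <- mean(img)
  img <- (img - mu) * fc + mu
  if (stats::runif(1) < cfg$blur_p) {
    img <- gaussian_blur3(img, stats::runif(1, cfg$blur_sigma[1], cfg$blur_sigma[2]))
  }
  pmin(pmax(img, 0), 1)
}

#' Resize and normalise an image
#'
#' Bilinear resize to a square target followed by per-channel normalisation
#' `(x - mean) / sd` (default 0.5/0.5; ImageNet statistics may be supplied
#' instead).
#'
#' @param img Numeric array (H, W, 3) in `[0, 1]`.
#' @param size Target side length (the standard pipeline uses 224).
#' @param mean,sd Normalisation constants (scalar or length-3).
#' @return Numeric array (size, size, 3).
#' @export
resize_normalize <- function(img, size = 224L, mean = 0.5, sd = 0.5) {
  d <- dim(img)
  if (length(d) != 3 || d[3] != 3) stop("expected an RGB (H, W, 3) array")
  if (d[1] != size || d[2] != size) {
    sx <- (seq_len(size) - 0.5) * d[1] / size + 0.5
    sy <- (seq_len(size) - 0.5) * d[2] / size + 0.5
    x0 <- pmin(pmax(floor(sx), 1), d[1] - 1); fx <- pmin(pmax(sx - x0, 0), 1)
    y0 <- pmin(pmax(floor(sy), 1), d[2] - 1); fy <- pmin(pmax(sy - y0, 0), 1)
    out <- array(0, c(size, size, 3))
    FX <- matrix(fx, size, size); FY <- matrix(fy, size, size, byrow = TRUE)
    for (ch in 1:3) {
      p <- img[, , ch]
      out[, , ch] <- p[x0, y0] * (1 - FX) * (1 - FY) + p[x0 + 1, y0] * FX * (1 - FY) +
        p[x0, y0 + 1] * (1 - FX) * FY + p[x0 + 1, y0 + 1] * FX * FY
    }
    img <- out
  }
  mean <- rep(mean, length.out = 3); sd <- rep(sd, length.out = 3)
  for (ch in 1:3) img[, , ch] <- (img[, , ch] - mean[ch]) / sd[ch]
  img
}

#' Load manifest images into memory
#'
#' Reads PNGs from the manifest paths (or takes arrays from the `images`
#' attribute produced by [generate_leaf_dataset()] with `keep_images = TRUE`).
#'
#' @param manifest Manifest tibble.
#' @return List of (H, W, 3) arrays aligned with manifest rows.
#' @export
load_images <- function(manifest) {
  imgs <- attr(manifest, "images")
  if (!is.null(imgs)) return(imgs)
  if (all(is.na(manifest$path))) {
    stop("manifest has no image paths and no in-memory images")
  }
  lapply(manifest$path, function(p) {
    a <- png::readPNG(p)
    if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
    a[, , 1:3, drop = FALSE]
  })
}

# stack a list of (H, W, 3) arrays into an engine ft batch
images_to_batch <- function(imgs) {
  d <- dim(imgs[[1]])
  arr <- array(0, c(d[1], d[2], 3, length(imgs)))
  for (i in seq_along(imgs)) arr[, , , i] <- imgs[[i]]
  as_ft(arr)
}
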