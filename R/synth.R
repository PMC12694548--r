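# Procedural synthetic vineyard-leaf scenes.
#
# The generator emulates the statistical structure of field photographs of
# grape leaves: eleven classes separable by silhouette (lobe count, serration
# frequency/amplitude) and colour, composed over cluttered backgrounds built
# from 2-4 natural elements (soil, grass, vine trunk), with a controlled
# occlusion mix (65% < 15%, 25% 15-30%, 10% 30-40% of the leaf mask).
# Geometry is a polar lobed curve with sinusoidal serration -- the goal is a
# class-separable, clutter-robust benchmark, not botanical realism.

#' Synthetic cultivar shape presets
#'
#' Eleven parameter tuples, one per synthetic class, pairwise distinct in at
#' least two parameters: lobe count, serration frequency and amplitude, vein
#' branching angle (degrees from the midrib), hue/saturation centre and size
#' scale.
#'
#' @return A tibble with one row per synthetic cultivar.
#' @export
cultivar_presets <- function() {
  tibble::tribble(
    ~class_id, ~cultivar, ~lobes, ~serr_freq, ~serr_amp, ~vein_angle, ~hue, ~sat, ~scale,
    1L, "Auxerrois",          3L, 14L, 0.030, 35, 0.26, 0.55, 0.70,
    2L, "Cabernet Franc",     5L, 18L, 0.050, 45, 0.30, 0.60, 0.62,
    3L, "Cabernet Sauvignon", 5L, 26L, 0.065, 50, 0.32, 0.70, 0.66,
    4L, "Chardonnay",         3L, 22L, 0.045, 40, 0.24, 0.50, 0.74,
    5L, "Merlot",             5L, 12L, 0.025, 55, 0.28, 0.65, 0.58,
    6L, "Mueller Thurgau",    7L, 16L, 0.040, 38, 0.22, 0.45, 0.68,
    7L, "Pinot Noir",         3L, 30L, 0.060, 48, 0.34, 0.60, 0.60,
    8L, "Riesling",           5L, 22L, 0.035, 42, 0.20, 0.55, 0.72,
    9L, "Sauvignon Blanc",    7L, 26L, 0.055, 52, 0.27, 0.40, 0.64,
    10L, "Syrah",             7L, 12L, 0.070, 45, 0.35, 0.75, 0.70,
    11L, "Tempranillo",       3L, 18L, 0.070, 60, 0.18, 0.65, 0.56
  )
}

#' Published per-class image counts
#'
#' The per-cultivar totals of the augmented eleven-cultivar grapevine-leaf
#' dataset (6051 images); `tiny_counts()` is the 20-per-class preset used for
#' continuous testing.
#'
#' @return Named integer vector of per-class counts.
#' @export
published_counts <- function() {
  stats::setNames(c(528L, 360L, 666L, 623L, 366L, 726L, 353L, 696L, 600L,
                    713L, 420L), cultivar_presets()$cultivar)
}

#' @rdname published_counts
#' @export
tiny_counts <- function() {
  stats::setNames(rep(20L, 11L), cultivar_presets()$cultivar)
}

#' Silhouette radial profile
#'
#' The leaf boundary radius as a function of polar angle:
#' `r(theta) = scale * (1 + lobe_amp*cos(lobes*theta)) *
#' (1 + serr_amp*cos(serr_freq*theta))`. With serration amplitude zero, the
#' derivative changes sign exactly `2 * lobes` times per revolution.
#'
#' @param params One row of [cultivar_presets()].
#' @param n Number of angular samples.
#' @param lobe_amp Lobe modulation depth.
#' @return Numeric vector of radii (unit scale).
#' @export
leaf_radial_profile <- function(params, n = 720, lobe_amp = 0.18) {
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  params$scale * (1 + lobe_amp * cos(params$lobes * theta)) *
    (1 + params$serr_amp * cos(params$serr_freq * theta))
}

hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

# smooth value noise: random coarse grid, bilinear-upsampled
value_noise <- function(size, cells = 8) {
  g <- matrix(stats::runif((cells + 1)^2), cells + 1, cells + 1)
  pos <- (seq_len(size) - 1) / (size - 1) * cells
  i0 <- pmin(floor(pos), cells - 1)
  fr <- pos - i0
  i0 <- i0 + 1
  ga <- g[i0, i0]; gb <- g[i0 + 1, i0]; gc <- g[i0, i0 + 1]; gd <- g[i0 + 1, i0 + 1]
  fx <- matrix(fr, size, size); fy <- matrix(fr, size, size, byrow = TRUE)
  ga * (1 - fx) * (1 - fy) + gb * fx * (1 - fy) + gc * (1 - fx) * fy + gd * fx * fy
}

# squared distance from each grid point to a segment (x1,y1)-(x2,y2)
seg_dist2 <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  len2 <- vx^2 + vy^2 + 1e-12
  t <- pmin(pmax(((px - x1) * vx + (py - y1) * vy) / len2, 0), 1)
  (px - x1 - t * vx)^2 + (py - y1 - t * vy)^2
}

#' Render a synthetic leaf sprite
#'
#' Draws a lobed, serrated leaf silhouette with a vein skeleton (midrib plus
#' side branches at the preset branching angle) on a transparent canvas.
#' Deterministic given `(params, seed)`.
#'
#' @param params One row of [cultivar_presets()] (possibly jittered).
#' @param seed Integer seed.
#' @param size Canvas size in pixels.
#' @return List with `rgb` (size x size x 3 array, zero outside the leaf) and
#'   logical `mask`.
#' @export
render_leaf <- function(params, seed, size = 224L) {
  set.seed(seed)
  cx <- 0.5 * (size + 1); cy <- 0.5 * (size + 1)
  px <- matrix(seq_len(size), size, size) - cx
  py <- matrix(seq_len(size), size, size, byrow = TRUE) - cy
  rho <- sqrt(px^2 + py^2)
  theta <- atan2(py, px)
  phase <- stats::runif(1, 0, 2 * pi)
  rmax <- 0.5 * size * params$scale *
    (1 + 0.18 * cos(params$lobes * (theta - phase))) *
    (1 + params$serr_amp * cos(params$serr_freq * (theta - phase)))
  mask <- rho <= rmax
  # veins: midrib through the centre at `phase`, branches at vein_angle
  vdir <- phase
  ang <- params$vein_angle * pi / 180
  L <- 0.5 * size * params$scale
  vein <- seg_dist2(px, py, -L * cos(vdir), -L * sin(vdir),
                    L * cos(vdir), L * sin(vdir)) < (size / 150)^2
  for (tpos in c(-0.5, -0.15, 0.2, 0.55)) {
    bx <- tpos * L * cos(vdir); by <- tpos * L * sin(vdir)
    for (sgn in c(-1, 1)) {
      ex <- bx + 0.45 * L * cos(vdir + sgn * ang)
      ey <- by + 0.45 * L * sin(vdir + sgn * ang)
      vein <- vein | seg_dist2(px, py, bx, by, ex, ey) < (size / 200)^2
    }
  }
  shade <- 0.75 + 0.25 * (1 - rho / (rmax + 1e-9))      # radial shading
  tex <- 0.92 + 0.16 * value_noise(size, 10)            # surface texture
  v <- pmin(pmax(0.55 * shade * tex, 0), 1)
  v[vein] <- v[vein] * 0.55                             # dark veins
  hue <- params$hue + 0.02 * (value_noise(size, 6) - 0.5)
  col <- hsv_to_rgb(hue, params$sat, v)
  rgb <- array(0, c(size, size, 3))
  rgb[, , 1] <- col$r * mask
  rgb[, , 2] <- col$g * mask
  rgb[, , 3] <- col$b * mask
  list(rgb = rgb, mask = mask)
}

#' Occlusion bands
#'
#' The three occlusion regimes of the scene generator: fraction of the leaf
#' mask covered by foreground clutter below 15% (none), 15-30% (slight),
#' 30-40% (moderate).
#'
#' @return Tibble with band name and `[lo, hi)` bounds.
#' @export
occlusion_bands <- function() {
  tibble::tribble(
    ~band, ~lo, ~hi,
    "none", 0, 0.15,
    "slight", 0.15, 0.30,
    "moderate", 0.30, 0.40
  )
}

element_palettes <- function() {
  list(soil = list(h = c(0.06, 0.10), s = c(0.35, 0.6), v = c(0.25, 0.55)),
       grass = list(h = c(0.23, 0.33), s = c(0.45, 0.75), v = c(0.3, 0.65)),
       trunk = list(h = c(0.05, 0.09), s = c(0.15, 0.4), v = c(0.15, 0.4)))
}

render_element <- function(name, size) {
  pal <- element_palettes()[[name]]
  n1 <- value_noise(size, 6); n2 <- value_noise(size, 16)
  mixed <- 0.6 * n1 + 0.4 * n2
  h <- pal$h[1] + (pal$h[2] - pal$h[1]) * n1
  s <- pal$s[1] + (pal$s[2] - pal$s[1]) * n2
  v <- pal$v[1] + (pal$v[2] - pal$v[1]) * mixed
  col <- hsv_to_rgb(h, s, v)
  out <- array(0, c(size, size, 3))
  out[, , 1] <- col$r; out[, , 2] <- col$g; out[, , 3] <- col$b
  out
}

#' Scene composition parameters
#'
#' @param elements 2-4 background element names from soil/grass/trunk
#'   (repeats allowed, e.g. two grass layers).
#' @param occlusion_band `"none"` (< 15%), `"slight"` (15-30%) or
#'   `"moderate"` (30-40%).
#' @param lighting Multiplicative lighting factor.
#' @param pose_angle Leaf rotation in degrees.
#' @return A `scene_params` list.
#' @export
scene_params <- function(elements = c("soil", "grass"),
                         occlusion_band = "none",
                         lighting = 1, pose_angle = 0) {
  stopifnot(length(elements) >= 2, length(elements) <= 4,
            all(elements %in% names(element_palettes())),
            occlusion_band %in% occlusion_bands()$band)
  structure(list(elements = elements, occlusion_band = occlusion_band,
                 lighting = lighting, pose_angle = pose_angle),
            class = "scene_params")
}

rotate_nn <- function(img, angle) {
  # nearest-neighbour rotation about the centre (used for sprite posing)
  size <- dim(img)[1]
  c0 <- 0.5 * (size + 1)
  a <- angle * pi / 180
  xs <- matrix(seq_len(size), size, size) - c0
  ys <- matrix(seq_len(size), size, size, byrow = TRUE) - c0
  sx <- round(c0 + cos(a) * xs + sin(a) * ys)
  sy <- round(c0 - sin(a) * xs + cos(a) * ys)
  ok <- sx >= 1 & sx <= size & sy >= 1 & sy <= size
  idx <- cbind(c(pmin(pmax(sx, 1), size)), c(pmin(pmax(sy, 1), size)))
  if (length(dim(img)) == 2) {
    out <- matrix(FALSE, size, size)
    out[ok] <- img[idx][ok]
  } else {
    out <- array(0, dim(img))
    for (ch in seq_len(dim(img)[3])) {
      plane <- img[, , ch]
      o <- matrix(0, size, size)
      o[ok] <- plane[idx][ok]
      out[, , ch] <- o
    }
  }
  out
}

# one grass-blade / branch shaped occluder mask centred at (ox, oy)
occluder_mask <- function(size, ox, oy, len, width, angle) {
  px <- matrix(seq_len(size), size, size)
  py <- matrix(seq_len(size), size, size, byrow = TRUE)
  ex <- len * cos(angle); ey <- len * sin(angle)
  seg_dist2(px, py, ox - ex, oy - ey, ox + ex, oy + ey) < width^2
}

#' Compose a full scene around a leaf sprite
#'
#' Tiles a background from 2-4 procedural natural-element textures, poses the
#' sprite, then draws elongated occluders (grass blades, twigs) over the leaf
#' until the occluded fraction of the leaf mask falls inside the requested
#' band; errors if the band is not reached within 100 attempts.
#'
#' @param sprite Output of [render_leaf()].
#' @param scene A [scene_params()] object.
#' @param seed Integer seed.
#' @return List with `img` (size x size x 3), achieved `occlusion` fraction,
#'   and the posed leaf `mask`.
#' @export
compose_scene <- function(sprite, scene, seed) {
  set.seed(seed)
  size <- dim(sprite$rgb)[1]
  bg <- array(0, c(size, size, 3))
  wsum <- matrix(0, size, size)
  for (el in scene$elements) {
    w <- value_noise(size, 4)^2 + 0.15
    tex <- render_element(el, size)
    for (ch in 1:3) bg[, , ch] <- bg[, , ch] + tex[, , ch] * w
    wsum <- wsum + w
  }
  for (ch in 1:3) bg[, , ch] <- bg[, , ch] / wsum
  rgbL <- rotate_nn(sprite$rgb, scene$pose_angle)
  mask <- rotate_nn(sprite$mask, scene$pose_angle)
  img <- bg
  for (ch in 1:3) img[, , ch] <- ifelse(mask, rgbL[, , ch], bg[, , ch])
  band <- occlusion_bands()[occlusion_bands()$band == scene$occlusion_band, ]
  leaf_area <- sum(mask)
  occluded <- matrix(FALSE, size, size)
  frac <- 0
  target <- if (band$lo == 0) 0 else stats::runif(1, band$lo + 0.01, band$hi - 0.02)
  attempts <- 0
  while (frac < target) {
    attempts <- attempts + 1
    if (attempts > 100) {
      stop("occlusion band '", scene$occlusion_band, "' not reached in 100 attempts")
    }
    on_leaf <- which(mask, arr.ind = TRUE)
    at <- on_leaf[sample.int(nrow(on_leaf), 1), ]
    om <- occluder_mask(size, at[1], at[2],
                        len = size * stats::runif(1, 0.1, 0.25),
                        width = size * stats::runif(1, 0.015, 0.035),
                        angle = stats::runif(1, 0, pi))
    cand <- occluded | om
    cand_frac <- sum(cand & mask) / leaf_area
    if (cand_frac >= band$hi) next      # would overshoot the band; redraw
    el <- sample(c("grass", "trunk"), 1)
    tex <- render_element(el, size)
    for (ch in 1:3) img[, , ch] <- ifelse(om, tex[, , ch], img[, , ch])
    occluded <- cand
    frac <- cand_frac
  }
  img <- pmin(pmax(img * scene$lighting, 0), 1)
  list(img = img, occlusion = frac, mask = mask)
}

# largest-remainder apportionment of n into shares `p` (ties to earlier slots)
apportion <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a labelled synthetic leaf dataset
#'
#' Renders class-per-folder PNG scenes (or just the manifest when
#' `render = FALSE`) with occlusion bands assigned per class by
#' largest-remainder apportionment of the requested mix. Per-image shape
#' jitter (serration amplitude, scale, hue) keeps classes separable while
#' providing intra-class variation. Deterministic given `seed`: regenerating
#' yields a byte-identical manifest.
#'
#' @param counts Named per-class counts ([published_counts()], [tiny_counts()],
#'   or any named integer vector matching the presets).
#' @param occlusion_mix Proportions for the none/slight/moderate bands.
#' @param seed Integer seed.
#' @param out_dir Output directory for PNGs, or `NULL` to skip writing.
#' @param size Image size in pixels.
#' @param render Render pixels (`FALSE` = manifest only).
#' @param keep_images Also return rendered arrays in the `images` attribute.
#' @return A manifest tibble (path, cultivar, class_id, occlusion band,
#'   achieved occlusion fraction, per-image seed). A JSON provenance record
#'   is written alongside the images when `out_dir` is given.
#' @export
generate_leaf_dataset <- function(counts = tiny_counts(),
                                  occlusion_mix = c(none = 0.65, slight = 0.25,
                                                    moderate = 0.10),
                                  seed = 1, out_dir = NULL, size = 224L,
                                  render = TRUE, keep_images = FALSE) {
  stopifnot(all(counts > 0), abs(sum(occlusion_mix) - 1) < 1e-8)
  presets <- cultivar_presets()
  presets <- presets[match(names(counts), presets$cultivar), ]
  if (anyNA(presets$class_id)) stop("unknown cultivar name in `counts`")
  rows <- list()
  for (i in seq_along(counts)) {
    n <- counts[[i]]
    bands <- rep(occlusion_bands()$band, apportion(n, occlusion_mix))
    rows[[i]] <- tibble::tibble(
      cultivar = presets$cultivar[i], class_id = presets$class_id[i],
      item = seq_len(n), occlusion = bands,
      seed = as.integer((seed * 97L + presets$class_id[i] * 10007L +
                           seq_len(n) * 131L) %% .Machine$integer.max))
  }
  manifest <- dplyr::bind_rows(rows)
  manifest$path <- if (is.null(out_dir)) NA_character_ else
    file.path(out_dir, gsub(" ", "_", manifest$cultivar),
              sprintf("%s_%04d.png", gsub(" ", "_", manifest$cultivar), manifest$item))
  manifest$occlusion_frac <- NA_real_
  images <- if (keep_images) vector("list", nrow(manifest)) else NULL
  if (render) {
    if (!is.null(out_dir)) {
      for (d in unique(dirname(manifest$path))) {
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
      }
    }
    for (j in seq_len(nrow(manifest))) {
      p <- presets[presets$class_id == manifest$class_id[j], ]
      sd <- manifest$seed[j]
      set.seed(sd)
      p$serr_amp <- p$serr_amp * stats::runif(1, 0.9, 1.1)
      p$scale <- p$scale * stats::runif(1, 0.9, 1.1)
      p$hue <- p$hue + stats::runif(1, -0.01, 0.01)
      n_el <- sample(2:4, 1)
      sc <- scene_params(
        elements = sample(names(element_palettes()), n_el, replace = TRUE),
        occlusion_band = manifest$occlusion[j],
        lighting = stats::runif(1, 0.75, 1.2),
        pose_angle = stats::runif(1, 0, 360))
      sprite <- render_leaf(p, seed = sd + 1L, size = size)
      scene <- compose_scene(sprite, sc, seed = sd + 2L)
      manifest$occlusion_frac[j] <- scene$occlusion
      if (!is.null(out_dir)) png::writePNG(aperm(scene$img, c(2, 1, 3)), manifest$path[j])
      if (keep_images) images[[j]] <- scene$img
    }
  }
  if (!is.null(out_dir)) {
    prov <- list(seed = seed, size = size, counts = as.list(counts),
                 occlusion_mix = as.list(occlusion_mix),
                 presets = presets)
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  if (keep_images) attr(manifest, "images") <- images
  manifest
}

#' Oracle shape descriptors from a leaf mask
#'
#' Measures the silhouette independently of the generator's parameters: the
#' angular radial profile's dominant low frequency (lobe count), dominant
#' high frequency (serration), and mean radius. A nearest-centroid rule on
#' these descriptors separates the synthetic classes, certifying that the
#' benchmark is learnable from shape alone.
#'
#' @param mask Logical leaf mask.
#' @return Named numeric vector (lobes, serration, mean_radius).
#' @export
leaf_shape_descriptors <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  th <- atan2(idx[, 2] - cy, idx[, 1] - cx)
  r <- sqrt((idx[, 1] - cx)^2 + (idx[, 2] - cy)^2)
  bins <- pmin(floor((th + pi) / (2 * pi) * 180) + 1, 180)
  prof <- vapply(split(r, factor(bins, levels = 1:180)),
                 function(v) if (length(v)) max(v) else NA_real_, 0)
  prof[is.na(prof)] <- mean(prof, na.rm = TRUE)
  sp <- Mod(stats::fft(prof - mean(prof)))[2:60]     # frequencies 1..59
  c(lobes = which.max(sp[2:10]) + 1,
    serration = which.max(sp[11:40]) + 10,
    mean_radius = mean(r) / nrow(mask))
}
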