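# Synthetic scene generator: silhouette structure, determinism, occlusion
# bands, apportionment, and class separability from oracle descriptors.

test_that("with zero serration the radial profile has 2*lobes extrema", {
  for (i in c(1, 2, 6)) {
    p <- cultivar_presets()[i, ]
    p$serr_amp <- 0
    prof <- leaf_radial_profile(p, n = 1440)
    sgn <- sign(diff(c(prof, prof[1])))   # circular: boundary extremum counts
    changes <- sum(diff(c(sgn[sgn != 0], sgn[sgn != 0][1])) != 0)
    expect_equal(changes, 2 * p$lobes)
  }
})

test_that("leaf rendering is deterministic with a valid mask", {
  p <- cultivar_presets()[4, ]
  a <- render_leaf(p, seed = 9, size = 64)
  b <- render_leaf(p, seed = 9, size = 64)
  expect_identical(a, b)
  expect_gt(sum(a$mask), 0)
  expect_equal(dim(a$mask), c(64L, 64L))
  expect_true(all(a$rgb >= 0 & a$rgb <= 1))
  # pixels outside the mask are empty
  expect_true(all(a$rgb[!array(a$mask, dim(a$rgb))] == 0))
})

test_that("achieved occlusion fractions fall inside their declared bands", {
  p <- cultivar_presets()[2, ]
  sp <- render_leaf(p, seed = 3, size = 96)
  for (row in seq_len(nrow(occlusion_bands()))) {
    band <- occlusion_bands()[row, ]
    sc <- compose_scene(sp, scene_params(c("soil", "grass"), band$band,
                                         pose_angle = 25), seed = 41 + row)
    expect_gte(sc$occlusion, ifelse(band$band == "none", 0, band$lo))
    expect_lt(sc$occlusion, band$hi)
  }
})

test_that("scene composition is deterministic given the seed", {
  p <- cultivar_presets()[7, ]
  sp <- render_leaf(p, seed = 1, size = 64)
  sc1 <- compose_scene(sp, scene_params(c("grass", "trunk"), "slight"), seed = 5)
  sc2 <- compose_scene(sp, scene_params(c("grass", "trunk"), "slight"), seed = 5)
  expect_identical(sc1, sc2)
})

test_that("occlusion-band apportionment matches closed-form counts", {
  expect_equal(vitileaf:::apportion(4, c(0.5, 0.25, 0.25)), c(2L, 1L, 1L))
  expect_equal(vitileaf:::apportion(8, c(0.5, 0.25, 0.25)), c(4L, 2L, 2L))
  expect_equal(sum(vitileaf:::apportion(353, c(0.65, 0.25, 0.10))), 353L)
})

test_that("the published preset manifest reproduces the printed totals", {
  man <- generate_leaf_dataset(published_counts(), seed = 2, render = FALSE)
  expect_equal(nrow(man), 6051L)
  expect_equal(as.integer(table(man$cultivar)[names(published_counts())]),
               unname(published_counts()))
  # per-class apportionment puts each band within one image per class of the mix
  cnt <- table(man$occlusion)[c("none", "slight", "moderate")]
  expect_true(all(abs(cnt - c(0.65, 0.25, 0.10) * 6051) <= 11))
})

test_that("regeneration with the same seed is byte-identical", {
  m1 <- generate_leaf_dataset(tiny_counts(), seed = 8, render = FALSE)
  m2 <- generate_leaf_dataset(tiny_counts(), seed = 8, render = FALSE)
  expect_identical(m1, m2)
  # and rendered pixel output round-trips identically through files
  d1 <- file.path(tempdir(), "synth1"); d2 <- file.path(tempdir(), "synth2")
  cnt <- tiny_counts()[c(1, 5)]
  cnt[] <- 3L
  g1 <- generate_leaf_dataset(cnt, seed = 4, out_dir = d1, size = 48)
  g2 <- generate_leaf_dataset(cnt, seed = 4, out_dir = d2, size = 48)
  expect_equal(g1$occlusion_frac, g2$occlusion_frac)
  for (i in seq_len(nrow(g1))) {
    expect_identical(readBin(g1$path[i], "raw", 1e6), readBin(g2$path[i], "raw", 1e6))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("nearest-centroid on oracle shape descriptors separates the classes", {
  pr <- cultivar_presets()
  reps <- 3
  desc <- list(); lab <- integer(0)
  for (i in seq_len(nrow(pr))) {
    for (r in seq_len(reps)) {
      p <- pr[i, ]
      set.seed(i * 100 + r)
      p$serr_amp <- p$serr_amp * stats::runif(1, 0.9, 1.1)
      p$scale <- p$scale * stats::runif(1, 0.9, 1.1)
      sp <- render_leaf(p, seed = i * 17 + r, size = 128)
      desc[[length(desc) + 1]] <- leaf_shape_descriptors(sp$mask)
      lab <- c(lab, i)
    }
  }
  X <- do.call(rbind, desc)
  X <- scale(X)
  centroids <- rowsum(X, lab) / reps
  pred <- apply(X, 1, function(v) {
    which.min(colSums((t(centroids) - v)^2))
  })
  expect_gt(mean(pred == lab), 0.95)
})
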