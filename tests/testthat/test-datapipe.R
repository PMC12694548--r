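# Splitting, folds, augmentation, resizing and manifest round-trips.

test_that("largest-remainder split apportionment matches small closed forms", {
  s <- split_sizes(c(A = 10, B = 10))
  expect_equal(s$train, c(8L, 8L))
  expect_equal(s$val, c(1L, 1L))
  expect_equal(s$test, c(1L, 1L))
  expect_error(split_sizes(c(A = 10), ratios = c(train = 0.8, val = 0.1)),
               "sum to 1")
})

test_that("published per-class counts split to the published totals", {
  s <- split_sizes(published_counts())
  expect_equal(sum(s$train), 4839L)
  expect_equal(sum(s$val), 606L)
  expect_equal(sum(s$test), 606L)
  expect_equal(sum(s$n), 6051L)
  # per-class proportions deviate from 80/10/10 by less than one image
  expect_true(all(abs(s$train - 0.8 * s$n) < 1))
  expect_true(all(abs(s$val - 0.1 * s$n) < 1))
  expect_true(all(abs(s$test - 0.1 * s$n) < 1))
})

test_that("stratified split is deterministic and exhaustive", {
  man <- generate_leaf_dataset(tiny_counts(), seed = 1, render = FALSE)
  m1 <- stratified_split(man, seed = 7)
  m2 <- stratified_split(man, seed = 7)
  expect_identical(m1, m2)
  expect_false(anyNA(m1$split))
  per <- table(m1$cultivar, m1$split)
  expect_true(all(per[, "train"] == 16))
  expect_true(all(per[, "val"] == 2))
})

test_that("fold assignment is balanced, exhaustive and seeded", {
  man <- generate_leaf_dataset(tiny_counts(), seed = 1, render = FALSE)
  f1 <- make_folds(man, k = 5, seed = 3)
  f2 <- make_folds(man, k = 5, seed = 3)
  expect_identical(f1, f2)
  expect_false(anyNA(f1$fold))
  per <- table(f1$cultivar, f1$fold)
  expect_true(all(abs(per - 4) <= 1))
  tiny <- man[man$item <= 3, ]
  expect_error(make_folds(tiny, k = 5), "fewer than k")
})

test_that("augmentation identity and involution cases", {
  set.seed(1)
  img <- array(stats::runif(24 * 24 * 3), c(24, 24, 3))
  idcfg <- augment_config(hflip_p = 0, rotate_deg = 0, factor_range = c(1, 1),
                          blur_p = 0)
  expect_equal(augment_image(img, idcfg), img)
  flipped <- img[, rev(seq_len(24)), ]
  expect_equal(flipped[, rev(seq_len(24)), ], img)     # flip is an involution
  # constant image is a fixed point of Gaussian blur
  const <- array(0.4, c(8, 8, 3))
  expect_equal(vitileaf:::gaussian_blur3(const, sigma = 1.3), const)
  # zero-angle rotation is exact identity
  expect_equal(vitileaf:::rotate_bilinear(img, 0), img)
})

test_that("resize_normalize contract", {
  set.seed(2)
  img <- array(stats::runif(64 * 64 * 3), c(64, 64, 3))
  out <- resize_normalize(img, 32)
  expect_equal(dim(out), c(32L, 32L, 3L))
  # already-sized input: values only shifted by normalisation
  same <- resize_normalize(img, 64)
  expect_equal(same, (img - 0.5) / 0.5)
  white <- array(1, c(16, 16, 3))
  expect_true(all(resize_normalize(white, 16) == 1))
  expect_error(resize_normalize(array(0, c(8, 8)), 8), "RGB")
})

test_that("manifests round-trip through CSV without loss", {
  man <- generate_leaf_dataset(tiny_counts()[1:3], seed = 5, render = FALSE)
  man <- stratified_split(man, seed = 1)
  man <- make_folds(man, k = 5, seed = 1)
  path <- tempfile(fileext = ".csv")
  write_manifest(man, path)
  back <- read_manifest(path)
  expect_equal(back$cultivar, man$cultivar)
  expect_equal(back$class_id, man$class_id)
  expect_equal(back$split, as.character(man$split))
  expect_equal(back$fold, man$fold)
  expect_equal(back$occlusion, man$occlusion)
})
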