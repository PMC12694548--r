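# Backbone contracts: activations, bottleneck behaviour, assembly shapes.

test_that("hard activations take their closed-form values", {
  expect_equal(hard_sigmoid(0), 0.5)
  expect_equal(hard_sigmoid(-3), 0)
  expect_equal(hard_sigmoid(3), 1)
  expect_equal(hard_swish(0), 0)
  x <- seq(-6, 6, by = 0.25)
  expect_equal(hard_swish(x), x * hard_sigmoid(x))
  expect_equal(hard_swish(1e6), 1e6)          # saturates to identity
  expect_equal(hard_sigmoid(c(-10, 10)), c(0, 1))
})

test_that("backbone maps an image batch to finite logits of the right shape", {
  m <- build_variant("MS", num_classes = 11, seed = 1)
  set.seed(2)
  x <- array(stats::runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  p <- predict_model(m, x)
  expect_equal(dim(p$logits), c(2L, 11L))
  expect_true(all(is.finite(p$logits)))
  expect_equal(ncol(p$feature), 576L)
})

test_that("final-layer resizing changes exactly the classifier head parameters", {
  d <- count_parameters("MS", 11) - count_parameters("MS", 2)
  expect_identical(d, 9L * (1024L + 1L))
})

test_that("residual bottleneck with a zeroed branch reproduces its input", {
  spec <- bottleneck_spec(24, 72, 24, kernel = 3, stride = 1,
                          attention = "none", activation = "relu")
  set.seed(1)
  blk <- bottleneck_block(spec)
  pars <- eng_params(blk)
  pars[["m.inner.project.w"]][] <- 0          # zero the compression conv
  blk <- eng_set(blk, pars)
  x <- rand_ft(8, 8, 24, 2, seed = 9)
  y <- eng_fwd(blk, x, train = FALSE)$y
  expect_equal(unclass(y), unclass(x), tolerance = 1e-12)
})

test_that("stride-2 bottleneck halves spatial dimensions", {
  spec <- bottleneck_spec(16, 64, 24, kernel = 3, stride = 2,
                          attention = "none", activation = "relu")
  set.seed(1)
  blk <- bottleneck_block(spec)
  x <- rand_ft(14, 14, 16, 2, seed = 3)
  y <- eng_fwd(blk, x, train = FALSE)$y
  expect_equal(unname(vitileaf:::ft_dim(y)[1:2]), c(7L, 7L))
  expect_equal(ncol(y), 24L)
})

test_that("attention forced to unit gates is the identity inside a bottleneck", {
  set.seed(1)
  se <- vitileaf:::nn_se(16)
  pars <- eng_params(se)
  pars[["m.fc2.w"]][] <- 0
  pars[["m.fc2.b"]][] <- 100                  # hard-sigmoid saturates at 1
  se <- eng_set(se, pars)
  x <- rand_ft(5, 5, 16, 2, seed = 2)
  expect_equal(unclass(eng_fwd(se, x)$y), unclass(x), tolerance = 1e-12)
})

test_that("same build seed gives bit-identical initial weights", {
  m1 <- build_variant("MS", seed = 42)
  m2 <- build_variant("MS", seed = 42)
  expect_identical(eng_params(m1$features), eng_params(m2$features))
  expect_identical(eng_params(m1$classifier), eng_params(m2$classifier))
})

test_that("unknown variant names are rejected with the valid list", {
  expect_error(build_variant("resnet50"), "valid names")
  expect_error(build_baseline("MS"), "valid names")
})

test_that("models accept any 32-divisible input size via global pooling", {
  m <- build_variant("MS", seed = 1)
  for (sz in c(32, 96)) {
    x <- array(stats::runif(sz * sz * 3), c(sz, sz, 3, 1))
    expect_equal(dim(predict_model(m, x)$logits), c(1L, 11L))
  }
})

test_that("weight save/load round-trips and verifies the manifest", {
  m <- build_variant("MS-CA", seed = 5)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(eng_params(m$features), eng_params(m2$features))
  x <- array(stats::runif(32 * 32 * 3), c(32, 32, 3, 1))
  expect_equal(predict_model(m, x)$logits, predict_model(m2, x)$logits)
  # corrupt the manifest: load must refuse
  bad <- readRDS(path)
  bad$meta$params <- bad$meta$params + 1L
  saveRDS(bad, path)
  expect_error(load_model(path), "does not match")
})
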