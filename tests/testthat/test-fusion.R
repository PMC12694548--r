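# Multi-branch fusion stage: channel conservation, zero-weight behaviour,
# gating identity, and the audited assembly budgets.

test_that("concatenation conserves channels and spatial size", {
  cfg <- ics_inception_config(16, 8, apply_cbam = FALSE)
  expect_equal(cfg$concat_channels, 8L + 8L + 16L)
  set.seed(1)
  x <- array(stats::rnorm(10 * 12 * 16 * 2), c(10, 12, 16, 2))
  y <- ics_inception_forward(cfg, x)
  expect_equal(dim(y), c(10, 12, 32, 2))
})

test_that("with zero conv weights only the pooling branch survives", {
  cfg <- ics_inception_config(6, 4, apply_cbam = FALSE)
  set.seed(2)
  blk <- ics_inception_block(cfg)
  pars <- eng_params(blk)
  for (k in grep("\\.conv\\.w$", names(pars), value = TRUE)) pars[[k]][] <- 0
  blk <- eng_set(blk, pars)
  x <- rand_ft(6, 6, 6, 1, seed = 3)
  y <- eng_fwd(blk, x, train = FALSE)$y
  expect_true(all(abs(y[, 1:8]) < 1e-12))          # both conv branches silent
  mp <- eng_fwd(vitileaf:::nn_maxpool(3), x)$y     # pool branch passes through
  expect_equal(as.vector(y[, 9:14]), as.vector(mp))
})

test_that("dual attention forced to unit gates equals plain concatenation", {
  cfg_on <- ics_inception_config(6, 4, apply_cbam = TRUE)
  cfg_off <- ics_inception_config(6, 4, apply_cbam = FALSE)
  set.seed(4)
  blk_on <- ics_inception_block(cfg_on)
  set.seed(4)
  blk_off <- ics_inception_block(cfg_off)
  pars <- eng_params(blk_on)
  pars[["m.cbam.fc2.w"]][] <- 0
  pars[["m.cbam.fc2.b"]][] <- 100       # sigmoid -> 1
  pars[["m.cbam.sconv.w"]][] <- 0
  pars[["m.cbam.sbn.beta"]][] <- 100    # sigmoid -> 1
  blk_on <- eng_set(blk_on, pars)
  x <- rand_ft(7, 7, 6, 2, seed = 5)
  y_on <- eng_fwd(blk_on, x, train = FALSE)$y
  y_off <- eng_fwd(blk_off, x, train = FALSE)$y
  expect_equal(unclass(y_on), unclass(y_off), tolerance = 1e-10)
})

test_that("branch-sum mismatch is rejected", {
  cfg <- ics_inception_config(16, 8)
  cfg$concat_channels <- 999L
  expect_error(ics_inception_block(cfg), "concat_channels")
})

test_that("fusion assemblies hit their published parameter budgets", {
  expect_equal(params_millions(count_parameters("ICS-MS-CE")), 1.12)
  expect_equal(params_millions(count_parameters("MS-CA-I")), 1.07)
  expect_equal(params_millions(count_parameters("ICS-MS")), 1.17)
  p <- vapply(c("ICS-MS-CE", "MS-CA", "MS"), count_parameters, 0L)
  expect_true(all(diff(p) > 0))
})

test_that("fusion raises MACs to the published 0.21 G while shrinking params", {
  expect_equal(macs_g(count_macs("ICS-MS")), 0.21)
  expect_equal(macs_g(count_macs("MS")), 0.06)
  expect_lt(count_parameters("ICS-MS-CE"), count_parameters("MS"))
})

test_that("classifier input width is unchanged by the head replacement", {
  layers <- arch_layers("ICS-MS-CE")
  clf <- layers[layers$stage == "classifier", ]
  expect_equal(clf$cin[1], 576)
  head <- layers[layers$stage == "ics_head", ]
  expect_equal(sum(head$cout[head$op == "conv" & head$k == 1 & head$cin == 96]), 480)
})
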