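# Loss closed forms, gradients, and the center-update recurrence.

test_that("cross-entropy closed forms", {
  # probability 1 on the true class -> 0
  logits <- matrix(c(100, 0, 0), 1)
  expect_equal(cross_entropy(logits, 1), 0, tolerance = 1e-10)
  # uniform prediction over 11 classes -> ln 11
  expect_equal(cross_entropy(matrix(0, 1, 11), 5), log(11))
  # mean reduction over a two-sample batch
  l1 <- cross_entropy(matrix(c(1, 0, 0), 1, 3), 1)
  l2 <- cross_entropy(matrix(c(0, 2, 1), 1, 3), 3)
  both <- cross_entropy(rbind(c(1, 0, 0), c(0, 2, 1)), c(1, 3))
  expect_equal(both, (l1 + l2) / 2)
  expect_error(cross_entropy(matrix(0, 1, 3), 4), "labels")
})

test_that("cross-entropy gradient matches numerical differentiation", {
  set.seed(8)
  lg <- matrix(stats::rnorm(12), 3, 4)
  y <- c(2, 4, 1)
  g <- vitileaf:::cross_entropy_grad(lg, y)
  ng <- num_grad(function(v) cross_entropy(matrix(v, 3, 4), y), as.vector(lg))
  expect_equal(as.vector(g), ng, tolerance = 1e-6)
})

test_that("center loss closed forms and gradient", {
  centers <- matrix(0, 2, 2)
  expect_equal(center_loss(matrix(c(3, 4), 1), 1, centers), 12.5)
  # features equal to centers -> 0
  mu <- matrix(stats::rnorm(6), 3, 2)
  expect_equal(center_loss(mu[c(1, 3), ], c(1, 3), mu), 0)
  # two samples at unit distance -> 1
  f <- rbind(c(1, 0), c(0, 1))
  expect_equal(center_loss(f, c(1, 2), matrix(0, 2, 2)), 1)
  expect_error(center_loss(matrix(0, 1, 3), 1, matrix(0, 2, 2)), "dimension")
  # gradient = f - mu_y, and against numerical differentiation
  set.seed(2)
  ff <- matrix(stats::rnorm(6), 3, 2)
  yy <- c(2, 1, 2)
  g <- vitileaf:::center_loss_grad(ff, yy, mu)
  expect_equal(g, ff - mu[yy, ])
  ng <- num_grad(function(v) center_loss(matrix(v, 3, 2), yy, mu), as.vector(ff))
  expect_equal(as.vector(g), ng, tolerance = 1e-6)
})

test_that("joint loss arithmetic and monotonicity in lambda", {
  expect_equal(joint_loss(2, 50, 0.01), 2.5)
  expect_equal(joint_loss(1.7, 123, 0), 1.7)
  expect_error(joint_loss(1, 1, -0.1), "non-negative")
  ls <- vapply(c(0, 0.01, 0.05, 0.1, 0.2), function(l) joint_loss(2, 30, l), 0)
  expect_true(all(diff(ls) > 0))
})

test_that("center updates follow the mini-batch recurrence", {
  # one sample, mu = 0, f = 4, alpha = 0.5 -> new mu = 1
  expect_equal(update_centers(matrix(4), 1, matrix(0), alpha = 0.5)[1, 1], 1)
  # absent classes never move
  centers <- matrix(stats::rnorm(6), 3, 2)
  out <- update_centers(matrix(c(1, 1), 1), 2, centers, alpha = 0.5)
  expect_equal(out[c(1, 3), ], centers[c(1, 3), ])
  # repeated single-sample updates converge geometrically to f
  mu <- matrix(0); f <- matrix(4)
  errs <- numeric(30)
  for (i in 1:30) {
    mu <- update_centers(f, 1, mu, alpha = 0.5)
    errs[i] <- abs(mu[1, 1] - 4)
  }
  expect_true(all(diff(errs) < 0))
  expect_equal(errs[30], 4 * 0.75^30, tolerance = 1e-10)  # contraction 1 - a/2
  expect_lt(errs[30], 1e-3)
})

test_that("the joint head adds exactly the projection plus center parameters", {
  delta <- count_parameters("ICS-MS") - count_parameters("ICS-MS-CE")
  dc <- vitileaf:::CENTER_DIM
  expect_identical(delta, 576L * dc + dc + 11L * dc)
  expect_equal(round(delta / 1e6, 2), 0.05)
  m <- build_variant("ICS-MS", seed = 1)
  expect_equal(dim(m$centers), c(11L, as.integer(dc)))
})

test_that("center projection requires the joint head", {
  m <- build_variant("ICS-MS-CE", seed = 1)
  expect_error(center_projection(m, matrix(0, 1, 576)), "joint")
  mj <- build_variant("ICS-MS", seed = 1)
  f <- matrix(stats::rnorm(2 * 576), 2)
  expect_equal(dim(center_projection(mj, f)), c(2L, as.integer(vitileaf:::CENTER_DIM)))
  # zero-weight projection: any batch has zero center loss against mu = 0
  pars <- eng_params(mj$center_proj)
  for (k in names(pars)) pars[[k]][] <- 0
  mj$center_proj <- eng_set(mj$center_proj, pars)
  pf <- center_projection(mj, f)
  expect_equal(center_loss(pf, c(1, 2), init_centers(11)), 0)
})
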