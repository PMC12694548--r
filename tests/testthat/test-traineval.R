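# Training loop contracts: determinism, the lambda = 0 degeneracy, batching,
# sweep bookkeeping and failure diagnostics.

small_cfg <- function(epochs = 2, ...) {
  train_config(batch_size = 8, epochs = epochs, lr = 1e-3, image_size = 32,
               seed = 11, eval_every = 1, augment = NULL, ...)
}

two_class_manifest <- function() {
  man <- fixture_small_dataset()
  keep <- man$class_id %in% 1:2
  m2 <- man[keep, ]
  attr(m2, "images") <- attr(man, "images")[keep]
  m2$split <- rep(c("train", "val"), c(10, 2))[
    ave(seq_len(nrow(m2)), m2$class_id, FUN = seq_along)]
  m2
}

test_that("lambda = 0 joint training matches plain cross-entropy bit for bit", {
  man <- two_class_manifest()
  imgs <- attr(man, "images")
  f_joint <- train_model(build_variant("ICS-MS", 2, seed = 5), man,
                         small_cfg(lambda = 0, loss = "joint"), imgs)
  f_ce <- train_model(build_variant("ICS-MS", 2, seed = 5), man,
                      small_cfg(loss = "ce"), imgs)
  expect_identical(f_joint$history$loss_ce, f_ce$history$loss_ce)
  expect_identical(f_joint$history$val_accuracy, f_ce$history$val_accuracy)
  expect_identical(eng_params(f_joint$model$features),
                   eng_params(f_ce$model$features))
})

test_that("a fixed seed reproduces the training history exactly", {
  man <- two_class_manifest()
  imgs <- attr(man, "images")
  f1 <- train_model(build_variant("ICS-MS-CE", 2, seed = 3), man,
                    small_cfg(loss = "ce"), imgs)
  f2 <- train_model(build_variant("ICS-MS-CE", 2, seed = 3), man,
                    small_cfg(loss = "ce"), imgs)
  expect_identical(f1$history, f2$history)
  expect_identical(eng_params(f1$model$features), eng_params(f2$model$features))
})

test_that("history logs the loss breakdown and the best checkpoint is kept", {
  man <- two_class_manifest()
  fit <- train_model(build_variant("ICS-MS", 2, seed = 2), man,
                     small_cfg(lambda = 0.01), attr(man, "images"))
  expect_named(fit$history,
               c("epoch", "loss_ce", "loss_center", "loss", "val_accuracy"))
  expect_true(all(fit$history$loss >= fit$history$loss_ce))
  expect_true(is.finite(fit$best$accuracy))
  expect_gt(fit$best$epoch, 0)
})

test_that("non-finite losses abort with a diagnostic", {
  man <- two_class_manifest()
  m <- build_variant("ICS-MS-CE", 2, seed = 1)
  pars <- eng_params(m$classifier)
  pars[["m.fc2.w"]][1, 1] <- Inf
  m$classifier <- eng_set(m$classifier, pars)
  expect_error(
    train_model(m, man, small_cfg(loss = "ce"), attr(man, "images")),
    "non-finite loss")
})

test_that("trailing singleton batches are merged", {
  b <- vitileaf:::make_batches(1:17, 8)
  expect_equal(lengths(b), c(8L, 9L))
  expect_setequal(unlist(b), 1:17)
})

test_that("evaluation refuses an empty split and reports all classes", {
  man <- two_class_manifest()
  fit <- train_model(build_variant("ICS-MS-CE", 2, seed = 1), man,
                     small_cfg(loss = "ce"), attr(man, "images"))
  expect_error(evaluate_model(fit$model, man, "test", small_cfg(),
                              attr(man, "images")), "empty")
  rep <- evaluate_model(fit$model, man, "val", small_cfg(), attr(man, "images"))
  expect_s3_class(rep, "leaf_metrics")
  expect_equal(sum(rep$confusion), 4)         # 2 val images per class
})

test_that("the lambda sweep reports exactly the requested weights", {
  man <- two_class_manifest()
  cfg <- small_cfg(epochs = 1)
  sw <- lambda_sweep(man, lambdas = c(0, 0.01), cfg,
                     build = function() build_variant("ICS-MS", 2, seed = cfg$seed),
                     images = attr(man, "images"))
  expect_equal(sw$lambda, c(0, 0.01))
  expect_named(sw, c("lambda", "accuracy", "precision", "recall", "f1", "loss"))
  expect_true(attr(sw, "best") %in% sw$lambda)
  expect_equal(attr(sw, "best"), sw$lambda[which.max(sw$accuracy)])
})

test_that("cross-validation covers every sample exactly once as test", {
  man <- fixture_small_dataset()
  man <- make_folds(man, k = 3, seed = 2)
  seen <- integer(nrow(man))
  for (f in 1:3) seen[man$fold == f] <- seen[man$fold == f] + 1L
  expect_true(all(seen == 1L))
})
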