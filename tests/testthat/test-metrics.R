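# Metric formulas against brute-force counting and an independent
# implementation.

# expand a confusion matrix into per-sample truth/pred vectors
cm_to_samples <- function(cm) {
  truth <- integer(0); pred <- integer(0)
  for (i in seq_len(nrow(cm))) for (j in seq_len(ncol(cm))) {
    truth <- c(truth, rep(i, cm[i, j]))
    pred <- c(pred, rep(j, cm[i, j]))
  }
  list(truth = truth, pred = pred)
}

test_that("the worked 3-class confusion matrix gives 83.33 on all four metrics", {
  cm <- rbind(c(8, 1, 1), c(0, 9, 1), c(2, 0, 8))
  s <- cm_to_samples(cm)
  r <- metrics_report(s$truth, s$pred, 3)
  expect_equal(r$accuracy, 100 * 25 / 30, tolerance = 1e-10)
  expect_equal(r$precision, 83 + 1 / 3, tolerance = 1e-10)
  expect_equal(r$recall, 83 + 1 / 3, tolerance = 1e-10)
  expect_equal(r$f1, 83 + 1 / 3, tolerance = 1e-10)
  expect_equal(unname(r$confusion), cm)
})

test_that("per-class counts match brute-force one-vs-rest counting", {
  set.seed(13)
  for (rep in 1:5) {
    n <- 60; C <- 4
    truth <- sample.int(C, n, replace = TRUE)
    pred <- sample.int(C, n, replace = TRUE)
    r <- metrics_report(truth, pred, C)
    for (k in seq_len(C)) {
      tp <- sum(truth == k & pred == k)
      fp <- sum(truth != k & pred == k)
      fn <- sum(truth == k & pred != k)
      tn <- sum(truth != k & pred != k)
      row <- r$per_class[k, ]
      expect_identical(c(row$tp, row$fp, row$fn, row$tn), c(tp, fp, fn, tn))
      if (tp + fp > 0) expect_equal(row$precision, 100 * tp / (tp + fp))
      if (tp + fn > 0) expect_equal(row$recall, 100 * tp / (tp + fn))
    }
    expect_equal(r$accuracy, 100 * sum(diag(r$confusion)) / n)
    # macro F1 bounded by the per-class extremes
    expect_gte(r$f1, min(r$per_class$f1) - 1e-12)
    expect_lte(r$f1, max(r$per_class$f1) + 1e-12)
  }
})

test_that("metrics agree with caret's independent implementation", {
  set.seed(29)
  truth <- sample.int(5, 200, replace = TRUE)
  pred <- ifelse(stats::runif(200) < 0.7, truth, sample.int(5, 200, TRUE))
  r <- metrics_report(truth, pred, 5)
  cc <- caret::confusionMatrix(factor(pred, 1:5), factor(truth, 1:5))
  expect_equal(r$accuracy, 100 * unname(cc$overall["Accuracy"]))
  expect_equal(r$per_class$precision,
               100 * unname(cc$byClass[, "Precision"]), tolerance = 1e-10)
  expect_equal(r$per_class$recall,
               100 * unname(cc$byClass[, "Sensitivity"]), tolerance = 1e-10)
})

test_that("degenerate predictor cases", {
  r <- metrics_report(rep(1:2, each = 50), rep(1:2, each = 50), 2)
  expect_equal(r$accuracy, 100)
  expect_equal(r$f1, 100)
  all_one <- metrics_report(rep(1:2, each = 50), rep(1, 100), 2)
  expect_equal(all_one$accuracy, 50)
  expect_equal(all_one$per_class$recall[1], 100)
  expect_equal(all_one$per_class$recall[2], 0)
  expect_error(metrics_report(integer(0), integer(0)), "empty")
})

test_that("fold aggregation: mean, sample SD, permutation invariance", {
  accs <- c(90, 92, 94, 91, 93)
  reports <- lapply(accs, function(a) {
    r <- metrics_report(1:2, 1:2, 2)
    r$accuracy <- a; r$precision <- a; r$recall <- a; r$f1 <- a
    r
  })
  agg <- aggregate_folds(reports)
  s <- agg$summary
  expect_equal(s$mean[s$metric == "accuracy"], 92)
  expect_equal(s$sd[s$metric == "accuracy"], stats::sd(accs))
  expect_equal(stats::sd(accs), 1.5811, tolerance = 1e-4)
  perm <- aggregate_folds(reports[c(3, 1, 5, 2, 4)])
  expect_equal(perm$summary, agg$summary)
  same <- aggregate_folds(reports[c(1, 1, 1)])
  expect_equal(same$summary$sd, rep(0, 4))
  expect_error(aggregate_folds(reports[1]), "at least 2")
})

test_that("tidy/glance/autoplot methods return the documented shapes", {
  r <- metrics_report(c(1, 1, 2, 2), c(1, 2, 2, 2), 2, labels = c("a", "b"))
  expect_s3_class(tidy(r), "tbl_df")
  expect_equal(nrow(tidy(r)), 2)
  g <- glance(r)
  expect_named(g, c("accuracy", "precision", "recall", "f1", "n"))
  expect_s3_class(autoplot(r), "ggplot")
})
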