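# Focal loss closed forms, metric arithmetic, k-fold partition contracts,
# bootstrap behavior, and convergence on a separable toy problem.

test_that("focal loss reduces to cross-entropy at gamma 0 and matches closed forms", {
  set.seed(1)
  for (rep in 1:5) {
    p1 <- runif(8, 0.01, 0.99)
    p <- cbind(p1, 1 - p1)
    labels <- rbinom(8, 1, 0.5)
    ce <- mean(-log(p[cbind(1:8, labels + 1)]))
    expect_equal(focal_loss(p, labels, gamma = 0, alpha = 1), ce, tolerance = 1e-12)
  }
  # p_t = 1 -> loss 0
  expect_equal(focal_loss(matrix(c(1, 0), 1), 0, gamma = 3), 0)
  # p_t = 0.5, gamma = 3 -> 0.125 * ln 2
  expect_equal(focal_loss(matrix(c(0.5, 0.5), 1), 1, gamma = 3),
               0.125 * log(2), tolerance = 1e-12)
  expect_error(focal_loss(matrix(c(0.5, 0.5), 1), 2), "labels")
})

test_that("focal loss is nonnegative and strictly decreasing in p_t", {
  pt <- seq(0.01, 0.99, by = 0.01)
  loss <- vapply(pt, function(q) focal_loss(matrix(c(q, 1 - q), 1), 0, 3), numeric(1))
  expect_true(all(loss >= 0))
  expect_true(all(diff(loss) < 0))
})

test_that("evaluation metrics match hand computation from a confusion matrix", {
  # TP=10 (P predicted P), FP=2, FN=3, TN=15
  true <- c(rep(1, 13), rep(0, 17))
  pred <- c(rep(1, 10), rep(0, 3), rep(1, 2), rep(0, 15))
  m <- classification_metrics(true, pred)
  expect_equal(m$accuracy, 25 / 30)
  prec_p <- 10 / 12; rec_p <- 10 / 13
  prec_h <- 15 / 18; rec_h <- 15 / 17
  expect_equal(m$precision, mean(c(prec_h, prec_p)))
  expect_equal(m$recall, mean(c(rec_h, rec_p)))
  expect_equal(as.numeric(m$confusion), c(15, 3, 2, 10))
  # all-correct predictor
  mall <- classification_metrics(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(unlist(mall[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  # majority predictor on balanced data
  mmaj <- classification_metrics(c(0, 0, 1, 1), c(0, 0, 0, 0))
  expect_equal(mmaj$accuracy, 0.5)
})

test_that("k-fold partitions are exact for randomized (n, k) sweeps", {
  set.seed(2)
  for (rep in 1:12) {
    n <- sample(10:60, 1)
    k <- sample(2:min(5, n), 1)
    labels <- rbinom(n, 1, 0.5)
    fold <- kfold_split(labels, k, seed = rep)
    expect_length(fold, n)
    expect_setequal(unique(fold), 1:k)   # every fold validates once
    # union of folds is the dataset, pairwise disjoint by construction;
    # per-class fold sizes differ by at most one
    for (cl in unique(labels)) {
      sizes <- tabulate(fold[labels == cl], k)
      expect_lte(max(sizes) - min(sizes), 1)
    }
  }
  expect_equal(sort(tabulate(kfold_split(rep(c(0, 1), 5), 5, seed = 1), 5)),
               rep(2L, 5))
  expect_error(kfold_split(c(0, 1), 5), "exceeds")
})

test_that("grouped folds never split a patient", {
  set.seed(3)
  for (rep in 1:5) {
    n_pat <- sample(8:15, 1)
    pats <- rep(sprintf("p%02d", 1:n_pat), each = 4)
    labels <- rep(rbinom(n_pat, 1, 0.5), each = 4)
    fold <- kfold_split(labels, 4, groups = pats, seed = rep)
    per_pat <- tapply(fold, pats, function(f) length(unique(f)))
    expect_true(all(per_pat == 1))
  }
})

test_that("bootstrap CI behaves on degenerate and enumerable cases", {
  all_right <- data.frame(true = rep(1, 20), pred = rep(1, 20))
  bs <- bootstrap_ci(all_right, n_resamples = 500, seed = 1)
  expect_equal(c(bs$ci_low, bs$ci_high, bs$width), c(1, 1, 0))
  # CI brackets the observed accuracy
  set.seed(4)
  pooled <- data.frame(true = rbinom(200, 1, 0.5), pred = rbinom(200, 1, 0.5))
  bs2 <- bootstrap_ci(pooled, n_resamples = 2000, seed = 2)
  obs <- mean(pooled$true == pooled$pred)
  expect_lte(bs2$ci_low, obs)
  expect_gte(bs2$ci_high, obs)
  expect_lte(bs2$ci_low, bs2$mean_accuracy)
  expect_gte(bs2$ci_high, bs2$mean_accuracy)
  # 4 records, 3 correct: resample accuracies live on {0, .25, .5, .75, 1}
  four <- data.frame(true = c(1, 1, 1, 0), pred = c(1, 1, 1, 1))
  ns <- asNamespace("qspiral")
  accs <- ns$with_local_seed(7, {
    idx <- sample.int(4, 4 * 3000, replace = TRUE)
    colMeans(matrix(as.numeric(four$true == four$pred)[idx], 4, 3000))
  })
  expect_true(all(accs %in% c(0, 0.25, 0.5, 0.75, 1)))
  bs3 <- bootstrap_ci(four, n_resamples = 3000, seed = 7)
  expect_true(all(c(bs3$ci_low, bs3$ci_high) %in% c(0, 0.25, 0.5, 0.75, 1)))
  # determinism per seed
  expect_identical(bootstrap_ci(four, 100, seed = 5), bootstrap_ci(four, 100, seed = 5))
})

test_that("training fits a separable toy problem and the scheduler only lowers the rate", {
  set.seed(5)
  # tabular-only model; single informative feature
  n <- 40
  labels <- rep(c(0L, 1L), n / 2)
  x <- matrix(runif(n * 6, 0, pi), n, 6)
  x[, 4] <- ifelse(labels == 1, runif(n, 2.2, pi), runif(n, 0, 0.9))
  ds <- exam_dataset(features = x, labels = labels,
                     ids = as.character(1:n), patient_ids = as.character(1:n))
  tr <- dataset_subset(ds, 1:32)
  va <- dataset_subset(ds, 33:40)
  model <- build_model(tiny_model_cfg(use_image = FALSE), seed = 5)
  cfg <- train_config(lr = 5e-2, max_epochs = 40, batch_size = 8,
                      early_stopping_patience = 40, seed = 5)
  fit <- train(model, tr, va, cfg)
  expect_lte(nrow(fit$history), 40)
  expect_true(all(diff(fit$history$lr) <= 0))
  expect_equal(evaluate(fit$model, tr)$metrics$accuracy, 1.0)
  expect_error(train(model, tr, tr, cfg), "overlap")
})

test_that("seeded training is reproducible", {
  set.seed(6)
  n <- 16
  labels <- rep(c(0L, 1L), n / 2)
  x <- matrix(runif(n * 6, 0, pi), n, 6)
  ds <- exam_dataset(features = x, labels = labels, ids = as.character(1:n))
  tr <- dataset_subset(ds, 1:12); va <- dataset_subset(ds, 13:16)
  run <- function() {
    m <- build_model(tiny_model_cfg(use_image = FALSE), seed = 9)
    train(m, tr, va, train_config(lr = 1e-2, max_epochs = 3, seed = 11))$model$params
  }
  expect_identical(run(), run())
})
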