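# Focal-loss training with Adam, plateau learning-rate decay and early
# stopping; metrics, stratified (optionally patient-grouped) k-fold
# cross-validation and the bootstrap confidence interval.

#' Training configuration
#'
#' Defaults follow the tuned recipe: batch size 4, Adam at 1e-4, focal loss
#' with gamma 3, ReduceLROnPlateau (factor 0.5, patience 3) and early
#' stopping after 10 epochs without validation improvement.
#'
#' @param batch_size minibatch size (>= 1).
#' @param lr initial Adam learning rate (> 0).
#' @param focal_gamma focusing parameter gamma (>= 0).
#' @param focal_alpha scalar weight, or `"balanced"` for inverse class
#'   frequency.
#' @param scheduler_factor,scheduler_patience learning-rate decay on
#'   validation-loss plateau.
#' @param early_stopping_patience epochs without improvement before stopping.
#' @param max_epochs epoch cap.
#' @param min_lr floor for the decayed learning rate.
#' @param seed RNG seed for shuffling.
#' @param verbose print per-epoch progress.
#' @export
train_config <- function(batch_size = 4L, lr = 1e-4, focal_gamma = 3,
                         focal_alpha = 1, scheduler_factor = 0.5,
                         scheduler_patience = 3L, early_stopping_patience = 10L,
                         max_epochs = 50L, min_lr = 1e-6, seed = 0L,
                         verbose = FALSE) {
  stopifnot(lr > 0, focal_gamma >= 0, batch_size >= 1)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 focal_gamma = focal_gamma, focal_alpha = focal_alpha,
                 scheduler_factor = scheduler_factor,
                 scheduler_patience = as.integer(scheduler_patience),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 max_epochs = as.integer(max_epochs), min_lr = min_lr,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Focal loss
#'
#' Mean over the batch of `-alpha * (1 - p_t)^gamma * log(p_t)` where `p_t`
#' is the predicted probability of the true class (clamped at 1e-8). With
#' `gamma = 0` and `alpha = 1` this is the cross-entropy.
#'
#' @param p matrix `n x 2` of class probabilities.
#' @param labels integer labels in `{0, 1}` (0 = healthy, 1 = PD).
#' @param gamma focusing parameter (>= 0).
#' @param alpha scalar weight or per-class weight vector of length 2.
#' @return scalar loss.
#' @export
focal_loss <- function(p, labels, gamma = 3, alpha = 1) {
  stopifnot(gamma >= 0, all(labels %in% c(0, 1)))
  p <- rbind(p)
  pt <- pmax(p[cbind(seq_len(nrow(p)), as.integer(labels) + 1L)], 1e-8)
  av <- if (length(alpha) > 1L) alpha[as.integer(labels) + 1L] else alpha
  mean(-av * (1 - pt)^gamma * log(pt))
}

resolve_alpha <- function(alpha, labels) {
  if (identical(alpha, "balanced")) {
    n <- length(labels)
    c(n / (2 * max(1, sum(labels == 0))), n / (2 * max(1, sum(labels == 1))))
  } else {
    alpha
  }
}

# ---- dataset container -------------------------------------------------------

#' Assemble a model-ready dataset
#'
#' @param images list of preprocessed `side x side x 3` arrays in `[0, 1]`
#'   (may be NULL for tabular-only models).
#' @param features normalized `n x n_features` matrix in `[0, pi]` (may be
#'   NULL for image-only models).
#' @param labels integer class labels, 0 = healthy, 1 = PD.
#' @param ids sample identifiers.
#' @param patient_ids per-sample patient identifiers (for grouped splits).
#' @return an `exam_dataset` list.
#' @export
exam_dataset <- function(images = NULL, features = NULL, labels, ids = NULL,
                         patient_ids = NULL) {
  n <- length(labels)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (is.null(patient_ids)) patient_ids <- ids
  structure(list(images = images, features = features,
                 labels = as.integer(labels), ids = as.character(ids),
                 patient_ids = as.character(patient_ids)),
            class = "exam_dataset")
}

#' @export
length.exam_dataset <- function(x) length(x$labels)

#' Subset an exam dataset
#' @param dataset an `exam_dataset`.
#' @param idx integer or logical index.
#' @export
dataset_subset <- function(dataset, idx) {
  exam_dataset(images = if (!is.null(dataset$images)) dataset$images[idx],
               features = if (!is.null(dataset$features))
                 dataset$features[idx, , drop = FALSE],
               labels = dataset$labels[idx], ids = dataset$ids[idx],
               patient_ids = dataset$patient_ids[idx])
}

batch_inputs <- function(model, dataset, idx) {
  cfg <- model$config
  ximg <- NULL; xtab <- NULL
  if (cfg$use_image) {
    side <- cfg$input_side
    ximg <- array(0, c(side, side, 3L, length(idx)))
    for (j in seq_along(idx)) ximg[, , , j] <- dataset$images[[idx[j]]]
  }
  if (cfg$use_tabular) xtab <- t(dataset$features[idx, , drop = FALSE])
  list(ximg = ximg, xtab = xtab)
}

# ---- optimizer ---------------------------------------------------------------

adam_step <- function(model, grads_by_name, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.null(model$opt)) model$opt <- list(m = list(), v = list(), t = 0)
  model$opt$t <- model$opt$t + 1
  t <- model$opt$t
  for (nm in names(grads_by_name)) {
    g <- grads_by_name[[nm]]
    if (is.null(g)) next
    m <- model$opt$m[[nm]]; v <- model$opt$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    model$opt$m[[nm]] <- m
    model$opt$v[[nm]] <- v
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    model$params[[nm]] <- model$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(model)
}

# One forward/backward pass over a minibatch; returns loss and applies Adam.
train_batch <- function(model, dataset, idx, lr, gamma, alpha) {
  inp <- batch_inputs(model, dataset, idx)
  ctx <- fw_ctx(model, training = TRUE)
  out <- fw_model(ctx, inp$ximg, inp$xtab)
  loss <- ad_focal(out$probs, dataset$labels[idx], gamma = gamma, alpha = alpha)
  grads <- ad_backward(loss)
  gb <- list()
  for (nm in ls(ctx$pn)) gb[[nm]] <- grads[[ctx$pn[[nm]]$id]]
  adam_step(model, gb, lr)
  ad_val(loss)
}

dataset_loss <- function(model, dataset, gamma, alpha, batch_size = 8L) {
  n <- length(dataset$labels)
  tot <- 0
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    inp <- batch_inputs(model, dataset, idx)
    p <- t(ad_val(fw_model(fw_ctx(model, training = FALSE),
                           inp$ximg, inp$xtab)$probs))
    tot <- tot + focal_loss(p, dataset$labels[idx], gamma, alpha) * length(idx)
  }
  tot / n
}

#' Train a model
#'
#' Adam on the focal loss with per-epoch shuffling, learning-rate reduction
#' on validation-loss plateau and early stopping; the weights with the best
#' validation loss are restored before returning. Fully seeded.
#'
#' @param model a built model (modified in place).
#' @param train_set,val_set disjoint `exam_dataset`s.
#' @param config a [train_config()].
#' @return list with the trained `model` and a per-epoch `history` data frame
#'   (train loss, validation loss, validation accuracy, learning rate).
#' @export
train <- function(model, train_set, val_set, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  if (length(train_set$labels) == 0 || length(val_set$labels) == 0) {
    stop("train: empty training or validation set", call. = FALSE)
  }
  if (length(intersect(train_set$ids, val_set$ids))) {
    stop("train: training and validation sets overlap", call. = FALSE)
  }
  alpha <- resolve_alpha(config$focal_alpha, train_set$labels)
  lr <- config$lr
  best_val <- Inf
  best_params <- model$params
  plateau <- 0L
  since_best <- 0L
  hist <- list()
  n <- length(train_set$labels)
  with_local_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      tot <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(n, start + config$batch_size - 1L)]
        tot <- tot + train_batch(model, train_set, idx, lr,
                                 config$focal_gamma, alpha) * length(idx)
      }
      train_loss <- tot / n
      val_loss <- dataset_loss(model, val_set, config$focal_gamma, alpha)
      val_acc <- evaluate(model, val_set)$metrics$accuracy
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                  val_loss = val_loss, val_acc = val_acc, lr = lr)
      if (config$verbose) {
        message(sprintf("epoch %d  train %.4f  val %.4f  acc %.3f  lr %.2e",
                        epoch, train_loss, val_loss, val_acc, lr))
      }
      if (val_loss < best_val - 1e-9) {
        best_val <- val_loss
        best_params <- model$params
        plateau <- 0L
        since_best <- 0L
      } else {
        plateau <- plateau + 1L
        since_best <- since_best + 1L
        if (plateau >= config$scheduler_patience) {
          lr <- max(config$min_lr, lr * config$scheduler_factor)
          plateau <- 0L
        }
        if (since_best >= config$early_stopping_patience) break
      }
    }
  })
  model$params <- best_params
  list(model = model, history = do.call(rbind, hist))
}

# ---- metrics -----------------------------------------------------------------

#' Evaluate a model on a dataset
#'
#' Argmax predictions, accuracy, macro-averaged precision/recall/F1 and the
#' 2x2 confusion matrix.
#'
#' @param model a built model.
#' @param dataset non-empty `exam_dataset`.
#' @param batch_size forward batch size.
#' @return list with `metrics` and per-sample `predictions` (id, true label,
#'   predicted label, class probabilities).
#' @export
evaluate <- function(model, dataset, batch_size = 8L) {
  n <- length(dataset$labels)
  stopifnot(n > 0)
  probs <- matrix(0, n, 2)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    inp <- batch_inputs(model, dataset, idx)
    ctx <- fw_ctx(model, training = FALSE)
    probs[idx, ] <- t(ad_val(fw_model(ctx, inp$ximg, inp$xtab)$probs))
  }
  pred <- max.col(probs, ties.method = "first") - 1L
  preds <- data.frame(id = dataset$ids, true = dataset$labels, pred = pred,
                      p_healthy = probs[, 1], p_pd = probs[, 2],
                      stringsAsFactors = FALSE)
  list(metrics = classification_metrics(dataset$labels, pred), predictions = preds)
}

#' Two-class classification metrics
#'
#' @param true,pred integer vectors of labels in `{0, 1}`.
#' @return list with accuracy, macro precision/recall/F1 and the confusion
#'   matrix (rows = true, cols = predicted).
#' @export
classification_metrics <- function(true, pred) {
  cm <- matrix(0, 2, 2, dimnames = list(true = c("H", "P"), pred = c("H", "P")))
  for (c1 in 0:1) for (c2 in 0:1) cm[c1 + 1, c2 + 1] <- sum(true == c1 & pred == c2)
  prec <- rec <- f1 <- numeric(2)
  for (c1 in 1:2) {
    prec[c1] <- if (sum(cm[, c1]) > 0) cm[c1, c1] / sum(cm[, c1]) else 0
    rec[c1] <- if (sum(cm[c1, ]) > 0) cm[c1, c1] / sum(cm[c1, ]) else 0
    f1[c1] <- if (prec[c1] + rec[c1] > 0) 2 * prec[c1] * rec[c1] / (prec[c1] + rec[c1]) else 0
  }
  list(accuracy = sum(diag(cm)) / sum(cm), precision = mean(prec),
       recall = mean(rec), f1 = mean(f1), confusion = cm)
}

# ---- cross-validation --------------------------------------------------------

#' Stratified (optionally grouped) k-fold assignment
#'
#' Partitions samples into k folds stratified by class; with `groups`, whole
#' groups (e.g. patients) are assigned to folds so no group spans two folds.
#' Fold sizes differ by at most one sample (one group when grouped, per
#' class).
#'
#' @param labels integer class labels.
#' @param k number of folds (`k <= n`).
#' @param groups optional per-sample grouping ids.
#' @param seed RNG seed.
#' @return integer fold assignment (1..k) per sample.
#' @export
kfold_split <- function(labels, k = 5L, groups = NULL, seed = 0L) {
  n <- length(labels)
  if (k > n) stop("kfold_split: k (", k, ") exceeds sample count (", n, ")",
                  call. = FALSE)
  if (k < 2) stop("kfold_split: k must be >= 2", call. = FALSE)
  with_local_seed(seed, {
    fold <- integer(n)
    if (is.null(groups)) {
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep_len(sample.int(k), length(idx))
      }
    } else {
      groups <- as.character(groups)
      gclass <- tapply(labels, groups, function(x) x[1])
      gnames <- names(gclass)
      gfold <- setNames(integer(length(gnames)), gnames)
      for (cl in unique(gclass)) {
        gs <- sample(gnames[gclass == cl])
        gfold[gs] <- rep_len(sample.int(k), length(gs))
      }
      fold <- gfold[groups]
    }
    as.integer(fold)
  })
}

#' k-fold cross-validation with training per fold
#'
#' Each fold serves as the validation set exactly once; a fresh model is
#' trained on the remaining folds. Per-fold predictions are pooled for the
#' bootstrap confidence interval.
#'
#' @param dataset an `exam_dataset`.
#' @param k number of folds.
#' @param model_cfg a [model_config()] used to build each fold's model.
#' @param train_cfg a [train_config()].
#' @param group_by_patient assign whole patients to folds (default TRUE).
#' @param seed split and per-fold training seed.
#' @return list with per-fold results (`folds`), pooled predictions
#'   (`pooled`) and the pooled [bootstrap_ci()] (`bootstrap`).
#' @export
kfold_cv <- function(dataset, k = 5L, model_cfg, train_cfg = train_config(),
                     group_by_patient = TRUE, seed = 0L) {
  fold <- kfold_split(dataset$labels, k,
                      groups = if (group_by_patient) dataset$patient_ids,
                      seed = seed)
  folds <- vector("list", k)
  pooled <- list()
  for (f in seq_len(k)) {
    tr <- dataset_subset(dataset, fold != f)
    va <- dataset_subset(dataset, fold == f)
    model <- build_model(model_cfg, seed = derive_seed(seed, 100L + f))
    cfg_f <- train_cfg
    cfg_f$seed <- derive_seed(seed, 200L + f)
    fit <- train(model, tr, va, cfg_f)
    ev <- evaluate(fit$model, va)
    folds[[f]] <- list(fold = f, metrics = ev$metrics, predictions = ev$predictions)
    pooled[[f]] <- ev$predictions
  }
  pooled <- do.call(rbind, pooled)
  list(folds = folds, pooled = pooled,
       bootstrap = bootstrap_ci(pooled, seed = derive_seed(seed, 300L)))
}

#' Percentile bootstrap confidence interval for accuracy
#'
#' Resamples pooled per-sample predictions with replacement and reports the
#' percentile interval of the mean accuracy.
#'
#' @param pooled data frame of predictions with columns `true` and `pred`.
#' @param n_resamples number of bootstrap resamples (default 10,000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return list with `mean_accuracy`, `ci_low`, `ci_high`, `width`,
#'   `n_resamples`, `level`.
#' @export
bootstrap_ci <- function(pooled, n_resamples = 10000L, level = 0.95, seed = 0L) {
  stopifnot(nrow(pooled) > 0)
  correct <- as.numeric(pooled$true == pooled$pred)
  n <- length(correct)
  accs <- with_local_seed(seed, {
    idx <- sample.int(n, n * n_resamples, replace = TRUE)
    colMeans(matrix(correct[idx], n, n_resamples))
  })
  qs <- unname(quantile(accs, c((1 - level) / 2, 1 - (1 - level) / 2), type = 7))
  list(mean_accuracy = mean(accs), ci_low = qs[1], ci_high = qs[2],
       width = qs[2] - qs[1], n_resamples = as.integer(n_resamples),
       level = level, observed_accuracy = mean(correct))
}
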