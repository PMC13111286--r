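# Grad-CAM and perturbation sensitivity.

test_that("grad_cam returns a normalized map and an all-zero map for constant scores", {
  model <- build_model(tiny_model_cfg(), seed = 1)
  set.seed(1)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  feat <- runif(6, 0, pi)
  sal <- grad_cam(model, img, feat, target_class = 1)
  expect_s3_class(sal, "saliency_map")
  expect_equal(dim(sal$values), c(32L, 32L))
  expect_true(all(sal$values >= 0 & sal$values <= 1))
  expect_equal(sal$source_layer, "stage2")
  # constant class score: zero the fusion output layer -> all gradients vanish
  m0 <- build_model(tiny_model_cfg(), seed = 1)
  m0$params[["fusion.out.w"]][] <- 0
  m0$params[["fusion.out.b"]][] <- 0
  sal0 <- grad_cam(m0, img, feat, target_class = 1)
  expect_true(all(sal0$values == 0))
  expect_error(grad_cam(model, img, feat, layer = "nonsense"), "unknown layer")
  expect_error(grad_cam(model, img, feat, layer = "stage9"), "out of range")
})

test_that("grad_cam on a single-stage toy reduces to the hand formula", {
  # one CA_SE stage, saturating analysis: compare against a direct
  # computation of ReLU(sum_k w_k A_k) from the recorded activations/grads
  ns <- asNamespace("qspiral")
  model <- build_model(tiny_model_cfg(use_tabular = FALSE), seed = 3)
  set.seed(3)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  ximg <- img; dim(ximg) <- c(32, 32, 3, 1)
  ctx <- ns$fw_ctx(model, training = FALSE)
  out <- ns$fw_model(ctx, ximg, NULL)
  score <- ns$ad_pick(out$logits, 2L, 1L)
  grads <- ns$ad_backward(score)
  act <- out$tvsfe$stages[[2]]
  A <- ns$ad_val(act); G <- grads[[act$id]]
  d <- dim(A)
  w <- colMeans(matrix(G[, , , 1], d[1] * d[2], d[3]))
  cam_ref <- pmax(matrix(matrix(A[, , , 1], d[1] * d[2], d[3]) %*% w, d[1], d[2]), 0)
  cam_ref <- as.matrix(EBImage::resize(cam_ref, w = 32, h = 32))
  cam_ref <- pmax(cam_ref, 0)
  if (max(cam_ref) > 0) cam_ref <- cam_ref / max(cam_ref)
  sal <- grad_cam(model, img, target_class = 1, layer = "stage_last")
  expect_equal(sal$values, cam_ref, tolerance = 1e-10)
})

test_that("sensitivity ignores a feature the model provably cannot use", {
  model <- build_model(tiny_model_cfg(use_image = FALSE), seed = 2)
  # zero all weights reading feature 3's qubit? simpler: classical ablation
  m <- build_model(tiny_model_cfg(use_image = FALSE, quantum = FALSE), seed = 2)
  # make the MLP ignore feature 6 entirely
  m$params[["vqfmn.mlp1.w"]][, 6] <- 0
  set.seed(2)
  n <- 24
  labels <- rep(c(0L, 1L), n / 2)
  x <- matrix(runif(n * 6, 0, pi), n, 6,
              dimnames = list(NULL, c("gender", "handedness", "age",
                                      "rms", "mrt", "std_diff")))
  ds <- exam_dataset(features = x, labels = labels, ids = as.character(1:n))
  rep1 <- perturbation_sensitivity(m, ds, n_repeats = 3, seed = 4)
  expect_s3_class(rep1, "sensitivity_report")
  expect_equal(unname(rep1$scores["std_diff"]), 0)
  expect_true(all(rep1$scores >= 0))
  expect_setequal(rep1$ranking, 1:6)
  # determinism
  rep2 <- perturbation_sensitivity(m, ds, n_repeats = 3, seed = 4)
  expect_identical(rep1, rep2)
  expect_error(perturbation_sensitivity(m, ds, n_repeats = 0), "n_repeats")
})

test_that("sensitivity ranks a planted signal feature first after training", {
  set.seed(7)
  n <- 48
  labels <- rep(c(0L, 1L), n / 2)
  x <- matrix(runif(n * 6, 0, pi), n, 6,
              dimnames = list(NULL, c("gender", "handedness", "age",
                                      "rms", "mrt", "std_diff")))
  x[, "rms"] <- ifelse(labels == 1, runif(n, 2.3, pi), runif(n, 0, 0.8))
  ds <- exam_dataset(features = x, labels = labels, ids = as.character(1:n))
  tr <- dataset_subset(ds, 1:36); va <- dataset_subset(ds, 37:48)
  m <- build_model(tiny_model_cfg(use_image = FALSE), seed = 7)
  fit <- train(m, tr, va, train_config(lr = 5e-2, max_epochs = 25, batch_size = 8,
                                       early_stopping_patience = 25, seed = 7))
  rep <- perturbation_sensitivity(fit$model, ds, n_repeats = 3, seed = 8)
  expect_equal(rep$feature_names[rep$ranking[1]], "rms")
})

test_that("overlays blend proportionally to saliency", {
  set.seed(5)
  img <- array(round(runif(16 * 16 * 3, 0, 255)), c(16, 16, 3))
  zero <- matrix(0, 16, 16)
  expect_equal(render_overlay(img, zero), img)
  out <- render_overlay(img, matrix(runif(256), 16, 16), alpha = 0.5)
  expect_equal(dim(out), dim(img))
  # full blend with saturated saliency yields the pure colormap color
  ones <- matrix(1, 16, 16)
  solid <- render_overlay(img, ones, alpha = 1)
  expect_lt(max(abs(sweep(solid, 3, solid[1, 1, ]))), 1e-9)
  expect_error(render_overlay(img, matrix(0, 8, 8)), "does not match")
})

test_that("saliency_mask_overlap counts top pixels inside the dilated mask", {
  s <- matrix(0, 20, 20)
  s[5:8, 5:8] <- 1
  mask <- matrix(FALSE, 20, 20)
  mask[5:8, 5:8] <- TRUE
  expect_equal(saliency_mask_overlap(s, mask, top_fraction = 16 / 400, dilate = 0), 1)
  mask2 <- matrix(FALSE, 20, 20)
  mask2[15:18, 15:18] <- TRUE
  expect_equal(saliency_mask_overlap(s, mask2, top_fraction = 16 / 400, dilate = 0), 0)
})
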