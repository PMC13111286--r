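# Explainability: Grad-CAM for the image track and perturbation-based
# sensitivity ranking for the structured track.

#' Grad-CAM saliency map for the image track
#'
#' Weights each channel of a CDAB stage's activation map by the spatial mean
#' of the target-class score gradient, takes the ReLU of the weighted sum,
#' bilinearly upsamples to the input side and min-max normalizes (an all-zero
#' map stays all-zero).
#'
#' @param model a built model with the image track enabled (evaluation mode).
#' @param image one preprocessed `side x side x 3` array in `[0, 1]`.
#' @param features the sample's normalized feature vector (required when the
#'   tabular track is enabled).
#' @param target_class 0 (healthy) or 1 (PD); defaults to the predicted class.
#' @param layer `"stage_last"` or `"stage<k>"` naming a CDAB stage.
#' @return a `saliency_map`: list with `values` (side x side in `[0, 1]`),
#'   `target_class` and `source_layer`.
#' @export
grad_cam <- function(model, image, features = NULL, target_class = NULL,
                     layer = "stage_last") {
  cfg <- model$config
  stopifnot(cfg$use_image)
  nstage <- length(cfg$stage_channels)
  sidx <- if (identical(layer, "stage_last")) nstage else {
    if (!grepl("^stage[0-9]+$", layer)) {
      stop("grad_cam: unknown layer '", layer, "'; use 'stage_last' or 'stage<k>'",
           call. = FALSE)
    }
    as.integer(sub("stage", "", layer))
  }
  if (is.na(sidx) || sidx < 1L || sidx > nstage) {
    stop("grad_cam: layer index out of range (model has ", nstage, " stages)",
         call. = FALSE)
  }
  ximg <- as_image_batch(image, cfg$input_side)
  stopifnot(dim(ximg)[4] == 1L)
  xtab <- if (cfg$use_tabular) {
    if (is.null(features)) {
      stop("grad_cam: the tabular track is enabled; supply `features`", call. = FALSE)
    }
    matrix(features, ncol = 1L)
  }
  ctx <- fw_ctx(model, training = FALSE)
  out <- fw_model(ctx, ximg, xtab)
  if (is.null(target_class)) {
    target_class <- which.max(ad_val(out$probs)[, 1]) - 1L
  }
  score <- ad_pick(out$logits, as.integer(target_class) + 1L, 1L)
  grads <- ad_backward(score)
  act_node <- out$tvsfe$stages[[sidx]]
  A <- ad_val(act_node)
  G <- grads[[act_node$id]]
  if (is.null(G)) G <- array(0, dim(A))
  d <- dim(A)
  w <- colMeans(matrix(G[, , , 1], d[1] * d[2], d[3]))
  cam <- matrix(matrix(A[, , , 1], d[1] * d[2], d[3]) %*% w, d[1], d[2])
  cam <- pmax(cam, 0)
  up <- if (all(dim(cam) == cfg$input_side)) cam else {
    as.matrix(EBImage::resize(cam, w = cfg$input_side, h = cfg$input_side))
  }
  up <- pmax(up, 0)
  if (max(up) > 0) up <- up / max(up)
  structure(list(values = up, target_class = as.integer(target_class),
                 source_layer = paste0("stage", sidx)),
            class = "saliency_map")
}

#' Perturbation-based sensitivity of structured features
#'
#' Perturbs one feature column at a time across the dataset -- shuffling it
#' (`mode = "permute"`, preserving marginals) or adding Gaussian noise with
#' the column's standard deviation (`mode = "noise"`) -- and scores each
#' feature by the mean drop it causes in accuracy (or in the probability of
#' the true class). Negative scores are clipped to zero.
#'
#' @param model a trained model with the tabular track enabled.
#' @param dataset an `exam_dataset` with `>= 2` samples and features.
#' @param mode perturbation type.
#' @param n_repeats perturbation repeats per feature (>= 1).
#' @param seed RNG seed.
#' @param score `"accuracy"` (drop in accuracy) or `"probability"` (drop in
#'   mean true-class probability).
#' @return a `sensitivity_report`: per-feature scores, descending `ranking`,
#'   and the run settings.
#' @export
perturbation_sensitivity <- function(model, dataset, mode = c("permute", "noise"),
                                     n_repeats = 5L, seed = 0L,
                                     score = c("accuracy", "probability")) {
  mode <- match.arg(mode)
  score <- match.arg(score)
  if (n_repeats < 1) stop("perturbation_sensitivity: n_repeats must be >= 1",
                          call. = FALSE)
  stopifnot(model$config$use_tabular, !is.null(dataset$features))
  n <- length(dataset$labels)
  if (n < 2) stop("perturbation_sensitivity: need at least 2 samples", call. = FALSE)
  base <- evaluate(model, dataset)
  base_score <- if (score == "accuracy") base$metrics$accuracy else {
    mean(base$predictions[cbind(seq_len(n),
                                ifelse(dataset$labels == 0, "p_healthy", "p_pd"))])
  }
  d <- ncol(dataset$features)
  fnames <- colnames(dataset$features)
  if (is.null(fnames)) fnames <- paste0("f", seq_len(d))
  drops <- matrix(0, n_repeats, d)
  with_local_seed(seed, {
    for (j in seq_len(d)) {
      for (r in seq_len(n_repeats)) {
        ds2 <- dataset
        col <- ds2$features[, j]
        ds2$features[, j] <- if (mode == "permute") col[sample.int(n)] else {
          clamp(col + rnorm(n, 0, sd(col)), 0, pi)
        }
        ev <- evaluate(model, ds2)
        s <- if (score == "accuracy") ev$metrics$accuracy else {
          mean(ev$predictions[cbind(seq_len(n),
                                    ifelse(dataset$labels == 0, "p_healthy", "p_pd"))])
        }
        drops[r, j] <- base_score - s
      }
    }
  })
  scores <- pmax(colMeans(drops), 0)
  names(scores) <- fnames
  structure(list(scores = scores, ranking = order(scores, decreasing = TRUE),
                 feature_names = fnames, mode = mode,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 baseline = base_score, score = score),
            class = "sensitivity_report")
}

#' Overlay a saliency map on an exam image
#'
#' Alpha-blends a heatmap over the drawing: the per-pixel blend weight is
#' `alpha * saliency`, so zero saliency leaves the image untouched and
#' `alpha = 1` with saturated saliency gives the pure colormap.
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param saliency a `saliency_map` or an `H x W` matrix in `[0, 1]`.
#' @param colormap heatmap palette: `"jet"` (blue-to-red) or `"hot"`.
#' @param alpha maximal blend weight in `[0, 1]`.
#' @return blended `H x W x 3` array in `[0, 255]`.
#' @export
render_overlay <- function(image, saliency, colormap = c("jet", "hot"),
                           alpha = 0.5) {
  check_rgb_image(image)
  colormap <- match.arg(colormap)
  s <- if (inherits(saliency, "saliency_map")) saliency$values else saliency
  if (!all(dim(s) == dim(image)[1:2])) {
    stop("render_overlay: saliency size ", paste(dim(s), collapse = "x"),
         " does not match image size ", paste(dim(image)[1:2], collapse = "x"),
         call. = FALSE)
  }
  ramp <- grDevices::colorRamp(switch(colormap,
    jet = c("#00007F", "blue", "cyan", "yellow", "red"),
    hot = c("black", "red", "yellow", "white")))
  heat <- ramp(as.numeric(clamp(s, 0, 1)))
  w <- alpha * as.numeric(s)
  out <- image
  for (ch in 1:3) {
    out[, , ch] <- (1 - w) * as.numeric(image[, , ch]) + w * heat[, ch]
  }
  out
}

#' Fraction of top-saliency pixels inside a mask
#'
#' Helper for validating saliency maps against a known pen-trace mask: takes
#' the top `top_fraction` of saliency values and reports the fraction of
#' those pixels falling inside the (dilated) mask.
#'
#' @param saliency a `saliency_map` or matrix.
#' @param mask logical matrix of the same size.
#' @param top_fraction fraction of pixels considered "top" (default 0.05).
#' @param dilate dilation radius in pixels applied to the mask.
#' @return scalar fraction in `[0, 1]`.
#' @export
saliency_mask_overlap <- function(saliency, mask, top_fraction = 0.05, dilate = 5L) {
  s <- if (inherits(saliency, "saliency_map")) saliency$values else saliency
  stopifnot(all(dim(s) == dim(mask)))
  if (dilate > 0) {
    mask <- EBImage::dilate(mask * 1, EBImage::makeBrush(2L * dilate + 1L,
                                                         shape = "disc")) > 0
  }
  k <- max(1L, round(length(s) * top_fraction))
  thr <- sort(as.numeric(s), decreasing = TRUE)[k]
  top <- s >= thr
  # ties at the threshold can exceed k pixels; sample deterministically by order
  idx <- order(as.numeric(s), decreasing = TRUE)[seq_len(k)]
  mean(mask[idx])
}
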