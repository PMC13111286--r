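# Image pipeline (denoise -> grayscale suppression -> resize/scale) and
# structured-feature imputation + [0, pi] normalization.

#' Denoise an exam image
#'
#' Applies a mean (box) filter followed by a median filter per channel, both
#' with edge replication. A kernel size of 1 is the identity for that filter.
#'
#' @param image `H x W x 3` array with intensities in `[0, 255]`.
#' @param mean_kernel,median_kernel odd kernel side lengths (>= 1).
#' @return the filtered image, rounded back to integers in `[0, 255]`.
#' @export
denoise <- function(image, mean_kernel = 3L, median_kernel = 3L) {
  check_rgb_image(image)
  for (k in c(mean_kernel, median_kernel)) {
    if (k < 1 || k %% 2L == 0L) {
      stop("denoise: kernel sizes must be odd and >= 1", call. = FALSE)
    }
  }
  out <- image
  if (mean_kernel > 1L) {
    for (ch in 1:3) {
      out[, , ch] <- meanfilt_cpp(out[, , ch], as.integer(mean_kernel))
    }
  }
  if (median_kernel > 1L) {
    for (ch in 1:3) {
      out[, , ch] <- medfilt_cpp(out[, , ch], as.integer(median_kernel))
    }
  }
  clamp(round(out), 0, 255)
}

#' Suppress near-grayscale pixels
#'
#' Implements the inter-channel difference rule: a pixel is set to white
#' (255, 255, 255) iff all three pairwise channel differences are strictly
#' below the threshold. This removes the printed template and background
#' while retaining the saturated pen trace. Idempotent (white is grayscale).
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param threshold strict inequality threshold, inside `(0, 256)`; default 45.
#' @return the suppressed image.
#' @export
suppress_grayscale <- function(image, threshold = 45) {
  check_rgb_image(image)
  if (threshold <= 0 || threshold >= 256) {
    stop("suppress_grayscale: threshold must lie in (0, 256)", call. = FALSE)
  }
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  gray <- abs(r - g) < threshold & abs(r - b) < threshold & abs(g - b) < threshold
  out <- image
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[gray] <- 255
    out[, , ch] <- plane
  }
  out
}

#' Resize to a square side and scale intensities to [0, 1]
#'
#' @param image non-empty `H x W x 3` array in `[0, 255]`.
#' @param side output side length in pixels (default 512, bilinear).
#' @return `side x side x 3` numeric array in `[0, 1]`.
#' @export
resize_and_scale <- function(image, side = 512L) {
  check_rgb_image(image)
  if (side <= 0) stop("resize_and_scale: side must be positive", call. = FALSE)
  d <- dim(image)
  out <- if (d[1] == side && d[2] == side) image
         else as.array(EBImage::resize(image, w = side, h = side))
  clamp(out / 255, 0, 1)
}

#' Full image preprocessing pipeline
#'
#' Denoise, suppress near-grayscale pixels, then resize and scale.
#'
#' @inheritParams denoise
#' @inheritParams suppress_grayscale
#' @inheritParams resize_and_scale
#' @return `side x side x 3` array in `[0, 1]`.
#' @export
preprocess_image <- function(image, side = 512L, threshold = 45,
                             mean_kernel = 3L, median_kernel = 3L) {
  image <- denoise(image, mean_kernel, median_kernel)
  image <- suppress_grayscale(image, threshold)
  resize_and_scale(image, side)
}

feature_columns <- c("gender", "handedness", "age", "rms", "mrt", "std_diff")
numeric_feature_columns <- c("age", "rms", "mrt", "std_diff")
categorical_feature_columns <- c("gender", "handedness")

#' Fit a simple imputer on a set of records
#'
#' Column means for numeric features, modes for categorical ones, computed on
#' the fitting split only (fit on training folds, apply everywhere).
#'
#' @param records data frame of structured records.
#' @return an object of class `feature_imputer`.
#' @export
fit_imputer <- function(records) {
  if (nrow(records) < 1) stop("fit_imputer: need at least one record", call. = FALSE)
  means <- lapply(numeric_feature_columns, function(cn) {
    v <- records[[cn]]
    m <- mean(v, na.rm = TRUE)
    if (!is.finite(m)) {
      stop("fit_imputer: column '", cn, "' has no observed values in the fitting split",
           call. = FALSE)
    }
    m
  })
  modes <- lapply(categorical_feature_columns, function(cn) {
    v <- records[[cn]]
    v <- v[!is.na(v)]
    if (!length(v)) {
      stop("fit_imputer: column '", cn, "' has no observed values in the fitting split",
           call. = FALSE)
    }
    names(sort(table(v), decreasing = TRUE))[1]
  })
  structure(list(means = setNames(means, numeric_feature_columns),
                 modes = setNames(modes, categorical_feature_columns)),
            class = "feature_imputer")
}

#' Impute missing structured features
#'
#' @param records data frame of structured records.
#' @param imputer a fitted [fit_imputer()] object; if `NULL`, fitted on
#'   `records` themselves.
#' @return `records` with missing numeric values replaced by fitted column
#'   means and missing categorical values by fitted modes.
#' @export
impute_features <- function(records, imputer = NULL) {
  if (is.null(imputer)) imputer <- fit_imputer(records)
  stopifnot(inherits(imputer, "feature_imputer"))
  for (cn in numeric_feature_columns) {
    v <- records[[cn]]
    v[is.na(v)] <- imputer$means[[cn]]
    records[[cn]] <- v
  }
  for (cn in categorical_feature_columns) {
    v <- records[[cn]]
    v[is.na(v)] <- imputer$modes[[cn]]
    records[[cn]] <- v
  }
  records
}

# Encode the six model features as a numeric matrix (categoricals to {0,1}).
encode_features <- function(records) {
  m <- cbind(
    gender = as.numeric(records$gender == "M"),
    handedness = as.numeric(records$handedness == "R"),
    age = as.numeric(records$age),
    rms = as.numeric(records$rms),
    mrt = as.numeric(records$mrt),
    std_diff = as.numeric(records$std_diff)
  )
  if (any(!is.finite(m))) {
    stop("encode_features: non-finite feature values; impute first", call. = FALSE)
  }
  m
}

#' Fit per-feature min-max ranges on the training split
#'
#' @param records data frame of (imputed) structured records.
#' @return an object of class `feature_ranges`.
#' @export
fit_feature_ranges <- function(records) {
  m <- encode_features(records)
  structure(list(min = apply(m, 2, min), max = apply(m, 2, max)),
            class = "feature_ranges")
}

#' Normalize structured features into [0, pi]
#'
#' Linear map `pi * (x - min) / (max - min)` using ranges fitted on the
#' training split; constant features map to 0 and out-of-range values are
#' clipped so the quantum rotation encoding stays within its domain.
#'
#' @param records data frame of (imputed) structured records.
#' @param fitted_ranges a [fit_feature_ranges()] object.
#' @return numeric matrix (`n x 6`, columns gender, handedness, age, rms,
#'   mrt, std_diff) with all entries in `[0, pi]`.
#' @export
normalize_features <- function(records, fitted_ranges) {
  if (!inherits(fitted_ranges, "feature_ranges")) {
    stop("normalize_features: ranges must be fitted with fit_feature_ranges()",
         call. = FALSE)
  }
  m <- encode_features(records)
  span <- fitted_ranges$max - fitted_ranges$min
  if (any(span < 0)) stop("normalize_features: max < min in fitted ranges", call. = FALSE)
  out <- sweep(m, 2, fitted_ranges$min)
  for (j in seq_along(span)) {
    out[, j] <- if (span[j] == 0) 0 else pi * out[, j] / span[j]
  }
  clamp(out, 0, pi)
}
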