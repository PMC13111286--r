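# Dataset readers/writers and model persistence.

required_meta_columns <- c("exam_id", "image_name", "patient_id", "class_label",
                           "gender", "handedness", "age", "rms", "mrt", "std_diff")

normalize_class_label <- function(x) {
  x <- as.character(x)
  map <- c("H" = "H", "Healthy" = "H", "healthy" = "H", "0" = "H",
           "P" = "P", "Patient" = "P", "patient" = "P", "PD" = "P", "1" = "P")
  out <- unname(map[x])
  if (any(is.na(out))) {
    stop("unrecognized class labels: ", paste(unique(x[is.na(out)]), collapse = ", "),
         "; accepted: H/Healthy/0 and P/Patient/PD/1", call. = FALSE)
  }
  out
}

#' Read an exam directory into a dataset manifest
#'
#' Expects class subfolders of images plus a `meta.csv` with the standard
#' metadata columns; images and rows are joined on `image_name`. Unmatched
#' images are excluded with a warning; rows without an image file likewise.
#'
#' @param path dataset root directory.
#' @return a `dataset_manifest` data frame with one row per matched sample
#'   (image path, metadata, integer `label` with H -> 0, P -> 1, and a
#'   `mask_path` column when a `masks/` folder is present).
#' @export
read_exam_directory <- function(path) {
  meta_path <- file.path(path, "meta.csv")
  if (!file.exists(meta_path)) {
    csvs <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
    if (length(csvs) != 1L) {
      stop("read_exam_directory: no metadata CSV found in ", path, call. = FALSE)
    }
    meta_path <- csvs[1]
  }
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required_meta_columns, names(meta))
  if (length(missing_cols)) {
    stop("read_exam_directory: metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(meta$exam_id)) {
    stop("read_exam_directory: duplicate exam_id values in metadata", call. = FALSE)
  }
  files <- list.files(path, pattern = "\\.(png|jpg|jpeg)$", recursive = TRUE,
                      full.names = TRUE, ignore.case = TRUE)
  files <- files[basename(dirname(files)) != "masks"]
  by_name <- setNames(files, basename(files))
  meta$class_label <- normalize_class_label(meta$class_label)
  meta$label <- ifelse(meta$class_label == "P", 1L, 0L)
  meta$image_path <- unname(by_name[meta$image_name])
  n_missing_files <- sum(is.na(meta$image_path))
  if (n_missing_files > 0) {
    warning(n_missing_files, " metadata row(s) have no matching image; excluded")
    meta <- meta[!is.na(meta$image_path), , drop = FALSE]
  }
  orphans <- setdiff(names(by_name), meta$image_name)
  if (length(orphans)) {
    warning(length(orphans), " image(s) have no metadata row; excluded")
  }
  mask_dir <- file.path(path, "masks")
  if (dir.exists(mask_dir)) {
    mp <- file.path(mask_dir, meta$image_name)
    meta$mask_path <- ifelse(file.exists(mp), mp, NA_character_)
  }
  attr(meta, "root") <- path
  attr(meta, "class_map") <- c(H = 0L, P = 1L)
  class(meta) <- c("dataset_manifest", class(meta))
  meta
}

#' Load and preprocess a dataset from a manifest
#'
#' Decodes each image, runs the preprocessing pipeline at the requested side,
#' and assembles an `exam_dataset`. Features are left un-normalized; call
#' [normalize_for_split()] (or [normalize_dataset()]) with the training index
#' to add the `[0, pi]` feature matrix without leakage.
#'
#' @param manifest a [read_exam_directory()] manifest.
#' @param side preprocessed image side.
#' @param with_images decode images (set FALSE for tabular-only work).
#' @param threshold,mean_kernel,median_kernel preprocessing settings.
#' @return an `exam_dataset` with the raw metadata attached as `$records`.
#' @export
load_dataset <- function(manifest, side = 512L, with_images = TRUE,
                         threshold = 45, mean_kernel = 3L, median_kernel = 3L) {
  images <- NULL
  if (with_images) {
    images <- lapply(manifest$image_path, function(p) {
      preprocess_image(read_exam_image(p), side = side, threshold = threshold,
                       mean_kernel = mean_kernel, median_kernel = median_kernel)
    })
  }
  ds <- exam_dataset(images = images, features = NULL, labels = manifest$label,
                     ids = as.character(manifest$exam_id),
                     patient_ids = manifest$patient_id)
  ds$records <- as.data.frame(manifest)
  ds
}

#' Normalized feature matrix fitted on a training split
#'
#' Imputes missing values and min-max normalizes to `[0, pi]`, with both the
#' imputation statistics and the ranges fitted on `fit_idx` only.
#'
#' @param records structured-record data frame.
#' @param fit_idx indices of the fitting (training) split.
#' @return `n x 6` feature matrix for all records.
#' @export
normalize_for_split <- function(records, fit_idx = seq_len(nrow(records))) {
  imp <- fit_imputer(records[fit_idx, , drop = FALSE])
  rec <- impute_features(records, imp)
  rng <- fit_feature_ranges(rec[fit_idx, , drop = FALSE])
  normalize_features(rec, rng)
}

#' Attach normalized features to a dataset
#'
#' @param dataset an `exam_dataset` with `$records`.
#' @param fit_idx fitting-split indices (default: all samples).
#' @return the dataset with `$features` set.
#' @export
normalize_dataset <- function(dataset, fit_idx = seq_along(dataset$labels)) {
  stopifnot(!is.null(dataset$records))
  dataset$features <- normalize_for_split(dataset$records, fit_idx)
  dataset
}

#' Write per-sample predictions to CSV
#'
#' @param records data frame with columns id, true, pred, p_healthy, p_pd.
#' @param path output CSV path.
#' @export
write_predictions <- function(records, path) {
  out <- data.frame(id = as.character(records$id),
                    true = as.integer(records$true),
                    pred = as.integer(records$pred),
                    p_healthy = sprintf("%.10f", records$p_healthy),
                    p_pd = sprintf("%.10f", records$p_pd),
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read predictions written by [write_predictions()]
#' @param path CSV path.
#' @export
read_predictions <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(id = "character", true = "integer", pred = "integer",
                          p_healthy = "numeric", p_pd = "numeric"))
}

#' Save a trained model to disk
#' @param model a built model environment.
#' @param path output path (RDS).
#' @export
save_model <- function(model, path) {
  saveRDS(list(config = model$config, params = model$params,
               state = lapply(model$state, as.list), seed = model$seed), path)
  invisible(path)
}

#' Load a model saved with [save_model()]
#' @param path RDS path.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  m <- new_model_env(obj$config, obj$seed)
  m$params <- obj$params
  m$state <- lapply(obj$state, function(s) list2env(s, parent = emptyenv()))
  m
}
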