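# Small shared helpers.

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed, staying inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 104729) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_rgb_image <- function(img) {
  is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L
}

check_rgb_image <- function(img, what = "image") {
  if (!is_rgb_image(img)) {
    stop(what, " must be an H x W x 3 array", call. = FALSE)
  }
  if (min(img) < 0 || max(img) > 255) {
    stop(what, " intensities must lie in [0, 255]", call. = FALSE)
  }
  invisible(img)
}

# Read an exam image into an H x W x 3 array of intensities in [0, 255].
read_exam_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  img <- tryCatch({
    if (grepl("\\.png$", path, ignore.case = TRUE)) {
      png::readPNG(path)
    } else {
      aperm(as.array(EBImage::readImage(path)), c(2L, 1L, 3L))
    }
  }, error = function(e) {
    stop("failed to decode image '", path, "': ", conditionMessage(e), call. = FALSE)
  })
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

write_exam_image <- function(img, path) {
  png::writePNG(clamp(img / 255, 0, 1), target = path)
}
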