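# Synthetic handwriting-exam generator.
#
# Emulates the layout of public spiral/meander exam collections: a printed
# near-grayscale template curve overdrawn by a colored subject trace, plus a
# per-sample metadata CSV with demographic and trace-derived features. Tremor
# is modeled as a sinusoidal displacement along the local curve normal plus
# Gaussian jitter, so group separation is controllable and the pen-trace mask
# is known exactly.

#' Tremor model parameters
#'
#' @param amplitude sinusoid amplitude in pixels (>= 0).
#' @param frequency oscillation cycles along the full trace (>= 0); the
#'   displacement at normalized arc length `s` is
#'   `amplitude * sin(2*pi*frequency*s)`.
#' @param jitter_sd standard deviation of additive Gaussian jitter in pixels.
#' @param seed RNG seed for the jitter draw.
#' @return an object of class `tremor_params`.
#' @export
tremor_params <- function(amplitude = 0, frequency = 0, jitter_sd = 0, seed = 0L) {
  if (amplitude < 0) stop("tremor_params: amplitude must be >= 0", call. = FALSE)
  if (frequency < 0) stop("tremor_params: frequency must be >= 0", call. = FALSE)
  if (jitter_sd < 0) stop("tremor_params: jitter_sd must be >= 0", call. = FALSE)
  structure(list(amplitude = amplitude, frequency = frequency,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "tremor_params")
}

#' Generate a template exam curve
#'
#' Spirals are Archimedean (`r = a + b*theta`) sampled densely over
#' `n_turns` full revolutions; meanders are square-wave paths sweeping the
#' canvas horizontally. Both are deterministic given `seed`, which perturbs
#' the start phase/scale slightly so exams differ across subjects.
#'
#' @param kind `"spiral"` or `"meander"`.
#' @param n_turns revolutions (spiral) or square-wave periods (meander), >= 1.
#' @param canvas_size square canvas side in pixels (>= 64).
#' @param seed RNG seed.
#' @return a `polyline_trace`: list with `points` (n x 2 matrix of x,y pixel
#'   coordinates) and `kind`; spirals carry the sampled `theta` attribute.
#' @export
generate_template <- function(kind, n_turns = 3L, canvas_size = 512L, seed = 0L) {
  if (!kind %in% c("spiral", "meander")) {
    stop("generate_template: kind must be 'spiral' or 'meander'", call. = FALSE)
  }
  if (n_turns < 1) stop("generate_template: n_turns must be >= 1", call. = FALSE)
  if (canvas_size < 64) stop("generate_template: canvas_size must be >= 64", call. = FALSE)
  cs <- canvas_size
  pts <- with_local_seed(seed, {
    if (kind == "spiral") {
      theta_max <- 2 * pi * n_turns
      n_pts <- max(256L, as.integer(200 * n_turns))
      theta <- seq(0, theta_max, length.out = n_pts)
      phase <- runif(1, 0, 2 * pi)
      scale <- runif(1, 0.92, 1)
      a <- 0.015 * cs
      b <- (0.44 * cs * scale - a) / theta_max
      r <- a + b * theta
      p <- cbind(cs / 2 + r * cos(theta + phase),
                 cs / 2 + r * sin(theta + phase))
      attr(p, "theta") <- theta
      p
    } else {
      margin <- cs * runif(1, 0.08, 0.12)
      amp <- cs / 2 - margin
      x0 <- margin; x1 <- cs - margin
      period <- (x1 - x0) / n_turns
      knots_x <- c(x0)
      knots_y <- c(cs / 2 - amp)
      for (k in seq_len(n_turns)) {
        xs <- x0 + (k - 1) * period
        knots_x <- c(knots_x, xs + period / 2, xs + period / 2, xs + period, xs + period)
        knots_y <- c(knots_y, cs / 2 - amp, cs / 2 + amp, cs / 2 + amp, cs / 2 - amp)
      }
      # densify the polyline at ~1.5 px spacing
      px <- numeric(0); py <- numeric(0)
      for (i in seq_len(length(knots_x) - 1L)) {
        seg <- max(2L, ceiling(sqrt((knots_x[i + 1] - knots_x[i])^2 +
                                    (knots_y[i + 1] - knots_y[i])^2) / 1.5))
        t <- seq(0, 1, length.out = seg)
        if (i > 1) t <- t[-1]
        px <- c(px, knots_x[i] + t * (knots_x[i + 1] - knots_x[i]))
        py <- c(py, knots_y[i] + t * (knots_y[i + 1] - knots_y[i]))
      }
      cbind(px, py)
    }
  })
  structure(list(points = unname(cbind(pts[, 1], pts[, 2])), kind = kind,
                 canvas_size = cs, theta = attr(pts, "theta")),
            class = "polyline_trace")
}

# Unit normals of a polyline via central-difference tangents.
polyline_normals <- function(p) {
  n <- nrow(p)
  tx <- c(p[2, 1] - p[1, 1], p[3:n, 1] - p[1:(n - 2), 1], p[n, 1] - p[n - 1, 1])
  ty <- c(p[2, 2] - p[1, 2], p[3:n, 2] - p[1:(n - 2), 2], p[n, 2] - p[n - 1, 2])
  len <- sqrt(tx^2 + ty^2)
  len[len == 0] <- 1
  cbind(-ty / len, tx / len)
}

#' Simulate a subject's overdrawn trace from a template
#'
#' Displaces each template point along the local normal by
#' `amplitude * sin(2*pi*frequency*s) + N(0, jitter_sd^2)`, where `s` is the
#' normalized arc length. Zero amplitude and jitter reproduce the template
#' exactly.
#'
#' @param template a `polyline_trace`.
#' @param tremor a `tremor_params`.
#' @return a `polyline_trace` with the same number of points.
#' @export
simulate_subject_trace <- function(template, tremor) {
  stopifnot(inherits(template, "polyline_trace"))
  if (!inherits(tremor, "tremor_params")) tremor <- do.call(tremor_params, tremor)
  p <- template$points
  n <- nrow(p)
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-n, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  s <- if (s[n] > 0) s / s[n] else seq(0, 1, length.out = n)
  disp <- tremor$amplitude * sin(2 * pi * tremor$frequency * s)
  if (tremor$jitter_sd > 0) {
    disp <- disp + with_local_seed(tremor$seed, rnorm(n, 0, tremor$jitter_sd))
  }
  nr <- polyline_normals(p)
  structure(list(points = p + disp * nr, kind = template$kind,
                 canvas_size = template$canvas_size, theta = template$theta),
            class = "polyline_trace")
}

# Stamp a polyline onto a logical canvas mask with a round pen of the given
# stroke width (no anti-aliasing).
rasterize_polyline_mask <- function(points, canvas_size, stroke_width = 3) {
  cs <- as.integer(canvas_size)
  n <- nrow(points)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] - points[-n, , drop = FALSE])^2))
  # resample at ~0.5 px spacing so the stroke is gap-free
  xs <- list(points[1, 1]); ys <- list(points[1, 2])
  for (i in seq_len(n - 1L)) {
    k <- max(1L, ceiling(seg[i] / 0.5))
    t <- seq_len(k) / k
    xs[[i + 1L]] <- points[i, 1] + t * (points[i + 1, 1] - points[i, 1])
    ys[[i + 1L]] <- points[i, 2] + t * (points[i + 1, 2] - points[i, 2])
  }
  x <- unlist(xs); y <- unlist(ys)
  r <- stroke_width / 2
  off <- expand.grid(dx = seq(-ceiling(r), ceiling(r)), dy = seq(-ceiling(r), ceiling(r)))
  off <- off[off$dx^2 + off$dy^2 <= r^2 + 0.26, , drop = FALSE]
  px <- rep(round(x), each = nrow(off)) + off$dx
  py <- rep(round(y), each = nrow(off)) + off$dy
  keep <- px >= 1 & px <= cs & py >= 1 & py <= cs
  mask <- matrix(FALSE, cs, cs)   # row = y, col = x
  mask[cbind(py[keep], px[keep])] <- TRUE
  mask
}

#' Rasterize an exam image from template and subject traces
#'
#' Draws the template in a near-grayscale color and the subject trace in a
#' saturated pen color on a white canvas; the subject trace is drawn last and
#' occludes the template. The pen color must survive grayscale suppression
#' (at least one inter-channel difference >= 45) and the template color must
#' not (all pairwise differences < 45).
#'
#' @param template,subject `polyline_trace` objects.
#' @param canvas_size square canvas side; defaults to the template's canvas.
#' @param template_color,pen_color RGB triplets in `[0, 255]`.
#' @param stroke_width pen width in pixels.
#' @return an `H x W x 3` integer-valued array in `[0, 255]`, with the logical
#'   subject-trace mask attached as attribute `"pen_mask"`.
#' @export
rasterize_exam <- function(template, subject, canvas_size = NULL,
                           template_color = c(128, 128, 128),
                           pen_color = c(0, 0, 255), stroke_width = 3) {
  if (is.null(canvas_size)) canvas_size <- template$canvas_size
  dif <- function(col) c(abs(col[1] - col[2]), abs(col[1] - col[3]), abs(col[2] - col[3]))
  if (any(dif(template_color) >= 45)) {
    stop("rasterize_exam: template_color must be near-grayscale ",
         "(all pairwise channel differences < 45)", call. = FALSE)
  }
  if (all(dif(pen_color) < 45)) {
    stop("rasterize_exam: pen_color would be destroyed by grayscale suppression; ",
         "need at least one pairwise channel difference >= 45", call. = FALSE)
  }
  cs <- as.integer(canvas_size)
  img <- array(255, c(cs, cs, 3L))
  tmask <- rasterize_polyline_mask(template$points, cs, stroke_width)
  pmask <- rasterize_polyline_mask(subject$points, cs, stroke_width)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[tmask] <- template_color[ch]
    plane[pmask] <- pen_color[ch]
    img[, , ch] <- plane
  }
  attr(img, "pen_mask") <- pmask
  img
}

#' Trace-template deviation features
#'
#' Computes the point-wise Euclidean deviations `d_i` between a subject trace
#' and its template and summarizes them as the root mean square (RMS), the
#' mean relative tremor (MRT, here the mean absolute first difference of the
#' deviations -- a stand-in definition capturing oscillation) and the standard
#' deviation of the deviations.
#'
#' @param template,subject `polyline_trace` objects with equal point counts.
#' @return list with `rms`, `mrt`, `std_diff`.
#' @export
compute_structured_features <- function(template, subject) {
  pt <- template$points
  ps <- subject$points
  if (nrow(pt) != nrow(ps)) {
    stop("compute_structured_features: traces have mismatched lengths (",
         nrow(pt), " vs ", nrow(ps), ")", call. = FALSE)
  }
  d <- sqrt(rowSums((ps - pt)^2))
  list(rms = sqrt(mean(d^2)),
       mrt = if (length(d) > 1) mean(abs(diff(d))) else 0,
       std_diff = if (length(d) > 1) sd(d) else 0)
}

#' Default tremor configuration for dataset generation
#'
#' Controls draw with jitter only; patients add the sinusoidal tremor.
#' @export
default_tremor_config <- function() {
  list(control = list(amplitude = 0, frequency = 0, jitter_sd = 1),
       pd = list(amplitude = 6, frequency = 24, jitter_sd = 1.5))
}

#' Generate a synthetic exam dataset on disk
#'
#' Writes a class-per-folder image tree (`Healthy/`, `Patient/`), a
#' `meta.csv` with columns `exam_id,image_name,patient_id,class_label,gender,
#' handedness,age,rms,mrt,std_diff`, and (optionally) the exact pen-trace
#' masks under `masks/`. Ages are drawn from class-conditional normals
#' (healthy 44.22 +/- 16.53, patients 58.75 +/- 7.51 years, truncated to
#' [18, 90]); controls draw with jitter only while patients add the
#' configured tremor. Deterministic per seed.
#'
#' @param n_control,n_pd numbers of subjects per class (>= 1).
#' @param draws_per_subject exam drawings per subject (alternating spiral /
#'   meander).
#' @param tremor_config list with `control` and `pd` tremor settings; see
#'   [default_tremor_config()].
#' @param seed master RNG seed.
#' @param out_dir output directory (created if missing).
#' @param canvas_size canvas side for rasterization.
#' @param keep_masks if `TRUE`, writes the subject-trace masks as PNGs.
#' @return the dataset manifest (invisibly), as from [read_exam_directory()].
#' @export
generate_dataset <- function(n_control, n_pd, draws_per_subject = 4L,
                             tremor_config = default_tremor_config(),
                             seed = 1L, out_dir,
                             canvas_size = 512L, keep_masks = FALSE) {
  if (n_control < 1 || n_pd < 1) {
    stop("generate_dataset: subject counts must be >= 1", call. = FALSE)
  }
  dir.create(file.path(out_dir, "Healthy"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "Patient"), recursive = TRUE, showWarnings = FALSE)
  if (keep_masks) dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("generate_dataset: cannot create ", out_dir, call. = FALSE)

  subjects <- data.frame(
    patient_id = c(sprintf("C%03d", seq_len(n_control)), sprintf("P%03d", seq_len(n_pd))),
    class_label = c(rep("H", n_control), rep("P", n_pd)),
    stringsAsFactors = FALSE
  )
  demo <- with_local_seed(derive_seed(seed, 1L), {
    age <- numeric(nrow(subjects))
    for (i in seq_len(nrow(subjects))) {
      mu <- if (subjects$class_label[i] == "H") 44.22 else 58.75
      sdv <- if (subjects$class_label[i] == "H") 16.53 else 7.51
      repeat {
        a <- rnorm(1, mu, sdv)
        if (a >= 18 && a <= 90) break
      }
      age[i] <- a
    }
    # gender ratios follow the source cohort: controls 6M/12F, patients 59M/15F
    p_male <- ifelse(subjects$class_label == "H", 6 / 18, 59 / 74)
    gender <- ifelse(runif(nrow(subjects)) < p_male, "M", "F")
    handedness <- ifelse(runif(nrow(subjects)) < 0.9, "R", "L")
    data.frame(age = round(age, 1), gender = gender, handedness = handedness,
               stringsAsFactors = FALSE)
  })

  rows <- vector("list", nrow(subjects) * draws_per_subject)
  exam_id <- 0L
  for (i in seq_len(nrow(subjects))) {
    cls <- subjects$class_label[i]
    tc <- if (cls == "H") tremor_config$control else tremor_config$pd
    for (d in seq_len(draws_per_subject)) {
      exam_id <- exam_id + 1L
      kind <- if (d %% 2L == 1L) "spiral" else "meander"
      sd_tmpl <- derive_seed(seed, exam_id * 2L)
      sd_trem <- derive_seed(seed, exam_id * 2L + 1L)
      tmpl <- generate_template(kind, n_turns = if (kind == "spiral") 3L else 4L,
                                canvas_size = canvas_size, seed = sd_tmpl)
      trem <- tremor_params(amplitude = tc$amplitude, frequency = tc$frequency,
                            jitter_sd = tc$jitter_sd, seed = sd_trem)
      subj <- simulate_subject_trace(tmpl, trem)
      img <- rasterize_exam(tmpl, subj)
      feats <- compute_structured_features(tmpl, subj)
      folder <- if (cls == "H") "Healthy" else "Patient"
      image_name <- sprintf("%s_%s_%d.png", subjects$patient_id[i], kind, d)
      write_exam_image(img, file.path(out_dir, folder, image_name))
      if (keep_masks) {
        png::writePNG(attr(img, "pen_mask") * 1,
                      file.path(out_dir, "masks", image_name))
      }
      rows[[exam_id]] <- data.frame(
        exam_id = exam_id, image_name = image_name,
        patient_id = subjects$patient_id[i], class_label = cls,
        gender = demo$gender[i], handedness = demo$handedness[i],
        age = demo$age[i],
        rms = round(feats$rms, 6), mrt = round(feats$mrt, 6),
        std_diff = round(feats$std_diff, 6), stringsAsFactors = FALSE
      )
    }
  }
  meta <- do.call(rbind, rows)
  write.csv(meta, file.path(out_dir, "meta.csv"), row.names = FALSE, quote = FALSE)
  invisible(read_exam_directory(out_dir))
}
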