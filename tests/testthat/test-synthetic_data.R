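# Synthetic exam generator: templates, tremor model, rasterization, features.

test_that("spiral templates are dense Archimedean curves with the full angular extent", {
  tr <- generate_template("spiral", n_turns = 3, canvas_size = 512, seed = 0)
  expect_s3_class(tr, "polyline_trace")
  expect_gte(nrow(tr$points), 2)
  # radius from canvas center is non-decreasing in theta
  r <- sqrt(rowSums(sweep(tr$points, 2, c(256, 256))^2))
  expect_true(all(diff(r) >= -1e-9))
  # angular extent equals 2*pi*n_turns
  expect_equal(max(tr$theta) - min(tr$theta), 6 * pi, tolerance = 1e-9)
  # points within canvas bounds
  expect_true(all(tr$points >= 0 & tr$points <= 512))
})

test_that("template generation is deterministic per seed and rejects bad input", {
  a <- generate_template("meander", 2, 512, seed = 0)
  b <- generate_template("meander", 2, 512, seed = 0)
  expect_identical(a$points, b$points)
  d <- generate_template("meander", 2, 512, seed = 1)
  expect_false(identical(a$points, d$points))
  expect_error(generate_template("circle", 2, 512), "spiral")
  expect_error(generate_template("spiral", 0), "n_turns")
  expect_error(generate_template("spiral", 2, canvas_size = 32), "canvas_size")
})

test_that("zero tremor reproduces the template exactly; parameters validated", {
  tmpl <- generate_template("spiral", 3, 256, seed = 5)
  subj <- simulate_subject_trace(tmpl, tremor_params(0, 0, 0))
  expect_identical(subj$points, tmpl$points)
  expect_error(tremor_params(-1, 0, 0), "amplitude")
  expect_error(tremor_params(0, 0, -0.5), "jitter_sd")
})

test_that("sinusoidal tremor displaces along the normal with the stated amplitude", {
  tmpl <- generate_template("spiral", 3, 512, seed = 2)
  subj <- simulate_subject_trace(tmpl, tremor_params(5, 4, 0))
  expect_equal(nrow(subj$points), nrow(tmpl$points))
  disp <- sqrt(rowSums((subj$points - tmpl$points)^2))
  expect_equal(max(disp), 5, tolerance = 1e-3)
  # determinism under a fixed seed (jitter included)
  s1 <- simulate_subject_trace(tmpl, tremor_params(3, 8, 1, seed = 9))
  s2 <- simulate_subject_trace(tmpl, tremor_params(3, 8, 1, seed = 9))
  expect_identical(s1$points, s2$points)
})

test_that("rasterized exams separate template and pen under the grayscale predicate", {
  tmpl <- generate_template("spiral", 2, 128, seed = 1)
  subj <- simulate_subject_trace(tmpl, tremor_params(3, 6, 0.5, seed = 1))
  img <- rasterize_exam(tmpl, subj, template_color = c(80, 80, 80),
                        pen_color = c(0, 0, 255))
  grayish <- function(px) all(abs(c(px[1] - px[2], px[1] - px[3], px[2] - px[3])) < 45)
  pmask <- attr(img, "pen_mask")
  # every pen pixel fails the grayscale predicate; non-pen pixels satisfy it
  idx_pen <- which(pmask, arr.ind = TRUE)
  for (k in seq_len(min(50, nrow(idx_pen)))) {
    expect_false(grayish(img[idx_pen[k, 1], idx_pen[k, 2], ]))
  }
  idx_bg <- which(!pmask, arr.ind = TRUE)
  for (k in seq_len(50)) {
    expect_true(grayish(img[idx_bg[k, 1], idx_bg[k, 2], ]))
  }
  # untouched canvas is pure white
  expect_equal(unname(img[1, 1, ]), c(255, 255, 255))
  # invalid colors rejected
  expect_error(rasterize_exam(tmpl, subj, pen_color = c(100, 110, 120)), "pen_color")
  expect_error(rasterize_exam(tmpl, subj, template_color = c(0, 0, 255)),
               "template_color")
})

test_that("structured features match their closed forms", {
  tmpl <- generate_template("spiral", 2, 256, seed = 3)
  f0 <- compute_structured_features(tmpl, tmpl)
  expect_equal(unlist(f0), c(rms = 0, mrt = 0, std_diff = 0))
  # constant deviation c: rms = c, mrt = 0, std_diff = 0
  shifted <- tmpl
  nr <- qspiral:::polyline_normals(tmpl$points)
  shifted$points <- tmpl$points + 2.5 * nr
  fc <- compute_structured_features(tmpl, shifted)
  expect_equal(fc$rms, 2.5, tolerance = 1e-9)
  expect_equal(fc$mrt, 0, tolerance = 1e-9)
  expect_equal(fc$std_diff, 0, tolerance = 1e-9)
  # d = [3, 4] -> rms = sqrt(12.5)
  t2 <- structure(list(points = cbind(c(0, 10), c(0, 0)), kind = "spiral",
                       canvas_size = 64, theta = NULL), class = "polyline_trace")
  s2 <- structure(list(points = cbind(c(0, 10), c(3, 4)), kind = "spiral",
                       canvas_size = 64, theta = NULL), class = "polyline_trace")
  expect_equal(compute_structured_features(t2, s2)$rms, sqrt(12.5), tolerance = 1e-12)
  # mismatched lengths rejected
  s3 <- s2; s3$points <- s3$points[1, , drop = FALSE]
  expect_error(compute_structured_features(t2, s3), "mismatched")
})

test_that("generate_dataset writes the expected layout with class signal", {
  dir <- tempfile("gen")
  man <- generate_dataset(4, 4, 4, seed = 1, out_dir = dir, canvas_size = 128)
  expect_equal(nrow(man), 32)
  expect_length(list.files(file.path(dir, "Healthy")), 16)
  expect_length(list.files(file.path(dir, "Patient")), 16)
  meta <- read.csv(file.path(dir, "meta.csv"))
  expect_setequal(names(meta), c("exam_id", "image_name", "patient_id",
                                 "class_label", "gender", "handedness", "age",
                                 "rms", "mrt", "std_diff"))
  expect_equal(nrow(meta), 32)
  # PD group mean RMS exceeds control mean at default tremor amplitude
  expect_gt(mean(meta$rms[meta$class_label == "P"]),
            mean(meta$rms[meta$class_label == "H"]))
  # regeneration with the same seed is byte-identical
  dir2 <- tempfile("gen")
  generate_dataset(4, 4, 4, seed = 1, out_dir = dir2, canvas_size = 128)
  expect_identical(readLines(file.path(dir, "meta.csv")),
                   readLines(file.path(dir2, "meta.csv")))
  unlink(c(dir, dir2), recursive = TRUE)
})

test_that("group RMS separation is monotone in tremor amplitude", {
  tmpl <- generate_template("spiral", 3, 256, seed = 7)
  rms_at <- vapply(c(0, 2, 4, 8), function(a) {
    subj <- simulate_subject_trace(tmpl, tremor_params(a, 12, 0.5, seed = 11))
    compute_structured_features(tmpl, subj)$rms
  }, numeric(1))
  expect_true(all(diff(rms_at) > 0))
})

test_that("the pen trace survives grayscale suppression on generated exams", {
  dir <- small_exam_dir(2, 2, 2, seed = 3, canvas = 128)
  man <- read_exam_directory(dir)
  for (i in seq_len(nrow(man))) {
    img <- qspiral:::read_exam_image(man$image_path[i])
    sup <- suppress_grayscale(img)
    nonwhite <- sum(sup[, , 1] < 255 | sup[, , 2] < 255 | sup[, , 3] < 255)
    expect_gte(nonwhite, 1)
  }
  unlink(dir, recursive = TRUE)
})
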