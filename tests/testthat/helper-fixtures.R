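# Shared tiny fixtures, built in code.

tiny_model_cfg <- function(image_circuit_depth = 1L, tabular_circuit_depth = 2L,
                           ...) {
  model_config(input_side = 32L, stem_channels = 4L,
               stage_channels = c(4L, 8L), stage_strides = c(1L, 2L),
               stage_variants = c("ca_se", "triplet"),
               se_reduction = 2L, ca_reduction = 2L,
               embedding_dim = 256L, head_hidden = 8L,
               image_qubits = 8L, image_circuit_depth = image_circuit_depth,
               tabular_circuit_depth = tabular_circuit_depth, ...)
}

random_records <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    exam_id = seq_len(n),
    image_name = sprintf("img%03d.png", seq_len(n)),
    patient_id = sprintf("S%03d", rep(seq_len(ceiling(n / 4)), each = 4)[seq_len(n)]),
    class_label = rep(c("H", "P"), length.out = n),
    gender = sample(c("M", "F"), n, replace = TRUE),
    handedness = sample(c("R", "L"), n, replace = TRUE),
    age = runif(n, 20, 80),
    rms = runif(n, 0, 10), mrt = runif(n, 0, 3), std_diff = runif(n, 0, 5),
    stringsAsFactors = FALSE
  )
}

# Fast synthetic exam dataset generated at a small canvas.
small_exam_dir <- function(n_control = 3, n_pd = 3, draws = 2, seed = 1,
                           canvas = 128, keep_masks = FALSE) {
  dir <- tempfile("examdir")
  generate_dataset(n_control, n_pd, draws, seed = seed, out_dir = dir,
                   canvas_size = canvas, keep_masks = keep_masks)
  dir
}
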