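# Assembly of the dual-track model: TVSFE image track (stem + CDAB stages +
# embedding head + amplitude-embedded circuit), VQFMN tabular track
# (RY-encoded strongly entangling circuit) and the fusion classifier.

#' Model configuration
#'
#' Defaults give the full-size model: 512x512 inputs, four CDAB stages of
#' widths 64/128/256/512 (first two with coordinate attention +
#' squeeze-and-excite, last two with triplet attention), a 256-dimensional
#' embedding feeding an 8-qubit amplitude-embedded circuit, and a 6-feature
#' RY circuit for the tabular track. The classical ablations are config
#' switches, not separate code paths: `quantum = FALSE` replaces both
#' circuits by dense layers of the same output width, and
#' `use_image` / `use_tabular` select single-track variants.
#'
#' @param input_side preprocessed image side in pixels.
#' @param stem_channels output channels of the 7x7 stem convolution.
#' @param stage_channels,stage_strides,stage_variants per-stage CDAB plan.
#' @param blocks_per_stage CDAB blocks per stage.
#' @param ghost_ratio,se_reduction,ca_reduction block hyperparameters.
#' @param embedding_dim image embedding width; must equal `2^image_qubits`.
#' @param head_hidden hidden width of the embedding head.
#' @param image_qubits,image_circuit_depth image-track circuit size.
#' @param n_features,tabular_circuit_depth tabular-track circuit size.
#' @param fusion_hidden widths of the two fusion dense layers.
#' @param leaky_slope LeakyReLU slope in the embedding head.
#' @param use_image,use_tabular,quantum ablation switches.
#' @return a `model_config` list.
#' @export
model_config <- function(input_side = 512L, stem_channels = 64L,
                         stage_channels = c(64L, 128L, 256L, 512L),
                         stage_strides = c(1L, 2L, 2L, 2L),
                         stage_variants = c("ca_se", "ca_se", "triplet", "triplet"),
                         blocks_per_stage = 1L,
                         ghost_ratio = 2L, se_reduction = 8L, ca_reduction = 8L,
                         embedding_dim = 256L, head_hidden = 256L,
                         image_qubits = 8L, image_circuit_depth = 2L,
                         n_features = 6L, tabular_circuit_depth = 4L,
                         fusion_hidden = c(64L, 32L), leaky_slope = 0.01,
                         use_image = TRUE, use_tabular = TRUE, quantum = TRUE) {
  stopifnot(length(stage_channels) == length(stage_strides),
            length(stage_channels) == length(stage_variants))
  if (use_image && 2^image_qubits != embedding_dim) {
    stop("model_config: embedding_dim must equal 2^image_qubits ",
         "(amplitude embedding feasibility)", call. = FALSE)
  }
  if (!use_image && !use_tabular) {
    stop("model_config: at least one track must be enabled", call. = FALSE)
  }
  cfg <- list(input_side = as.integer(input_side),
              stem_channels = as.integer(stem_channels),
              stage_channels = as.integer(stage_channels),
              stage_strides = as.integer(stage_strides),
              stage_variants = stage_variants,
              blocks_per_stage = as.integer(blocks_per_stage),
              ghost_ratio = as.integer(ghost_ratio),
              se_reduction = as.integer(se_reduction),
              ca_reduction = as.integer(ca_reduction),
              embedding_dim = as.integer(embedding_dim),
              head_hidden = as.integer(head_hidden),
              image_qubits = as.integer(image_qubits),
              image_circuit_depth = as.integer(image_circuit_depth),
              n_features = as.integer(n_features),
              tabular_circuit_depth = as.integer(tabular_circuit_depth),
              fusion_hidden = as.integer(fusion_hidden),
              leaky_slope = leaky_slope,
              use_image = use_image, use_tabular = use_tabular, quantum = quantum)
  class(cfg) <- "model_config"
  cfg
}

#' Reduced model configuration for desk-scale experiments
#'
#' 128x128 inputs, a 16-channel stem and two CDAB stages (16 then 32
#' channels). The quantum interface is unchanged (256-dim embedding,
#' 8 qubits).
#'
#' @param input_side preprocessed image side (default 128).
#' @param ... overrides passed on to [model_config()].
#' @export
reduced_model_config <- function(input_side = 128L, ...) {
  model_config(input_side = as.integer(input_side), stem_channels = 16L,
               stage_channels = c(16L, 32L), stage_strides = c(1L, 2L),
               stage_variants = c("ca_se", "triplet"),
               se_reduction = 4L, ca_reduction = 4L,
               head_hidden = 64L, ...)
}

#' Build a model from a configuration
#'
#' @param config a [model_config()].
#' @param seed seed for parameter initialization.
#' @return a model environment holding the flat parameter list, batch-norm
#'   state and configuration.
#' @export
build_model <- function(config, seed = 0L) {
  stopifnot(inherits(config, "model_config"))
  model <- new_model_env(config, seed)
  with_local_seed(seed, {
    if (config$use_image) {
      reg_conv(model, "tvsfe.stem", 7L, 7L, 3L, config$stem_channels)
      reg_bn(model, "tvsfe.stem.bn", config$stem_channels)
      cin <- config$stem_channels
      for (s in seq_along(config$stage_channels)) {
        for (b in seq_len(config$blocks_per_stage)) {
          cfg <- block_config(cin, config$stage_channels[s],
                              stride = if (b == 1L) config$stage_strides[s] else 1L,
                              attention_variant = config$stage_variants[s],
                              ghost_ratio = config$ghost_ratio,
                              se_reduction = config$se_reduction,
                              ca_reduction = config$ca_reduction)
          reg_cdab(model, sprintf("tvsfe.s%d.b%d", s, b), cfg)
          model$config[[sprintf("blockcfg.s%d.b%d", s, b)]] <- cfg
          cin <- config$stage_channels[s]
        }
      }
      reg_linear(model, "tvsfe.head1", cin, config$head_hidden)
      reg_linear(model, "tvsfe.head2", config$head_hidden, config$embedding_dim)
      reg_ln(model, "tvsfe.ln", config$embedding_dim)
      if (config$quantum) {
        qp <- circuit_params(config$image_qubits, config$image_circuit_depth,
                             seed = derive_seed(seed, 11L))
        reg_param(model, "tvsfe.qtheta", qp$angles)
        model$config$image_circuit <- qp
      } else {
        reg_linear(model, "tvsfe.classical_q", config$embedding_dim,
                   config$image_qubits)
      }
    }
    if (config$use_tabular) {
      if (config$quantum) {
        qp <- circuit_params(config$n_features, config$tabular_circuit_depth,
                             seed = derive_seed(seed, 12L))
        reg_param(model, "vqfmn.qtheta", qp$angles)
        model$config$tabular_circuit <- qp
      } else {
        reg_linear(model, "vqfmn.mlp1", config$n_features, config$n_features)
        reg_linear(model, "vqfmn.mlp2", config$n_features, config$n_features)
      }
    }
    din <- (if (config$use_image) config$image_qubits else 0L) +
           (if (config$use_tabular) config$n_features else 0L)
    if (config$use_image) reg_ln(model, "fusion.ln_img", config$image_qubits)
    if (config$use_tabular) reg_ln(model, "fusion.ln_tab", config$n_features)
    reg_linear(model, "fusion.fc1", din, config$fusion_hidden[1])
    reg_linear(model, "fusion.fc2", config$fusion_hidden[1], config$fusion_hidden[2])
    reg_linear(model, "fusion.out", config$fusion_hidden[2], 2L)
  })
  model
}

# ---- internal forward passes -------------------------------------------------

# ximg: (H, W, 3, N) node. Returns the 8-value readout plus intermediates.
fw_tvsfe <- function(ctx, ximg) {
  cfg <- ctx$model$config
  x <- fw_conv(ctx, ximg, "tvsfe.stem", stride = 2L, pad = 3L)
  x <- ad_relu(fw_bn(ctx, x, "tvsfe.stem.bn"))
  x <- ad_maxpool(x, k = 3L, stride = 2L, pad = 1L)
  stages <- list()
  for (s in seq_along(cfg$stage_channels)) {
    for (b in seq_len(cfg$blocks_per_stage)) {
      x <- fw_cdab(ctx, x, sprintf("tvsfe.s%d.b%d", s, b),
                   cfg[[sprintf("blockcfg.s%d.b%d", s, b)]])
    }
    stages[[s]] <- x
  }
  g <- ad_gap(x)                                     # (C, N)
  h <- ad_leaky_relu(fw_linear(ctx, g, "tvsfe.head1"), cfg$leaky_slope)
  emb <- fw_linear(ctx, h, "tvsfe.head2")
  emb <- ad_layernorm(emb, P(ctx, "tvsfe.ln.g"), P(ctx, "tvsfe.ln.b"))
  emb <- ad_l2norm(emb)
  z <- if (cfg$quantum) {
    ad_quantum_amplitude(emb, P(ctx, "tvsfe.qtheta"), cfg$image_circuit)
  } else {
    ad_tanh(fw_linear(ctx, emb, "tvsfe.classical_q"))
  }
  list(z = z, embedding = emb, stages = stages)
}

# xtab: (d, N) node of normalized features in [0, pi].
fw_vqfmn <- function(ctx, xtab) {
  cfg <- ctx$model$config
  if (cfg$quantum) {
    ad_quantum_ry(xtab, P(ctx, "vqfmn.qtheta"), cfg$tabular_circuit)
  } else {
    h <- ad_relu(fw_linear(ctx, xtab, "vqfmn.mlp1"))
    fw_linear(ctx, h, "vqfmn.mlp2")
  }
}

fw_fusion <- function(ctx, z_img, z_tab) {
  cfg <- ctx$model$config
  parts <- list()
  if (!is.null(z_img)) {
    parts <- c(parts, list(ad_layernorm(z_img, P(ctx, "fusion.ln_img.g"),
                                        P(ctx, "fusion.ln_img.b"))))
  }
  if (!is.null(z_tab)) {
    parts <- c(parts, list(ad_layernorm(z_tab, P(ctx, "fusion.ln_tab.g"),
                                        P(ctx, "fusion.ln_tab.b"))))
  }
  x <- if (length(parts) == 1L) parts[[1]] else {
    a <- ad_val(parts[[1]]); b <- ad_val(parts[[2]])
    n1 <- nrow(a)
    ad_node(parts[[1]]$tape, rbind(a, b),
            c(parts[[1]]$id, parts[[2]]$id), function(g) {
              list(g[seq_len(n1), , drop = FALSE],
                   g[-seq_len(n1), , drop = FALSE])
            })
  }
  x <- ad_relu(fw_linear(ctx, x, "fusion.fc1"))
  x <- ad_relu(fw_linear(ctx, x, "fusion.fc2"))
  fw_linear(ctx, x, "fusion.out")
}

# Full forward. ximg: (H,W,3,N) array or NULL; xtab: (d,N) matrix or NULL.
fw_model <- function(ctx, ximg, xtab) {
  cfg <- ctx$model$config
  tv <- NULL; z_img <- NULL; z_tab <- NULL
  if (cfg$use_image) {
    tv <- fw_tvsfe(ctx, ad_leaf(ctx$tape, ximg))
    z_img <- tv$z
  }
  if (cfg$use_tabular) {
    z_tab <- fw_vqfmn(ctx, ad_leaf(ctx$tape, xtab))
  }
  logits <- fw_fusion(ctx, z_img, z_tab)
  list(logits = logits, probs = ad_softmax(logits), tvsfe = tv, z_tab = z_tab)
}

# Coerce user-supplied images to an (H, W, 3, N) batch.
as_image_batch <- function(images, side) {
  if (is.list(images)) {
    arr <- array(0, c(side, side, 3L, length(images)))
    for (i in seq_along(images)) arr[, , , i] <- images[[i]]
    return(arr)
  }
  d <- dim(images)
  if (length(d) == 3L) dim(images) <- c(d, 1L)
  d <- dim(images)
  if (d[1] != side || d[2] != side) {
    stop("input images must be ", side, "x", side, " (got ", d[1], "x", d[2],
         "); run resize_and_scale() first", call. = FALSE)
  }
  images
}

# ---- exported forward operations --------------------------------------------

#' Image-track forward pass
#'
#' Stem convolution, CDAB stages, global average pooling, the LeakyReLU
#' embedding head with layer + L2 normalization, then the amplitude-embedded
#' entangling circuit with Pauli-Z readout.
#'
#' @param model a built model with `use_image = TRUE`.
#' @param images a preprocessed `side x side x 3` array in `[0,1]`, a
#'   4-d batch, or a list of such arrays.
#' @return matrix (`n x image_qubits`) of Pauli-Z expectations in `[-1, 1]`,
#'   with the unit-norm embeddings attached as attribute `"embedding"`
#'   (`n x embedding_dim`).
#' @export
tvsfe_forward <- function(model, images) {
  stopifnot(model$config$use_image)
  x <- as_image_batch(images, model$config$input_side)
  ctx <- fw_ctx(model, training = FALSE)
  tv <- fw_tvsfe(ctx, ad_leaf(ctx$tape, x))
  out <- t(ad_val(tv$z))
  attr(out, "embedding") <- t(ad_val(tv$embedding))
  out
}

#' Tabular-track forward pass
#'
#' RY angle embedding of normalized features followed by strongly entangling
#' layers and Pauli-Z readout (or the classical MLP under the no-quantum
#' ablation).
#'
#' @param model a built model with `use_tabular = TRUE`.
#' @param features numeric matrix (`n x n_features`) with values in `[0, pi]`.
#' @return matrix (`n x n_features`) of per-qubit expectations.
#' @export
vqfmn_forward <- function(model, features) {
  stopifnot(model$config$use_tabular)
  features <- rbind(features)
  if (model$config$quantum && any(features < 0 | features > pi)) {
    stop("vqfmn_forward: features must lie in [0, pi]; normalize first", call. = FALSE)
  }
  ctx <- fw_ctx(model, training = FALSE)
  t(ad_val(fw_vqfmn(ctx, ad_leaf(ctx$tape, t(features)))))
}

#' Fuse track outputs and classify
#'
#' Layer-normalizes each track's readout, concatenates, applies the dense
#' fusion layers and a two-class softmax.
#'
#' @param model a built model.
#' @param img_out matrix `n x image_qubits` (or NULL if the image track is
#'   disabled).
#' @param tab_out matrix `n x n_features` (or NULL).
#' @return matrix `n x 2` of class probabilities (healthy, PD).
#' @export
fuse_and_classify <- function(model, img_out = NULL, tab_out = NULL) {
  ctx <- fw_ctx(model, training = FALSE)
  zi <- if (!is.null(img_out)) ad_leaf(ctx$tape, t(rbind(img_out)))
  zt <- if (!is.null(tab_out)) ad_leaf(ctx$tape, t(rbind(tab_out)))
  t(ad_val(ad_softmax(fw_fusion(ctx, zi, zt))))
}

#' Full model forward pass
#'
#' @param model a built model.
#' @param images preprocessed image batch (ignored if the image track is off).
#' @param features normalized feature matrix (ignored if the tabular track is
#'   off).
#' @return matrix `n x 2` of class probabilities (healthy, PD).
#' @export
model_forward <- function(model, images = NULL, features = NULL) {
  cfg <- model$config
  ximg <- if (cfg$use_image) as_image_batch(images, cfg$input_side)
  xtab <- if (cfg$use_tabular) {
    f <- rbind(features)
    if (cfg$quantum && any(f < 0 | f > pi)) {
      stop("model_forward: features must lie in [0, pi]; normalize first",
           call. = FALSE)
    }
    t(f)
  }
  ctx <- fw_ctx(model, training = FALSE)
  t(ad_val(fw_model(ctx, ximg, xtab)$probs))
}

#' Count trainable parameters
#'
#' @param model a built model.
#' @return list with per-track and total trainable scalar parameter counts.
#' @export
count_parameters <- function(model) {
  n_of <- function(prefix) {
    sel <- startsWith(names(model$params), prefix)
    sum(vapply(model$params[sel], length, integer(1)))
  }
  out <- list(tvsfe = n_of("tvsfe."), vqfmn = n_of("vqfmn."),
              fusion = n_of("fusion."))
  out$total <- out$tvsfe + out$vqfmn + out$fusion
  out
}
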