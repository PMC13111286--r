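# Network building blocks: ghost convolution, coordinate attention,
# squeeze-and-excite, triplet attention and their composition into CDAB
# (cross-dimensional attention bottleneck) blocks.
#
# Parameters live in a flat named list on the model environment; the builders
# below register initialized arrays under hierarchical names and the fw_*
# interpreters fetch them as tape leaves during a forward pass.

new_model_env <- function(config, seed = 0L) {
  m <- new.env(parent = emptyenv())
  m$config <- config
  m$params <- list()
  m$state <- list()
  m$seed <- as.integer(seed)
  m
}

reg_param <- function(model, name, value) {
  model$params[[name]] <- value
  invisible(name)
}

init_conv_w <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))), c(kh, kw, cin, cout))
}

init_dw_w <- function(kh, kw, c) {
  array(rnorm(kh * kw * c, 0, sqrt(2 / (kh * kw))), c(kh, kw, c))
}

init_linear_w <- function(dout, din) {
  matrix(rnorm(dout * din, 0, sqrt(2 / din)), dout, din)
}

reg_conv <- function(model, name, kh, kw, cin, cout, bias = TRUE) {
  reg_param(model, paste0(name, ".w"), init_conv_w(kh, kw, cin, cout))
  if (bias) reg_param(model, paste0(name, ".b"), numeric(cout))
}

reg_bn <- function(model, name, c) {
  reg_param(model, paste0(name, ".g"), rep(1, c))
  reg_param(model, paste0(name, ".b"), numeric(c))
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(c)
  st$running_var <- rep(1, c)
  model$state[[name]] <- st
}

reg_linear <- function(model, name, din, dout, bias = TRUE) {
  reg_param(model, paste0(name, ".w"), init_linear_w(dout, din))
  if (bias) reg_param(model, paste0(name, ".b"), numeric(dout))
}

reg_ln <- function(model, name, d) {
  reg_param(model, paste0(name, ".g"), rep(1, d))
  reg_param(model, paste0(name, ".b"), numeric(d))
}

# Forward-pass context: tape + cached parameter leaves.
fw_ctx <- function(model, training = FALSE) {
  list(tape = ad_tape(), model = model, training = training,
       pn = new.env(parent = emptyenv()))
}

P <- function(ctx, name) {
  nd <- ctx$pn[[name]]
  if (is.null(nd)) {
    v <- ctx$model$params[[name]]
    if (is.null(v)) stop("unknown parameter: ", name, call. = FALSE)
    nd <- ad_leaf(ctx$tape, v)
    ctx$pn[[name]] <- nd
  }
  nd
}

fw_conv <- function(ctx, x, name, stride = 1L, pad = 0L) {
  b <- if (!is.null(ctx$model$params[[paste0(name, ".b")]])) P(ctx, paste0(name, ".b"))
  ad_conv2d(x, P(ctx, paste0(name, ".w")), b, stride = stride, pad = pad)
}

fw_bn <- function(ctx, x, name) {
  ad_batchnorm(x, P(ctx, paste0(name, ".g")), P(ctx, paste0(name, ".b")),
               ctx$model$state[[name]], ctx$training)
}

fw_linear <- function(ctx, x, name) {
  b <- if (!is.null(ctx$model$params[[paste0(name, ".b")]])) P(ctx, paste0(name, ".b"))
  ad_linear(x, P(ctx, paste0(name, ".w")), b)
}

# ---- ghost module ------------------------------------------------------------

reg_ghost <- function(model, name, cin, cout, ratio = 2L, kernel = 3L) {
  if (cout %% ratio != 0L) {
    stop("ghost module: out_channels (", cout, ") must be divisible by ratio (",
         ratio, ")", call. = FALSE)
  }
  m <- cout %/% ratio
  reg_conv(model, paste0(name, ".primary"), kernel, kernel, cin, m)
  for (j in seq_len(ratio - 1L)) {
    reg_param(model, paste0(name, ".cheap", j, ".w"), init_dw_w(kernel, kernel, m))
    reg_param(model, paste0(name, ".cheap", j, ".b"), numeric(m))
  }
  invisible(list(m = m, ratio = ratio, kernel = kernel))
}

fw_ghost <- function(ctx, x, name, ratio = 2L, kernel = 3L, stride = 1L) {
  pad <- (kernel - 1L) %/% 2L
  primary <- fw_conv(ctx, x, paste0(name, ".primary"), stride = stride, pad = pad)
  cheap <- lapply(seq_len(ratio - 1L), function(j) {
    ad_dwconv2d(primary, P(ctx, paste0(name, ".cheap", j, ".w")),
                P(ctx, paste0(name, ".cheap", j, ".b")), stride = 1L, pad = pad)
  })
  ad_concat(c(list(primary), cheap), axis = 3L)
}

# ---- squeeze-and-excite ------------------------------------------------------

reg_se <- function(model, name, c, reduction = 8L) {
  if (reduction >= c) {
    stop("squeeze_excite: reduction (", reduction, ") must be < channels (", c, ")",
         call. = FALSE)
  }
  reg_linear(model, paste0(name, ".fc1"), c, max(1L, c %/% reduction))
  reg_linear(model, paste0(name, ".fc2"), max(1L, c %/% reduction), c)
}

fw_se <- function(ctx, x, name, saturate = FALSE) {
  if (saturate) return(x)
  d <- dim(ad_val(x))
  g <- ad_gap(x)
  g <- ad_relu(fw_linear(ctx, g, paste0(name, ".fc1")))
  g <- ad_sigmoid(fw_linear(ctx, g, paste0(name, ".fc2")))
  gate <- ad_reshape(g, c(1L, 1L, d[3], d[4]))
  ad_bmul(x, gate)
}

# ---- coordinate attention ----------------------------------------------------

reg_ca <- function(model, name, c, reduction = 8L) {
  if (reduction >= c) {
    stop("coordinate_attention: reduction (", reduction, ") must be < channels (",
         c, ")", call. = FALSE)
  }
  cr <- max(1L, c %/% reduction)
  reg_conv(model, paste0(name, ".shared"), 1L, 1L, c, cr)
  reg_conv(model, paste0(name, ".gate_h"), 1L, 1L, cr, c)
  reg_conv(model, paste0(name, ".gate_w"), 1L, 1L, cr, c)
}

fw_ca <- function(ctx, x, name, saturate = FALSE) {
  if (saturate) return(x)
  d <- dim(ad_val(x))
  H <- d[1]; W <- d[2]
  zh <- ad_mean_axis(x, 2L)                      # (H,1,C,N)
  zw <- ad_aperm(ad_mean_axis(x, 1L), c(2L, 1L, 3L, 4L))  # (W,1,C,N)
  y <- ad_concat(list(zh, zw), axis = 1L)        # (H+W,1,C,N)
  y <- ad_relu(fw_conv(ctx, y, paste0(name, ".shared")))
  yh <- ad_slice(y, 1L, seq_len(H))
  yw <- ad_aperm(ad_slice(y, 1L, H + seq_len(W)), c(2L, 1L, 3L, 4L))
  gh <- ad_sigmoid(fw_conv(ctx, yh, paste0(name, ".gate_h")))  # (H,1,C,N)
  gw <- ad_sigmoid(fw_conv(ctx, yw, paste0(name, ".gate_w")))  # (1,W,C,N)
  ad_bmul(ad_bmul(x, gh), gw)
}

# ---- triplet attention -------------------------------------------------------

reg_triplet <- function(model, name, kernel = 7L) {
  for (br in c("hw", "ch", "cw")) {
    reg_conv(model, paste0(name, ".", br), kernel, kernel, 2L, 1L)
  }
  invisible(kernel)
}

# One branch: Z-pool over the (rotated) channel axis, 7x7 conv, sigmoid gate.
fw_triplet_branch <- function(ctx, xp, name, kernel) {
  pad <- (kernel - 1L) %/% 2L
  zp <- ad_zpool(xp)
  gate <- ad_sigmoid(fw_conv(ctx, zp, name, pad = pad))
  ad_bmul(xp, gate)
}

fw_triplet <- function(ctx, x, name, kernel = 7L, saturate = FALSE) {
  if (saturate) return(x)
  b1 <- fw_triplet_branch(ctx, x, paste0(name, ".hw"), kernel)
  xp2 <- ad_aperm(x, c(3L, 2L, 1L, 4L))
  b2 <- ad_aperm(fw_triplet_branch(ctx, xp2, paste0(name, ".ch"), kernel),
                 c(3L, 2L, 1L, 4L))
  xp3 <- ad_aperm(x, c(1L, 3L, 2L, 4L))
  b3 <- ad_aperm(fw_triplet_branch(ctx, xp3, paste0(name, ".cw"), kernel),
                 c(1L, 3L, 2L, 4L))
  ad_scale(ad_add(ad_add(b1, b2), b3), 1 / 3)
}

# ---- CDAB block --------------------------------------------------------------

#' Configuration of one CDAB block
#'
#' @param in_channels,out_channels channel counts; `out_channels` must be
#'   divisible by `ghost_ratio`.
#' @param stride 1 or 2.
#' @param attention_variant `"ca_se"` (coordinate attention then
#'   squeeze-and-excite) or `"triplet"`.
#' @param ghost_ratio ghost-module expansion ratio (>= 2).
#' @param se_reduction,ca_reduction bottleneck reductions for the gates.
#' @return a validated `block_config` list.
#' @export
block_config <- function(in_channels, out_channels, stride = 1L,
                         attention_variant = c("ca_se", "triplet"),
                         ghost_ratio = 2L, se_reduction = 8L, ca_reduction = 8L) {
  attention_variant <- match.arg(attention_variant)
  if (!stride %in% c(1L, 2L)) stop("block_config: stride must be 1 or 2", call. = FALSE)
  if (ghost_ratio < 2L) stop("block_config: ghost_ratio must be >= 2", call. = FALSE)
  if (out_channels %% ghost_ratio != 0L) {
    stop("block_config: out_channels must be divisible by ghost_ratio", call. = FALSE)
  }
  list(in_channels = as.integer(in_channels), out_channels = as.integer(out_channels),
       stride = as.integer(stride), attention_variant = attention_variant,
       ghost_ratio = as.integer(ghost_ratio), se_reduction = as.integer(se_reduction),
       ca_reduction = as.integer(ca_reduction))
}

reg_cdab <- function(model, name, cfg) {
  reg_ghost(model, paste0(name, ".ghost"), cfg$in_channels, cfg$out_channels,
            cfg$ghost_ratio)
  if (cfg$attention_variant == "ca_se") {
    reg_ca(model, paste0(name, ".ca"), cfg$out_channels, cfg$ca_reduction)
    reg_se(model, paste0(name, ".se"), cfg$out_channels, cfg$se_reduction)
  } else {
    reg_triplet(model, paste0(name, ".ta"))
  }
  reg_bn(model, paste0(name, ".bn_main"), cfg$out_channels)
  reg_bn(model, paste0(name, ".bn_out"), cfg$out_channels)
  if (cfg$stride != 1L || cfg$in_channels != cfg$out_channels) {
    reg_conv(model, paste0(name, ".proj"), 1L, 1L, cfg$in_channels,
             cfg$out_channels, bias = FALSE)
  }
}

fw_cdab <- function(ctx, x, name, cfg) {
  main <- fw_ghost(ctx, x, paste0(name, ".ghost"), cfg$ghost_ratio,
                   stride = cfg$stride)
  main <- if (cfg$attention_variant == "ca_se") {
    fw_se(ctx, fw_ca(ctx, main, paste0(name, ".ca")), paste0(name, ".se"))
  } else {
    fw_triplet(ctx, main, paste0(name, ".ta"))
  }
  main <- fw_bn(ctx, main, paste0(name, ".bn_main"))
  res <- if (cfg$stride != 1L || cfg$in_channels != cfg$out_channels) {
    fw_conv(ctx, x, paste0(name, ".proj"), stride = cfg$stride, pad = 0L)
  } else {
    x
  }
  ad_relu(fw_bn(ctx, ad_add(main, res), paste0(name, ".bn_out")))
}

# ---- exported functional wrappers -------------------------------------------
#
# These run a single H x W x C feature map through a freshly initialized
# (seeded) block in evaluation mode; trained use goes through the assembled
# model instead. Returned arrays carry the parameter list as attribute
# "params" so layer sizes can be inspected.

as_map4 <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L) stop("expected an H x W x C feature map", call. = FALSE)
  x
}

run_functional <- function(x, reg_fn, fw_fn, seed = 0L) {
  x4 <- as_map4(x)
  model <- new_model_env(list(), seed)
  with_local_seed(seed, reg_fn(model))
  ctx <- fw_ctx(model, training = FALSE)
  out <- fw_fn(ctx, ad_leaf(ctx$tape, x4))
  res <- ad_val(out)
  if (dim(res)[4] == 1L) dim(res) <- dim(res)[1:3]
  attr(res, "params") <- model$params
  res
}

#' Ghost module (functional form)
#'
#' Generates `out_channels / ratio` feature maps with a standard convolution
#' and the remaining maps with cheap depthwise convolutions on those primary
#' outputs, concatenated along the channel axis. Uses strictly fewer
#' parameters than a dense 3x3 convolution of the same width.
#'
#' @param x `H x W x C` feature map.
#' @param out_channels output channels, divisible by `ratio`.
#' @param ratio ghost ratio (>= 2).
#' @param stride convolution stride.
#' @param seed seed for the (random) parameter initialization.
#' @return `H x W x out_channels` array with attribute `"params"`.
#' @export
ghost_module <- function(x, out_channels, ratio = 2L, stride = 1L, seed = 0L) {
  cin <- dim(as_map4(x))[3]
  if (out_channels %% ratio != 0L) {
    stop("ghost_module: out_channels must be divisible by ratio", call. = FALSE)
  }
  run_functional(x,
    function(m) reg_ghost(m, "g", cin, as.integer(out_channels), as.integer(ratio)),
    function(ctx, xn) fw_ghost(ctx, xn, "g", as.integer(ratio), stride = stride),
    seed)
}

#' Coordinate attention (functional form)
#'
#' Pools the input separately along height and width, passes the joint
#' descriptor through a shared reduced 1x1 convolution, and gates the input
#' with per-axis sigmoid attention maps. Shape-preserving.
#'
#' @param x `H x W x C` feature map.
#' @param reduction channel reduction of the shared bottleneck (< C).
#' @param saturate_gates test hook: force both gates to exactly 1.
#' @param seed parameter initialization seed.
#' @return gated feature map with attribute `"params"`.
#' @export
coordinate_attention <- function(x, reduction = 8L, saturate_gates = FALSE, seed = 0L) {
  c <- dim(as_map4(x))[3]
  run_functional(x,
    function(m) reg_ca(m, "ca", c, as.integer(reduction)),
    function(ctx, xn) fw_ca(ctx, xn, "ca", saturate = saturate_gates),
    seed)
}

#' Squeeze-and-excite attention (functional form)
#'
#' Global average pooling followed by a two-layer bottleneck producing one
#' sigmoid gate per channel.
#'
#' @inheritParams coordinate_attention
#' @return gated feature map with attribute `"params"`.
#' @export
squeeze_excite <- function(x, reduction = 8L, saturate_gates = FALSE, seed = 0L) {
  c <- dim(as_map4(x))[3]
  run_functional(x,
    function(m) reg_se(m, "se", c, as.integer(reduction)),
    function(ctx, xn) fw_se(ctx, xn, "se", saturate = saturate_gates),
    seed)
}

#' Triplet attention (functional form)
#'
#' Three branches capture height-width, channel-width and channel-height
#' interactions: each rotates the tensor, Z-pools (stacked max and mean) over
#' the branch's channel axis, applies a 7x7 convolution and sigmoid gate,
#' rotates back; the output is the mean of the branches.
#'
#' @param x `H x W x C` feature map.
#' @param seed parameter initialization seed.
#' @return gated feature map with attribute `"params"`.
#' @export
triplet_attention <- function(x, seed = 0L) {
  run_functional(x,
    function(m) reg_triplet(m, "ta"),
    function(ctx, xn) fw_triplet(ctx, xn, "ta"),
    seed)
}

#' CDAB block (functional form)
#'
#' Ghost module, attention (coordinate + squeeze-and-excite, or triplet),
#' batch normalization, plus a residual path (identity, or a strided 1x1
#' projection when shapes change); the two paths are summed, normalized and
#' passed through a ReLU.
#'
#' @param x `H x W x C` feature map with `C == config$in_channels`.
#' @param config a [block_config()].
#' @param seed parameter initialization seed.
#' @return output feature map with attribute `"params"`.
#' @export
cdab_block <- function(x, config, seed = 0L) {
  cin <- dim(as_map4(x))[3]
  if (cin != config$in_channels) {
    stop("cdab_block: input has ", cin, " channels but config expects ",
         config$in_channels, call. = FALSE)
  }
  run_functional(x,
    function(m) reg_cdab(m, "blk", config),
    function(ctx, xn) fw_cdab(ctx, xn, "blk", config),
    seed)
}
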