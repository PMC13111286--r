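# Attention blocks: shape contracts, gate ranges, parameter economy,
# symmetries, and gradient flow through a CDAB residual.

map3 <- function(h, w, c, seed = 1, sd = 1) {
  set.seed(seed)
  array(rnorm(h * w * c, 0, sd), c(h, w, c))
}

test_that("ghost module meets its shape contract with fewer parameters than dense conv", {
  x <- map3(16, 16, 6)
  out <- ghost_module(x, out_channels = 8, ratio = 2)
  expect_equal(dim(out), c(16L, 16L, 8L))
  for (cfg in list(c(6, 8, 2), c(8, 16, 2), c(12, 12, 4), c(16, 32, 2))) {
    xg <- map3(8, 8, cfg[1])
    og <- ghost_module(xg, cfg[2], cfg[3])
    n_ghost <- sum(lengths(attr(og, "params")))
    n_dense <- 3 * 3 * cfg[1] * cfg[2] + cfg[2]
    expect_lt(n_ghost, n_dense)
  }
  # zero input -> output equals the bias pattern (linearity)
  z <- ghost_module(array(0, c(8, 8, 4)), 8, 2, seed = 3)
  expect_true(all(abs(sweep(z, 3, apply(z, 3, mean))) < 1e-12))
  expect_error(ghost_module(x, out_channels = 7, ratio = 2), "divisible")
})

test_that("ghost module stride halves the spatial size", {
  out <- ghost_module(map3(16, 16, 4), 8, 2, stride = 2L)
  expect_equal(dim(out), c(8L, 8L, 8L))
})

test_that("squeeze-and-excite preserves shape with gates in (0,1) and GAP invariance", {
  x <- map3(10, 12, 8)
  out <- squeeze_excite(x, reduction = 4)
  expect_equal(dim(out), dim(x))
  gate <- out / x
  gate <- gate[is.finite(gate)]
  expect_true(all(gate > 0 & gate < 1))
  # spatial permutation leaves the gates unchanged (GAP invariance)
  perm <- sample(10)
  xp <- x[perm, , ]
  outp <- squeeze_excite(xp, reduction = 4)
  expect_equal(unclass(outp) / xp, (unclass(out) / x)[perm, , ],
               tolerance = 1e-12, ignore_attr = TRUE)
  # saturated gates are the identity
  expect_equal(squeeze_excite(x, 4, saturate_gates = TRUE), x, ignore_attr = TRUE)
  expect_error(squeeze_excite(x, reduction = 8), "reduction")
})

test_that("coordinate attention preserves shape and respects pooled symmetry", {
  x <- map3(7, 9, 8)
  out <- coordinate_attention(x, reduction = 4)
  expect_equal(dim(out), dim(x))
  expect_equal(coordinate_attention(x, 4, saturate_gates = TRUE), x,
               ignore_attr = TRUE)
  # spatially constant input -> gates constant along their pooled axis
  xc <- array(rep(rnorm(8), each = 7 * 9), c(7, 9, 8))
  outc <- coordinate_attention(xc, reduction = 4, seed = 2)
  gate <- outc / xc
  for (ch in 1:8) {
    expect_lt(max(gate[, , ch]) - min(gate[, , ch]), 1e-12)
  }
  expect_error(coordinate_attention(x, reduction = 8), "reduction")
})

test_that("triplet attention preserves shape; Z-pool is exact for constants", {
  x <- map3(6, 8, 5)
  out <- triplet_attention(x)
  expect_equal(dim(out), dim(x))
  # Z-pool of a constant map: max and mean channels both equal the constant
  xc <- array(2.5, c(4, 4, 3, 1))
  tape <- qspiral:::ad_tape()
  zp <- qspiral:::ad_val(qspiral:::ad_zpool(qspiral:::ad_leaf(tape, xc)))
  expect_equal(dim(zp), c(4L, 4L, 2L, 1L))
  expect_true(all(zp == 2.5))
  # gates strictly inside (0, 1): single-branch output magnitude < input
  xpos <- abs(map3(6, 8, 5)) + 0.1
  outp <- triplet_attention(xpos, seed = 4)
  expect_true(all(outp > 0 & outp < xpos))
})

test_that("CDAB blocks satisfy shape contracts and keep outputs finite", {
  x <- map3(12, 12, 8)
  cfg1 <- block_config(8, 8, stride = 1, attention_variant = "ca_se",
                       se_reduction = 4, ca_reduction = 4)
  out1 <- cdab_block(x, cfg1)
  expect_equal(dim(out1), c(12L, 12L, 8L))
  cfg2 <- block_config(8, 16, stride = 2, attention_variant = "triplet")
  out2 <- cdab_block(x, cfg2)
  expect_equal(dim(out2), c(6L, 6L, 16L))
  # normalization stability over varied input scales
  for (sc in c(1e-3, 1, 50)) {
    o <- cdab_block(map3(8, 8, 8, seed = 5, sd = sc), cfg1, seed = 6)
    expect_true(all(is.finite(o)))
  }
  expect_error(cdab_block(map3(8, 8, 4), cfg1), "channels")
  expect_error(block_config(4, 9, ghost_ratio = 2), "divisible")
  expect_error(block_config(4, 8, stride = 3), "stride")
})

test_that("gradient reaches the input through the CDAB residual path", {
  ns <- asNamespace("qspiral")
  cfg <- block_config(4, 4, stride = 1, attention_variant = "ca_se",
                      se_reduction = 2, ca_reduction = 2)
  model <- ns$new_model_env(list(), 0L)
  set.seed(8)
  ns$reg_cdab(model, "blk", cfg)
  x0 <- array(rnorm(6 * 6 * 4), c(6, 6, 4, 1))
  loss_of <- function(xa) {
    ctx <- ns$fw_ctx(model, training = FALSE)
    out <- ns$fw_cdab(ctx, ns$ad_leaf(ctx$tape, xa), "blk", cfg)
    list(ctx = ctx, node = out, value = sum(ns$ad_val(out)^2))
  }
  r <- loss_of(x0)
  v <- ns$ad_val(r$node)
  loss <- ns$ad_node(r$ctx$tape, sum(v^2), r$node$id, function(g) list(2 * v * g))
  grads <- ns$ad_backward(loss)
  gx <- grads[[2L]]  # input leaf is the second node (after first param fetch order)
  # locate input node id robustly
  gx <- grads[[which(vapply(seq_len(r$ctx$tape$n), function(i)
    identical(r$ctx$tape$nodes[[i]]$value, x0), logical(1)))[1]]]
  expect_gt(sqrt(sum(gx^2)), 0)
  # finite-difference spot check through the whole block
  i <- 17L
  eps <- 1e-5
  xp <- x0; xp[i] <- xp[i] + eps
  xm <- x0; xm[i] <- xm[i] - eps
  fd <- (loss_of(xp)$value - loss_of(xm)$value) / (2 * eps)
  expect_equal(gx[i], fd, tolerance = 1e-4)
})
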