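# Reverse-mode automatic differentiation on a linear tape.
#
# Every network forward pass appends nodes to a tape; each node stores its
# value, the ids of its parents and a closure mapping the upstream gradient to
# per-parent gradients. Because the graph is built strictly forward, a single
# reverse sweep over node ids is a valid topological order. Feature maps are
# H x W x C x N arrays, vector activations are d x N matrices.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 64L)
  t$n <- 0L
  t
}

ad_node <- function(tape, value, parents = integer(0), back = NULL) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- list(value = value, parents = as.integer(parents), back = back)
  tape$n <- n
  structure(list(tape = tape, id = n), class = "adnode")
}

ad_leaf <- function(tape, value) ad_node(tape, value)

ad_val <- function(x) {
  if (inherits(x, "adnode")) x$tape$nodes[[x$id]]$value else x
}

#' @noRd
ad_backward <- function(root, seed = NULL) {
  tape <- root$tape
  grads <- vector("list", tape$n)
  rv <- tape$nodes[[root$id]]$value
  if (is.null(seed)) {
    seed <- if (is.null(dim(rv))) rep(1, length(rv)) else array(1, dim(rv))
  }
  grads[[root$id]] <- seed
  for (i in seq(root$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- tape$nodes[[i]]
    if (is.null(nd$back) || !length(nd$parents)) next
    pg <- nd$back(g)
    for (j in seq_along(nd$parents)) {
      gj <- pg[[j]]
      if (is.null(gj)) next
      p <- nd$parents[[j]]
      grads[[p]] <- if (is.null(grads[[p]])) gj else grads[[p]] + gj
    }
  }
  grads
}

ad_grad_of <- function(grads, node) grads[[node$id]]

# ---- broadcasting helpers ----------------------------------------------------

# Expand `a` (with some unit dims) to the full dim `d` by index replication.
bc_expand <- function(a, d) {
  da <- dim(a)
  if (identical(da, d)) return(a)
  idx <- lapply(seq_along(d), function(ax) {
    if (da[ax] == 1L && d[ax] > 1L) rep(1L, d[ax]) else seq_len(d[ax])
  })
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

# Sum `g` (full dim) down to target dims `dt` (with unit dims where broadcast).
bc_reduce <- function(g, dt) {
  dg <- dim(g)
  for (ax in seq_along(dt)) {
    if (dt[ax] == 1L && dg[ax] > 1L) {
      perm <- c(ax, setdiff(seq_along(dg), ax))
      gp <- aperm(g, perm)
      dim(gp) <- c(dg[ax], prod(dg[-ax]))
      s <- colSums(gp)
      newd <- dg
      newd[ax] <- 1L
      dim(s) <- newd[perm][-1L]
      g <- aperm(array(s, dim = c(1L, newd[perm][-1L])), order(perm))
      dg <- newd
    }
  }
  g
}

# Mean over one axis of a 4-d array, keeping the axis as a unit dim.
mean_over_axis <- function(v, ax) {
  d <- dim(v)
  perm <- c(ax, setdiff(seq_along(d), ax))
  vp <- aperm(v, perm)
  dim(vp) <- c(d[ax], prod(d[-ax]))
  m <- colMeans(vp)
  newd <- d
  newd[ax] <- 1L
  aperm(array(m, dim = c(1L, d[perm][-1L])), order(perm))
}

# ---- elementwise -------------------------------------------------------------

ad_relu <- function(x) {
  v <- ad_val(x)
  mask <- v > 0
  ad_node(x$tape, v * mask, x$id, function(g) list(g * mask))
}

ad_leaky_relu <- function(x, slope = 0.01) {
  v <- ad_val(x)
  mask <- v > 0
  out <- ifelse(mask, v, slope * v)
  ad_node(x$tape, out, x$id, function(g) list(g * ifelse(mask, 1, slope)))
}

ad_sigmoid <- function(x) {
  v <- ad_val(x)
  s <- 1 / (1 + exp(-v))
  ad_node(x$tape, s, x$id, function(g) list(g * s * (1 - s)))
}

ad_tanh <- function(x) {
  v <- tanh(ad_val(x))
  ad_node(x$tape, v, x$id, function(g) list(g * (1 - v^2)))
}

ad_add <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_node(a$tape, av + bv, c(a$id, b$id), function(g) list(g, g))
}

# x (full shape) * gate (same rank, unit dims where broadcast)
ad_bmul <- function(x, gate) {
  xv <- ad_val(x); gv <- ad_val(gate)
  dx <- dim(xv); dgt <- dim(gv)
  ge <- bc_expand(gv, dx)
  ad_node(x$tape, xv * ge, c(x$id, gate$id), function(g) {
    list(g * ge, bc_reduce(g * xv, dgt))
  })
}

ad_scale <- function(x, s) {
  v <- ad_val(x)
  ad_node(x$tape, v * s, x$id, function(g) list(g * s))
}

# ---- shape ops ---------------------------------------------------------------

ad_aperm <- function(x, perm) {
  v <- ad_val(x)
  inv <- order(perm)
  ad_node(x$tape, aperm(v, perm), x$id, function(g) list(aperm(g, inv)))
}

ad_reshape <- function(x, d) {
  v <- ad_val(x)
  od <- dim(v)
  nv <- v
  dim(nv) <- d
  ad_node(x$tape, nv, x$id, function(g) { dim(g) <- od; list(g) })
}

# Concatenate 4-d arrays along `axis`.
ad_concat <- function(xs, axis) {
  vs <- lapply(xs, ad_val)
  d0 <- dim(vs[[1]])
  sizes <- vapply(vs, function(v) dim(v)[axis], integer(1))
  dout <- d0
  dout[axis] <- sum(sizes)
  out <- array(0, dout)
  starts <- cumsum(c(0L, sizes))
  idx_all <- lapply(dout, seq_len)
  for (i in seq_along(vs)) {
    idx <- idx_all
    idx[[axis]] <- (starts[i] + 1L):starts[i + 1L]
    out <- do.call(`[<-`, c(list(out), idx, list(value = vs[[i]])))
  }
  ad_node(xs[[1]]$tape, out, vapply(xs, function(x) x$id, integer(1)), function(g) {
    lapply(seq_along(vs), function(i) {
      idx <- idx_all
      idx[[axis]] <- (starts[i] + 1L):starts[i + 1L]
      do.call(`[`, c(list(g), idx, list(drop = FALSE)))
    })
  })
}

ad_slice <- function(x, axis, range) {
  v <- ad_val(x)
  d <- dim(v)
  idx <- lapply(d, seq_len)
  idx[[axis]] <- range
  out <- do.call(`[`, c(list(v), idx, list(drop = FALSE)))
  ad_node(x$tape, out, x$id, function(g) {
    dz <- array(0, d)
    list(do.call(`[<-`, c(list(dz), idx, list(value = g))))
  })
}

# ---- convolutions ------------------------------------------------------------

ad_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  v <- ad_val(x); wv <- ad_val(w)
  d <- dim(v)                                  # H W C N
  kd <- dim(wv)                                # kh kw cin cout
  stopifnot(kd[3] == d[3])
  cols <- im2col_cpp(v, d[1], d[2], d[3], d[4], kd[1], kd[2], stride, pad)
  wm <- matrix(wv, nrow = kd[1] * kd[2] * kd[3])
  om <- cols %*% wm
  oh <- (d[1] + 2L * pad - kd[1]) %/% stride + 1L
  ow <- (d[2] + 2L * pad - kd[2]) %/% stride + 1L
  if (!is.null(b)) om <- om + rep(ad_val(b), each = nrow(om))
  out <- aperm(array(om, c(oh, ow, d[4], kd[4])), c(1L, 2L, 4L, 3L))
  parents <- c(x$id, w$id, if (!is.null(b)) b$id)
  ad_node(x$tape, out, parents, function(g) {
    gm <- matrix(aperm(g, c(1L, 2L, 4L, 3L)), nrow = oh * ow * d[4])
    dw <- crossprod(cols, gm)
    dim(dw) <- kd
    dxv <- col2im_cpp(gm %*% t(wm), d[1], d[2], d[3], d[4], kd[1], kd[2], stride, pad)
    dim(dxv) <- d
    c(list(dxv, dw), if (!is.null(b)) list(colSums(gm)))
  })
}

# Depthwise convolution: one kh x kw filter per channel (weights kh x kw x C).
ad_dwconv2d <- function(x, w, b = NULL, stride = 1L, pad = 1L) {
  v <- ad_val(x); wv <- ad_val(w)
  d <- dim(v)
  kd <- dim(wv)
  stopifnot(kd[3] == d[3])
  K <- kd[1] * kd[2]
  cols <- im2col_cpp(v, d[1], d[2], d[3], d[4], kd[1], kd[2], stride, pad)
  R <- nrow(cols)
  dim(cols) <- c(R, K, d[3])
  wm <- matrix(wv, nrow = K)
  om <- matrix(0, R, d[3])
  for (k in seq_len(K)) om <- om + cols[, k, ] * rep(wm[k, ], each = R)
  if (!is.null(b)) om <- om + rep(ad_val(b), each = R)
  oh <- (d[1] + 2L * pad - kd[1]) %/% stride + 1L
  ow <- (d[2] + 2L * pad - kd[2]) %/% stride + 1L
  out <- aperm(array(om, c(oh, ow, d[4], d[3])), c(1L, 2L, 4L, 3L))
  parents <- c(x$id, w$id, if (!is.null(b)) b$id)
  ad_node(x$tape, out, parents, function(g) {
    gm <- matrix(aperm(g, c(1L, 2L, 4L, 3L)), nrow = R)
    dw <- matrix(0, K, d[3])
    dcols <- array(0, c(R, K, d[3]))
    for (k in seq_len(K)) {
      dw[k, ] <- colSums(cols[, k, ] * gm)
      dcols[, k, ] <- gm * rep(wm[k, ], each = R)
    }
    dim(dcols) <- c(R, K * d[3])
    dxv <- col2im_cpp(dcols, d[1], d[2], d[3], d[4], kd[1], kd[2], stride, pad)
    dim(dxv) <- d
    dim(dw) <- kd
    c(list(dxv, dw), if (!is.null(b)) list(colSums(gm)))
  })
}

ad_maxpool <- function(x, k = 3L, stride = 2L, pad = 1L) {
  v <- ad_val(x)
  d <- dim(v)
  mp <- maxpool_cpp(v, d[1], d[2], d[3], d[4], k, stride, pad)
  ad_node(x$tape, mp$out, x$id, function(g) {
    dx <- maxpool_bw_cpp(as.numeric(g), mp$argmax, length(v))
    dim(dx) <- d
    list(dx)
  })
}

# ---- pooling / reductions ----------------------------------------------------

ad_mean_axis <- function(x, ax) {
  v <- ad_val(x)
  d <- dim(v)
  out <- mean_over_axis(v, ax)
  ad_node(x$tape, out, x$id, function(g) list(bc_expand(g, d) / d[ax]))
}

# Global average pooling: (H,W,C,N) -> (C,N)
ad_gap <- function(x) {
  v <- ad_val(x)
  d <- dim(v)
  m <- v
  dim(m) <- c(d[1] * d[2], d[3] * d[4])
  out <- matrix(colMeans(m), d[3], d[4])
  ad_node(x$tape, out, x$id, function(g) {
    gg <- rep(as.numeric(g) / (d[1] * d[2]), each = d[1] * d[2])
    dim(gg) <- d
    list(gg)
  })
}

# Z-pool over the channel axis: (H,W,C,N) -> (H,W,2,N) stacking max and mean.
ad_zpool <- function(x) {
  v <- ad_val(x)
  d <- dim(v)
  m <- aperm(v, c(1L, 2L, 4L, 3L))
  dim(m) <- c(d[1] * d[2] * d[4], d[3])
  amax <- max.col(m, ties.method = "first")
  rows <- seq_len(nrow(m))
  mx <- m[cbind(rows, amax)]
  mn <- rowMeans(m)
  out <- array(0, c(d[1], d[2], 2L, d[4]))
  out[, , 1L, ] <- array(mx, c(d[1], d[2], d[4]))
  out[, , 2L, ] <- array(mn, c(d[1], d[2], d[4]))
  ad_node(x$tape, out, x$id, function(g) {
    g1 <- as.numeric(g[, , 1L, , drop = FALSE])
    g2 <- as.numeric(g[, , 2L, , drop = FALSE])
    dm <- matrix(g2 / d[3], nrow(m), d[3])
    dm[cbind(rows, amax)] <- dm[cbind(rows, amax)] + g1
    dim(dm) <- c(d[1], d[2], d[4], d[3])
    list(aperm(dm, c(1L, 2L, 4L, 3L)))
  })
}

# ---- dense / normalization ---------------------------------------------------

# x: (din, N); W: (dout, din); b: dout
ad_linear <- function(x, w, b = NULL) {
  xv <- ad_val(x); wv <- ad_val(w)
  out <- wv %*% xv
  if (!is.null(b)) out <- out + ad_val(b)
  parents <- c(x$id, w$id, if (!is.null(b)) b$id)
  ad_node(x$tape, out, parents, function(g) {
    c(list(crossprod(wv, g), tcrossprod(g, xv)),
      if (!is.null(b)) list(rowSums(g)))
  })
}

# Layer normalization across the feature dim of a (d, N) matrix.
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- ad_val(x)
  d <- nrow(xv)
  mu <- colMeans(xv)
  xc <- sweep(xv, 2, mu)
  va <- colMeans(xc^2)
  sdv <- sqrt(va + eps)
  xhat <- sweep(xc, 2, sdv, "/")
  gv <- ad_val(gamma)
  out <- xhat * gv + ad_val(beta)
  ad_node(x$tape, out, c(x$id, gamma$id, beta$id), function(g) {
    dxhat <- g * gv
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dx <- sweep(sweep(dxhat, 2, m1) - sweep(xhat, 2, m2, "*"), 2, sdv, "/")
    list(dx, rowSums(g * xhat), rowSums(g))
  })
}

# L2 normalization of each column of a (d, N) matrix.
ad_l2norm <- function(x, eps = 1e-12) {
  xv <- ad_val(x)
  nrm <- sqrt(colSums(xv^2)) + eps
  out <- sweep(xv, 2, nrm, "/")
  ad_node(x$tape, out, x$id, function(g) {
    dots <- colSums(out * g)
    list(sweep(g - sweep(out, 2, dots, "*"), 2, nrm, "/"))
  })
}

# Batch normalization over (H,W,N) per channel. `st` is an environment holding
# running_mean / running_var, updated in training mode.
ad_batchnorm <- function(x, gamma, beta, st, training, momentum = 0.1, eps = 1e-5) {
  xv <- ad_val(x)
  d <- dim(xv)
  C <- d[3]
  m <- aperm(xv, c(1L, 2L, 4L, 3L))
  dim(m) <- c(d[1] * d[2] * d[4], C)
  nel <- nrow(m)
  if (training && nel > 1L) {
    mu <- colMeans(m)
    va <- colMeans(m^2) - mu^2
    va <- pmax(va, 0)
    st$running_mean <- (1 - momentum) * st$running_mean + momentum * mu
    st$running_var <- (1 - momentum) * st$running_var + momentum * va
  } else {
    mu <- st$running_mean
    va <- st$running_var
  }
  sdv <- sqrt(va + eps)
  xhat <- sweep(sweep(m, 2, mu), 2, sdv, "/")
  gv <- ad_val(gamma)
  om <- sweep(xhat, 2, gv, "*")
  om <- sweep(om, 2, ad_val(beta), "+")
  dim(om) <- c(d[1], d[2], d[4], C)
  out <- aperm(om, c(1L, 2L, 4L, 3L))
  batch_stats <- training && nel > 1L
  ad_node(x$tape, out, c(x$id, gamma$id, beta$id), function(g) {
    gm <- aperm(g, c(1L, 2L, 4L, 3L))
    dim(gm) <- c(nel, C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    if (batch_stats) {
      t1 <- sweep(gm, 2, dbeta / nel)
      t2 <- sweep(xhat, 2, dgamma / nel, "*")
      dm <- sweep(t1 - t2, 2, gv / sdv, "*")
    } else {
      dm <- sweep(gm, 2, gv / sdv, "*")
    }
    dim(dm) <- c(d[1], d[2], d[4], C)
    list(aperm(dm, c(1L, 2L, 4L, 3L)), dgamma, dbeta)
  })
}

# ---- classifier heads --------------------------------------------------------

# Column-wise softmax of a (k, N) logit matrix.
ad_softmax <- function(x) {
  xv <- ad_val(x)
  mx <- apply(xv, 2, max)
  e <- exp(sweep(xv, 2, mx))
  p <- sweep(e, 2, colSums(e), "/")
  ad_node(x$tape, p, x$id, function(g) {
    list(p * sweep(g, 2, colSums(g * p)))
  })
}

# Focal loss on class probabilities. labels are 0-based class indices.
ad_focal <- function(p, labels, gamma = 3, alpha = 1, eps = 1e-8) {
  pv <- ad_val(p)
  N <- ncol(pv)
  sel <- cbind(as.integer(labels) + 1L, seq_len(N))
  pt <- pmax(pv[sel], eps)
  av <- if (length(alpha) > 1L) alpha[as.integer(labels) + 1L] else rep(alpha, N)
  loss <- mean(-av * (1 - pt)^gamma * log(pt))
  ad_node(p$tape, loss, p$id, function(g) {
    dpt <- av * (gamma * (1 - pt)^pmax(gamma - 1, 0) * log(pt) - (1 - pt)^gamma / pt) / N
    dp <- matrix(0, nrow(pv), N)
    dp[sel] <- dpt
    list(dp * as.numeric(g))
  })
}

# Pick one scalar entry of a (k, N) matrix (class score for Grad-CAM).
ad_pick <- function(x, row, col = 1L) {
  xv <- ad_val(x)
  ad_node(x$tape, xv[row, col], x$id, function(g) {
    dz <- matrix(0, nrow(xv), ncol(xv))
    dz[row, col] <- as.numeric(g)
    list(dz)
  })
}
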