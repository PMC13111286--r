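# Independent dense-matrix quantum oracle: builds explicit 2^n x 2^n gate
# matrices with Kronecker products and multiplies them out. Used only to
# cross-check the statevector simulator; shares no code with it.

oracle_embed_1q <- function(u, n, q) {
  # qubit 0 = most significant bit of the basis index
  left <- diag(2^q)
  right <- diag(2^(n - 1 - q))
  kronecker(kronecker(left, u), right)
}

oracle_ry <- function(th) {
  matrix(c(cos(th / 2), sin(th / 2), -sin(th / 2), cos(th / 2)), 2, 2)
}

oracle_rz <- function(th) {
  diag(exp(complex(imaginary = c(-th / 2, th / 2))))
}

oracle_cnot <- function(n, ctrl, tgt) {
  dim <- 2^n
  m <- matrix(0, dim, dim)
  for (i in 0:(dim - 1)) {
    cbit <- bitwAnd(i, bitwShiftL(1L, n - 1L - ctrl)) > 0
    j <- if (cbit) bitwXor(i, bitwShiftL(1L, n - 1L - tgt)) else i
    m[j + 1, i + 1] <- 1
  }
  m
}

# Full unitary of the strongly entangling block for given circuit_params.
oracle_sel_unitary <- function(params) {
  n <- params$n_qubits
  u <- diag(2^n) + 0i
  for (l in seq_len(params$depth)) {
    for (q in 0:(n - 1)) {
      u <- oracle_embed_1q(oracle_rz(params$angles[l, q + 1, 1]), n, q) %*% u
      u <- oracle_embed_1q(oracle_ry(params$angles[l, q + 1, 2]), n, q) %*% u
      u <- oracle_embed_1q(oracle_rz(params$angles[l, q + 1, 3]), n, q) %*% u
    }
    r <- params$ranges[l]
    if (n > 1 && r > 0) {
      for (q in 0:(n - 1)) {
        u <- oracle_cnot(n, q, (q + r) %% n) %*% u
      }
    }
  }
  u
}

oracle_z_expect <- function(amps, n) {
  vapply(0:(n - 1), function(q) {
    z <- oracle_embed_1q(diag(c(1, -1)), n, q)
    Re(sum(Conj(amps) * (z %*% amps)))
  }, numeric(1))
}

# Central finite differences of a scalar function of a numeric vector.
fd_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}
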