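# Exact statevector simulation of the two variational circuits.
#
# Convention: qubit 0 is the most significant bit of the computational-basis
# index, so for n qubits the basis state |q0 q1 ... q_{n-1}> has index
# sum_q q_bit * 2^(n-1-q). States are complex vectors of length 2^n.
# Rotations are RY(theta) = exp(-i theta Y / 2), RZ(theta) = exp(-i theta Z/2).
# Gradients use adjoint-mode differentiation: for a gate U = exp(-i theta P/2)
# the parameter gradient of L = sum_q g_q <Z_q> is Im(<b_k| P |psi_k>), where
# psi_k is the state after gate k and b_k the back-propagated costate.

.qs_cache <- new.env(parent = emptyenv())

# +-1 sign of Z on qubit q for every basis index: 2^n x n matrix.
z_signs <- function(n_qubits) {
  key <- as.character(n_qubits)
  if (!is.null(.qs_cache[[key]])) return(.qs_cache[[key]])
  idx <- 0:(2^n_qubits - 1)
  s <- vapply(0:(n_qubits - 1), function(q) {
    1 - 2 * (bitwAnd(idx, bitwShiftL(1L, n_qubits - 1L - q)) > 0L)
  }, numeric(2^n_qubits))
  s <- matrix(s, ncol = n_qubits)
  .qs_cache[[key]] <- s
  s
}

#' Construct a quantum state
#'
#' @param amplitudes complex vector of length `2^n_qubits`; must be normalized
#'   to unit 2-norm within `1e-9`.
#' @param n_qubits number of qubits.
#' @return an object of class `quantum_state`.
#' @export
quantum_state <- function(amplitudes, n_qubits) {
  if (length(amplitudes) != 2^n_qubits) {
    stop("quantum_state: length(amplitudes) must equal 2^n_qubits", call. = FALSE)
  }
  nrm <- sum(Mod(amplitudes)^2)
  if (abs(nrm - 1) > 1e-9) {
    stop("quantum_state: amplitudes are not normalized (sum |a|^2 = ",
         format(nrm), ")", call. = FALSE)
  }
  structure(list(amplitudes = as.complex(amplitudes), n_qubits = as.integer(n_qubits)),
            class = "quantum_state")
}

#' Amplitude embedding of a real vector
#'
#' Encodes a length-`2^n_qubits` real vector as the amplitudes of an n-qubit
#' state after L2 renormalization (a no-op for unit input).
#'
#' @param v real vector of length `2^n_qubits` with nonzero norm.
#' @param n_qubits number of qubits.
#' @return a `quantum_state`.
#' @export
amplitude_embed <- function(v, n_qubits) {
  if (length(v) != 2^n_qubits) {
    stop("amplitude_embed: input length ", length(v),
         " does not equal 2^", n_qubits, call. = FALSE)
  }
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) stop("amplitude_embed: zero vector cannot be embedded", call. = FALSE)
  quantum_state(as.complex(v / nrm), n_qubits)
}

#' RY angle embedding of a feature vector
#'
#' Prepares the product state `RY(x_1)|0> (x) ... (x) RY(x_d)|0>`; each
#' single-qubit Pauli-Z expectation then equals `cos(x_i)`.
#'
#' @param x numeric features, each in `[0, pi]`; one qubit per feature.
#' @return a `quantum_state` on `length(x)` qubits.
#' @export
angle_embed_ry <- function(x) {
  if (any(x < 0 | x > pi)) {
    stop("angle_embed_ry: features must lie in [0, pi]", call. = FALSE)
  }
  amps <- 1 + 0i
  for (xi in x) amps <- kronecker(amps, complex(real = c(cos(xi / 2), sin(xi / 2))))
  quantum_state(amps, length(x))
}

#' Trainable circuit parameters for the strongly entangling layers
#'
#' @param n_qubits number of qubits.
#' @param depth number of entangling layers.
#' @param angles optional `depth x n_qubits x 3` array of rotation angles; if
#'   missing, drawn uniformly from `[0, 2*pi)` under `seed`.
#' @param ranges optional integer vector of per-layer CNOT ring offsets; the
#'   default cycles through `1, 2, ..., n_qubits - 1`.
#' @param seed RNG seed for random initialization.
#' @return an object of class `circuit_params`.
#' @export
circuit_params <- function(n_qubits, depth, angles = NULL, ranges = NULL, seed = 0L) {
  stopifnot(n_qubits >= 1)
  depth <- as.integer(depth)
  if (depth > 0L) {
    if (is.null(angles)) {
      angles <- with_local_seed(seed, array(runif(depth * n_qubits * 3, 0, 2 * pi),
                                            c(depth, n_qubits, 3)))
    }
    angles <- array(as.numeric(angles), c(depth, n_qubits, 3))
    if (any(!is.finite(angles))) stop("circuit_params: non-finite angles", call. = FALSE)
    if (is.null(ranges)) {
      ranges <- if (n_qubits > 1) ((seq_len(depth) - 1L) %% (n_qubits - 1L)) + 1L
                else rep(0L, depth)
    }
    if (length(ranges) != depth) stop("circuit_params: need one range per layer", call. = FALSE)
  } else {
    angles <- array(numeric(0), c(0, n_qubits, 3))
    ranges <- integer(0)
  }
  structure(list(n_qubits = as.integer(n_qubits), depth = depth,
                 angles = angles, ranges = as.integer(ranges)),
            class = "circuit_params")
}

# ---- gate application --------------------------------------------------------

pair_idx_1q <- function(n, q) {
  key <- paste0("p1q.", n, ".", q)
  cached <- .qs_cache[[key]]
  if (!is.null(cached)) return(cached)
  stride <- bitwShiftL(1L, n - 1L - q)
  idx0 <- which(bitwAnd(0:(2^n - 1L), stride) == 0L)
  out <- list(i0 = idx0, i1 = idx0 + stride)
  .qs_cache[[key]] <- out
  out
}

pair_idx_cnot <- function(n, ctrl, tgt) {
  key <- paste0("pcx.", n, ".", ctrl, ".", tgt)
  cached <- .qs_cache[[key]]
  if (!is.null(cached)) return(cached)
  sc <- bitwShiftL(1L, n - 1L - ctrl)
  st <- bitwShiftL(1L, n - 1L - tgt)
  v <- 0:(2^n - 1L)
  idx0 <- which(bitwAnd(v, sc) > 0L & bitwAnd(v, st) == 0L)
  out <- list(i0 = idx0, i1 = idx0 + st)
  .qs_cache[[key]] <- out
  out
}

apply_1q <- function(psi, n, q, u) {
  ix <- pair_idx_1q(n, q)
  a0 <- psi[ix$i0]
  a1 <- psi[ix$i1]
  psi[ix$i0] <- u[1, 1] * a0 + u[1, 2] * a1
  psi[ix$i1] <- u[2, 1] * a0 + u[2, 2] * a1
  psi
}

apply_cnot <- function(psi, n, ctrl, tgt) {
  ix <- pair_idx_cnot(n, ctrl, tgt)
  tmp <- psi[ix$i0]
  psi[ix$i0] <- psi[ix$i1]
  psi[ix$i1] <- tmp
  psi
}

ry_mat <- function(th) {
  c2 <- cos(th / 2); s2 <- sin(th / 2)
  matrix(complex(real = c(c2, s2, -s2, c2)), 2, 2)
}

rz_mat <- function(th) {
  diag(exp(complex(imaginary = c(-th / 2, th / 2))))
}

gate_mat <- function(g) if (g$type == "RY") ry_mat(g$theta) else rz_mat(g$theta)

# Apply Pauli generator of a rotation gate to a state (for adjoint gradients).
apply_pauli <- function(psi, n, q, type) {
  if (type == "RY") {
    apply_1q(psi, n, q, matrix(complex(real = c(0, 0, 0, 0),
                                       imaginary = c(0, 1, -1, 0)), 2, 2))
  } else {
    psi * z_signs(n)[, q + 1L]
  }
}

# Flat gate list for the strongly entangling block. Rotation gates carry
# `src` ("param" or "input") and `idx` into the corresponding flat vector.
sel_gate_list <- function(params) {
  gates <- list()
  n <- params$n_qubits
  a <- params$angles
  k <- 0L
  for (l in seq_len(params$depth)) {
    for (q in 0:(n - 1L)) {
      for (j in 1:3) {
        k <- k + 1L
        gates[[k]] <- list(type = c("RZ", "RY", "RZ")[j], q = q,
                           theta = a[l, q + 1L, j], src = "param",
                           idx = flat_angle_index(params$depth, n, l, q, j))
      }
    }
    r <- params$ranges[l]
    if (n > 1L && r > 0L) {
      for (q in 0:(n - 1L)) {
        k <- k + 1L
        gates[[k]] <- list(type = "CNOT", ctrl = q, tgt = (q + r) %% n)
      }
    }
  }
  gates
}

# angles array index (l, q+1, j) maps to flat index l + depth*((q*3)+j-1)
# because R arrays are column-major with dim (depth, n_qubits, 3)... the
# mapping above must match `as.numeric(angles)`; see flat_angle_index().
flat_angle_index <- function(depth, n_qubits, l, q, j) {
  l + depth * (q + n_qubits * (j - 1L))
}

run_gates <- function(psi, n, gates) {
  for (g in gates) {
    psi <- if (g$type == "CNOT") apply_cnot(psi, n, g$ctrl, g$tgt)
           else apply_1q(psi, n, g$q, gate_mat(g))
  }
  psi
}

unapply_gate <- function(psi, n, g) {
  if (g$type == "CNOT") return(apply_cnot(psi, n, g$ctrl, g$tgt))
  apply_1q(psi, n, g$q, Conj(t(gate_mat(g))))
}

#' Apply strongly entangling layers to a quantum state
#'
#' Each layer applies a general rotation `RZ(a) RY(b) RZ(c)` to every qubit
#' followed by a ring of CNOTs with layer range `r` (control `q`, target
#' `(q + r) mod n`). The map is unitary and norm-preserving.
#'
#' @param state a `quantum_state`.
#' @param params a `circuit_params` with matching qubit count.
#' @return the evolved `quantum_state`.
#' @export
entangling_layers <- function(state, params) {
  stopifnot(inherits(state, "quantum_state"), inherits(params, "circuit_params"))
  if (params$n_qubits != state$n_qubits) {
    stop("entangling_layers: params are for ", params$n_qubits,
         " qubits but state has ", state$n_qubits, call. = FALSE)
  }
  psi <- run_gates(state$amplitudes, state$n_qubits, sel_gate_list(params))
  quantum_state(psi, state$n_qubits)
}

#' Per-qubit Pauli-Z expectation values
#'
#' @param state a `quantum_state`.
#' @return numeric vector of length `n_qubits`, each value in `[-1, 1]`.
#' @export
pauli_z_expectations <- function(state) {
  stopifnot(inherits(state, "quantum_state"))
  prob <- Mod(state$amplitudes)^2
  as.numeric(crossprod(z_signs(state$n_qubits), prob))
}

# ---- adjoint differentiation -------------------------------------------------

# Forward pass retaining what the backward pass needs.
circuit_run <- function(psi0, n, gates) {
  psi <- run_gates(psi0, n, gates)
  list(psi = psi, gates = gates, n = n)
}

# Backward pass: gz is dL/d<Z_q>. Returns gradients for parameter angles
# (dparam, flat), input angles (dinput, flat) and the costate b = U^dagger
# lambda used for amplitude-embedding input gradients.
circuit_adjoint <- function(fw, gz, n_param, n_input = 0L) {
  n <- fw$n
  signs <- z_signs(n)
  lambda <- fw$psi * as.numeric(signs %*% gz)
  phi <- fw$psi
  b <- lambda
  dparam <- numeric(n_param)
  dinput <- numeric(n_input)
  for (g in rev(fw$gates)) {
    if (g$type != "CNOT") {
      gr <- sum(Im(Conj(b) * apply_pauli(phi, n, g$q, g$type)))
      if (g$src == "param") dparam[g$idx] <- dparam[g$idx] + gr
      else dinput[g$idx] <- dinput[g$idx] + gr
    }
    phi <- unapply_gate(phi, n, g)
    b <- unapply_gate(b, n, g)
  }
  list(dparam = dparam, dinput = dinput, b = b)
}

# Full image-track circuit: amplitude embedding + entangling layers + <Z>.
image_circuit_forward <- function(v, params) {
  nrm <- sqrt(sum(v^2))
  a <- v / nrm
  fw <- circuit_run(as.complex(a), params$n_qubits, sel_gate_list(params))
  list(z = as.numeric(crossprod(z_signs(params$n_qubits), Mod(fw$psi)^2)),
       fw = fw, a = a, nrm = nrm)
}

image_circuit_backward <- function(res, gz, params) {
  bk <- circuit_adjoint(res$fw, gz, n_param = length(params$angles))
  da <- 2 * Re(bk$b)
  dv <- (da - res$a * sum(res$a * da)) / res$nrm
  list(dv = dv, dangles = array(bk$dparam, dim(params$angles)))
}

# Full tabular-track circuit: RY embedding + entangling layers + <Z>.
ry_circuit_forward <- function(x, params) {
  n <- length(x)
  gates <- c(lapply(seq_len(n), function(i) {
    list(type = "RY", q = i - 1L, theta = x[i], src = "input", idx = i)
  }), sel_gate_list(params))
  psi0 <- complex(real = c(1, numeric(2^n - 1)))
  fw <- circuit_run(psi0, n, gates)
  list(z = as.numeric(crossprod(z_signs(n), Mod(fw$psi)^2)), fw = fw)
}

ry_circuit_backward <- function(res, gz, params) {
  bk <- circuit_adjoint(res$fw, gz, n_param = length(params$angles),
                        n_input = length(gz))
  list(dx = bk$dinput, dangles = array(bk$dparam, dim(params$angles)))
}

#' Gradients of a variational circuit's Pauli-Z readout
#'
#' Computes exact adjoint-mode gradients of `L = sum_q g_q <Z_q>` with respect
#' to both the circuit inputs and the entangling-layer angles. The result
#' matches central finite differences to numerical precision.
#'
#' @param inputs for `embedding = "ry"`, the feature angles (one per qubit);
#'   for `embedding = "amplitude"`, a real vector of length `2^n_qubits`.
#' @param params a `circuit_params`.
#' @param loss_grad numeric vector `g` of upstream gradients dL/d<Z_q>;
#'   defaults to all ones (i.e. L is the sum of the expectations).
#' @param embedding which encoding feeds the circuit.
#' @return list with `d_inputs` and `d_params` (same shape as `params$angles`).
#' @export
circuit_gradient <- function(inputs, params, loss_grad = NULL,
                             embedding = c("ry", "amplitude")) {
  embedding <- match.arg(embedding)
  if (is.null(loss_grad)) loss_grad <- rep(1, params$n_qubits)
  if (any(!is.finite(loss_grad))) stop("circuit_gradient: non-finite loss gradient", call. = FALSE)
  if (embedding == "ry") {
    if (length(inputs) != params$n_qubits) {
      stop("circuit_gradient: one feature per qubit required", call. = FALSE)
    }
    res <- ry_circuit_forward(inputs, params)
    bk <- ry_circuit_backward(res, loss_grad, params)
    list(value = res$z, d_inputs = bk$dx, d_params = bk$dangles)
  } else {
    res <- image_circuit_forward(inputs, params)
    bk <- image_circuit_backward(res, loss_grad, params)
    list(value = res$z, d_inputs = bk$dv, d_params = bk$dangles)
  }
}

# ---- autodiff bridge ---------------------------------------------------------

# x: (2^n, N) node of (approximately unit) embedding columns.
ad_quantum_amplitude <- function(x, theta, params_template) {
  xv <- ad_val(x)
  N <- ncol(xv)
  tv <- ad_val(theta)
  p <- params_template
  p$angles <- array(tv, dim(p$angles))
  runs <- vector("list", N)
  out <- matrix(0, p$n_qubits, N)
  for (i in seq_len(N)) {
    runs[[i]] <- image_circuit_forward(xv[, i], p)
    out[, i] <- runs[[i]]$z
  }
  ad_node(x$tape, out, c(x$id, theta$id), function(g) {
    dx <- matrix(0, nrow(xv), N)
    dth <- array(0, dim(p$angles))
    for (i in seq_len(N)) {
      bk <- image_circuit_backward(runs[[i]], g[, i], p)
      dx[, i] <- bk$dv
      dth <- dth + bk$dangles
    }
    list(dx, dth)
  })
}

# x: (d, N) node of feature angles in [0, pi].
ad_quantum_ry <- function(x, theta, params_template) {
  xv <- ad_val(x)
  N <- ncol(xv)
  tv <- ad_val(theta)
  p <- params_template
  p$angles <- array(tv, dim(p$angles))
  runs <- vector("list", N)
  out <- matrix(0, p$n_qubits, N)
  for (i in seq_len(N)) {
    runs[[i]] <- ry_circuit_forward(xv[, i], p)
    out[, i] <- runs[[i]]$z
  }
  ad_node(x$tape, out, c(x$id, theta$id), function(g) {
    dx <- matrix(0, nrow(xv), N)
    dth <- array(0, dim(p$angles))
    for (i in seq_len(N)) {
      bk <- ry_circuit_backward(runs[[i]], g[, i], p)
      dx[, i] <- bk$dx
      dth <- dth + bk$dangles
    }
    list(dx, dth)
  })
}
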