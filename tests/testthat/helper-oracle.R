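# Dense-matrix brute-force oracle: builds the full 2^n x 2^n unitary of a
# gate (or circuit) by explicit Kronecker products, independently of the
# simulator's gate-wise tensor contraction.

dense_gate_unitary <- function(n, op) {
  if (op$name == "CNOT") {
    P0 <- diag(c(1, 0)) + 0i
    P1 <- diag(c(0, 1)) + 0i
    X <- matrix(c(0, 1, 1, 0), 2, 2) + 0i
    partsA <- partsB <- rep(list(diag(2) + 0i), n)
    partsA[[op$wires[1] + 1]] <- P0
    partsB[[op$wires[1] + 1]] <- P1
    partsB[[op$wires[2] + 1]] <- X
    Reduce(kronecker, partsA) + Reduce(kronecker, partsB)
  } else {
    parts <- rep(list(diag(2) + 0i), n)
    parts[[op$wires[1] + 1]] <- gate_matrix(op$name, op$params)
    Reduce(kronecker, parts)
  }
}

# full circuit unitary (slots resolved with `values`)
dense_circuit_unitary <- function(spec, values = NULL) {
  if (is.null(values)) values <- spec$values
  U <- diag(2^spec$n_qubits) + 0i
  b <- spec$bindings
  for (k in seq_along(spec$ops)) {
    op <- spec$ops[[k]]
    if (anyNA(op$params)) {
      hits <- b[b$op == k, ]
      op$params[hits$pos] <- values[hits$slot + 1]
    }
    U <- dense_gate_unitary(spec$n_qubits, op) %*% U
  }
  U
}

random_state <- function(n) {
  a <- complex(real = rnorm(2^n), imaginary = rnorm(2^n))
  pure_state(n, a / sqrt(sum(Mod(a)^2)))
}

random_gate <- function(n) {
  nms <- c("X", "Y", "Z", "H", "S", "RX", "RY", "RZ", "U3", "CNOT")
  np <- c(0, 0, 0, 0, 0, 1, 1, 1, 3, 0)
  i <- sample(length(nms), 1)
  wires <- if (nms[i] == "CNOT") sample(0:(n - 1), 2) else sample(0:(n - 1), 1)
  gate_op(nms[i], wires, runif(np[i], -pi, pi))
}

state_norm <- function(state) sqrt(sum(Mod(state$amplitudes)^2))

# small deterministic 14x14 test image
fixture_image <- function(seed = 123) {
  set.seed(seed)
  matrix(runif(196), 14, 14)
}
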