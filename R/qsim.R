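# Exact statevector simulation of few-qubit parameterized circuits.
#
# Basis ordering: qubit 0 is the MOST significant bit of the basis index, so
# for n qubits the amplitude at (1-based) position i belongs to the bitstring
# of (i-1) written with qubit 0 first. |10> on two qubits is amplitudes
# c(0, 0, 1, 0).

.GATES <- list(
  X    = list(code = 1L,  nparams = 0L, nwires = 1L),
  Y    = list(code = 2L,  nparams = 0L, nwires = 1L),
  Z    = list(code = 3L,  nparams = 0L, nwires = 1L),
  H    = list(code = 4L,  nparams = 0L, nwires = 1L),
  S    = list(code = 5L,  nparams = 0L, nwires = 1L),
  RX   = list(code = 6L,  nparams = 1L, nwires = 1L),
  RY   = list(code = 7L,  nparams = 1L, nwires = 1L),
  RZ   = list(code = 8L,  nparams = 1L, nwires = 1L),
  U3   = list(code = 9L,  nparams = 3L, nwires = 1L),
  CNOT = list(code = 10L, nparams = 0L, nwires = 2L)
)

#' Pure quantum state of an n-qubit register
#'
#' Holds the complex amplitude vector of a normalized n-qubit pure state
#' \eqn{|\psi\rangle = \sum_i a_i |i\rangle}. Qubit 0 is the most significant
#' bit of the basis index.
#'
#' @param n_qubits Number of qubits (1 to 12).
#' @param amplitudes Complex vector of length `2^n_qubits`; defaults to the
#'   computational ground state \eqn{|0\cdots0\rangle}. Must have unit norm.
#' @return An object of class `pure_state` with fields `n_qubits` and
#'   `amplitudes`.
#' @examples
#' psi <- pure_state(1, c(1, 1) / sqrt(2))
#' expval_z(psi, 0)
#' @export
pure_state <- function(n_qubits, amplitudes = NULL) {
  n_qubits <- as.integer(n_qubits)
  if (length(n_qubits) != 1L || is.na(n_qubits) || n_qubits < 1L || n_qubits > 12L)
    stop("n_qubits must be a single integer in 1..12")
  dim_ <- 2L^n_qubits
  if (is.null(amplitudes)) {
    amplitudes <- complex(dim_)
    amplitudes[1L] <- 1 + 0i
  }
  amplitudes <- as.complex(amplitudes)
  if (length(amplitudes) != dim_)
    stop("amplitudes must have length 2^n_qubits = ", dim_)
  nrm <- sum(Mod(amplitudes)^2)
  if (abs(nrm - 1) > 1e-8)
    stop("state is not normalized: sum |amplitude|^2 = ", format(nrm))
  structure(list(n_qubits = n_qubits, amplitudes = amplitudes),
            class = "pure_state")
}

#' @rdname pure_state
#' @export
ground_state <- function(n_qubits) pure_state(n_qubits)

#' @export
print.pure_state <- function(x, ...) {
  cat("<pure_state>", x$n_qubits, "qubits,", length(x$amplitudes),
      "amplitudes, norm", format(sqrt(sum(Mod(x$amplitudes)^2))), "\n")
  invisible(x)
}

#' Single gate application record
#'
#' @param name Gate name, one of X, Y, Z, H, S, RX, RY, RZ, U3, CNOT.
#' @param wires Integer wire indices (0-based); one wire for single-qubit
#'   gates, two for CNOT with the control listed first.
#' @param params Numeric angles in radians (RX/RY/RZ: 1; U3: 3; others: 0).
#'   `NA` marks an angle position fed by a trainable slot of the enclosing
#'   circuit.
#' @return An object of class `gate_op`.
#' @export
gate_op <- function(name, wires, params = numeric(0)) {
  info <- .GATES[[name]]
  if (is.null(info)) stop("unknown gate name: ", name)
  wires <- as.integer(wires)
  if (length(wires) != info$nwires)
    stop(name, " takes ", info$nwires, " wire(s), got ", length(wires))
  if (anyDuplicated(wires)) stop("wire indices must be distinct")
  if (any(wires < 0L)) stop("wire indices must be >= 0")
  params <- as.numeric(params)
  if (length(params) != info$nparams)
    stop(name, " takes ", info$nparams, " parameter(s), got ", length(params))
  structure(list(name = name, wires = wires, params = params),
            class = "gate_op")
}

#' Unitary matrix of a single gate
#'
#' Returns the 2x2 (or 4x4 for CNOT) complex matrix of the named gate.
#' CNOT is the matrix with the first listed wire as control:
#' rows (1000, 0100, 0001, 0010).
#'
#' @inheritParams gate_op
#' @return A complex matrix satisfying \eqn{U U^\dagger = I}.
#' @examples
#' gate_matrix("RY", pi)
#' gate_matrix("U3", c(0, 0, 0))
#' @export
gate_matrix <- function(name, params = numeric(0)) {
  info <- .GATES[[name]]
  if (is.null(info)) stop("unknown gate name: ", name)
  if (length(params) != info$nparams)
    stop(name, " takes ", info$nparams, " parameter(s), got ", length(params))
  th <- as.numeric(params)
  m <- switch(name,
    X = matrix(c(0, 1, 1, 0), 2, 2),
    Y = matrix(c(0, 1i, -1i, 0), 2, 2),
    Z = matrix(c(1, 0, 0, -1), 2, 2),
    H = matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2),
    S = matrix(c(1, 0, 0, 1i), 2, 2),
    RX = matrix(c(cos(th / 2), -1i * sin(th / 2),
                  -1i * sin(th / 2), cos(th / 2)), 2, 2),
    RY = matrix(c(cos(th / 2), sin(th / 2),
                  -sin(th / 2), cos(th / 2)), 2, 2),
    RZ = diag(c(exp(-1i * th / 2), exp(1i * th / 2))),
    U3 = {
      ct <- cos(th[1] / 2); st <- sin(th[1] / 2)
      matrix(c(ct, exp(1i * th[2]) * st,
               -exp(1i * th[3]) * st, exp(1i * (th[2] + th[3])) * ct), 2, 2)
    },
    CNOT = {
      cn <- diag(4) + 0i
      cn[3:4, 3:4] <- matrix(c(0, 1, 1, 0), 2, 2)
      cn
    }
  )
  m + 0i  # always complex, even for real-valued gates
}

#' Parameterized circuit specification
#'
#' An ordered gate list plus a binding table that maps trainable parameter
#' slots to the angle positions they feed. One slot may feed several angle
#' positions (parameter sharing); every slot `0..n_slots-1` must feed at
#' least one position, and angle positions carrying a slot are `NA` in the
#' gate's `params`.
#'
#' @param n_qubits Register width the circuit acts on.
#' @param ops List of [gate_op()] records, applied in order.
#' @param bindings `NULL`, or a data.frame with columns `slot` (0-based slot
#'   index), `op` (1-based op index) and `pos` (1-based angle position within
#'   that op).
#' @param values Optional default values for the trainable slots
#'   (`values[s+1]` feeds slot `s`).
#' @return An object of class `circuit_spec`.
#' @export
circuit_spec <- function(n_qubits, ops, bindings = NULL, values = NULL) {
  n_qubits <- as.integer(n_qubits)
  if (!all(vapply(ops, inherits, logical(1), "gate_op")))
    stop("ops must be a list of gate_op objects")
  for (op in ops) {
    if (any(op$wires >= n_qubits))
      stop("wire index out of range for ", n_qubits, "-qubit circuit")
  }
  if (is.null(bindings)) {
    bindings <- data.frame(slot = integer(0), op = integer(0), pos = integer(0))
  }
  bindings <- as.data.frame(bindings)
  if (nrow(bindings)) {
    if (!all(c("slot", "op", "pos") %in% names(bindings)))
      stop("bindings needs columns slot, op, pos")
    if (any(bindings$op < 1L | bindings$op > length(ops)))
      stop("binding refers to a nonexistent op")
    npar <- vapply(ops, function(o) length(o$params), integer(1))
    if (any(bindings$pos < 1L | bindings$pos > npar[bindings$op]))
      stop("binding refers to a nonexistent angle position")
    ns <- max(bindings$slot) + 1L
    if (!all(0:(ns - 1L) %in% bindings$slot))
      stop("every trainable slot must feed at least one angle position")
  }
  # every NA angle position must be fed by some slot
  for (k in seq_along(ops)) {
    nas <- which(is.na(ops[[k]]$params))
    for (p in nas) {
      if (!any(bindings$op == k & bindings$pos == p))
        stop("op ", k, " has an unbound NA angle position")
    }
  }
  spec <- structure(list(n_qubits = n_qubits, ops = ops, bindings = bindings,
                         values = values),
                    class = "circuit_spec")
  if (!is.null(values) && length(values) != n_slots(spec))
    stop("values length must equal the number of trainable slots (",
         n_slots(spec), ")")
  spec
}

#' Number of trainable parameter slots of a circuit
#' @param spec A [circuit_spec()].
#' @return Integer count of distinct trainable slots.
#' @export
n_slots <- function(spec) {
  if (nrow(spec$bindings) == 0L) 0L else max(spec$bindings$slot) + 1L
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat("<circuit_spec>", x$n_qubits, "qubits,", length(x$ops), "gates,",
      n_slots(x), "trainable slots\n")
  invisible(x)
}

# lower to flat arrays for the C++ backend; angles filled with literals,
# slot-bound positions zeroed (resolved later)
.compile_circuit <- function(spec) {
  m <- length(spec$ops)
  codes <- integer(m); w1 <- integer(m); w2 <- integer(m)
  angles <- matrix(0, nrow = max(m, 1L), ncol = 3)
  for (k in seq_len(m)) {
    op <- spec$ops[[k]]
    info <- .GATES[[op$name]]
    codes[k] <- info$code
    w1[k] <- op$wires[1L]
    w2[k] <- if (info$nwires == 2L) op$wires[2L] else 0L
    if (info$nparams > 0L) {
      p <- op$params
      p[is.na(p)] <- 0
      angles[k, seq_along(p)] <- p
    }
  }
  list(n = spec$n_qubits, codes = codes, w1 = w1, w2 = w2, angles = angles,
       bind = spec$bindings)
}

.resolve_angles <- function(cmp, values) {
  a <- cmp$angles
  b <- cmp$bind
  if (nrow(b)) {
    if (length(values) != max(b$slot) + 1L)
      stop("expected ", max(b$slot) + 1L, " slot values, got ", length(values))
    a[cbind(b$op, b$pos)] <- values[b$slot + 1L]
  }
  a
}

#' Apply one gate to a state
#'
#' Applies the gate's unitary to the listed wires by tensor contraction;
#' the remaining wires are untouched and the norm is preserved.
#'
#' @param state A [pure_state()].
#' @param op A [gate_op()] with fully specified (non-`NA`) angles.
#' @return The transformed [pure_state()].
#' @examples
#' apply_gate(ground_state(1), gate_op("X", 0))
#' @export
apply_gate <- function(state, op) {
  stopifnot(inherits(state, "pure_state"), inherits(op, "gate_op"))
  if (any(op$wires >= state$n_qubits))
    stop("wire index out of range for ", state$n_qubits, "-qubit state")
  if (anyNA(op$params)) stop("gate has unbound angle positions")
  spec <- circuit_spec(state$n_qubits, list(op))
  run_circuit(spec, initial = state)
}

#' Run a parameterized circuit
#'
#' Applies every gate of `spec` in order to `initial` (default: the ground
#' state), with trainable slots bound to `values`.
#'
#' @param spec A [circuit_spec()].
#' @param values Numeric vector of slot values; defaults to `spec$values`.
#' @param initial Input [pure_state()]; default \eqn{|0\cdots0\rangle}.
#' @return The output [pure_state()].
#' @export
run_circuit <- function(spec, values = NULL, initial = NULL) {
  stopifnot(inherits(spec, "circuit_spec"))
  if (is.null(values)) values <- spec$values
  if (is.null(values)) values <- numeric(0)
  if (is.null(initial)) initial <- ground_state(spec$n_qubits)
  stopifnot(inherits(initial, "pure_state"))
  if (initial$n_qubits != spec$n_qubits)
    stop("state and circuit widths differ")
  if (length(spec$ops) == 0L) return(initial)
  cmp <- .compile_circuit(spec)
  a <- .resolve_angles(cmp, values)
  amps <- cpp_run_circuit(initial$amplitudes, cmp$n, cmp$codes, cmp$w1,
                          cmp$w2, a)
  structure(list(n_qubits = spec$n_qubits, amplitudes = amps),
            class = "pure_state")
}

#' Pauli-Z expectation of one wire
#'
#' \eqn{\langle\psi|Z_w|\psi\rangle = \sum_i |a_i|^2 (\pm 1)}, +1 where the
#' wire's bit is 0. Always real, in \eqn{[-1, 1]}.
#'
#' @param state A [pure_state()].
#' @param wire Wire index (0-based).
#' @return A real number in `[-1, 1]`.
#' @export
expval_z <- function(state, wire) {
  stopifnot(inherits(state, "pure_state"))
  wire <- as.integer(wire)
  if (wire < 0L || wire >= state$n_qubits) stop("wire out of range")
  cpp_expval_z(state$amplitudes, state$n_qubits, wire)
}

#' Parameter-shift gradient of a Pauli-Z expectation
#'
#' Analytic gradient of \eqn{\langle Z_{wire}\rangle} after running `spec`
#' from the ground state, with respect to each trainable slot. Each angle
#' position contributes \eqn{[f(\theta+\pi/2) - f(\theta-\pi/2)]/2}; slots
#' feeding several positions accumulate their contributions. Only rotation
#' gates (RX/RY/RZ/U3) may sit in trainable slots.
#'
#' @param spec A [circuit_spec()].
#' @param values Slot values at which to differentiate.
#' @param wire Measured wire (0-based).
#' @return Numeric gradient vector, one entry per trainable slot.
#' @export
grad_param_shift <- function(spec, values, wire) {
  stopifnot(inherits(spec, "circuit_spec"))
  ns <- n_slots(spec)
  if (length(values) != ns)
    stop("expected ", ns, " slot values, got ", length(values))
  cmp <- .compile_circuit(spec)
  b <- spec$bindings
  shiftable <- c(6L, 7L, 8L, 9L)  # RX RY RZ U3
  bad <- setdiff(unique(cmp$codes[b$op]), shiftable)
  if (length(bad))
    stop("parameter-shift rule requires trainable gates to be RX/RY/RZ/U3")
  base <- .resolve_angles(cmp, values)
  init <- ground_state(spec$n_qubits)$amplitudes
  f_at <- function(a) {
    st <- cpp_run_circuit(init, cmp$n, cmp$codes, cmp$w1, cmp$w2, a)
    cpp_expval_z(st, cmp$n, as.integer(wire))
  }
  g <- numeric(ns)
  for (r in seq_len(nrow(b))) {
    ap <- base; ap[b$op[r], b$pos[r]] <- ap[b$op[r], b$pos[r]] + pi / 2
    am <- base; am[b$op[r], b$pos[r]] <- am[b$op[r], b$pos[r]] - pi / 2
    g[b$slot[r] + 1L] <- g[b$slot[r] + 1L] + (f_at(ap) - f_at(am)) / 2
  }
  g
}

#' Serialize a circuit to a line-oriented text format
#'
#' One gate per line: `NAME wire[,wire]` followed by one token per angle
#' position, `slot:k` for a trainable slot or `lit:v` for a literal angle.
#'
#' @param spec A [circuit_spec()].
#' @return Character vector, one line per gate.
#' @examples
#' circuit_to_text(encode_patch(matrix(0.5, 3, 3)))[1:3]
#' @export
circuit_to_text <- function(spec) {
  stopifnot(inherits(spec, "circuit_spec"))
  b <- spec$bindings
  vapply(seq_along(spec$ops), function(k) {
    op <- spec$ops[[k]]
    toks <- c(op$name, paste(op$wires, collapse = ","))
    for (p in seq_along(op$params)) {
      hit <- b$slot[b$op == k & b$pos == p]
      toks <- c(toks, if (length(hit)) paste0("slot:", hit[1L])
                      else paste0("lit:", format(op$params[p], digits = 17)))
    }
    paste(toks, collapse = " ")
  }, character(1))
}

#' Parse the line-oriented circuit text format
#'
#' @param lines Character vector as produced by [circuit_to_text()].
#' @param n_qubits Register width; inferred as `max wire + 1` when `NULL`.
#' @return A [circuit_spec()].
#' @export
circuit_from_text <- function(lines, n_qubits = NULL) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ops <- list(); bind <- list()
  for (k in seq_along(lines)) {
    toks <- strsplit(lines[k], "[[:space:]]+")[[1]]
    if (length(toks) < 2L) stop("malformed circuit line: ", lines[k])
    name <- toks[1L]
    info <- .GATES[[name]]
    if (is.null(info)) stop("unknown gate name: ", name)
    wires <- as.integer(strsplit(toks[2L], ",")[[1]])
    ptoks <- toks[-(1:2)]
    if (length(ptoks) != info$nparams)
      stop("gate ", name, " expects ", info$nparams, " angle token(s)")
    params <- rep(NA_real_, info$nparams)
    for (p in seq_along(ptoks)) {
      if (startsWith(ptoks[p], "slot:")) {
        bind[[length(bind) + 1L]] <-
          data.frame(slot = as.integer(sub("slot:", "", ptoks[p])),
                     op = k, pos = p)
      } else if (startsWith(ptoks[p], "lit:")) {
        params[p] <- as.numeric(sub("lit:", "", ptoks[p]))
      } else stop("malformed angle token: ", ptoks[p])
    }
    ops[[k]] <- gate_op(name, wires, params)
  }
  if (is.null(n_qubits))
    n_qubits <- max(vapply(ops, function(o) max(o$wires), integer(1))) + 1L
  bindings <- if (length(bind)) do.call(rbind, bind) else NULL
  circuit_spec(n_qubits, ops, bindings)
}
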