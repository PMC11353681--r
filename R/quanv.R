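# Quanvolution: angle embedding of 3x3 patches, the shared 15-parameter
# entangled kernel circuit, and the sliding-window layer that turns an image
# into a multi-channel feature map of Pauli-Z expectations.

#' Angle-embedding circuit for a 3x3 patch
#'
#' Encodes the nine pixel values of a patch into the rotation angles of nine
#' RX gates, one per qubit: qubit `i` carries pixel `(row = i %/% 3,
#' col = i %% 3)` (row-major) with angle `pixel * pi/2`, so pixel values in
#' \eqn{[0,1]} map to angles in \eqn{[0, \pi/2]}.
#'
#' @param patch 3x3 numeric matrix with values in `[0, 1]`.
#' @return A 9-qubit [circuit_spec()] of nine literal RX gates.
#' @examples
#' spec <- encode_patch(matrix(0.5, 3, 3))
#' expval_z(run_circuit(spec), 0)  # cos(pi/4)
#' @export
encode_patch <- function(patch) {
  patch <- as.matrix(patch)
  if (!all(dim(patch) == c(3L, 3L))) stop("patch must be 3x3")
  if (anyNA(patch) || any(patch < 0 | patch > 1))
    stop("patch values must lie in [0, 1]")
  ops <- lapply(0:8, function(i)
    gate_op("RX", i, patch[i %/% 3L + 1L, i %% 3L + 1L] * pi / 2))
  circuit_spec(9L, ops)
}

# the 10-gate SU(4)-style block on a wire pair, with the 15 shared slot ids
.kernel_block <- function(qa, qb) {
  list(
    list("U3", qa, 0:2), list("U3", qb, 3:5),
    list("CNOT", c(qb, qa), integer(0)),
    list("RZ", qa, 6L), list("RY", qb, 7L),
    list("CNOT", c(qa, qb), integer(0)),
    list("RY", qb, 8L),
    list("CNOT", c(qb, qa), integer(0)),
    list("U3", qa, 9:11), list("U3", qb, 12:14)
  )
}

#' Build the 9-qubit quanvolutional kernel circuit
#'
#' The kernel is a strongly entangling 9-qubit circuit built from one
#' SU(4)-style two-qubit block per adjacent wire pair (0,1), (1,2), ...,
#' (7,8): U3 on each qubit, three CNOTs interleaved with RZ/RY rotations,
#' then a final U3 on each qubit (80 gates in total). All eight blocks SHARE
#' the same 15 trainable angles, so the whole kernel exposes exactly 15
#' parameters -- the quantum analogue of convolutional weight sharing.
#'
#' @param params Numeric vector of the 15 kernel angles (radians), bound as
#'   the circuit's default slot values.
#' @return A 9-qubit [circuit_spec()] with 15 trainable slots.
#' @examples
#' k <- build_kernel(rep(0, 15))
#' n_slots(k)
#' @export
build_kernel <- function(params) {
  params <- as.numeric(params)
  if (length(params) != 15L) stop("kernel takes exactly 15 parameters")
  ops <- list(); bind <- list()
  for (i in 0:7) {
    for (g in .kernel_block(i, i + 1L)) {
      nm <- g[[1]]; wires <- g[[2]]; slots <- g[[3]]
      k <- length(ops) + 1L
      ops[[k]] <- gate_op(nm, wires, rep(NA_real_, length(slots)))
      if (length(slots))
        bind[[length(bind) + 1L]] <-
          data.frame(slot = slots, op = k, pos = seq_along(slots))
    }
  }
  circuit_spec(9L, ops, do.call(rbind, bind), values = params)
}

# ---- compiled fast path -----------------------------------------------------
# encoding (9 RX) + kernel lowered once; per patch only the first 9 angles
# change. Used by the sliding-window layers and the classifier's backward pass.

.quanv_compiled <- function(params) {
  enc <- encode_patch(matrix(0, 3, 3))
  ker <- build_kernel(params)
  spec <- circuit_spec(9L, c(enc$ops, ker$ops),
                       transform(ker$bindings, op = op + 9L),
                       values = params)
  cmp <- .compile_circuit(spec)
  cmp$angles <- .resolve_angles(cmp, params)
  cmp$init <- ground_state(9L)$amplitudes
  cmp
}

# patch given as length-9 row-major vector
.quanv_forward <- function(cmp, patch9) {
  a <- cmp$angles
  a[1:9, 1] <- patch9 * (pi / 2)
  cpp_forward_expvals(cmp$init, 9L, cmp$codes, cmp$w1, cmp$w2, a)
}

# gradient of sum(coef * <Z_w>) w.r.t. the 15 kernel slots and the 9 pixels
.quanv_backward <- function(cmp, patch9, coef) {
  a <- cmp$angles
  a[1:9, 1] <- patch9 * (pi / 2)
  res <- cpp_adjoint_grad(cmp$init, 9L, cmp$codes, cmp$w1, cmp$w2, a, coef)
  b <- cmp$bind
  slot_grad <- numeric(15)
  contrib <- res$grad[cbind(b$op, b$pos)]
  for (s in 0:14) slot_grad[s + 1L] <- sum(contrib[b$slot == s])
  list(expvals = res$expvals,
       slot_grad = slot_grad,
       pixel_grad = res$grad[1:9, 1] * (pi / 2))
}

#' Quanvolve a single 3x3 patch
#'
#' Runs the angle-embedding circuit followed by the kernel circuit on
#' \eqn{|0\rangle^{\otimes 9}} and measures \eqn{\langle Z\rangle} on every
#' wire, producing the nine channel values of one output pixel.
#'
#' @param patch 3x3 numeric matrix in `[0, 1]`.
#' @param params The 15 kernel angles.
#' @return Numeric vector of nine expectations in `[-1, 1]`.
#' @export
quanvolve_patch <- function(patch, params) {
  patch <- as.matrix(patch)
  if (!all(dim(patch) == c(3L, 3L))) stop("patch must be 3x3")
  if (anyNA(patch) || any(patch < 0 | patch > 1))
    stop("patch values must lie in [0, 1]")
  cmp <- .quanv_compiled(params)
  as.numeric(.quanv_forward(cmp, as.vector(t(patch))))
}

#' Slide the quantum kernel over an image
#'
#' Applies [quanvolve_patch()] at every 3x3 window of the image with the
#' given stride and no padding. The window at output cell (r, c) covers input
#' rows `stride*(r-1) + 1:3` and the analogous columns; each window yields
#' nine channels, so a 14x14 image becomes a 6x6x9 feature map.
#'
#' @param image Numeric H x W matrix with values in `[0, 1]`, H, W >= 3.
#' @param params The 15 kernel angles.
#' @param kernel Kernel side length (fixed at 3 by the 9-qubit register).
#' @param stride Window step; default 2.
#' @return A `feature_map`: numeric array H' x W' x 9 with entries in
#'   `[-1, 1]`.
#' @export
quanvolve_image <- function(image, params, kernel = 3L, stride = 2L) {
  image <- as.matrix(image)
  if (kernel != 3L) stop("kernel size is fixed at 3 (one qubit per pixel)")
  h <- nrow(image); w <- ncol(image)
  if (h < kernel || w < kernel) stop("image smaller than the kernel")
  if (anyNA(image) || any(image < 0 | image > 1))
    stop("image values must lie in [0, 1]")
  oh <- (h - kernel) %/% stride + 1L
  ow <- (w - kernel) %/% stride + 1L
  cmp <- .quanv_compiled(params)
  fm <- array(0, dim = c(oh, ow, 9L))
  for (r in seq_len(oh)) {
    rows <- (stride * (r - 1L) + 1L):(stride * (r - 1L) + kernel)
    for (c in seq_len(ow)) {
      cols <- (stride * (c - 1L) + 1L):(stride * (c - 1L) + kernel)
      fm[r, c, ] <- .quanv_forward(cmp, as.vector(t(image[rows, cols])))
    }
  }
  structure(fm, class = "feature_map")
}

#' Rescale a feature map from [-1, 1] to [0, 1]
#'
#' Elementwise `v -> (v + 1) / 2`, so a second quanvolutional layer can
#' angle-embed the previous layer's expectations.
#'
#' @param fm A `feature_map` with entries in `[-1, 1]`.
#' @return A `feature_map` with entries in `[0, 1]`.
#' @export
rescale_map <- function(fm) {
  v <- unclass(fm)
  if (any(v < -1 - 1e-9 | v > 1 + 1e-9)) stop("feature map outside [-1, 1]")
  structure(pmin(pmax((v + 1) / 2, 0), 1), dim = dim(v),
            class = "feature_map")
}

#' Second quanvolutional layer
#'
#' Two compositions of the second shared 15-parameter kernel are supported.
#' Mode `"spatial"` (default) treats each of the 9 input channels as its own
#' 6x6 image and quanvolves it (kernel 3, stride 2), giving 2x2x9 per channel,
#' concatenated to 2x2x81 with input channel `c` occupying output channels
#' `(c-1)*9 + 1:9`. Mode `"stacked"` re-encodes each spatial cell's 9 channel
#' values as one 3x3 patch (row-major) and passes it through the kernel,
#' keeping the 6x6x9 shape.
#'
#' @param fm A rescaled `feature_map` (entries in `[0, 1]`); 6x6x9 for the
#'   default pipeline.
#' @param params2 The 15 angles of the second kernel.
#' @param mode `"spatial"` or `"stacked"`.
#' @return A `feature_map`: 2x2x81 (spatial) or same-shape (stacked).
#' @export
quanv_layer2 <- function(fm, params2, mode = c("spatial", "stacked")) {
  mode <- match.arg(mode)
  v <- unclass(fm)
  if (length(dim(v)) != 3L) stop("feature map must be H x W x C")
  if (any(v < 0 | v > 1))
    stop("layer-2 input must be rescaled to [0, 1]")
  nch <- dim(v)[3]
  if (mode == "spatial") {
    if (dim(v)[1] < 3L || dim(v)[2] < 3L)
      stop("spatial mode needs channel planes at least 3x3")
    per <- lapply(seq_len(nch), function(ch)
      unclass(quanvolve_image(v[, , ch], params2)))
    oh <- dim(per[[1]])[1]; ow <- dim(per[[1]])[2]
    out <- array(0, dim = c(oh, ow, 9L * nch))
    for (ch in seq_len(nch))
      out[, , (ch - 1L) * 9L + 1:9] <- per[[ch]]
    structure(out, class = "feature_map")
  } else {
    if (nch != 9L) stop("stacked mode needs exactly 9 channels")
    cmp <- .quanv_compiled(params2)
    out <- array(0, dim = dim(v))
    for (r in seq_len(dim(v)[1]))
      for (c in seq_len(dim(v)[2]))
        out[r, c, ] <- .quanv_forward(cmp, v[r, c, ])
    structure(out, class = "feature_map")
  }
}

#' Export a feature map as CSV
#'
#' One row per spatial cell: `r`, `c`, then one column per channel
#' (`ch0..chN`).
#'
#' @param fm A `feature_map`.
#' @param path Output file path.
#' @return The data.frame that was written, invisibly.
#' @export
write_feature_map_csv <- function(fm, path) {
  v <- unclass(fm)
  d <- dim(v)
  grid <- expand.grid(c = seq_len(d[2]), r = seq_len(d[1]))
  rows <- cbind(r = grid$r, c = grid$c,
                t(vapply(seq_len(nrow(grid)),
                         function(i) v[grid$r[i], grid$c[i], ],
                         numeric(d[3]))))
  colnames(rows) <- c("r", "c", paste0("ch", seq_len(d[3]) - 1L))
  df <- as.data.frame(rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
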