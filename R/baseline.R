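# Architecture-matched classical CNN baseline: two 3x3 stride-2 convolutions
# with 9 channels each (the second grouped channel-wise, mirroring the
# per-channel spatial composition of the second quanvolution layer), tanh
# activations to mirror the [-1, 1] expectation range, and the same dense head.

.conv_windows <- function(h, kernel = 3L, stride = 2L) (h - kernel) %/% stride + 1L

#' Initialize the classical CNN baseline
#'
#' Layer 1: nine 3x3 filters over the single input channel (stride 2, bias,
#' tanh). Layer 2: one 3x3 filter per channel (grouped, stride 2, bias,
#' tanh). Head: dense layer on the 2x2x9 = 36 flattened features. Weights
#' and biases Uniform[-1/sqrt(fan_in), 1/sqrt(fan_in)].
#'
#' @param seed Integer RNG seed.
#' @return An object of class `cnn_model`.
#' @export
init_baseline <- function(seed) {
  set.seed(as.integer(seed))
  l1 <- 1 / sqrt(9); l2 <- 1 / sqrt(9); lf <- 1 / sqrt(36)
  structure(list(W1 = array(stats::runif(81, -l1, l1), dim = c(3, 3, 9)),
                 b1 = stats::runif(9, -l1, l1),
                 W2 = array(stats::runif(81, -l2, l2), dim = c(3, 3, 9)),
                 b2 = stats::runif(9, -l2, l2),
                 fc_weights = stats::runif(36, -lf, lf),
                 fc_bias = stats::runif(1, -lf, lf),
                 mode = "classical"),
            class = "cnn_model")
}

.pack_cnn <- function(m) c(as.vector(m$W1), m$b1, as.vector(m$W2), m$b2,
                           m$fc_weights, m$fc_bias)

.unpack_cnn <- function(theta) {
  structure(list(W1 = array(theta[1:81], dim = c(3, 3, 9)),
                 b1 = theta[82:90],
                 W2 = array(theta[91:171], dim = c(3, 3, 9)),
                 b2 = theta[172:180],
                 fc_weights = theta[181:216], fc_bias = theta[217],
                 mode = "classical"),
            class = "cnn_model")
}

.cnn_forward_full <- function(image, model) {
  h <- nrow(image)
  o1 <- .conv_windows(h)
  z1 <- array(0, dim = c(o1, o1, 9L))
  for (k in 1:9) for (r in seq_len(o1)) for (c in seq_len(o1)) {
    z1[r, c, k] <- sum(image[(2 * r - 1):(2 * r + 1),
                             (2 * c - 1):(2 * c + 1)] * model$W1[, , k]) +
      model$b1[k]
  }
  a1 <- tanh(z1)
  o2 <- .conv_windows(o1)
  z2 <- array(0, dim = c(o2, o2, 9L))
  for (k in 1:9) for (r in seq_len(o2)) for (c in seq_len(o2)) {
    z2[r, c, k] <- sum(a1[(2 * r - 1):(2 * r + 1),
                          (2 * c - 1):(2 * c + 1), k] * model$W2[, , k]) +
      model$b2[k]
  }
  a2 <- tanh(z2)
  flat <- .flatten_fm(a2)
  logit <- sum(model$fc_weights * flat) + model$fc_bias
  list(logit = logit, a1 = a1, a2 = a2, flat = flat, o1 = o1, o2 = o2)
}

#' Forward pass of the classical baseline CNN
#'
#' @param image Numeric matrix in `[0, 1]` (14x14 for the default pipeline).
#' @param model A `cnn_model` from [init_baseline()].
#' @return The scalar logit.
#' @export
baseline_forward <- function(image, model) {
  stopifnot(inherits(model, "cnn_model"))
  .cnn_forward_full(as.matrix(image), model)$logit
}

.cnn_grad_one <- function(image, label, model) {
  fw <- .cnn_forward_full(image, model)
  dlogit <- .sigmoid(fw$logit) - label
  g_w <- dlogit * fw$flat
  g_b <- dlogit
  g_a2 <- .unflatten_fm(dlogit * model$fc_weights, dim(fw$a2))
  dz2 <- g_a2 * (1 - fw$a2^2)
  o1 <- fw$o1; o2 <- fw$o2
  gW2 <- array(0, dim = c(3, 3, 9)); gb2 <- numeric(9)
  g_a1 <- array(0, dim = dim(fw$a1))
  for (k in 1:9) for (r in seq_len(o2)) for (c in seq_len(o2)) {
    rows <- (2 * r - 1):(2 * r + 1); cols <- (2 * c - 1):(2 * c + 1)
    gW2[, , k] <- gW2[, , k] + dz2[r, c, k] * fw$a1[rows, cols, k]
    gb2[k] <- gb2[k] + dz2[r, c, k]
    g_a1[rows, cols, k] <- g_a1[rows, cols, k] + dz2[r, c, k] * model$W2[, , k]
  }
  dz1 <- g_a1 * (1 - fw$a1^2)
  gW1 <- array(0, dim = c(3, 3, 9)); gb1 <- numeric(9)
  for (k in 1:9) for (r in seq_len(o1)) for (c in seq_len(o1)) {
    rows <- (2 * r - 1):(2 * r + 1); cols <- (2 * c - 1):(2 * c + 1)
    gW1[, , k] <- gW1[, , k] + dz1[r, c, k] * image[rows, cols]
    gb1[k] <- gb1[k] + dz1[r, c, k]
  }
  list(loss = bce_with_logits(fw$logit, label), logit = fw$logit,
       grad = c(as.vector(gW1), gb1, as.vector(gW2), gb2, g_w, g_b))
}

#' Train the classical baseline CNN
#'
#' Same optimizer, loss, batch protocol and epoch bookkeeping as
#' [train_model()], applied to the architecture-matched CNN.
#'
#' @inheritParams train_model
#' @return List with `model` (a `cnn_model`) and `history`.
#' @export
train_baseline <- function(train, val = NULL, config = train_config()) {
  .check_train_set(train)
  model0 <- init_baseline(config$seed)
  grad_fn <- function(theta, image, label)
    .cnn_grad_one(image, label, .unpack_cnn(theta))
  logit_fn <- function(theta, image) baseline_forward(image, .unpack_cnn(theta))
  res <- .adam_train(.pack_cnn(model0), grad_fn, logit_fn, train, val, config)
  list(model = .unpack_cnn(res$theta), history = res$history)
}
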