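# Hybrid model: two quanvolution layers -> flatten -> fully connected ->
# sigmoid threshold, trained with Adam on BCE-with-logits. Gradients for the
# quantum kernels come from adjoint-mode backpropagation through the exact
# simulator (cross-checked against the parameter-shift rule and finite
# differences in the tests).

# flatten H x W x C row-major with channels last (channel varies fastest)
.flatten_fm <- function(v) as.vector(aperm(unclass(v), c(3, 2, 1)))

.unflatten_fm <- function(g, d) aperm(array(g, dim = d[c(3, 2, 1)]), c(3, 2, 1))

.sigmoid <- function(z) 1 / (1 + exp(-z))

#' Binary cross-entropy on a raw logit
#'
#' Numerically stable form `max(z,0) - z*y + log(1 + exp(-|z|))`; never
#' evaluates `exp` of a large positive argument.
#'
#' @param logit Real score before the sigmoid.
#' @param label 0 or 1.
#' @return Non-negative loss value (vectorized over inputs).
#' @examples
#' bce_with_logits(0, 1)  # log(2)
#' @export
bce_with_logits <- function(logit, label) {
  if (!all(label %in% c(0, 1))) stop("labels must be 0 or 1")
  pmax(logit, 0) - logit * label + log1p(exp(-abs(logit)))
}

#' Threshold a logit into a class label
#'
#' Positive class 1 (normal/benign) iff `sigmoid(logit) > threshold`;
#' a score exactly at the threshold is classified 0 (malignant).
#'
#' @param logit Real score(s).
#' @param threshold Decision threshold in (0, 1); default 0.5.
#' @return Integer label(s) in \{0, 1\}.
#' @export
predict_label <- function(logit, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  as.integer(.sigmoid(logit) > threshold)
}

#' Initialize the hybrid quanvolutional model
#'
#' Quantum kernel angles are drawn Uniform[0, 2*pi); dense weights and bias
#' Uniform[-1/sqrt(324), 1/sqrt(324)]. Both layer-2 modes flatten to 324
#' features (2*2*81 spatial, 6*6*9 stacked).
#'
#' @param seed Integer RNG seed.
#' @param mode Layer-2 composition, `"spatial"` or `"stacked"`.
#' @return An object of class `quanv_model` with fields `kernel1`, `kernel2`,
#'   `fc_weights` (length 324), `fc_bias`, `mode`.
#' @export
init_model <- function(seed, mode = c("spatial", "stacked")) {
  mode <- match.arg(mode)
  set.seed(as.integer(seed))
  lim <- 1 / sqrt(324)
  structure(list(kernel1 = stats::runif(15, 0, 2 * pi),
                 kernel2 = stats::runif(15, 0, 2 * pi),
                 fc_weights = stats::runif(324, -lim, lim),
                 fc_bias = stats::runif(1, -lim, lim),
                 mode = mode),
            class = "quanv_model")
}

.pack_quantum <- function(m) c(m$kernel1, m$kernel2, m$fc_weights, m$fc_bias)

.unpack_quantum <- function(theta, mode) {
  structure(list(kernel1 = theta[1:15], kernel2 = theta[16:30],
                 fc_weights = theta[31:354], fc_bias = theta[355],
                 mode = mode),
            class = "quanv_model")
}

# full forward with caches for the backward pass
.quantum_forward_full <- function(image, model, cmp1, cmp2) {
  h <- nrow(image); w <- ncol(image)
  oh <- (h - 3L) %/% 2L + 1L; ow <- (w - 3L) %/% 2L + 1L
  fm1 <- array(0, dim = c(oh, ow, 9L))
  patches1 <- vector("list", oh * ow)
  for (r in seq_len(oh)) for (c in seq_len(ow)) {
    p9 <- as.vector(t(image[(2 * r - 1):(2 * r + 1), (2 * c - 1):(2 * c + 1)]))
    patches1[[(r - 1L) * ow + c]] <- p9
    fm1[r, c, ] <- .quanv_forward(cmp1, p9)
  }
  fm1r <- (fm1 + 1) / 2
  if (model$mode == "spatial") {
    o2 <- (oh - 3L) %/% 2L + 1L
    fm2 <- array(0, dim = c(o2, o2, 81L))
    patches2 <- vector("list", 9L * o2 * o2)
    for (ch in 1:9) for (r in seq_len(o2)) for (c in seq_len(o2)) {
      p9 <- as.vector(t(fm1r[(2 * r - 1):(2 * r + 1),
                             (2 * c - 1):(2 * c + 1), ch]))
      patches2[[(ch - 1L) * o2 * o2 + (r - 1L) * o2 + c]] <- p9
      fm2[r, c, (ch - 1L) * 9L + 1:9] <- .quanv_forward(cmp2, p9)
    }
  } else {
    fm2 <- array(0, dim = c(oh, ow, 9L))
    patches2 <- vector("list", oh * ow)
    for (r in seq_len(oh)) for (c in seq_len(ow)) {
      p9 <- fm1r[r, c, ]
      patches2[[(r - 1L) * ow + c]] <- p9
      fm2[r, c, ] <- .quanv_forward(cmp2, p9)
    }
  }
  flat <- .flatten_fm(fm2)
  if (length(flat) != length(model$fc_weights))
    stop("flattened feature length ", length(flat),
         " does not match fc_weights (", length(model$fc_weights), ")")
  logit <- sum(model$fc_weights * flat) + model$fc_bias
  list(logit = logit, fm1 = fm1, fm1r = fm1r, fm2 = fm2, flat = flat,
       patches1 = patches1, patches2 = patches2, oh = oh, ow = ow)
}

#' Forward pass of the hybrid model
#'
#' quanvolve (layer 1) -> rescale -> layer 2 -> flatten (row-major,
#' channels fastest) -> dense head. Returns the raw logit; the loss is
#' computed with logits and [predict_label()] applies the sigmoid threshold.
#'
#' @param image Numeric matrix in `[0, 1]` (14x14 for the default pipeline).
#' @param model A `quanv_model` from [init_model()].
#' @return The scalar logit.
#' @export
model_forward <- function(image, model) {
  stopifnot(inherits(model, "quanv_model"))
  cmp1 <- .quanv_compiled(model$kernel1)
  cmp2 <- .quanv_compiled(model$kernel2)
  .quantum_forward_full(as.matrix(image), model, cmp1, cmp2)$logit
}

# loss + full gradient for one example; dlogit = sigmoid(z) - y
.quantum_grad_one <- function(image, label, model, cmp1, cmp2) {
  fw <- .quantum_forward_full(image, model, cmp1, cmp2)
  z <- fw$logit
  dlogit <- .sigmoid(z) - label
  g_w <- dlogit * fw$flat
  g_b <- dlogit
  g_fm2 <- .unflatten_fm(dlogit * model$fc_weights, dim(fw$fm2))
  g_k1 <- numeric(15); g_k2 <- numeric(15)
  g_fm1r <- array(0, dim = dim(fw$fm1))
  oh <- fw$oh; ow <- fw$ow
  if (model$mode == "spatial") {
    o2 <- dim(fw$fm2)[1]
    for (ch in 1:9) for (r in seq_len(o2)) for (c in seq_len(o2)) {
      coef <- g_fm2[r, c, (ch - 1L) * 9L + 1:9]
      p9 <- fw$patches2[[(ch - 1L) * o2 * o2 + (r - 1L) * o2 + c]]
      bw <- .quanv_backward(cmp2, p9, coef)
      g_k2 <- g_k2 + bw$slot_grad
      rows <- (2 * r - 1):(2 * r + 1); cols <- (2 * c - 1):(2 * c + 1)
      g_fm1r[rows, cols, ch] <- g_fm1r[rows, cols, ch] +
        matrix(bw$pixel_grad, 3, 3, byrow = TRUE)
    }
  } else {
    for (r in seq_len(oh)) for (c in seq_len(ow)) {
      coef <- g_fm2[r, c, ]
      p9 <- fw$patches2[[(r - 1L) * ow + c]]
      bw <- .quanv_backward(cmp2, p9, coef)
      g_k2 <- g_k2 + bw$slot_grad
      g_fm1r[r, c, ] <- g_fm1r[r, c, ] + bw$pixel_grad
    }
  }
  g_fm1 <- g_fm1r * 0.5  # rescale v -> (v+1)/2
  for (r in seq_len(oh)) for (c in seq_len(ow)) {
    coef <- g_fm1[r, c, ]
    bw <- .quanv_backward(cmp1, fw$patches1[[(r - 1L) * ow + c]], coef)
    g_k1 <- g_k1 + bw$slot_grad
  }
  list(loss = bce_with_logits(z, label), logit = z,
       grad = c(g_k1, g_k2, g_w, g_b))
}

# ---- shared Adam training loop ---------------------------------------------
# grad_fn(theta, image, label) -> list(loss, grad); logit_fn(theta, image)

.adam_init <- function(npar) list(m = numeric(npar), v = numeric(npar), t = 0L)

# one Adam step with bias correction; g already includes any weight decay
.adam_update <- function(state, theta, g, lr, b1 = 0.9, b2 = 0.999,
                         eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- b1 * state$m + (1 - b1) * g
  state$v <- b2 * state$v + (1 - b2) * g^2
  mh <- state$m / (1 - b1^state$t)
  vh <- state$v / (1 - b2^state$t)
  list(theta = theta - lr * mh / (sqrt(vh) + eps), state = state)
}

.adam_train <- function(theta, grad_fn, logit_fn, train, val, config) {
  n <- dim(train$images)[1]
  opt <- .adam_init(length(theta))
  lr <- config$learning_rate; wd <- config$weight_decay
  history <- vector("list", config$epochs)
  eval_set <- function(th, set) {
    logits <- vapply(seq_len(dim(set$images)[1]),
                     function(i) logit_fn(th, set$images[i, , ]), numeric(1))
    preds <- predict_label(logits, config$threshold)
    list(loss = mean(bce_with_logits(logits, set$labels)),
         acc = mean(preds == set$labels))
  }
  set.seed(config$seed)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      g <- numeric(length(theta))
      for (i in idx) {
        res <- grad_fn(theta, train$images[i, , ], train$labels[i])
        g <- g + res$grad
      }
      g <- g / length(idx) + wd * theta
      upd <- .adam_update(opt, theta, g, lr)
      theta <- upd$theta
      opt <- upd$state
    }
    tr <- eval_set(theta, train)
    vl <- if (!is.null(val)) eval_set(theta, val) else list(loss = NA_real_,
                                                            acc = NA_real_)
    history[[ep]] <- data.frame(epoch = ep, train_loss = tr$loss,
                                train_acc = tr$acc, val_loss = vl$loss,
                                val_acc = vl$acc)
  }
  list(theta = theta, history = do.call(rbind, history))
}

#' Training configuration
#'
#' Defaults follow the study protocol: Adam with learning rate 1e-2, weight
#' decay 1e-5 (applied as an L2 term to all parameters, quantum angles
#' included), batch size 10, 15 epochs, sigmoid threshold 0.5.
#'
#' @param learning_rate Adam step size.
#' @param weight_decay L2 coefficient added to every gradient.
#' @param batch_size Minibatch size.
#' @param epochs Number of passes over the training set.
#' @param seed Integer seed controlling initialization and batch shuffling.
#' @param layer2_mode `"spatial"` or `"stacked"` (see [quanv_layer2()]).
#' @param threshold Decision threshold in (0, 1).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-2, weight_decay = 1e-5,
                         batch_size = 10L, epochs = 15L, seed = 1L,
                         layer2_mode = c("spatial", "stacked"),
                         threshold = 0.5) {
  layer2_mode <- match.arg(layer2_mode)
  if (learning_rate <= 0 || batch_size < 1L || epochs < 1L)
    stop("rates and sizes must be positive")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 layer2_mode = layer2_mode, threshold = threshold),
            class = "train_config")
}

.check_train_set <- function(set) {
  if (is.null(set) || dim(set$images)[1] == 0L) stop("empty split")
  if (!all(set$labels %in% c(0L, 1L))) stop("labels must be binary")
}

#' Train the hybrid quanvolutional classifier
#'
#' Minibatch Adam on BCE-with-logits over all 355 parameters (30 quantum
#' angles + 325 dense), with epoch-end loss/accuracy over the full training
#' and validation sets. Fully reproducible: initialization and shuffling
#' derive from `config$seed`.
#'
#' @param train,val `labeled_image_set`s (validation optional).
#' @param config A [train_config()].
#' @return List with `model` (a `quanv_model`) and `history` (one data.frame
#'   row per epoch: epoch, train_loss, train_acc, val_loss, val_acc).
#' @export
train_model <- function(train, val = NULL, config = train_config()) {
  .check_train_set(train)
  model0 <- init_model(config$seed, config$layer2_mode)
  mode <- config$layer2_mode
  grad_fn <- function(theta, image, label) {
    mdl <- .unpack_quantum(theta, mode)
    .quantum_grad_one(image, label, mdl,
                      .quanv_compiled(mdl$kernel1), .quanv_compiled(mdl$kernel2))
  }
  logit_fn <- function(theta, image)
    model_forward(image, .unpack_quantum(theta, mode))
  res <- .adam_train(.pack_quantum(model0), grad_fn, logit_fn, train, val,
                     config)
  list(model = .unpack_quantum(res$theta, mode), history = res$history)
}

#' Evaluate a model on a labeled split
#'
#' Runs the forward pass on every image, thresholds the sigmoid scores and
#' builds a classification report.
#'
#' @param model A `quanv_model` or `cnn_model`.
#' @param set A `labeled_image_set`.
#' @param threshold Decision threshold.
#' @return List with `logits`, `predictions`, `accuracy`, `loss`, `report`
#'   (a [class_report()]).
#' @export
evaluate_model <- function(model, set, threshold = 0.5) {
  fwd <- if (inherits(model, "cnn_model")) {
    function(img) baseline_forward(img, model)
  } else {
    function(img) model_forward(img, model)
  }
  logits <- vapply(seq_len(dim(set$images)[1]),
                   function(i) fwd(set$images[i, , ]), numeric(1))
  preds <- predict_label(logits, threshold)
  list(logits = logits, predictions = preds,
       accuracy = mean(preds == set$labels),
       loss = mean(bce_with_logits(logits, set$labels)),
       report = class_report(confusion(set$labels, preds)))
}

#' Count trainable parameters per architecture
#'
#' @param mode `"spatial"`, `"stacked"` (hybrid quantum model) or
#'   `"classical"` (the CNN baseline).
#' @return Named list: extractor, dense head and total parameter counts.
#' @export
param_count <- function(mode = c("spatial", "stacked", "classical")) {
  mode <- match.arg(mode)
  if (mode == "classical") {
    list(conv_layers = 2L * (9L * 9L + 9L), dense_head = 36L + 1L,
         total = 180L + 37L)
  } else {
    list(quantum_extractor = 30L, dense_head = 324L + 1L, total = 355L)
  }
}

# ---- checkpoints ------------------------------------------------------------

#' Save a trained model as a flat JSON checkpoint
#'
#' Layout: `format`, `model_type`, arrays `kernel1`/`kernel2`/`fc_weights`/
#' `fc_bias` (quantum) or `W1`/`b1`/`W2`/`b2`/`fc_weights`/`fc_bias` with
#' dims (classical), plus `config`, `history` and the saved RNG state.
#'
#' @param model A `quanv_model` or `cnn_model`.
#' @param path Output file.
#' @param config Optional [train_config()] to embed.
#' @param history Optional epoch history data.frame.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, config = NULL, history = NULL) {
  is_q <- inherits(model, "quanv_model")
  obj <- list(format = "quanvnet-checkpoint-1",
              model_type = if (is_q) "quantum" else "classical",
              mode = model$mode)
  if (is_q) {
    obj$kernel1 <- model$kernel1; obj$kernel2 <- model$kernel2
    obj$fc_weights <- model$fc_weights; obj$fc_bias <- model$fc_bias
  } else {
    obj$W1 <- as.vector(model$W1); obj$b1 <- model$b1
    obj$W2 <- as.vector(model$W2); obj$b2 <- model$b2
    obj$fc_weights <- model$fc_weights; obj$fc_bias <- model$fc_bias
  }
  if (!is.null(config)) obj$config <- unclass(config)
  if (!is.null(history)) obj$history <- history
  if (exists(".Random.seed", envir = globalenv()))
    obj$rng_state <- get(".Random.seed", envir = globalenv())
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path Checkpoint file.
#' @return List with `model`, `config` (or NULL) and `history` (or NULL).
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "quanvnet-checkpoint-1"))
    stop("not a quanvnet checkpoint: ", path)
  model <- if (obj$model_type == "quantum") {
    structure(list(kernel1 = obj$kernel1, kernel2 = obj$kernel2,
                   fc_weights = obj$fc_weights, fc_bias = obj$fc_bias,
                   mode = obj$mode),
              class = "quanv_model")
  } else {
    structure(list(W1 = array(obj$W1, dim = c(3, 3, 9)), b1 = obj$b1,
                   W2 = array(obj$W2, dim = c(3, 3, 9)), b2 = obj$b2,
                   fc_weights = obj$fc_weights, fc_bias = obj$fc_bias,
                   mode = obj$mode),
              class = "cnn_model")
  }
  cfg <- if (!is.null(obj$config)) {
    do.call(train_config, obj$config[setdiff(names(obj$config), NULL)])
  } else NULL
  list(model = model, config = cfg, history = obj$history)
}
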