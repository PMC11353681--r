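# Hybrid classifier: loss, thresholding, forward pass, Adam training loop
# and the architecture-matched CNN baseline.

make_separable_set <- function(n = 20, seed = 99) {
  # two trivially separable image families: bright top half vs bright bottom
  set.seed(seed)
  images <- array(0, dim = c(n, 14, 14))
  labels <- rep(0:1, length.out = n)
  for (i in seq_len(n)) {
    img <- matrix(runif(196, 0, 0.15), 14, 14)
    if (labels[i] == 1L) img[1:7, ] <- img[1:7, ] + 0.8
    else img[8:14, ] <- img[8:14, ] + 0.8
    images[i, , ] <- pmin(img, 1)
  }
  labeled_image_set(images, labels)
}

test_that("bce_with_logits matches closed forms and is symmetric", {
  expect_equal(bce_with_logits(0, 1), log(2), tolerance = 1e-12)
  expect_equal(bce_with_logits(20, 1), log1p(exp(-20)), tolerance = 1e-15)
  expect_equal(bce_with_logits(20, 1), 2.061154e-09, tolerance = 1e-6)
  for (z in c(-3, -0.5, 0.2, 7)) {
    expect_equal(bce_with_logits(z, 1), bce_with_logits(-z, 0),
                 tolerance = 1e-12)
    expect_gte(bce_with_logits(z, 1), 0)
  }
  # no overflow for extreme logits
  expect_true(is.finite(bce_with_logits(800, 0)))
  expect_error(bce_with_logits(0, 2), "0 or 1")
})

test_that("predict_label thresholds the sigmoid with ties to class 0", {
  expect_equal(predict_label(0, 0.5), 0L)   # sigmoid(0) = 0.5, not > 0.5
  expect_equal(predict_label(3), 1L)
  expect_equal(predict_label(-3), 0L)
  expect_equal(predict_label(c(-1, 0, 1)), c(0L, 0L, 1L))
  expect_error(predict_label(0, 1.5), "\\(0, 1\\)")
})

test_that("zero dense weights give logit equal to the bias", {
  m <- init_model(1)
  m$fc_weights <- rep(0, 324)
  m$fc_bias <- 0.73
  expect_equal(model_forward(fixture_image(), m), 0.73, tolerance = 1e-12)
  expect_true(is.finite(model_forward(fixture_image(7), init_model(2))))
})

test_that("forward pass composes the module-level pieces", {
  set.seed(31)
  m <- init_model(31)
  img <- fixture_image(5)
  fm1 <- quanvolve_image(img, m$kernel1)
  fm2 <- quanv_layer2(rescale_map(fm1), m$kernel2, mode = "spatial")
  flat <- as.vector(aperm(unclass(fm2), c(3, 2, 1)))
  expect_equal(model_forward(img, m),
               sum(m$fc_weights * flat) + m$fc_bias, tolerance = 1e-10)
  # stacked mode too
  ms <- init_model(31, mode = "stacked")
  fm2s <- quanv_layer2(rescale_map(quanvolve_image(img, ms$kernel1)),
                       ms$kernel2, mode = "stacked")
  flats <- as.vector(aperm(unclass(fm2s), c(3, 2, 1)))
  expect_equal(model_forward(img, ms),
               sum(ms$fc_weights * flats) + ms$fc_bias, tolerance = 1e-10)
})

test_that("optimizer gradients match finite differences on a frozen minibatch", {
  set.seed(17)
  img <- fixture_image(17)
  for (mode in c("spatial", "stacked")) {
    m <- init_model(17, mode = mode)
    theta <- c(m$kernel1, m$kernel2, m$fc_weights, m$fc_bias)
    gr <- quanvnet:::.quantum_grad_one(
      img, 1, m, quanvnet:::.quanv_compiled(m$kernel1),
      quanvnet:::.quanv_compiled(m$kernel2))
    idx <- c(1, 7, 15, 16, 23, 30, 31, 200, 355)  # both kernels + head
    fd <- vapply(idx, function(i) {
      h <- 1e-5
      tp <- theta; tp[i] <- tp[i] + h
      tm <- theta; tm[i] <- tm[i] - h
      (bce_with_logits(model_forward(img, quanvnet:::.unpack_quantum(tp, mode)), 1) -
         bce_with_logits(model_forward(img, quanvnet:::.unpack_quantum(tm, mode)), 1)) /
        (2 * h)
    }, numeric(1))
    expect_lt(max(abs(gr$grad[idx] - fd)), 1e-5)
  }
})

test_that("one Adam step with zero loss gradient follows the closed-form decay update", {
  # with a zero loss gradient the step sees only g = wd * theta; after bias
  # correction the t=1 update is theta - lr * g / (|g| + eps)
  lr <- 1e-2; wd <- 1e-5; eps <- 1e-8
  theta <- c(0.5, -2, 0, 4)
  g <- wd * theta
  expected <- theta - lr * g / (abs(g) + eps)
  upd <- quanvnet:::.adam_update(quanvnet:::.adam_init(4), theta, g, lr)
  expect_equal(upd$theta, expected, tolerance = 1e-12)
  # decay shrinks magnitudes, leaves exact zeros alone
  expect_true(all(abs(upd$theta[theta != 0]) < abs(theta[theta != 0])))
  expect_equal(upd$theta[3], 0)
})

test_that("training is deterministic and overfits a separable set", {
  set <- make_separable_set(20)
  cfg <- train_config(epochs = 30, seed = 4, batch_size = 10)
  fit1 <- train_model(set, val = NULL, config = cfg)
  expect_equal(nrow(fit1$history), 30L)
  expect_equal(fit1$history$train_acc[30], 1.0)
  # loss decreased from the untrained model
  m0 <- init_model(cfg$seed, cfg$layer2_mode)
  loss0 <- mean(vapply(seq_len(20), function(i)
    bce_with_logits(model_forward(set$images[i, , ], m0), set$labels[i]),
    numeric(1)))
  expect_lt(fit1$history$train_loss[1], loss0)
  # bitwise-identical rerun
  fit2 <- train_model(set, val = NULL, config = cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model$kernel1, fit2$model$kernel1)
})

test_that("training rejects degenerate inputs", {
  set <- make_separable_set(4)
  bad <- set; bad$labels <- c(0L, 2L, 1L, 0L)
  expect_error(train_model(bad, config = train_config(epochs = 1)), "binary")
  empty <- labeled_image_set(array(0, dim = c(0, 14, 14)), integer(0))
  expect_error(train_model(empty, config = train_config(epochs = 1)), "empty")
})

test_that("baseline CNN has the mirrored shape arithmetic", {
  m <- init_baseline(3)
  img <- fixture_image(3)
  fw <- quanvnet:::.cnn_forward_full(img, m)
  expect_equal(dim(fw$a1), c(6L, 6L, 9L))
  expect_equal(dim(fw$a2), c(2L, 2L, 9L))
  expect_length(fw$flat, 36L)
  zero <- m
  zero$W1[] <- 0; zero$b1[] <- 0; zero$W2[] <- 0; zero$b2[] <- 0
  zero$fc_weights[] <- 0; zero$fc_bias <- 1.5
  expect_equal(baseline_forward(img, zero), 1.5, tolerance = 1e-12)
})

test_that("baseline CNN gradients match finite differences", {
  set.seed(23)
  m <- init_baseline(23)
  img <- fixture_image(23)
  theta <- quanvnet:::.pack_cnn(m)
  gr <- quanvnet:::.cnn_grad_one(img, 0, m)
  idx <- sample(length(theta), 5)
  fd <- vapply(idx, function(i) {
    h <- 1e-6
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (bce_with_logits(baseline_forward(img, quanvnet:::.unpack_cnn(tp)), 0) -
       bce_with_logits(baseline_forward(img, quanvnet:::.unpack_cnn(tm)), 0)) /
      (2 * h)
  }, numeric(1))
  expect_lt(max(abs(gr$grad[idx] - fd)), 1e-5)
})

test_that("baseline training runs, is deterministic, and learns the separable set", {
  set <- make_separable_set(20)
  cfg <- train_config(epochs = 25, seed = 6)
  fit <- train_baseline(set, config = cfg)
  expect_equal(nrow(fit$history), 25L)
  expect_gte(fit$history$train_acc[25], 0.9)
  fit2 <- train_baseline(set, config = cfg)
  expect_identical(fit$history, fit2$history)
})

test_that("parameter audit: 30 quantum + 325 dense = 355; baseline 217", {
  pc <- param_count("spatial")
  expect_equal(pc$quantum_extractor, 30L)
  expect_equal(pc$dense_head, 325L)
  expect_equal(pc$total, 355L)
  expect_equal(param_count("stacked")$total, 355L)
  pb <- param_count("classical")
  expect_equal(pb$total, 217L)
  expect_length(quanvnet:::.pack_quantum(init_model(1)), 355L)
  expect_length(quanvnet:::.pack_cnn(init_baseline(1)), 217L)
})

test_that("checkpoints round-trip models, config and history", {
  set <- make_separable_set(4)
  cfg <- train_config(epochs = 1, seed = 2, batch_size = 2)
  fit <- train_model(set, config = cfg)
  path <- tempfile(fileext = ".json")
  save_checkpoint(fit$model, path, config = cfg, history = fit$history)
  back <- load_checkpoint(path)
  expect_equal(back$model$kernel1, fit$model$kernel1, tolerance = 1e-12)
  expect_equal(back$model$fc_weights, fit$model$fc_weights, tolerance = 1e-12)
  expect_equal(back$config$learning_rate, cfg$learning_rate)
  expect_equal(back$history$train_acc, fit$history$train_acc,
               tolerance = 1e-12)
  img <- fixture_image()
  expect_equal(model_forward(img, back$model), model_forward(img, fit$model),
               tolerance = 1e-10)
  # classical checkpoint too
  fitc <- train_baseline(set, config = cfg)
  pathc <- tempfile(fileext = ".json")
  save_checkpoint(fitc$model, pathc)
  backc <- load_checkpoint(pathc)
  expect_equal(baseline_forward(img, backc$model),
               baseline_forward(img, fitc$model), tolerance = 1e-10)
})

test_that("evaluate_model reports accuracy and a classification report", {
  set <- make_separable_set(10)
  m <- init_model(5)
  res <- evaluate_model(m, set)
  expect_length(res$logits, 10L)
  expect_true(all(res$predictions %in% c(0L, 1L)))
  expect_equal(res$accuracy, mean(res$predictions == set$labels))
  expect_s3_class(res$report, "class_report")
  # higher threshold can never add positives
  res_hi <- evaluate_model(m, set, threshold = 0.9)
  expect_true(all(res_hi$predictions <= res$predictions))
})
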