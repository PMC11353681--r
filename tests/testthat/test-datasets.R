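# Data handling: archive loading, preprocessing, balanced subsetting and the
# synthetic ultrasound generator.

# build a small MedMNIST-layout .npz with deterministic contents using the
# system numpy (the archive format is produced by numpy in the first place)
make_npz_fixture <- function(path, n_train = 14, n_val = 2, n_test = 4) {
  script <- sprintf(paste0(
    "import numpy as np\n",
    "def imgs(n, off):\n",
    "    return ((np.arange(n*28*28).reshape(n,28,28) + off) %% 256).astype('uint8')\n",
    "def labs(n, off):\n",
    "    return ((np.arange(n) + off) %% 3).astype('uint8').reshape(n,1)\n",
    "np.savez('%s', train_images=imgs(%d,0), train_labels=labs(%d,0),\n",
    "         val_images=imgs(%d,7), val_labels=labs(%d,1),\n",
    "         test_images=imgs(%d,11), test_labels=labs(%d,2))\n"),
    path, n_train, n_train, n_val, n_val, n_test, n_test)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", sf, stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0L)
  path
}

test_that("the MedMNIST archive loader scales, binarizes and keeps split sizes", {
  npz <- make_npz_fixture(tempfile(fileext = ".npz"))
  splits <- load_medmnist_archive(npz)
  expect_named(splits, c("train", "val", "test"))
  expect_equal(dim(splits$train$images), c(14L, 28L, 28L))
  expect_equal(dim(splits$val$images), c(2L, 28L, 28L))
  expect_equal(dim(splits$test$images), c(4L, 28L, 28L))
  # uint8 -> [0,1]; fixture pixel (i,r,c) = ((i-1)*784 + (r-1)*28 + (c-1)) mod 256
  expect_equal(splits$train$images[1, 1, 5], 4 / 255, tolerance = 1e-12)
  expect_equal(splits$train$images[2, 3, 1], (784 + 2 * 28) %% 256 / 255,
               tolerance = 1e-12)
  # labels (0,1,2,...) with malignant_code 0: 0 -> 0, 1/2 -> 1
  expect_equal(splits$train$labels, as.integer(((0:13) %% 3) != 0))
  expect_equal(splits$val$labels[1], 1L)  # raw code 1 -> positive
  # alternate malignant code
  alt <- load_medmnist_archive(npz, malignant_code = 2L)
  expect_equal(alt$train$labels, as.integer(((0:13) %% 3) != 2))
})

test_that("the loader rejects incomplete archives", {
  bad <- tempfile(fileext = ".npz")
  script <- sprintf(
    "import numpy as np\nnp.savez('%s', train_images=np.zeros((2,4,4),dtype='uint8'))\n",
    bad)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  stopifnot(system2("python", sf, stdout = FALSE, stderr = FALSE) == 0L)
  expect_error(load_medmnist_archive(bad), "missing arrays")
  expect_error(load_medmnist_archive(tempfile()), "not found")
})

test_that("split arithmetic: 780 images at 7:1:2 give 546/78/156", {
  sizes <- split_sizes(780)
  expect_equal(unname(sizes), c(546L, 78L, 156L))
  expect_equal(unname(split_sizes(780)["train"]), 546L)
  expect_equal(780L - 546L - 78L, 156L)
  # largest-remainder apportionment always conserves the total
  for (n in c(1, 7, 99, 101, 780)) expect_equal(sum(split_sizes(n)), n)
  set.seed(1)
  s <- labeled_image_set(array(runif(20 * 4 * 4), c(20, 4, 4)),
                         rep(0:1, 10))
  sp <- split_dataset(s, seed = 3)
  expect_equal(vapply(sp, function(x) dim(x$images)[1], integer(1)),
               c(train = 14L, val = 2L, test = 4L))
})

test_that("downsample_2x is non-overlapping 2x2 mean pooling", {
  expect_equal(downsample_2x(matrix(0.3, 6, 6)), matrix(0.3, 3, 3))
  blk <- matrix(c(0, 1, 0, 1), 2, 2)  # block mean 0.5
  expect_equal(downsample_2x(blk), matrix(0.5, 1, 1))
  checker <- outer(1:28, 1:28, function(r, c) (r + c) %% 2)
  expect_equal(downsample_2x(checker), matrix(0.5, 14, 14))
  expect_error(downsample_2x(matrix(0, 3, 4)), "even")
  # batch and set forms
  arr <- array(runif(3 * 28 * 28), c(3, 28, 28))
  out <- downsample_2x(arr)
  expect_equal(dim(out), c(3L, 14L, 14L))
  expect_equal(out[2, , ], downsample_2x(arr[2, , ]))
  s <- labeled_image_set(arr, c(0, 1, 0))
  expect_equal(dim(downsample_2x(s)$images), c(3L, 14L, 14L))
})

test_that("normalization maps to [0,1], is idempotent, and zeroes constants", {
  x <- matrix(c(-2, 0, 3, 8), 2, 2)
  nx <- normalize_images(x)
  expect_equal(min(nx), 0)
  expect_equal(max(nx), 1)
  already <- matrix(c(0, 0.25, 0.5, 1), 2, 2)
  expect_equal(normalize_images(already), already, tolerance = 1e-12)
  expect_equal(normalize_images(matrix(5, 3, 3)), matrix(0, 3, 3))
  expect_error(normalize_images(numeric(0)), "empty")
})

test_that("balanced_subset keeps the minority class whole and is seeded", {
  set.seed(2)
  s <- labeled_image_set(array(runif(140 * 2 * 2), c(140, 2, 2)),
                         c(rep(1L, 100), rep(0L, 40)))
  b <- balanced_subset(s, seed = 5)
  expect_equal(sum(b$labels == 0), 40L)
  expect_equal(sum(b$labels == 1), 40L)
  b2 <- balanced_subset(s, seed = 5)
  expect_identical(b$images, b2$images)
  expect_identical(b$labels, b2$labels)
  # balanced input returned unchanged up to shuffle
  eq <- labeled_image_set(array(runif(8 * 2 * 2), c(8, 2, 2)),
                          rep(0:1, each = 4))
  be <- balanced_subset(eq, seed = 1)
  expect_equal(sort(as.vector(be$images)), sort(as.vector(eq$images)))
  one <- labeled_image_set(array(runif(4 * 2 * 2), c(4, 2, 2)), rep(1L, 4))
  expect_error(balanced_subset(one, 1), "both classes")
})

test_that("the synthetic generator is deterministic with forced class counts", {
  cfg <- synth_config(n_images = 100, class_balance = 0.5, seed = 7)
  s1 <- generate_synthetic(cfg)
  expect_equal(sum(s1$labels == 1), 50L)
  expect_equal(sum(s1$labels == 0), 50L)
  expect_true(all(s1$images >= 0 & s1$images <= 1))
  s2 <- generate_synthetic(cfg)
  expect_identical(s1$images, s2$images)
  expect_identical(s1$labels, s2$labels)
  expect_equal(dim(attr(s1, "masks")), c(100L, 28L, 28L))
})

test_that("zero irregularity collapses both classes to the ellipse family", {
  cfg <- synth_config(n_images = 60, irregularity = 0, seed = 3)
  s <- generate_synthetic(cfg)
  f <- mask_features(attr(s, "masks"))
  # same shape family: roughness distributions are statistically indistinct
  expect_lt(abs(mean(f$roughness[s$labels == 0]) -
                  mean(f$roughness[s$labels == 1])), 0.03)
})

test_that("spiculated lesions are rougher than smooth ones by construction", {
  cfg <- synth_config(n_images = 200, irregularity = 0.4, seed = 11)
  s <- generate_synthetic(cfg)
  f <- mask_features(attr(s, "masks"))
  expect_gt(mean(f$roughness[s$labels == 0]),
            mean(f$roughness[s$labels == 1]))
})

test_that("hand-crafted mask features linearly separate the synthetic classes", {
  cfg <- synth_config(n_images = 200, seed = 19)
  s <- generate_synthetic(cfg)
  d <- cbind(y = s$labels, mask_features(attr(s, "masks")))
  fit <- suppressWarnings(glm(y ~ area + roughness, data = d,
                              family = binomial))
  acc <- mean((predict(fit, type = "response") > 0.5) == (d$y == 1))
  expect_gt(acc, 0.9)
})

test_that("PNG directory round-trip preserves images and labels", {
  cfg <- synth_config(n_images = 6, seed = 2)
  s <- generate_synthetic(cfg)
  dir <- tempfile("imgdir")
  write_image_dir(s, dir)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  back <- read_image_dir(dir)
  expect_equal(back$labels, s$labels)
  # PNG stores 8 or 16 bit; round-trip agrees to quantization error
  expect_lt(max(abs(back$images - s$images)), 1 / 255)
  expect_error(read_image_dir(tempfile()), "labels.csv")
})
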