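# Data handling: BreastMNIST-compatible .npz archives, preprocessing
# (2x mean-pool downsampling, min-max normalization, balanced subsetting),
# a synthetic speckled-ultrasound lesion generator, and PNG-directory I/O.

#' Labeled image set
#'
#' @param images Numeric array N x H x W with values in `[0, 1]`.
#' @param labels Integer vector of 0/1 labels; 1 = normal/benign (positive
#'   class), 0 = malignant.
#' @param split_name One of `"train"`, `"val"`, `"test"`.
#' @return An object of class `labeled_image_set`.
#' @export
labeled_image_set <- function(images, labels, split_name = "train") {
  if (length(dim(images)) != 3L) stop("images must be an N x H x W array")
  labels <- as.integer(labels)
  if (dim(images)[1] != length(labels))
    stop("images and labels disagree in length")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary")
  if (anyNA(images) || any(images < 0 | images > 1))
    stop("image values must lie in [0, 1]")
  if (!split_name %in% c("train", "val", "test"))
    stop("split_name must be train, val or test")
  structure(list(images = images, labels = labels, split_name = split_name),
            class = "labeled_image_set")
}

#' @export
print.labeled_image_set <- function(x, ...) {
  d <- dim(x$images)
  cat("<labeled_image_set>", x$split_name, ":", d[1], "images", d[2], "x",
      d[3], "; positives", sum(x$labels), "/", d[1], "\n")
  invisible(x)
}

# ---- minimal .npy / .npz reading -------------------------------------------
# No installed R package parses the numpy container formats, so the small
# subset needed here (v1/v2 headers; u1/i1/u2/i2/i4/i8/f4/f8, C or Fortran
# order) is read directly.

.read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(as.integer(magic),
                 as.integer(c(0x93, charToRaw("NUMPY")))))
    stop("not a .npy file: ", path)
  ver <- readBin(con, "raw", 2)
  hlen <- if (as.integer(ver[1]) >= 2L) {
    readBin(con, "integer", 1, size = 4, endian = "little")
  } else {
    readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  }
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_s <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1]])
  shape <- shape[!is.na(shape)]
  n <- if (length(shape)) prod(shape) else 1L
  code <- sub("^[<>|=]", "", descr)
  little <- !grepl("^>", descr)
  endian <- if (little) "little" else "big"
  data <- switch(code,
    u1 = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    i1 = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE)),
    u2 = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                            endian = endian)),
    i2 = as.numeric(readBin(con, "integer", n, size = 2, endian = endian)),
    i4 = as.numeric(readBin(con, "integer", n, size = 4, endian = endian)),
    i8 = stop("64-bit integer arrays are not supported: ", path),
    f4 = readBin(con, "numeric", n, size = 4, endian = endian),
    f8 = readBin(con, "numeric", n, size = 8, endian = endian),
    stop("unsupported dtype in ", path, ": ", descr)
  )
  if (length(shape) <= 1L) return(data)
  if (fortran) {
    array(data, dim = shape)
  } else {
    aperm(array(data, dim = rev(shape)), rev(seq_along(shape)))
  }
}

#' Load a MedMNIST-format .npz archive as binary-labeled splits
#'
#' Reads the six arrays `train_images`, `train_labels`, `val_images`,
#' `val_labels`, `test_images`, `test_labels`, scales uint8 pixels to
#' `[0, 1]` and binarizes the class labels: the malignant code maps to 0,
#' everything else (normal/benign) to the positive class 1. Split sizes are
#' preserved as shipped (546/78/156 for BreastMNIST's 780 images at 7:1:2).
#'
#' @param path Path to the `.npz` archive.
#' @param malignant_code Integer label code of the malignant class in the
#'   archive (0 in BreastMNIST).
#' @return Named list of three [labeled_image_set()]s: `train`, `val`, `test`.
#' @export
load_medmnist_archive <- function(path, malignant_code = 0L) {
  if (!file.exists(path)) stop("archive not found: ", path)
  exdir <- tempfile("npz")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  files <- utils::unzip(path, exdir = exdir)
  need <- c("train_images", "train_labels", "val_images", "val_labels",
            "test_images", "test_labels")
  have <- sub("\\.npy$", "", basename(files))
  if (!all(need %in% have))
    stop("archive is missing arrays: ",
         paste(setdiff(need, have), collapse = ", "))
  get <- function(nm) .read_npy(files[match(paste0(nm, ".npy"), basename(files))])
  out <- list()
  for (split in c("train", "val", "test")) {
    imgs <- get(paste0(split, "_images"))
    labs <- get(paste0(split, "_labels"))
    if (length(dim(imgs)) == 4L) {
      if (dim(imgs)[4] == 1L) imgs <- array(imgs, dim = dim(imgs)[1:3])
      else stop("non-grayscale input: ", split, " images have ",
                dim(imgs)[4], " channels")
    }
    if (length(dim(imgs)) != 3L) stop("unexpected image array rank")
    if (max(imgs) > 1) imgs <- imgs / 255
    labs <- as.integer(as.vector(labs))
    out[[split]] <- labeled_image_set(imgs,
                                      as.integer(labs != malignant_code),
                                      split)
  }
  out
}

#' Downsample an image (or batch) by 2x mean pooling
#'
#' Non-overlapping 2x2 blocks are averaged, halving each spatial dimension
#' (28x28 -> 14x14); values stay in `[0, 1]`.
#'
#' @param x H x W matrix with even dims, or an N x H x W array, or a
#'   `labeled_image_set`.
#' @return Object of the same kind at half resolution.
#' @export
downsample_2x <- function(x) {
  pool1 <- function(img) {
    h <- nrow(img); w <- ncol(img)
    if (h %% 2L || w %% 2L) stop("dimensions must be even for 2x pooling")
    0.25 * (img[seq(1, h, 2), seq(1, w, 2), drop = FALSE] +
            img[seq(2, h, 2), seq(1, w, 2), drop = FALSE] +
            img[seq(1, h, 2), seq(2, w, 2), drop = FALSE] +
            img[seq(2, h, 2), seq(2, w, 2), drop = FALSE])
  }
  if (inherits(x, "labeled_image_set")) {
    d <- dim(x$images)
    out <- array(0, dim = c(d[1], d[2] %/% 2L, d[3] %/% 2L))
    for (i in seq_len(d[1])) out[i, , ] <- pool1(x$images[i, , ])
    return(labeled_image_set(out, x$labels, x$split_name))
  }
  if (is.matrix(x)) return(pool1(x))
  if (length(dim(x)) == 3L) {
    d <- dim(x)
    out <- array(0, dim = c(d[1], d[2] %/% 2L, d[3] %/% 2L))
    for (i in seq_len(d[1])) out[i, , ] <- pool1(x[i, , ])
    return(out)
  }
  stop("x must be a matrix, an N x H x W array or a labeled_image_set")
}

#' Min-max normalize images to [0, 1]
#'
#' Global (per-dataset) min-max rescaling; a constant input maps to all
#' zeros. Data already spanning `[0, 1]` pass through unchanged.
#'
#' @param images Numeric matrix/array, or a `labeled_image_set`.
#' @return The same kind of object with values in `[0, 1]`.
#' @export
normalize_images <- function(images) {
  if (inherits(images, "labeled_image_set")) {
    return(labeled_image_set(normalize_images(images$images), images$labels,
                             images$split_name))
  }
  if (length(images) == 0L) stop("empty input")
  lo <- min(images); hi <- max(images)
  if (hi == lo) return(images * 0)
  (images - lo) / (hi - lo)
}

#' Nearly balanced training subset
#'
#' Keeps every minority-class item plus an equal-count uniform random sample
#' of the majority class, then shuffles the order; both draws are governed by
#' `seed`.
#'
#' @param set A `labeled_image_set` containing both classes.
#' @param seed Integer seed.
#' @return A balanced `labeled_image_set`.
#' @export
balanced_subset <- function(set, seed) {
  stopifnot(inherits(set, "labeled_image_set"))
  pos <- which(set$labels == 1L); neg <- which(set$labels == 0L)
  if (!length(pos) || !length(neg)) stop("both classes must be present")
  set.seed(as.integer(seed))
  if (length(pos) > length(neg)) {
    keep <- c(sample(pos, length(neg)), neg)
  } else if (length(neg) > length(pos)) {
    keep <- c(pos, sample(neg, length(pos)))
  } else {
    keep <- c(pos, neg)
  }
  keep <- sample(keep)
  labeled_image_set(set$images[keep, , , drop = FALSE], set$labels[keep],
                    set$split_name)
}

#' Split sizes for an n-image dataset at a fixed ratio
#'
#' Largest-remainder apportionment of `n` into the ratio parts (default
#' 7:1:2, the train/val/test convention), so 780 images yield 546/78/156.
#'
#' @param n Total number of images.
#' @param ratio Positive weights, one per split.
#' @return Integer vector summing to `n`, named train/val/test for
#'   three-way ratios.
#' @export
split_sizes <- function(n, ratio = c(7, 1, 2)) {
  q <- n * ratio / sum(ratio)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base <- as.integer(base)
  if (length(ratio) == 3L) names(base) <- c("train", "val", "test")
  base
}

#' Deterministically split a set into train/val/test
#'
#' @param set A `labeled_image_set`.
#' @param ratio Split weights; default 7:1:2.
#' @param seed Seed for the shuffle before splitting.
#' @return Named list of `labeled_image_set`s.
#' @export
split_dataset <- function(set, ratio = c(7, 1, 2), seed = 1L) {
  stopifnot(inherits(set, "labeled_image_set"))
  n <- dim(set$images)[1]
  sizes <- split_sizes(n, ratio)
  set.seed(as.integer(seed))
  ord <- sample.int(n)
  out <- list(); at <- 0L
  for (k in seq_along(sizes)) {
    nm <- c("train", "val", "test")[k]
    idx <- ord[(at + 1L):(at + sizes[k])]
    at <- at + sizes[k]
    out[[nm]] <- labeled_image_set(set$images[idx, , , drop = FALSE],
                                   set$labels[idx], nm)
  }
  out
}

# ---- synthetic ultrasound generator ----------------------------------------

#' Configuration for the synthetic ultrasound generator
#'
#' @param n_images Number of images to generate.
#' @param class_balance Fraction of positive (benign) images, in (0, 1).
#' @param image_size Square image side; default 28.
#' @param speckle_scale Contrast of the multiplicative speckle field in
#'   `[0, 1]`; default 0.4.
#' @param irregularity Spicule amplitude of malignant lesion boundaries
#'   (fraction of the base radius); default 0.4.
#' @param seed Integer seed; the whole set is a deterministic function of
#'   this configuration.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_images, class_balance = 0.5, image_size = 28L,
                         speckle_scale = 0.4, irregularity = 0.4, seed = 1L) {
  if (n_images < 1L) stop("n_images must be positive")
  if (class_balance <= 0 || class_balance >= 1)
    stop("class_balance must be in (0, 1)")
  structure(list(n_images = as.integer(n_images),
                 class_balance = class_balance,
                 image_size = as.integer(image_size),
                 speckle_scale = speckle_scale,
                 irregularity = irregularity, seed = as.integer(seed)),
            class = "synth_config")
}

# 3x3 box blur with edge replication
.box_blur <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- m[c(1, 1:h, h), c(1, 1:w, w)]
  out <- matrix(0, h, w)
  for (dr in 0:2) for (dc in 0:2)
    out <- out + pad[(1 + dr):(h + dr), (1 + dc):(w + dc)]
  out / 9
}

#' Generate a synthetic speckled-ultrasound image set
#'
#' Emulates low-resolution breast-ultrasound statistics: a mid-gray echo
#' background under multiplicative squared-Rayleigh (exponential) speckle,
#' with one hypoechoic (dark) lesion per image. Positive-class (benign)
#' lesions are smooth filled ellipses with a blurred boundary; negative-class
#' (malignant) lesions modulate the same ellipse with angular spicules,
#' radius \eqn{r(\phi) = r_0(\phi)(1 + irregularity \cdot \sin(k\phi +
#' \phi_0))}, and a sharp boundary. The set is a deterministic function of
#' the configuration.
#'
#' @param cfg A [synth_config()].
#' @return A `labeled_image_set` with an additional `"masks"` attribute: an
#'   N x H x W logical array of ground-truth lesion masks.
#' @export
generate_synthetic <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_images; sz <- cfg$image_size
  n_pos <- round(n * cfg$class_balance)
  labels <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
  images <- array(0, dim = c(n, sz, sz))
  masks <- array(FALSE, dim = c(n, sz, sz))
  xs <- matrix(rep(seq_len(sz), each = sz), sz, sz)   # column index
  ys <- matrix(rep(seq_len(sz), times = sz), sz, sz)  # row index
  bg <- 0.60; lesion <- 0.08
  for (i in seq_len(n)) {
    cx <- sz / 2 + stats::runif(1, -1, 1)
    cy <- sz / 2 + stats::runif(1, -1, 1)
    a <- stats::runif(1, 0.23, 0.27) * sz
    b <- a * stats::runif(1, 0.82, 1.0)
    alpha <- stats::runif(1, 0, pi)
    k <- sample(4:6, 1)
    phi0 <- stats::runif(1, 0, 2 * pi)
    dx <- xs - cx; dy <- ys - cy
    r <- sqrt(dx^2 + dy^2)
    phi <- atan2(dy, dx)
    psi <- phi - alpha
    r_ell <- a * b / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
    if (labels[i] == 1L) {
      r_bound <- r_ell
      edge <- 3.0   # heavily blurred margin (px at native resolution)
    } else {
      r_bound <- r_ell * (1 + cfg$irregularity * sin(k * phi + phi0))
      edge <- 0.3   # sharp spiculated margin
    }
    m_soft <- 1 / (1 + exp(-(r_bound - r) / edge))
    intensity <- bg * (1 - m_soft) + lesion * m_soft
    speckle <- matrix(stats::rexp(sz * sz), sz, sz)  # squared-Rayleigh
    speckle <- .box_blur(.box_blur(speckle))         # correlated grains
    mult <- (1 - cfg$speckle_scale) + cfg$speckle_scale * speckle
    images[i, , ] <- pmin(pmax(intensity * mult, 0), 1)
    masks[i, , ] <- m_soft > 0.5
  }
  out <- labeled_image_set(images, labels, "train")
  attr(out, "masks") <- masks
  out
}

#' Shape features of lesion masks
#'
#' For each mask: fractional area and radial roughness (standard deviation /
#' mean of boundary-pixel distances from the mask centroid). Roughness
#' separates spiculated from smooth lesions by construction.
#'
#' @param masks N x H x W logical array (e.g. the `"masks"` attribute of
#'   [generate_synthetic()] output).
#' @return data.frame with columns `area`, `roughness`.
#' @export
mask_features <- function(masks) {
  n <- dim(masks)[1]
  out <- data.frame(area = numeric(n), roughness = numeric(n))
  for (i in seq_len(n)) {
    m <- masks[i, , ]
    out$area[i] <- mean(m)
    px <- which(m, arr.ind = TRUE)
    if (nrow(px) < 4L) { out$roughness[i] <- 0; next }
    h <- nrow(m); w <- ncol(m)
    shift <- function(mm, dr, dc) {
      res <- matrix(FALSE, h, w)
      rs <- max(1, 1 + dr):min(h, h + dr)
      cs <- max(1, 1 + dc):min(w, w + dc)
      res[rs, cs] <- mm[rs - dr, cs - dc]
      res
    }
    nb <- shift(m, 1, 0) & shift(m, -1, 0) & shift(m, 0, 1) & shift(m, 0, -1)
    boundary <- m & !nb
    bp <- which(boundary, arr.ind = TRUE)
    if (nrow(bp) < 4L) { out$roughness[i] <- 0; next }
    cen <- colMeans(px)
    d <- sqrt((bp[, 1] - cen[1])^2 + (bp[, 2] - cen[2])^2)
    out$roughness[i] <- stats::sd(d) / mean(d)
  }
  out
}

# ---- PNG directory I/O ------------------------------------------------------

#' Write a labeled image set as a directory of PNGs plus labels.csv
#'
#' @param set A `labeled_image_set`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_image_dir <- function(set, dir) {
  stopifnot(inherits(set, "labeled_image_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(set$images)[1]
  fnames <- sprintf("img_%04d.png", seq_len(n))
  for (i in seq_len(n))
    png::writePNG(set$images[i, , ], file.path(dir, fnames[i]))
  utils::write.csv(data.frame(filename = fnames, label = set$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a directory of PNGs with a labels.csv
#'
#' @param dir Directory containing `labels.csv` (columns filename, label)
#'   and the referenced grayscale PNG files.
#' @param split_name Split tag for the returned set.
#' @return A `labeled_image_set`.
#' @export
read_image_dir <- function(dir, split_name = "train") {
  csv <- file.path(dir, "labels.csv")
  if (!file.exists(csv)) stop("labels.csv not found in ", dir)
  tab <- utils::read.csv(csv, stringsAsFactors = FALSE)
  if (!all(c("filename", "label") %in% names(tab)))
    stop("labels.csv needs columns filename, label")
  first <- png::readPNG(file.path(dir, tab$filename[1]))
  if (length(dim(first)) == 3L) first <- first[, , 1]
  imgs <- array(0, dim = c(nrow(tab), nrow(first), ncol(first)))
  for (i in seq_len(nrow(tab))) {
    im <- png::readPNG(file.path(dir, tab$filename[i]))
    if (length(dim(im)) == 3L) im <- im[, , 1]
    imgs[i, , ] <- im
  }
  labeled_image_set(imgs, tab$label, split_name)
}
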