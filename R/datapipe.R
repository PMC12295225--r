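# Dataset handling: synthetic cell-image generation, the augmentation and
# normalization protocol, stratified splitting, Gaussian-noise perturbation
# and image-folder I/O.
#
# Images are (H, W, 3) arrays in \[0, 1\]. A labeled image set is a list with
# `images` (list of arrays), `labels` (integers in 1..C), `class_names` and
# `split`.

#' Channel normalization constants (ImageNet convention)
#' @return List with `mean` and `sd`, both length 3.
#' @export
norm_stats <- function() {
  list(mean = c(0.485, 0.456, 0.406), sd = c(0.229, 0.224, 0.225))
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specification for the synthetic cell-image generator
#'
#' The generator emulates four cell morphologies found in retinal pigment
#' epithelial cell cultures: fusiform (elongated spindle-shaped cells),
#' epithelioid (rounded blobs), cobblestone (dense polygonal tessellation)
#' and mixed (a blend of the others).
#'
#' @param num_classes Number of classes (4: fusiform, epithelioid,
#'   cobblestone, mixed).
#' @param per_class_count Images per class.
#' @param image_size Square image side.
#' @param elongation Axis ratio of fusiform cells.
#' @param blob_count Cell count for the epithelioid morphology.
#' @param tessellation_density Cells per image side for cobblestone.
#' @param noise_sd Background Gaussian noise standard deviation on the
#'   \[0, 1\] intensity scale.
#' @param seed Generator seed; the output is deterministic given the spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(num_classes = 4L, per_class_count = 16L,
                           image_size = 224L, elongation = 5,
                           blob_count = 12L, tessellation_density = 9L,
                           noise_sd = 0.05, seed = 1L) {
  stopifnot(num_classes >= 2, num_classes <= 4, per_class_count >= 1,
            image_size >= 16)
  structure(list(num_classes = as.integer(num_classes),
                 per_class_count = as.integer(per_class_count),
                 image_size = as.integer(image_size),
                 elongation = elongation, blob_count = as.integer(blob_count),
                 tessellation_density = as.integer(tessellation_density),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

draw_ellipses <- function(S, n_cells, a_range, elong, theta0 = NULL,
                          theta_jitter = pi) {
  gx <- matrix(seq_len(S), S, S)
  gy <- matrix(seq_len(S), S, S, byrow = TRUE)
  canvas <- matrix(0, S, S)
  if (is.null(theta0)) theta0 <- stats::runif(1, 0, pi)
  for (i in seq_len(n_cells)) {
    cx <- stats::runif(1, 0.05 * S, 0.95 * S)
    cy <- stats::runif(1, 0.05 * S, 0.95 * S)
    th <- theta0 + stats::runif(1, -theta_jitter, theta_jitter)
    a <- stats::runif(1, a_range[1], a_range[2]) * S
    b <- a / elong
    xr <- (gx - cx) * cos(th) + (gy - cy) * sin(th)
    yr <- -(gx - cx) * sin(th) + (gy - cy) * cos(th)
    r2 <- (xr / a)^2 + (yr / b)^2
    canvas <- pmax(canvas, exp(-3 * r2))
  }
  canvas
}

# fusiform cultures grow as locally aligned bundles of thin spindles
draw_fusiform <- function(S, elong) {
  n <- stats::rpois(1, 24) + 12
  draw_ellipses(S, n, c(0.08, 0.16), elong,
                theta0 = stats::runif(1, 0, pi), theta_jitter = pi / 10)
}

# epithelioid: sparse rounded cells
draw_epithelioid <- function(S, blob_count) {
  n <- stats::rpois(1, blob_count) + 4
  draw_ellipses(S, n, c(0.04, 0.08), 1.15)
}

draw_tessellation <- function(S, dens) {
  step <- S / dens
  cx <- as.vector(outer(rep(1, dens), (seq_len(dens) - 0.5) * step)) +
    stats::runif(dens * dens, -0.25 * step, 0.25 * step)
  cy <- as.vector(outer((seq_len(dens) - 0.5) * step, rep(1, dens))) +
    stats::runif(dens * dens, -0.25 * step, 0.25 * step)
  gx <- matrix(seq_len(S), S, S)
  gy <- matrix(seq_len(S), S, S, byrow = TRUE)
  d1 <- matrix(Inf, S, S); d2 <- matrix(Inf, S, S)
  for (i in seq_along(cx)) {
    d <- sqrt((gx - cy[i])^2 + (gy - cx[i])^2)
    swap <- d < d1
    d2 <- ifelse(swap, d1, pmin(d2, d))
    d1 <- pmin(d1, d)
  }
  # bright cell bodies separated by dark borders at Voronoi boundaries
  border <- exp(-((d2 - d1) / (0.12 * step))^2)
  body <- exp(-(d1 / (0.6 * step))^2)
  pmin(1, 0.85 * body + 0.1) * (1 - 0.9 * border)
}

synth_image <- function(class_id, spec) {
  S <- spec$image_size
  canvas <- switch(class_id,
    draw_fusiform(S, spec$elongation),
    draw_epithelioid(S, spec$blob_count),
    draw_tessellation(S, spec$tessellation_density),
    { # mixed morphology: the field of view is spatially partitioned into
      # two regions, each grown as a different pure morphology
      picks <- sample(1:3, 2)
      draw_pure <- function(k) switch(k,
        draw_fusiform(S, spec$elongation),
        draw_epithelioid(S, spec$blob_count),
        draw_tessellation(S, spec$tessellation_density))
      th <- stats::runif(1, 0, pi)
      off <- stats::runif(1, 0.35, 0.65) * S
      gx <- matrix(seq_len(S), S, S); gy <- matrix(seq_len(S), S, S, byrow = TRUE)
      side <- (gx - S / 2) * cos(th) + (gy - S / 2) * sin(th) + S / 2 < off
      c1 <- draw_pure(picks[1]); c2 <- draw_pure(picks[2])
      ifelse(side, c1, c2)
    })
  # bright-field rendering: dark violet-tinted cells on a light background
  bg <- 0.88
  tint <- c(0.55, 0.45, 0.70)
  img <- array(0, c(S, S, 3))
  for (ch in 1:3)
    img[, , ch] <- bg - canvas * (bg - tint[ch] * 0.55) +
      stats::rnorm(S * S, 0, spec$noise_sd)
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic labeled cell-image set
#'
#' Class-conditional procedural images, byte-identical for identical
#' spec + seed. Classes are learnably distinct (a linear classifier on
#' downsampled pixels separates them well above chance).
#'
#' @param spec A [synthetic_spec()].
#' @return A labeled image set: list with `images`, `labels` (1..C),
#'   `class_names`, `split`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  cls_names <- c("fusiform", "epithelioid", "cobblestone", "mixed")[seq_len(spec$num_classes)]
  with_local_seed(spec$seed, {
    images <- list(); labels <- integer()
    for (k in seq_len(spec$num_classes)) {
      for (i in seq_len(spec$per_class_count)) {
        images[[length(images) + 1L]] <- synth_image(k, spec)
        labels <- c(labels, k)
      }
    }
    list(images = images, labels = labels, class_names = cls_names,
         split = "all")
  })
}

#' Stratified train/test split
#'
#' Splits each class independently at the given ratio (sizes within one
#' image of the exact ratio per class); the two parts partition the input.
#'
#' @param ds A labeled image set.
#' @param ratio Training fraction.
#' @param seed Shuffle seed.
#' @return List with `train` and `test` labeled image sets.
#' @export
split_dataset <- function(ds, ratio = 0.8, seed = 0L) {
  with_local_seed(seed, {
    tr_idx <- integer()
    for (k in sort(unique(ds$labels))) {
      idx <- which(ds$labels == k)
      idx <- sample(idx)
      n_tr <- round(ratio * length(idx))
      tr_idx <- c(tr_idx, idx[seq_len(n_tr)])
    }
    te_idx <- setdiff(seq_along(ds$labels), tr_idx)
    mk <- function(ix, tag) list(images = ds$images[ix], labels = ds$labels[ix],
                                 class_names = ds$class_names, split = tag)
    list(train = mk(sort(tr_idx), "train"), test = mk(te_idx, "test"))
  })
}

#' Add Gaussian noise to an image
#'
#' Additive zero-mean noise with standard deviation `sigma` on the \[0, 1\]
#' intensity scale, clipped back to \[0, 1\].
#'
#' @param image (H, W, 3) array in \[0, 1\].
#' @param sigma Noise standard deviation.
#' @param seed Noise seed.
#' @return Noisy image.
#' @export
add_gaussian_noise <- function(image, sigma = 0.05, seed = 0L) {
  if (sigma == 0) return(image)
  with_local_seed(seed, pmin(pmax(image + stats::rnorm(length(image), 0, sigma), 0), 1))
}

normalize_image <- function(img) {
  st <- norm_stats()
  for (ch in 1:3) img[, , ch] <- (img[, , ch] - st$mean[ch]) / st$sd[ch]
  img
}

#' Undo channel standardization
#'
#' @param img Standardized (H, W, 3) array.
#' @return Image on the original \[0, 1\] scale (up to clipping).
#' @export
denormalize_image <- function(img) {
  st <- norm_stats()
  for (ch in 1:3) img[, , ch] <- img[, , ch] * st$sd[ch] + st$mean[ch]
  img
}

resize_image <- function(img, size) {
  if (dim(img)[1] == size && dim(img)[2] == size) return(img)
  out <- EBImage::resize(img, w = size, h = size)
  array(out, c(size, size, 3))
}

#' Training-time transform
#'
#' Random rotation in \[-15, 15\] degrees, the standard ImageNet AutoAugment
#' policy, bilinear resize to `size` and channel standardization with the
#' ImageNet constants. Deterministic given `seed`.
#'
#' @param image RGB (H, W, 3) array in \[0, 1\].
#' @param seed Augmentation seed.
#' @param size Output side length.
#' @param rotate Apply the random rotation (disable to force angle 0).
#' @param autoaugment Apply the AutoAugment policy.
#' @return Standardized (size, size, 3) array.
#' @export
train_transform <- function(image, seed = 0L, size = 224L, rotate = TRUE,
                            autoaugment = TRUE) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("expected an RGB (H, W, 3) image array")
  with_local_seed(seed, {
    if (rotate) {
      ang <- stats::runif(1, -15, 15)
      image <- warp_rotate(image, ang)
    }
    if (autoaugment) image <- autoaugment_imagenet(image)
    normalize_image(resize_image(image, size))
  })
}

#' Test-time transform: resize + standardization only
#'
#' @inheritParams train_transform
#' @return Standardized (size, size, 3) array.
#' @export
test_transform <- function(image, size = 224L) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("expected an RGB (H, W, 3) image array")
  normalize_image(resize_image(image, size))
}

#' Stack a labeled image set into a model-ready batch
#'
#' @param ds Labeled image set.
#' @param size Output side length.
#' @param train Use the training transform (with per-image seeds derived
#'   from `seed`) instead of the test transform.
#' @param seed Base augmentation seed.
#' @param noise_sigma Optional Gaussian noise injected before
#'   standardization (robustness evaluation).
#' @return List with `x` (size, size, 3, N) and `y` labels.
#' @export
dataset_to_batch <- function(ds, size = 224L, train = FALSE, seed = 0L,
                             noise_sigma = 0) {
  N <- length(ds$images)
  x <- array(0, c(size, size, 3, N))
  for (i in seq_len(N)) {
    img <- ds$images[[i]]
    if (noise_sigma > 0) img <- add_gaussian_noise(img, noise_sigma, seed + i)
    x[, , , i] <- if (train) train_transform(img, seed = seed + i, size = size)
    else test_transform(img, size = size)
  }
  list(x = x, y = ds$labels)
}

# ---- image-folder I/O -----------------------------------------------------

#' Write a labeled image set as an image-folder tree (one directory per
#' class, PNG files)
#'
#' @param ds Labeled image set.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_image_folder <- function(ds, dir) {
  for (k in seq_along(ds$class_names)) {
    d <- file.path(dir, ds$class_names[k])
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    idx <- which(ds$labels == k)
    for (j in seq_along(idx)) {
      png::writePNG(ds$images[[idx[j]]],
                    file.path(d, sprintf("img_%04d.png", j)))
    }
  }
  invisible(dir)
}

#' Read an image-folder tree (one directory per class; PNG/JPEG/TIFF)
#'
#' @param dir Dataset root; subdirectory names become class names.
#' @return A labeled image set.
#' @export
read_image_folder <- function(dir) {
  classes <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0) stop("no class subdirectories under ", dir)
  images <- list(); labels <- integer()
  for (k in seq_along(classes)) {
    files <- sort(list.files(file.path(dir, classes[k]),
                             pattern = "\\.(png|jpe?g|tiff?)$",
                             ignore.case = TRUE, full.names = TRUE))
    for (f in files) {
      img <- EBImage::readImage(f)
      a <- as.array(img)
      if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
      if (dim(a)[3] > 3L) a <- a[, , 1:3]
      a <- aperm(a, c(2L, 1L, 3L))   # (x, y, c) image convention -> (H, W, C)
      images[[length(images) + 1L]] <- a
      labels <- c(labels, k)
    }
  }
  list(images = images, labels = labels, class_names = classes, split = "all")
}
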