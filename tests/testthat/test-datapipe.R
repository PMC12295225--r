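# Synthetic generator, transforms, splitting, noise and folder I/O.

test_that("the synthetic generator is deterministic with correct counts", {
  spec <- synthetic_spec(per_class_count = 3L, image_size = 32L, seed = 42L)
  d1 <- generate_synthetic(spec)
  d2 <- generate_synthetic(spec)
  expect_identical(d1$images, d2$images)
  expect_equal(as.vector(table(d1$labels)), rep(3L, 4L))
  expect_equal(d1$class_names, c("fusiform", "epithelioid", "cobblestone", "mixed"))
  rng <- range(unlist(d1$images))
  expect_gte(rng[1], 0); expect_lte(rng[2], 1)
})

test_that("a linear classifier separates the synthetic classes well above chance", {
  ds <- generate_synthetic(synthetic_spec(per_class_count = 50L,
                                          image_size = 48L, seed = 9L))
  # probe on 12x12 downsampled gray pixels with a held-out split
  X <- t(vapply(ds$images, function(im) {
    g <- 0.3 * im[, , 1] + 0.6 * im[, , 2] + 0.1 * im[, , 3]
    as.vector(EBImage::resize(g, 12, 12))
  }, numeric(144)))
  set.seed(1)
  idx <- sample(200, 160)
  fit <- nnet::multinom(y ~ ., data = data.frame(y = factor(ds$labels[idx]),
                                                 X[idx, ]),
                        trace = FALSE, MaxNWts = 10000, decay = 0.1)
  pred <- predict(fit, newdata = data.frame(X[-idx, ]))
  expect_gt(mean(pred == factor(ds$labels[-idx])), 0.6)
})

test_that("the training transform standardizes with the published constants", {
  gray <- array(0.5, c(40, 40, 3))
  out <- train_transform(gray, seed = 1, size = 32, rotate = FALSE,
                         autoaugment = FALSE)
  st <- norm_stats()
  for (ch in 1:3) {
    expect_equal(mean(out[, , ch]), (0.5 - st$mean[ch]) / st$sd[ch],
                 tolerance = 1e-6)
  }
  # de-standardizing recovers the original intensity scale
  back <- denormalize_image(out)
  expect_equal(as.vector(back), rep(0.5, length(back)), tolerance = 1e-6)
})

test_that("transforms are deterministic under a fixed seed", {
  set.seed(99)
  img <- array(runif(48 * 48 * 3), c(48, 48, 3))
  a <- train_transform(img, seed = 7, size = 32)
  b <- train_transform(img, seed = 7, size = 32)
  expect_identical(a, b)
  c <- train_transform(img, seed = 8, size = 32)
  expect_gt(max(abs(a - c)), 0)
  expect_error(train_transform(array(0, c(8, 8)), seed = 1), "RGB")
})

test_that("rotation stays within +/- 15 degrees and preserves the image center", {
  img <- array(0.2, c(33, 33, 3))
  img[17, 17, ] <- 1          # bright center pixel is rotation-invariant
  out <- ilvit:::warp_rotate(img, 15)
  expect_equal(out[17, 17, ], c(1, 1, 1), tolerance = 1e-6)
  expect_equal(dim(out), dim(img))
})

test_that("stratified splitting is an exact, deterministic partition", {
  ds <- list(images = as.list(seq_len(100)),
             labels = rep(1:4, each = 25L),
             class_names = letters[1:4], split = "all")
  sp <- split_dataset(ds, 0.8, seed = 3)
  expect_equal(length(sp$train$labels), 80L)
  expect_equal(length(sp$test$labels), 20L)
  expect_equal(as.vector(table(sp$train$labels)), rep(20L, 4))
  expect_equal(as.vector(table(sp$test$labels)), rep(5L, 4))
  ids <- c(unlist(sp$train$images), unlist(sp$test$images))
  expect_setequal(ids, 1:100)                      # union = original, disjoint
  expect_equal(length(ids), 100L)
  sp2 <- split_dataset(ds, 0.8, seed = 3)
  expect_identical(sp$train$images, sp2$train$images)
})

test_that("gaussian noise has the stated scale and respects the intensity range", {
  img <- array(0.5, c(200, 200, 3))                 # interior intensity, no clipping
  expect_identical(add_gaussian_noise(img, sigma = 0), img)
  noisy <- add_gaussian_noise(img, sigma = 0.05, seed = 4)
  expect_equal(sd(noisy - img), 0.05, tolerance = 0.005)
  dark <- array(0.01, c(50, 50, 3))
  out <- add_gaussian_noise(dark, sigma = 0.3, seed = 5)
  expect_gte(min(out), 0); expect_lte(max(out), 1)
})

test_that("image-folder round trip preserves labels and images", {
  ds <- generate_synthetic(synthetic_spec(per_class_count = 2L,
                                          image_size = 24L, seed = 2L))
  dir <- file.path(tempdir(), "imgset")
  unlink(dir, recursive = TRUE)
  write_image_folder(ds, dir)
  back <- read_image_folder(dir)
  expect_equal(length(back$images), 8L)
  expect_setequal(back$class_names, ds$class_names)
  # PNG quantizes to 8 bits; content matches to that precision
  i1 <- ds$images[[which(ds$labels == 1)[1]]]
  j1 <- back$images[[which(back$labels == which(back$class_names == "fusiform"))[1]]]
  expect_equal(dim(j1), dim(i1))
  expect_lt(max(abs(i1 - j1)), 1 / 255)
})
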