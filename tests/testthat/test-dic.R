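# Dynamic Inception Convolution: kernel attention, adaptive aggregation and
# the four-branch depthwise mixer.

test_that("kernel attention is a softmax over the K kernels", {
  set.seed(1)
  bank <- dynamic_kernel_bank(8L, 4L, kernel = 3L, K = 4L)
  x <- array(rnorm(2 * 8 * 16 * 16), c(16, 16, 8, 2))

  w <- kernel_attention(x, bank)
  expect_true(all(w >= 0))
  expect_equal(rowSums(w), c(1, 1), tolerance = 1e-6)

  # forced equal logits: zero the attention subnet -> every weight 1/K
  bank$fc1_W[] <- 0; bank$fc1_b[] <- 0; bank$fc2_W[] <- 0; bank$fc2_b[] <- 0
  w0 <- kernel_attention(x, bank)
  expect_equal(as.vector(w0), rep(1 / 4, 8), tolerance = 1e-12)

  # degenerate K = 1
  bank1 <- dynamic_kernel_bank(8L, 4L, K = 1L)
  expect_equal(as.vector(kernel_attention(x, bank1)), c(1, 1))
})

test_that("kernel attention matches a straight-line recomputation", {
  set.seed(2)
  bank <- dynamic_kernel_bank(8L, 4L, K = 4L)
  x <- array(rnorm(2 * 8 * 16 * 16), c(16, 16, 8, 2))
  w <- kernel_attention(x, bank)
  for (n in 1:2) {
    g <- colMeans(matrix(x[, , , n], 16 * 16, 8))      # explicit global mean
    z <- as.vector(g %*% bank$fc1_W) + bank$fc1_b      # two matrix products
    l <- as.vector(z %*% bank$fc2_W) + bank$fc2_b
    e <- exp(l - max(l))
    expect_equal(as.vector(w[n, ]), e / sum(e), tolerance = 1e-6)
  }
})

test_that("one-hot weights select a single kernel's plain convolution", {
  set.seed(3)
  bank <- dynamic_kernel_bank(3L, 4L, kernel = 3L, K = 3L)
  x <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  for (j in 1:3) {
    w <- matrix(0, 2, 3); w[, j] <- 1
    y <- aggregate_and_convolve(x, bank, w)
    conv <- ilvit:::nn_conv2d(3L, 3L, 3L, 4L)
    conv$W <- bank$kernels[, , , , j]; conv$b <- bank$b
    yj <- ilvit:::nn_forward(conv, x, tiny_meta(2L, 6L, 6L))$y
    expect_equal(y, yj, tolerance = 1e-12)
  }
})

test_that("aggregation is linear: blended kernel equals weighted sum of K convolutions", {
  set.seed(4)
  bank <- dynamic_kernel_bank(3L, 4L, kernel = 3L, K = 4L)
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  w <- kernel_attention(x, bank)
  y <- aggregate_and_convolve(x, bank, w)
  ysep <- array(0, dim(y))
  for (k in 1:4) {
    onehot <- matrix(0, 2, 4); onehot[, k] <- 1
    bank_nb <- bank; yk <- aggregate_and_convolve(x, bank, onehot)
    # remove the bias contribution K-1 extra times afterwards
    ysep <- ysep + sweep(yk, 3, bank$b, "-") * rep(w[, k], each = prod(dim(y)[1:3]))
  }
  ysep <- sweep(ysep, 3, bank$b, "+")
  expect_equal(y, ysep, tolerance = 1e-5)
})

test_that("each sample is convolved with its own blended kernel", {
  set.seed(5)
  bank <- dynamic_kernel_bank(3L, 2L, K = 2L)
  x <- array(rnorm(5 * 5 * 3 * 2), c(5, 5, 3, 2))
  w <- matrix(c(1, 0, 0, 1), 2, 2)     # sample 1 -> kernel 1, sample 2 -> kernel 2
  y <- aggregate_and_convolve(x, bank, w)
  wm <- matrix(colMeans(w), 2, 2, byrow = TRUE)
  ym <- aggregate_and_convolve(x, bank, wm)
  expect_gt(max(abs(y - ym)), 1e-4)    # differs from blending the mean weights
  # per-sample loop oracle
  for (n in 1:2) {
    y1 <- aggregate_and_convolve(x[, , , n, drop = FALSE], bank, w[n, , drop = FALSE])
    expect_equal(y[, , , n], y1[, , , 1], tolerance = 1e-12)
  }
})

test_that("inception mixer preserves channels, spatial dims and the identity branch", {
  set.seed(6)
  cfg <- dic_config(embed_dim = 8L, branch_ratios = c(1, 1, 1, 1) / 4,
                    band_kernel = 5L)
  mixer <- ilvit:::new_inception_mixer(cfg)
  x <- array(rnorm(5 * 5 * 8 * 1), c(5, 5, 8, 1))
  y <- inception_mix(x, mixer)
  expect_equal(dim(y), dim(x))
  expect_identical(y[, , 7:8, ], x[, , 7:8, ])   # identity branch bit-identical

  # depthwise branches match an explicit per-pixel loop oracle
  naive_dw <- function(xs, w) {
    kh <- dim(w)[1]; kw <- dim(w)[2]
    H <- dim(xs)[1]; Wd <- dim(xs)[2]
    out <- array(0, dim(xs))
    for (c in seq_len(dim(xs)[3])) for (h in 1:H) for (v in 1:Wd) {
      acc <- 0
      for (i in 1:kh) for (j in 1:kw) {
        hi <- h + i - 1 - kh %/% 2; wi <- v + j - 1 - kw %/% 2
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= Wd)
          acc <- acc + xs[hi, wi, c] * w[i, j, c]
      }
      out[h, v, c] <- acc
    }
    out
  }
  ch <- cfg$branch_channels
  y_hw <- naive_dw(x[, , 1:ch[1], 1, drop = FALSE][, , , 1], mixer$hw$W) +
    rep(mixer$hw$b, each = 25)
  expect_equal(y[, , 1:ch[1], 1], array(y_hw, c(5, 5, ch[1])), tolerance = 1e-6)
  y_w <- naive_dw(x[, , (ch[1] + 1):(ch[1] + ch[2]), 1, drop = FALSE][, , , 1],
                  mixer$w$W) + rep(mixer$w$b, each = 25)
  expect_equal(y[, , (ch[1] + 1):(ch[1] + ch[2]), 1],
               array(y_w, c(5, 5, ch[2])), tolerance = 1e-6)
})

test_that("invalid channel splits and channel mismatches raise errors", {
  expect_error(dic_config(embed_dim = 7L, branch_ratios = c(0.3, 0.3, 0.3, 0.1)),
               "channel")
  mixer <- ilvit:::new_inception_mixer(dic_config(embed_dim = 8L,
                                                  branch_ratios = rep(0.25, 4),
                                                  band_kernel = 5L))
  expect_error(inception_mix(array(0, c(4, 4, 6, 1)), mixer), "mismatch")
  bank <- dynamic_kernel_bank(8L, 4L)
  expect_error(kernel_attention(array(0, c(4, 4, 3, 1)), bank), "mismatch")
})

test_that("the DIC stem meets its shape and parameter contracts", {
  set.seed(7)
  stem <- new_dic_stem(dic_config())
  x <- array(rnorm(224 * 224 * 3 * 2), c(224, 224, 3, 2))
  y <- dic_stem(x, stem)
  expect_equal(dim(y), c(56, 56, 96, 2))
  expect_true(all(is.finite(y)))
  expect_error(dic_stem(array(0, c(30, 30, 3, 1)), stem), "divisible")

  # fewer parameters than K dense copies of a 7x7 stride-4 projection
  dense_7x7_K <- 4 * (3 * 96 * 49 + 96)
  expect_lt(count_parameters(stem), dense_7x7_K)
})
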