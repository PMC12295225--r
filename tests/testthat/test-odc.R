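# Omni-dimensional dynamic convolution: four-factor attentions and the
# modulated-kernel convolution.

test_that("attention factors are sigmoid-bounded and match forced logits", {
  set.seed(1)
  od <- new_odconv(odc_config(6L, 5L, kernel_size = 3L, num_kernels = 3L,
                              reduction = 2L))
  x <- array(rnorm(6 * 6 * 6 * 2), c(6, 6, 6, 2))
  f <- odc_attentions(x, od)
  for (a in f) expect_true(all(a > 0 & a < 1))
  expect_equal(dim(f$a_s), c(2L, 9L))
  expect_equal(dim(f$a_c), c(2L, 6L))
  expect_equal(dim(f$a_f), c(2L, 5L))
  expect_equal(dim(f$a_w), c(2L, 3L))

  # zeroed trunk -> every factor sigmoid(0) = 0.5
  for (p in c("fc1_W", "fc1_b", "hs_W", "hs_b", "hc_W", "hc_b",
              "hf_W", "hf_b", "hw_W", "hw_b")) od[[p]][] <- 0
  f0 <- odc_attentions(x, od)
  for (a in f0) expect_equal(as.vector(a), rep(0.5, length(a)), tolerance = 1e-12)
})

test_that("attention factors match an independent straight-line recomputation", {
  set.seed(2)
  od <- new_odconv(odc_config(6L, 5L, kernel_size = 3L, num_kernels = 2L,
                              reduction = 2L))
  x <- array(rnorm(5 * 5 * 6 * 2), c(5, 5, 6, 2))
  f <- odc_attentions(x, od)
  sig <- function(z) 1 / (1 + exp(-z))
  for (n in 1:2) {
    g <- colMeans(matrix(x[, , , n], 25, 6))
    z <- pmax(as.vector(g %*% od$fc1_W) + od$fc1_b, 0)
    expect_equal(as.vector(f$a_s[n, ]), sig(as.vector(z %*% od$hs_W) + od$hs_b),
                 tolerance = 1e-6)
    expect_equal(as.vector(f$a_c[n, ]), sig(as.vector(z %*% od$hc_W) + od$hc_b),
                 tolerance = 1e-6)
    expect_equal(as.vector(f$a_f[n, ]), sig(as.vector(z %*% od$hf_W) + od$hf_b),
                 tolerance = 1e-6)
    expect_equal(as.vector(f$a_w[n, ]), sig(as.vector(z %*% od$hw_W) + od$hw_b),
                 tolerance = 1e-6)
  }
})

test_that("n = 1 with unit factors reduces to a plain convolution", {
  set.seed(3)
  od <- new_odconv(odc_config(4L, 3L, kernel_size = 3L, num_kernels = 1L))
  x <- array(rnorm(6 * 6 * 4 * 2), c(6, 6, 4, 2))
  ones <- function(k) matrix(1, 2, k)
  y <- odc_forward(x, od, factors = list(a_s = ones(9), a_c = ones(4),
                                         a_f = ones(3), a_w = ones(1)))
  conv <- ilvit:::nn_conv2d(3L, 3L, 4L, 3L)
  conv$W <- od$W[, , , , 1]; conv$b <- od$b
  y0 <- ilvit:::nn_forward(conv, x, tiny_meta(2L, 6L, 6L))$y
  expect_equal(y, y0, tolerance = 1e-12)
})

test_that("output matches the brute-force kernel-assembly oracle", {
  set.seed(4)
  od <- new_odconv(odc_config(4L, 3L, kernel_size = 3L, num_kernels = 2L,
                              reduction = 2L))
  x <- array(rnorm(6 * 6 * 4 * 1), c(6, 6, 4, 1))
  fac <- list(a_s = matrix(runif(9), 1), a_c = matrix(runif(4), 1),
              a_f = matrix(runif(3), 1), a_w = matrix(runif(2), 1))
  y <- odc_forward(x, od, factors = fac)
  # oracle: scale each kernel element by its per-dimension factors, sum with
  # a_w, then convolve by nested loops
  Weff <- array(0, c(3, 3, 4, 3))
  for (t in 1:2) for (i in 1:3) for (j in 1:3) for (ci in 1:4) for (co in 1:3) {
    Weff[i, j, ci, co] <- Weff[i, j, ci, co] +
      fac$a_w[1, t] * fac$a_f[1, co] * fac$a_c[1, ci] *
      fac$a_s[1, (j - 1) * 3 + i] * od$W[i, j, ci, co, t]
  }
  oracle <- array(0, c(6, 6, 3, 1))
  for (co in 1:3) for (h in 1:6) for (v in 1:6) {
    acc <- od$b[co]
    for (ci in 1:4) for (i in 1:3) for (j in 1:3) {
      hi <- h + i - 2; wi <- v + j - 2
      if (hi >= 1 && hi <= 6 && wi >= 1 && wi <= 6)
        acc <- acc + x[hi, wi, ci, 1] * Weff[i, j, ci, co]
    }
    oracle[h, v, co, 1] <- acc
  }
  expect_equal(y, oracle, tolerance = 1e-5)
})

test_that("output is linear in the kernel-wise factor", {
  set.seed(5)
  od <- new_odconv(odc_config(4L, 3L, kernel_size = 1L, num_kernels = 2L))
  od$b[] <- 0
  x <- array(rnorm(4 * 4 * 4 * 1), c(4, 4, 4, 1))
  fac <- list(a_s = matrix(runif(1), 1), a_c = matrix(runif(4), 1),
              a_f = matrix(runif(3), 1), a_w = matrix(runif(2), 1))
  y1 <- odc_forward(x, od, factors = fac)
  fac2 <- fac; fac2$a_w <- 3 * fac$a_w
  expect_equal(odc_forward(x, od, factors = fac2), 3 * y1, tolerance = 1e-10)
})

test_that("zeroing the kernel-wise factor removes that kernel's influence", {
  set.seed(6)
  od <- new_odconv(odc_config(4L, 3L, kernel_size = 3L, num_kernels = 2L))
  x <- array(rnorm(5 * 5 * 4 * 1), c(5, 5, 4, 1))
  fac <- list(a_s = matrix(runif(9), 1), a_c = matrix(runif(4), 1),
              a_f = matrix(runif(3), 1), a_w = matrix(c(0.7, 0), 1))
  y1 <- odc_forward(x, od, factors = fac)
  od$W[, , , , 2] <- rnorm(length(od$W[, , , , 2]))   # perturb the gated-out kernel
  expect_equal(odc_forward(x, od, factors = fac), y1, tolerance = 1e-12)
})

test_that("token-mode pointwise path agrees with the image-layout path", {
  set.seed(7)
  od <- new_odconv(odc_config(6L, 6L, kernel_size = 1L, num_kernels = 2L,
                              reduction = 2L))
  x <- array(rnorm(4 * 4 * 6 * 3), c(4, 4, 6, 3))
  meta <- tiny_meta(3L, 4L, 4L)
  y_img <- odc_forward(x, od)
  tok <- ilvit:::fm_to_tokens(x)
  f_tok <- ilvit:::nn_forward(od, tok, meta)
  expect_equal(ilvit:::tokens_to_fm(f_tok$y, 4L, 4L, 3L), y_img, tolerance = 1e-10)
})

test_that("channel mismatch raises a configuration error", {
  od <- new_odconv(odc_config(6L, 4L))
  expect_error(odc_forward(array(0, c(4, 4, 3, 1)), od), "mismatch")
  expect_error(odc_attentions(array(0, c(4, 4, 5, 1)), od), "mismatch")
})
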