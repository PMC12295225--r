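# Activation-gated linear attention and the block assembly.

test_that("single-token linear attention matches the closed form", {
  set.seed(1)
  Q <- matrix(rnorm(4), 1, 4)
  K <- matrix(rnorm(4), 1, 4)
  V <- matrix(rnorm(4), 1, 4)
  out <- linear_attention(Q, K, V)
  smV <- exp(V - max(V)); smV <- smV / sum(smV)
  sig <- function(z) 1 / (1 + exp(-z))
  # out_f = sigmoid(Q_f) * sum_g sigmoid(K_g) * softmax(V)_g ... with the
  # d_k x d_k summary, f indexes the query gate, g the key gate
  expected <- sig(Q) %*% (t(sig(K)) %*% smV) / sqrt(4)
  expect_equal(out, expected, tolerance = 1e-12)
})

test_that("right-to-left association equals left-to-right on random inputs", {
  set.seed(2)
  for (rep in 1:20) {
    Q <- matrix(rnorm(16 * 8), 16, 8)
    K <- matrix(rnorm(16 * 8), 16, 8)
    V <- matrix(rnorm(16 * 8), 16, 8)
    right <- linear_attention(Q, K, V)                    # sig(Q) (sig(K)' smV)
    smV <- t(apply(V, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
    sig <- function(z) 1 / (1 + exp(-z))
    left <- (sig(Q) %*% t(sig(K))) %*% smV / sqrt(8)      # (sig(Q) sig(K)') smV
    expect_equal(right, left, tolerance = 1e-5)
  }
})

test_that("mismatched key/value token counts raise an error", {
  expect_error(linear_attention(matrix(0, 2, 4), matrix(0, 3, 4), matrix(0, 2, 4)),
               "mismatch")
})

test_that("linear attention MAC count grows linearly in token count", {
  # analytic count under the profiler's attention-product accounting:
  # 2 L d_k^2 for the gated form vs L^2 d_k for the quadratic form
  lin <- ilvit:::new_mha(8L, 8L, 1L, mode = "linear")
  sm <- ilvit:::new_mha(8L, 8L, 1L, mode = "softmax")
  f_lin <- function(L) ilvit:::attention_product_flops(
    lin, list(N = 1L), list(H = L, W = 1L), list(H = L, W = 1L))
  f_sm <- function(L) ilvit:::attention_product_flops(
    sm, list(N = 1L), list(H = L, W = 1L), list(H = L, W = 1L))
  expect_equal(f_lin(128) / f_lin(64), 2)
  expect_equal(f_sm(128) / f_sm(64), 4)
  expect_equal(f_lin(64), 2 * 64 * 8 * 8)
})

test_that("multi-head attention keeps shape and reduces to single-head", {
  set.seed(3)
  x <- matrix(rnorm(32 * 8), 32, 8)
  mha2 <- ilvit:::new_mha(8L, 8L, 2L, mode = "linear")
  y <- multi_head_attention(x, mha2, H = 4L, W = 4L)
  expect_equal(dim(y), dim(x))

  mha1 <- ilvit:::new_mha(8L, 8L, 1L, mode = "linear", qkv_bias = FALSE)
  y1 <- multi_head_attention(x, mha1, H = 4L, W = 4L)
  # degenerate single head equals the plain per-sample computation
  qkv <- x %*% mha1$qkv$W
  manual <- x * 0
  for (n in 1:2) {
    rows <- ((n - 1) * 16 + 1):(n * 16)
    manual[rows, ] <- linear_attention(qkv[rows, 1:8], qkv[rows, 9:16],
                                       qkv[rows, 17:24])
  }
  expect_equal(y1, manual, tolerance = 1e-12)
})

test_that("key/value token permutation leaves linear attention unchanged", {
  set.seed(4)
  x <- matrix(rnorm(16 * 8), 16, 8)
  mha <- ilvit:::new_mha(8L, 8L, 2L, mode = "linear", qkv_bias = FALSE)
  y <- multi_head_attention(x, mha, H = 4L, W = 4L)
  # permuting tokens permutes K and V rows together; the aggregated summary
  # is invariant, so outputs follow the query permutation only
  perm <- sample(16)
  y_perm <- multi_head_attention(x[perm, ], mha, H = 4L, W = 4L)
  expect_equal(y_perm, y[perm, ], tolerance = 1e-10)
})

test_that("no token mixing flows through the query gate", {
  set.seed(5)
  # zeroing token t of Q changes only output token t
  Q <- matrix(rnorm(6 * 4), 6, 4)
  K <- matrix(rnorm(6 * 4), 6, 4)
  V <- matrix(rnorm(6 * 4), 6, 4)
  base <- linear_attention(Q, K, V)
  Q2 <- Q; Q2[3, ] <- 0
  pert <- linear_attention(Q2, K, V)
  expect_equal(pert[-3, ], base[-3, ], tolerance = 1e-12)
  expect_gt(max(abs(pert[3, ] - base[3, ])), 1e-6)
})

test_that("the COKA block preserves shape and matches its composition oracle", {
  set.seed(6)
  cfg <- tiny_model_config("V4")
  blk <- ilvit:::new_block(cfg, 1L, FALSE)
  x <- matrix(rnorm(32 * 8), 32, 8)
  meta <- tiny_meta(2L, 4L, 4L)
  y <- coka_block(x, blk, H = 4L, W = 4L)
  expect_equal(dim(y), dim(x))

  # straight-line composition of the four sub-operations called independently
  h <- ilvit:::nn_forward(blk$norm1, x, meta)$y
  h <- ilvit:::nn_forward(blk$odc, h, meta)$y
  a <- ilvit:::nn_forward(blk$attn, h, meta)$y
  x2 <- x + a
  h2 <- ilvit:::nn_forward(blk$norm2, x2, meta)$y
  ff <- kan_layer(kan_layer(h2, blk$kan1), blk$kan2)
  expect_equal(y, x2 + ff, tolerance = 1e-6)
})

test_that("a baseline block with zeroed value/FFN paths is the identity map", {
  set.seed(7)
  cfg <- tiny_model_config("baseline")
  blk <- ilvit:::new_block(cfg, 1L, FALSE)
  # zero the value projection (so attention output is 0) and the MLP output
  blk$attn$qkv$W[, 17:24] <- 0
  blk$attn$qkv$b[17:24] <- 0
  blk$attn$v_pool$W[] <- 0; blk$attn$v_pool$b[] <- 0
  blk$fc2$W[] <- 0; blk$fc2$b[] <- 0
  x <- matrix(rnorm(16 * 8), 16, 8)
  y <- coka_block(x, blk, H = 4L, W = 4L)
  expect_equal(y, x, tolerance = 1e-12)
})

test_that("the block is a residual map: branch contributions bound the deviation", {
  set.seed(8)
  cfg <- tiny_model_config("V4")
  blk <- ilvit:::new_block(cfg, 1L, FALSE)
  x <- matrix(rnorm(32 * 8), 32, 8)
  meta <- tiny_meta(2L, 4L, 4L)
  # recompute the two branch outputs independently; their norms bound the
  # block's deviation from the identity
  h <- ilvit:::nn_forward(blk$norm1, x, meta)$y
  h <- ilvit:::nn_forward(blk$odc, h, meta)$y
  a <- ilvit:::nn_forward(blk$attn, h, meta)$y
  h2 <- ilvit:::nn_forward(blk$norm2, x + a, meta)$y
  ff <- kan_layer(kan_layer(h2, blk$kan1), blk$kan2)
  y <- coka_block(x, blk, H = 4L, W = 4L)
  expect_lte(max(abs(y - x)), max(abs(a)) + max(abs(ff)) + 1e-10)
  # scaling the FFN coefficients toward zero shrinks its contribution linearly
  for (p in c("coef", "base_W", "b")) {
    blk$kan1[[p]] <- blk$kan1[[p]] * 0
    blk$kan2[[p]] <- blk$kan2[[p]] * 0
  }
  y0 <- coka_block(x, blk, H = 4L, W = 4L)
  expect_equal(y0, x + a, tolerance = 1e-10)
})
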