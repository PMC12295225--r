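# KAN layer: B-spline basis properties and the edge-function contract.

r_basis_oracle <- function(t, grid, k) {
  # plain Cox-de Boor recursion, independent of the package implementation
  knots <- if (k > 0) {
    h <- diff(grid)
    c(grid[1] - rev(seq_len(k)) * h[1], grid,
      grid[length(grid)] + seq_len(k) * h[length(h)])
  } else grid
  nb0 <- length(knots) - 1
  B <- sapply(seq_len(nb0), function(i) {
    up <- if (i == nb0) t <= knots[i + 1] else t < knots[i + 1]
    as.numeric(t >= knots[i] & up)
  })
  if (k == 0) return(B)
  for (j in seq_len(k)) {
    nb <- nb0 - j
    B <- sapply(seq_len(nb), function(i)
      (t - knots[i]) / (knots[i + j] - knots[i]) * B[, i] +
        (knots[i + j + 1] - t) / (knots[i + j + 1] - knots[i + 1]) * B[, i + 1])
  }
  B
}

test_that("order-0 basis is the indicator of the containing interval", {
  grid <- seq(-1, 1, length.out = 6)
  B <- bspline_basis(c(-0.9, -0.2, 0.45, 0.99), grid, k = 0L)
  expect_true(all(B %in% c(0, 1)))
  expect_equal(rowSums(B), rep(1, 4))
})

test_that("basis is non-negative, sums to one inside the grid, and matches the oracle", {
  set.seed(1)
  grid <- seq(-1, 1, length.out = 6)
  t <- runif(100, -0.999, 0.999)
  for (k in 1:3) {
    B <- bspline_basis(t, grid, k)
    expect_true(all(B >= -1e-12))
    expect_equal(ncol(B), 5 + k)                      # G + k basis functions
    expect_equal(rowSums(B), rep(1, 100), tolerance = 1e-9)
    expect_equal(B, r_basis_oracle(t, grid, k), tolerance = 1e-12)
  }
  expect_error(bspline_basis(0.1, c(0, 0, 1), 2L), "increasing")
})

test_that("the cubic basis is C^2: value, first and second derivative continuous at knots", {
  grid <- seq(-1, 1, length.out = 6)
  k <- 3L
  eps <- 1e-6
  deriv <- function(t) ilvit:::bspline_basis_deriv(t, grid, k)
  for (knot in grid[2:5]) {
    lo <- knot - eps; hi <- knot + eps
    expect_equal(bspline_basis(hi, grid, k), bspline_basis(lo, grid, k),
                 tolerance = 1e-4)
    expect_equal(deriv(hi), deriv(lo), tolerance = 1e-4)
    # second derivative by finite differences of the first derivative
    d2_lo <- (deriv(lo) - deriv(lo - eps)) / eps
    d2_hi <- (deriv(hi + eps) - deriv(hi)) / eps
    expect_equal(d2_hi, d2_lo, tolerance = 1e-2)
  }
})

test_that("zero spline coefficients reduce the layer to the base-gate path", {
  set.seed(2)
  kl <- new_kan_layer(kan_config(6L, 4L, grid_size = 4L))
  kl$coef[] <- 0
  x <- matrix(rnorm(20 * 6), 20, 6)
  y <- kan_layer(x, kl)
  silu <- function(z) z / (1 + exp(-z))
  expect_equal(y, sweep(silu(x) %*% kl$base_W, 2, kl$b, "+"), tolerance = 1e-12)
})

test_that("parameter count matches the analytic formula", {
  cfg <- kan_config(6L, 4L, grid_size = 5L, spline_order = 3L)
  kl <- new_kan_layer(cfg)
  expect_equal(count_parameters(kl), kan_param_count(cfg))
  expect_equal(kan_param_count(cfg), 6 * 4 * (5 + 3) + 6 * 4 + 4)
})

test_that("least squares on the basis fits sin(pi x) to RMSE < 1e-2 at G=10, k=3", {
  set.seed(3)
  grid <- seq(-1, 1, length.out = 11)
  t <- seq(-1, 1, length.out = 400)
  B <- bspline_basis(t, grid, 3L)
  target <- sin(pi * t)
  fit <- lm.fit(B, target)
  rmse <- sqrt(mean(fit$residuals^2))
  expect_lt(rmse, 1e-2)
})

test_that("the layer output is exactly linear in the spline coefficients", {
  set.seed(4)
  kl <- new_kan_layer(kan_config(5L, 3L, grid_size = 4L))
  x <- matrix(rnorm(15 * 5), 15, 5)
  base <- {
    k0 <- kl$coef
    kl$coef[] <- 0
    b <- kan_layer(x, kl)
    kl$coef <- k0
    b
  }
  spline1 <- kan_layer(x, kl) - base
  kl$coef <- 2 * kl$coef
  spline2 <- kan_layer(x, kl) - base
  expect_equal(spline2, 2 * spline1, tolerance = 1e-10)
})

test_that("out-of-range inputs extrapolate linearly and keep finite gradients", {
  set.seed(5)
  kl <- new_kan_layer(kan_config(4L, 3L, grid_size = 4L))
  x_far <- matrix(rnorm(12 * 4) * 4, 12, 4)
  y <- kan_layer(x_far, kl)
  expect_true(all(is.finite(y)))
  # beyond the boundary the spline part is affine in the input
  xa <- matrix(2.0, 1, 4); xb <- matrix(2.5, 1, 4); xc <- matrix(3.0, 1, 4)
  kl$base_W[] <- 0; kl$b[] <- 0                       # isolate the spline term
  ya <- kan_layer(xa, kl); yb <- kan_layer(xb, kl); yc <- kan_layer(xc, kl)
  expect_equal(yc - yb, yb - ya, tolerance = 1e-9)
})

test_that("gradients reach every spline coefficient", {
  set.seed(6)
  kl <- new_kan_layer(kan_config(3L, 2L, grid_size = 3L))
  # inputs spread across all grid intervals so every basis activates
  x <- matrix(runif(60 * 3, -0.99, 0.99), 60, 3)
  f <- ilvit:::nn_forward(kl, x, tiny_meta(1L, 60L, 1L), training = TRUE)
  bw <- ilvit:::nn_backward(kl, f$cache, matrix(1, 60, 2))
  expect_true(all(abs(bw$grads$coef) > 0))
  expect_true(all(abs(bw$grads$base_W) > 0))
})
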