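# Kolmogorov-Arnold Network layer: trainable univariate spline functions on
# every edge, phi_ij(x) = w_b[i,j] * silu(x) + sum_m c[i,j,m] * B_m(x), with
# outputs out_j = sum_i phi_ij(x_i). The spline basis lives on a static
# uniform grid; inputs beyond the grid range are linearly extrapolated from
# the boundary basis values.

#' Configuration for a KAN layer
#'
#' @param in_dim,out_dim Feature dimensions.
#' @param grid_size Number of grid intervals `G` on `grid_range`.
#' @param spline_order B-spline order `k` (piecewise polynomial degree).
#' @param grid_range Numeric length-2 interval covered by the grid.
#' @return A `kan_config` list. The number of basis functions per edge is
#'   `G + k`.
#' @export
kan_config <- function(in_dim, out_dim, grid_size = 5L, spline_order = 3L,
                       grid_range = c(-1, 1)) {
  stopifnot(in_dim >= 1, out_dim >= 1, grid_size >= 1, spline_order >= 1,
            length(grid_range) == 2, grid_range[1] < grid_range[2])
  structure(list(in_dim = as.integer(in_dim), out_dim = as.integer(out_dim),
                 grid_size = as.integer(grid_size),
                 spline_order = as.integer(spline_order),
                 grid_range = as.numeric(grid_range)),
            class = "kan_config")
}

extend_knots <- function(grid, k) {
  h <- diff(grid)
  c(grid[1] - rev(seq_len(k)) * h[1], grid,
    grid[length(grid)] + seq_len(k) * h[length(h)])
}

#' Evaluate the B-spline basis by the Cox-de Boor recursion
#'
#' @param t Numeric vector of evaluation points.
#' @param grid Strictly increasing knot vector spanning the grid range
#'   (`G + 1` points for `G` intervals); it is extended by `k` uniformly
#'   spaced knots on each side internally.
#' @param k Spline order; `k = 0` gives the indicator of the containing knot
#'   interval.
#' @return Matrix `length(t) x (G + k)` of basis values; non-negative, and
#'   summing to 1 for `t` inside the grid (partition of unity).
#' @export
bspline_basis <- function(t, grid, k = 3L) {
  if (any(diff(grid) <= 0)) stop("grid knots must be strictly increasing")
  knots <- if (k > 0) extend_knots(grid, k) else grid
  bspline_eval_cpp(t, knots, as.integer(max(k, 0L)))$B
}

bspline_basis_deriv <- function(t, grid, k) {
  bspline_eval_cpp(t, extend_knots(grid, k), as.integer(k))$D
}

#' Build a KAN layer
#'
#' @param cfg A [kan_config()].
#' @return A KAN layer; apply with [kan_layer()] or `nn_forward()`.
#' @export
new_kan_layer <- function(cfg) {
  nb <- cfg$grid_size + cfg$spline_order
  grid <- seq(cfg$grid_range[1], cfg$grid_range[2], length.out = cfg$grid_size + 1L)
  l <- new_layer("nn_kan",
                 list(cfg = cfg, grid = grid, nb = nb,
                      d_in = cfg$in_dim, d_out = cfg$out_dim),
                 params = c("coef", "base_W", "b"))
  sd <- 0.1 / sqrt(cfg$in_dim)
  l$coef <- array(stats::rnorm(cfg$in_dim * cfg$out_dim * nb, 0, sd),
                  c(cfg$in_dim, cfg$out_dim, nb))
  l$base_W <- matrix(trunc_normal(cfg$in_dim * cfg$out_dim,
                                  sd = sqrt(2 / cfg$in_dim) / 2),
                     cfg$in_dim, cfg$out_dim)
  l$b <- numeric(cfg$out_dim)
  l
}

kan_basis_pair <- function(layer, x) {
  rng <- layer$cfg$grid_range
  k <- layer$cfg$spline_order
  tv <- as.vector(x)
  tc <- pmin(pmax(tv, rng[1]), rng[2])
  over <- tv - tc
  ev <- bspline_eval_cpp(tc, extend_knots(layer$grid, k), k)
  list(B = ev$B + ev$D * over, D = ev$D)  # linear extrapolation outside the grid
}

# coefficient tensor (d_in, d_out, nb) as a (d_in * nb) x d_out matrix whose
# rows match the column layout of the flattened basis (input index fastest)
kan_coef_mat <- function(coef) {
  d <- dim(coef)
  matrix(aperm(coef, c(1L, 3L, 2L)), d[1] * d[3], d[2])
}

#' Apply a KAN layer token-wise
#'
#' @param x Matrix of inputs (rows = tokens/samples, columns = `in_dim`
#'   features).
#' @param layer A layer from [new_kan_layer()].
#' @return Matrix with `out_dim` columns: `out_j = sum_i phi_ij(x_i)`.
#' @export
kan_layer <- function(x, layer) {
  if (ncol(x) != layer$d_in)
    stop("feature dimension mismatch: expected ", layer$d_in, ", got ", ncol(x))
  nn_forward(layer, x, list(N = nrow(x), H = 1L, W = 1L))$y
}

#' @exportS3Method
nn_forward.nn_kan <- function(layer, x, meta, training = FALSE) {
  R <- nrow(x)
  bp <- kan_basis_pair(layer, x)
  # basis flattened to R x (d_in * nb), input index fastest within each m
  Bm <- bp$B; dim(Bm) <- c(R, layer$d_in * layer$nb)
  sx <- silu_fwd(x)
  y <- sweep(sx %*% layer$base_W + Bm %*% kan_coef_mat(layer$coef),
             2L, layer$b, "+")
  list(y = y, meta = meta, cache = list(x = x, B = bp$B, D = bp$D, sx = sx))
}

#' @exportS3Method
nn_backward.nn_kan <- function(layer, cache, dy) {
  R <- nrow(dy)
  d_in <- layer$d_in; nb <- layer$nb
  Bm <- cache$B; dim(Bm) <- c(R, d_in * nb)
  Cm <- kan_coef_mat(layer$coef)
  dCm <- crossprod(Bm, dy)
  dcoef <- aperm(array(dCm, c(d_in, nb, layer$d_out)), c(1L, 3L, 2L))
  P <- tcrossprod(dy, Cm)                       # R x (d_in * nb)
  Dm <- cache$D; dim(Dm) <- c(R, d_in * nb)
  dx_spline <- rowSums(array(P * Dm, c(R, d_in, nb)), dims = 2L)
  dx <- (dy %*% t(layer$base_W)) * silu_bwd(cache$x) + dx_spline
  list(dx = dx,
       grads = list(coef = dcoef,
                    base_W = crossprod(cache$sx, dy),
                    b = colSums(dy)))
}

# Convention: spline coefficient contraction plus the base path count as
# (G + k + 1) MACs per edge per token.
#' @exportS3Method
nn_flops.nn_kan <- function(layer, meta) {
  list(flops = meta$N * meta$H * meta$W * layer$d_in * layer$d_out * (layer$nb + 1),
       meta = meta)
}

#' Analytic KAN parameter count
#'
#' `in_dim * out_dim * (G + k)` spline coefficients plus `in_dim * out_dim`
#' base weights plus `out_dim` bias terms.
#'
#' @param cfg A [kan_config()].
#' @return Integer count.
#' @export
kan_param_count <- function(cfg) {
  cfg$in_dim * cfg$out_dim * (cfg$grid_size + cfg$spline_order) +
    cfg$in_dim * cfg$out_dim + cfg$out_dim
}
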