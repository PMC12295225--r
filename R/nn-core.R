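# Minimal neural-network core: layers are environments carrying parameter
# arrays; forward passes return explicit caches so that backward passes are
# pure functions of (layer, cache, upstream gradient). Token sequences are
# (N*L) x d matrices with rows grouped per sample (sample-major, then
# column-major over the H x W grid); feature maps are (H, W, C, N) arrays.

new_layer <- function(class, fields = list(), params = character()) {
  e <- new.env(parent = emptyenv())
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e$param_names <- params
  class(e) <- c(class, "ilvit_layer")
  e
}

trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  pmin(pmax(x, -2 * sd), 2 * sd)
}

#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(x) {
  x <- x - x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x)
  e / rowSums(e)
}

# global average pool over H, W of an (H, W, C, N) array -> N x C matrix
gap_hw <- function(x) {
  d <- dim(x)
  t(matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
}

# gradient of row-softmax: given p = softmax(x) and dp, returns dx
softmax_rows_bwd <- function(p, dp) p * (dp - rowSums(dp * p))

# tanh approximation of GELU (the convention of the transformer libraries)
gelu_fwd <- function(x) {
  0.5 * x * (1 + tanh(0.7978845608028654 * (x + 0.044715 * x^3)))
}
gelu_bwd <- function(x) {
  u <- 0.7978845608028654 * (x + 0.044715 * x^3)
  th <- tanh(u)
  0.5 * (1 + th) + 0.5 * x * (1 - th^2) * 0.7978845608028654 * (1 + 3 * 0.044715 * x^2)
}
silu_fwd <- function(x) x * sigmoid(x)
silu_bwd <- function(x) { s <- sigmoid(x); s * (1 + x * (1 - s)) }

# ---- token / feature-map conversions ------------------------------------

fm_to_tokens <- function(x) {
  d <- dim(x)                                  # (H, W, C, N)
  y <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(y) <- c(d[1] * d[2] * d[4], d[3])
  y
}

tokens_to_fm <- function(x, H, W, N) {
  C <- ncol(x)
  dim(x) <- c(H, W, N, C)
  aperm(x, c(1L, 2L, 4L, 3L))
}

avgpool2_fwd <- function(x) {                  # (H, W, C, N), kernel 2 stride 2
  d <- dim(x)
  io <- seq(1L, d[1], by = 2L); jo <- seq(1L, d[2], by = 2L)
  (x[io, jo, , , drop = FALSE] + x[io + 1L, jo, , , drop = FALSE] +
     x[io, jo + 1L, , , drop = FALSE] + x[io + 1L, jo + 1L, , , drop = FALSE]) / 4
}

avgpool2_bwd <- function(dy, H, W) {
  d <- dim(dy)
  dx <- array(0, c(H, W, d[3], d[4]))
  io <- seq(1L, H, by = 2L); jo <- seq(1L, W, by = 2L)
  g <- dy / 4
  dx[io, jo, , ] <- g; dx[io + 1L, jo, , ] <- g
  dx[io, jo + 1L, , ] <- g; dx[io + 1L, jo + 1L, , ] <- g
  dx
}

# ---- generics ------------------------------------------------------------

nn_forward <- function(layer, x, meta, training = FALSE) UseMethod("nn_forward")
nn_backward <- function(layer, cache, dy) UseMethod("nn_backward")

# FLOP accounting walks layers with shape metadata; the convention counts
# multiply-accumulates of convolutions and affine maps only (see vignette).
nn_flops <- function(layer, meta) UseMethod("nn_flops")

nn_collect <- function(layer, prefix = "") {
  refs <- list()
  for (p in layer$param_names) {
    refs[[paste0(prefix, p)]] <- list(env = layer, field = p)
  }
  for (ch in layer$child_names %||% character()) {
    refs <- c(refs, nn_collect(layer[[ch]], paste0(prefix, ch, ".")))
  }
  refs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count trainable parameters of a model or layer
#'
#' Sums the lengths of every trainable parameter array reachable from the
#' layer, recursively. Deterministic and independent of input shape.
#'
#' @param model A model built by [build_model()] or any layer object.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  refs <- nn_collect(model)
  sum(vapply(refs, function(r) length(r$env[[r$field]]), numeric(1)))
}

# ---- linear --------------------------------------------------------------

nn_linear <- function(d_in, d_out, bias = TRUE, sd = 0.02) {
  l <- new_layer("nn_linear",
                 list(d_in = d_in, d_out = d_out, has_bias = bias),
                 params = if (bias) c("W", "b") else "W")
  l$W <- matrix(trunc_normal(d_in * d_out, sd), d_in, d_out)
  if (bias) l$b <- numeric(d_out)
  l
}

#' @exportS3Method
nn_forward.nn_linear <- function(layer, x, meta, training = FALSE) {
  y <- x %*% layer$W
  if (layer$has_bias) y <- sweep(y, 2L, layer$b, "+")
  list(y = y, meta = meta, cache = list(x = x))
}

#' @exportS3Method
nn_backward.nn_linear <- function(layer, cache, dy) {
  grads <- list(W = crossprod(cache$x, dy))
  if (layer$has_bias) grads$b <- colSums(dy)
  list(dx = tcrossprod(dy, layer$W), grads = grads)
}

#' @exportS3Method
nn_flops.nn_linear <- function(layer, meta) {
  list(flops = meta$N * meta$H * meta$W * layer$d_in * layer$d_out, meta = meta)
}

# ---- layer normalization -------------------------------------------------

nn_layernorm <- function(d, eps = 1e-6) {
  l <- new_layer("nn_layernorm", list(d = d, eps = eps), params = c("g", "b"))
  l$g <- rep(1, d); l$b <- numeric(d)
  l
}

layernorm_fwd <- function(x, g, b, eps) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = sweep(xhat * rep(g, each = nrow(x)), 2L, b, "+"), xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dy, xhat, inv, g) {
  d <- ncol(dy)
  dxhat <- dy * rep(g, each = nrow(dy))
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

#' @exportS3Method
nn_forward.nn_layernorm <- function(layer, x, meta, training = FALSE) {
  f <- layernorm_fwd(x, layer$g, layer$b, layer$eps)
  list(y = f$y, meta = meta, cache = list(xhat = f$xhat, inv = f$inv))
}

#' @exportS3Method
nn_backward.nn_layernorm <- function(layer, cache, dy) {
  bw <- layernorm_bwd(dy, cache$xhat, cache$inv, layer$g)
  list(dx = bw$dx, grads = list(g = bw$dg, b = bw$db))
}

#' @exportS3Method
nn_flops.nn_layernorm <- function(layer, meta) list(flops = 0, meta = meta)

# ---- elementwise activation ---------------------------------------------

nn_act <- function(type = c("gelu", "relu", "silu", "sigmoid")) {
  type <- match.arg(type)
  new_layer("nn_act", list(type = type))
}

#' @exportS3Method
nn_forward.nn_act <- function(layer, x, meta, training = FALSE) {
  y <- switch(layer$type,
              gelu = gelu_fwd(x), relu = pmax(x, 0),
              silu = silu_fwd(x), sigmoid = sigmoid(x))
  list(y = y, meta = meta, cache = list(x = x, y = y))
}

#' @exportS3Method
nn_backward.nn_act <- function(layer, cache, dy) {
  g <- switch(layer$type,
              gelu = gelu_bwd(cache$x),
              relu = (cache$x > 0) + 0,
              silu = silu_bwd(cache$x),
              sigmoid = cache$y * (1 - cache$y))
  list(dx = dy * g, grads = list())
}

#' @exportS3Method
nn_flops.nn_act <- function(layer, meta) list(flops = 0, meta = meta)

# ---- dense 2-d convolution (feature-map in, feature-map out) -------------

nn_conv2d <- function(kh, kw, c_in, c_out, stride = 1L, pad = NULL, bias = TRUE) {
  if (is.null(pad)) pad <- c(kh %/% 2L, kw %/% 2L)
  if (length(pad) == 1L) pad <- c(pad, pad)
  l <- new_layer("nn_conv2d",
                 list(kh = kh, kw = kw, c_in = c_in, c_out = c_out,
                      stride = as.integer(stride), pad = as.integer(pad),
                      has_bias = bias),
                 params = if (bias) c("W", "b") else "W")
  fan_in <- kh * kw * c_in
  l$W <- array(stats::rnorm(fan_in * c_out, 0, sqrt(2 / fan_in)), c(kh, kw, c_in, c_out))
  if (bias) l$b <- numeric(c_out)
  l
}

conv_out_dim <- function(H, k, s, p) (H + 2L * p - k) %/% s + 1L

#' @exportS3Method
nn_forward.nn_conv2d <- function(layer, x, meta, training = FALSE) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[4]
  Ho <- conv_out_dim(H, layer$kh, layer$stride, layer$pad[1])
  Wo <- conv_out_dim(W, layer$kw, layer$stride, layer$pad[2])
  Wm <- matrix(layer$W, ncol = layer$c_out)
  y <- array(0, c(Ho, Wo, layer$c_out, N))
  cols <- vector("list", N)
  for (n in seq_len(N)) {
    cn <- im2col_cpp(x[, , , n], H, W, layer$c_in, layer$kh, layer$kw,
                     layer$stride, layer$stride, layer$pad[1], layer$pad[2])
    cols[[n]] <- cn
    yn <- crossprod(cn, Wm)
    if (layer$has_bias) yn <- sweep(yn, 2L, layer$b, "+")
    y[, , , n] <- yn
  }
  list(y = y, meta = list(N = N, H = Ho, W = Wo), cache = list(cols = cols, H = H, W = W))
}

#' @exportS3Method
nn_backward.nn_conv2d <- function(layer, cache, dy) {
  d <- dim(dy); N <- d[4]
  Wm <- matrix(layer$W, ncol = layer$c_out)
  dW <- matrix(0, nrow(Wm), ncol(Wm)); db <- numeric(layer$c_out)
  dx <- array(0, c(cache$H, cache$W, layer$c_in, N))
  for (n in seq_len(N)) {
    dyn <- matrix(dy[, , , n], ncol = layer$c_out)
    dW <- dW + cache$cols[[n]] %*% dyn
    if (layer$has_bias) db <- db + colSums(dyn)
    dcols <- Wm %*% t(dyn)
    dx[, , , n] <- col2im_cpp(dcols, cache$H, cache$W, layer$c_in,
                              layer$kh, layer$kw, layer$stride, layer$stride,
                              layer$pad[1], layer$pad[2])
  }
  grads <- list(W = array(dW, dim(layer$W)))
  if (layer$has_bias) grads$b <- db
  list(dx = dx, grads = grads)
}

#' @exportS3Method
nn_flops.nn_conv2d <- function(layer, meta) {
  Ho <- conv_out_dim(meta$H, layer$kh, layer$stride, layer$pad[1])
  Wo <- conv_out_dim(meta$W, layer$kw, layer$stride, layer$pad[2])
  list(flops = meta$N * Ho * Wo * layer$c_out * layer$c_in * layer$kh * layer$kw,
       meta = list(N = meta$N, H = Ho, W = Wo))
}

# ---- depthwise convolution ----------------------------------------------

nn_dwconv2d <- function(kh, kw, C, stride = 1L, pad = NULL, bias = TRUE) {
  if (is.null(pad)) pad <- c(kh %/% 2L, kw %/% 2L)
  if (length(pad) == 1L) pad <- c(pad, pad)
  l <- new_layer("nn_dwconv2d",
                 list(kh = kh, kw = kw, C = C, stride = as.integer(stride),
                      pad = as.integer(pad), has_bias = bias),
                 params = if (bias) c("W", "b") else "W")
  fan_in <- kh * kw
  l$W <- array(stats::rnorm(kh * kw * C, 0, sqrt(2 / fan_in)), c(kh, kw, C))
  if (bias) l$b <- numeric(C)
  l
}

#' @exportS3Method
nn_forward.nn_dwconv2d <- function(layer, x, meta, training = FALSE) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[4]
  Ho <- conv_out_dim(H, layer$kh, layer$stride, layer$pad[1])
  Wo <- conv_out_dim(W, layer$kw, layer$stride, layer$pad[2])
  y <- array(0, c(Ho, Wo, layer$C, N))
  for (n in seq_len(N)) {
    yn <- dwconv_fwd_cpp(x[, , , n], layer$W, H, W, layer$C, layer$kh, layer$kw,
                         layer$stride, layer$stride, layer$pad[1], layer$pad[2])
    y[, , , n] <- yn
  }
  if (layer$has_bias) y <- y + rep(layer$b, each = Ho * Wo)
  list(y = y, meta = list(N = N, H = Ho, W = Wo), cache = list(x = x, H = H, W = W))
}

#' @exportS3Method
nn_backward.nn_dwconv2d <- function(layer, cache, dy) {
  d <- dim(dy); N <- d[4]
  dW <- array(0, dim(layer$W))
  dx <- array(0, dim(cache$x))
  for (n in seq_len(N)) {
    dW <- dW + dwconv_bwd_w_cpp(cache$x[, , , n], dy[, , , n], cache$H, cache$W,
                                layer$C, layer$kh, layer$kw, layer$stride,
                                layer$stride, layer$pad[1], layer$pad[2])
    dx[, , , n] <- dwconv_bwd_x_cpp(dy[, , , n], layer$W, cache$H, cache$W,
                                    layer$C, layer$kh, layer$kw, layer$stride,
                                    layer$stride, layer$pad[1], layer$pad[2])
  }
  grads <- list(W = dW)
  if (layer$has_bias) grads$b <- colSums(matrix(aperm(dy, c(1, 2, 4, 3)), ncol = layer$C))
  list(dx = dx, grads = grads)
}

#' @exportS3Method
nn_flops.nn_dwconv2d <- function(layer, meta) {
  Ho <- conv_out_dim(meta$H, layer$kh, layer$stride, layer$pad[1])
  Wo <- conv_out_dim(meta$W, layer$kw, layer$stride, layer$pad[2])
  list(flops = meta$N * Ho * Wo * layer$C * layer$kh * layer$kw,
       meta = list(N = meta$N, H = Ho, W = Wo))
}
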