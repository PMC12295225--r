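# Contrastive normalization and quantized layers.
#
# ContraNorm subtracts a token-similarity-weighted mixture of tokens from
# each token before layer normalization, dispersing representations in the
# embedding space to counter dimensional collapse:
#   x <- (1 + s) * x - s * softmax(x x^T) x,   then LayerNorm(x)
# With s = 0 this is exactly plain layer normalization.

#' Build a contrastive normalization layer
#'
#' @param d Feature dimension.
#' @param scale Dispersal strength `s >= 0`; 0 reduces to layer
#'   normalization.
#' @return A layer object.
#' @export
new_contranorm <- function(d, scale = 0.1) {
  stopifnot(scale >= 0)
  l <- new_layer("nn_contranorm", list(d = d, s = scale, eps = 1e-6),
                 params = c("g", "b"))
  l$g <- rep(1, d); l$b <- numeric(d)
  l
}

#' Apply contrastive normalization to a token matrix
#'
#' @param x Token matrix (L x d) for a single sample, or a batch as an
#'   (L, d, N) array.
#' @param scale Dispersal strength `s`.
#' @param gamma,beta Optional affine parameters of the embedded layer
#'   normalization (defaults: identity).
#' @return Normalized tokens of the same shape.
#' @export
contranorm <- function(x, scale = 0.1, gamma = NULL, beta = NULL) {
  if (length(dim(x)) == 3L) {
    out <- x
    for (n in seq_len(dim(x)[3])) out[, , n] <- contranorm(x[, , n], scale, gamma, beta)
    return(out)
  }
  d <- ncol(x)
  if (is.null(gamma)) gamma <- rep(1, d)
  if (is.null(beta)) beta <- numeric(d)
  y <- contranorm_disperse(x, scale)
  layernorm_fwd(y, gamma, beta, 1e-6)$y
}

contranorm_disperse <- function(x, s) {
  if (s == 0) return(x)
  P <- softmax_rows(tcrossprod(x))
  (1 + s) * x - s * (P %*% x)
}

#' @exportS3Method
nn_forward.nn_contranorm <- function(layer, x, meta, training = FALSE) {
  s <- layer$s
  L <- meta$H * meta$W
  N <- meta$N
  if (s == 0) {
    f <- layernorm_fwd(x, layer$g, layer$b, layer$eps)
    return(list(y = f$y, meta = meta,
                cache = list(xhat = f$xhat, inv = f$inv, P = NULL)))
  }
  y1 <- x
  Ps <- vector("list", N)
  for (n in seq_len(N)) {
    rows <- ((n - 1L) * L + 1L):(n * L)
    xs <- x[rows, , drop = FALSE]
    P <- softmax_rows(tcrossprod(xs))
    Ps[[n]] <- P
    y1[rows, ] <- (1 + s) * xs - s * (P %*% xs)
  }
  f <- layernorm_fwd(y1, layer$g, layer$b, layer$eps)
  list(y = f$y, meta = meta,
       cache = list(xhat = f$xhat, inv = f$inv, P = Ps, x = x, L = L, N = N))
}

#' @exportS3Method
nn_backward.nn_contranorm <- function(layer, cache, dy) {
  bw <- layernorm_bwd(dy, cache$xhat, cache$inv, layer$g)
  grads <- list(g = bw$dg, b = bw$db)
  s <- layer$s
  if (s == 0 || is.null(cache$P)) return(list(dx = bw$dx, grads = grads))
  dy1 <- bw$dx
  dx <- dy1
  for (n in seq_len(cache$N)) {
    rows <- ((n - 1L) * cache$L + 1L):(n * cache$L)
    xs <- cache$x[rows, , drop = FALSE]
    g1 <- dy1[rows, , drop = FALSE]
    P <- cache$P[[n]]
    dP <- -s * tcrossprod(g1, xs)                  # d/dP of  -s * P x
    dA <- P * (dP - rowSums(dP * P))               # softmax backward, row-wise
    dx[rows, ] <- (1 + s) * g1 - s * crossprod(P, g1) + (dA + t(dA)) %*% xs
  }
  list(dx = dx, grads = grads)
}

#' @exportS3Method
nn_flops.nn_contranorm <- function(layer, meta) list(flops = 0, meta = meta)

# ---- uniform quantization ------------------------------------------------

#' Quantization parameters
#'
#' @param bit_width Bit width `b`; codes occupy `\[0, 2^b - 1\]`.
#' @param scale Positive step size.
#' @param zero_point Integer code mapped to real 0.
#' @param mode `"uniform"` or `"log2"`.
#' @return A `quant_params` list.
#' @export
quant_params <- function(bit_width = 8L, scale = 1, zero_point = 0L,
                         mode = c("uniform", "log2")) {
  mode <- match.arg(mode)
  if (scale <= 0) stop("quantization scale must be positive, got ", scale)
  structure(list(bit_width = as.integer(bit_width), scale = scale,
                 zero_point = as.integer(zero_point), mode = mode),
            class = "quant_params")
}

#' Calibrate uniform quantization parameters from observed values
#'
#' Uses the observed min/max as the representable range (asymmetric
#' per-tensor quantization).
#'
#' @param x Numeric values observed during calibration.
#' @param bit_width Bit width.
#' @return A [quant_params()] object.
#' @export
calibrate_quant <- function(x, bit_width = 8L) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) hi <- lo + 1e-8
  n <- 2^bit_width - 1
  scale <- (hi - lo) / n
  quant_params(bit_width, scale, as.integer(round(-lo / scale)))
}

#' Uniform quantization to integer codes
#'
#' `code = clamp(round(x / scale) + zero_point, 0, 2^b - 1)`.
#'
#' @param x Numeric values.
#' @param qp A [quant_params()].
#' @return Integer codes with the shape of `x`.
#' @export
quantize_uniform <- function(x, qp) {
  if (qp$scale <= 0) stop("quantization scale must be positive")
  code <- round(x / qp$scale) + qp$zero_point
  pmin(pmax(code, 0), 2^qp$bit_width - 1)
}

#' Dequantize uniform codes back to reals
#'
#' @param codes Integer codes.
#' @param qp A [quant_params()].
#' @return Numeric values `(codes - zero_point) * scale`.
#' @export
dequantize_uniform <- function(codes, qp) (codes - qp$zero_point) * qp$scale

fake_quant_uniform <- function(x, qp) dequantize_uniform(quantize_uniform(x, qp), qp)

# ---- log2 quantization of post-softmax activations -----------------------

#' Log2 quantization of post-softmax activations
#'
#' Probabilities in (0, 1] are coded by the rounded negative base-2
#' logarithm: `code = clamp(round(-log2 p), 0, 2^b - 1)`.
#'
#' @param p Post-softmax activations, all in (0, 1].
#' @param bit_width Bit width of the exponent code.
#' @return Integer exponent codes.
#' @export
log2_quantize <- function(p, bit_width = 8L) {
  if (any(p <= 0)) stop("log2 quantization requires strictly positive inputs")
  pmin(pmax(round(-log2(p)), 0), 2^bit_width - 1)
}

#' Dequantize log2 exponent codes
#'
#' @param codes Integer exponent codes.
#' @return `2^(-codes)`.
#' @export
log2_dequantize <- function(codes) 2^(-codes)

fake_quant_log2 <- function(p, bit_width = 4L) log2_dequantize(log2_quantize(p, bit_width))

# ---- polynomial exponential approximation --------------------------------

#' Second-order polynomial approximation of exp on \[-ln 2, 0\]
#'
#' Arbitrary non-positive arguments are range-decomposed as
#' `e^x = 2^(-z) * e^r` with `r` in `\[-ln 2, 0\]`, where the residual
#' exponential is approximated by `a (r + b)^2 + c` with integer-friendly
#' constants.
#'
#' @param x Numeric vector (values above 0 are clamped to 0).
#' @return Approximation of `exp(x)`.
#' @export
poly_exp <- function(x) {
  x <- pmin(x, 0)
  ln2 <- log(2)
  z <- floor(-x / ln2)
  r <- x + z * ln2                      # r in (-ln 2, 0]
  p <- 0.3585 * (r + 1.353)^2 + 0.344
  p * 2^(-z)
}

#' Softmax computed with the polynomial exponential
#'
#' @param x Logit matrix (softmax along rows).
#' @return Row-stochastic matrix approximating `softmax(x)`.
#' @export
softmax_poly <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- matrix(poly_exp(x), nrow(x), ncol(x))
  e / rowSums(e)
}

# ---- quantized layers (fake-quant with straight-through gradients) -------

# Activation quantizer: tracks running min/max during training forward
# passes and fake-quantizes once calibrated. Straight-through estimator:
# gradients pass unchanged inside the clip range.
new_qact <- function(bit_width = 8L) {
  new_layer("nn_qact",
            list(bit_width = as.integer(bit_width), lo = NULL, hi = NULL))
}

#' @exportS3Method
nn_forward.nn_qact <- function(layer, x, meta, training = FALSE) {
  if (training || is.null(layer$lo)) {
    layer$lo <- if (is.null(layer$lo)) min(x) else min(layer$lo, min(x))
    layer$hi <- if (is.null(layer$hi)) max(x) else max(layer$hi, max(x))
  }
  qp <- calibrate_quant(c(layer$lo, layer$hi), layer$bit_width)
  y <- fake_quant_uniform(x, qp)
  list(y = y, meta = meta,
       cache = list(mask = (x >= layer$lo - qp$scale / 2) &
                      (x <= layer$hi + qp$scale / 2)))
}

#' @exportS3Method
nn_backward.nn_qact <- function(layer, cache, dy) {
  list(dx = dy * cache$mask, grads = list())
}

#' @exportS3Method
nn_flops.nn_qact <- function(layer, meta) list(flops = 0, meta = meta)

# Linear layer with uniformly fake-quantized weights.
new_qlinear <- function(d_in, d_out, bit_width = 8L, bias = TRUE) {
  l <- nn_linear(d_in, d_out, bias = bias)
  l$bit_width <- as.integer(bit_width)
  class(l) <- c("nn_qlinear", class(l))
  l
}

#' @exportS3Method
nn_forward.nn_qlinear <- function(layer, x, meta, training = FALSE) {
  qp <- calibrate_quant(layer$W, layer$bit_width)
  Wq <- fake_quant_uniform(layer$W, qp)
  y <- x %*% Wq
  if (layer$has_bias) y <- sweep(y, 2L, layer$b, "+")
  list(y = y, meta = meta, cache = list(x = x, Wq = Wq))
}

#' @exportS3Method
nn_backward.nn_qlinear <- function(layer, cache, dy) {
  grads <- list(W = crossprod(cache$x, dy))   # straight-through on weights
  if (layer$has_bias) grads$b <- colSums(dy)
  list(dx = tcrossprod(dy, cache$Wq), grads = grads)
}

#' @exportS3Method
nn_flops.nn_qlinear <- function(layer, meta) {
  list(flops = meta$N * meta$H * meta$W * layer$d_in * layer$d_out, meta = meta)
}
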