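# Omni-Dimensional Dynamic Convolution (ODC): n candidate kernels modulated
# by four attention factors -- spatial (kernel positions), input-channel,
# output-channel (filter) and kernel-wise -- produced by a shared
# GAP -> FC -> ReLU -> four-head FC trunk with sigmoid gates.

#' Configuration for omni-dimensional dynamic convolution
#'
#' @param in_channels,out_channels Channel counts.
#' @param kernel_size Odd square kernel size.
#' @param num_kernels Number of candidate kernels `n`.
#' @param reduction Bottleneck ratio of the attention trunk.
#' @param groups Convolution groups (only 1 is supported).
#' @param kernel_attn Gate for the kernel-wise factor: `"sigmoid"` applies a
#'   sigmoid like the other three factors; `"softmax"` normalizes over the
#'   `n` kernels instead.
#' @return An `odc_config` list.
#' @export
odc_config <- function(in_channels, out_channels, kernel_size = 3L,
                       num_kernels = 4L, reduction = 16L, groups = 1L,
                       kernel_attn = c("sigmoid", "softmax")) {
  kernel_attn <- match.arg(kernel_attn)
  stopifnot(in_channels >= 1, out_channels >= 1, kernel_size %% 2 == 1,
            num_kernels >= 1, reduction >= 1)
  if (groups != 1L) stop("only groups = 1 is supported")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel_size = as.integer(kernel_size),
                 num_kernels = as.integer(num_kernels),
                 reduction = as.integer(reduction),
                 groups = 1L, kernel_attn = kernel_attn),
            class = "odc_config")
}

#' Build an ODC layer
#'
#' @param cfg An [odc_config()].
#' @return An ODC layer; apply with [odc_forward()] or `nn_forward()`.
#' @export
new_odconv <- function(cfg) {
  ks <- cfg$kernel_size
  hidden <- max(1L, cfg$in_channels %/% cfg$reduction)
  l <- new_layer("nn_odconv",
                 list(cfg = cfg, kh = ks, kw = ks, hidden = hidden,
                      pad = c(ks %/% 2L, ks %/% 2L)),
                 params = c("W", "b", "fc1_W", "fc1_b",
                            "hs_W", "hs_b", "hc_W", "hc_b",
                            "hf_W", "hf_b", "hw_W", "hw_b"))
  fan_in <- ks * ks * cfg$in_channels
  l$W <- array(stats::rnorm(fan_in * cfg$out_channels * cfg$num_kernels,
                            0, sqrt(2 / fan_in)),
               c(ks, ks, cfg$in_channels, cfg$out_channels, cfg$num_kernels))
  l$b <- numeric(cfg$out_channels)
  l$fc1_W <- matrix(trunc_normal(cfg$in_channels * hidden), cfg$in_channels, hidden)
  l$fc1_b <- numeric(hidden)
  # gate biases start open (sigmoid(3) ~ 0.95) so the modulated kernel is
  # close to a plain convolution at initialization instead of attenuating
  # the signal by 1/16
  l$hs_W <- matrix(trunc_normal(hidden * ks * ks), hidden, ks * ks)
  l$hs_b <- rep(3, ks * ks)
  l$hc_W <- matrix(trunc_normal(hidden * cfg$in_channels), hidden, cfg$in_channels)
  l$hc_b <- rep(3, cfg$in_channels)
  l$hf_W <- matrix(trunc_normal(hidden * cfg$out_channels), hidden, cfg$out_channels)
  l$hf_b <- rep(3, cfg$out_channels)
  l$hw_W <- matrix(trunc_normal(hidden * cfg$num_kernels), hidden, cfg$num_kernels)
  l$hw_b <- rep(3, cfg$num_kernels)
  l
}

odc_trunk <- function(layer, x) {
  d <- dim(x); N <- d[4]
  g <- gap_hw(x)
  z0 <- sweep(g %*% layer$fc1_W, 2L, layer$fc1_b, "+")
  z <- pmax(z0, 0)
  ls <- sweep(z %*% layer$hs_W, 2L, layer$hs_b, "+")
  lc <- sweep(z %*% layer$hc_W, 2L, layer$hc_b, "+")
  lf <- sweep(z %*% layer$hf_W, 2L, layer$hf_b, "+")
  lw <- sweep(z %*% layer$hw_W, 2L, layer$hw_b, "+")
  aw <- if (layer$cfg$kernel_attn == "softmax")
    softmax_rows(matrix(lw, N, layer$cfg$num_kernels)) else sigmoid(lw)
  list(g = g, z0 = z0, z = z,
       a_s = sigmoid(ls), a_c = sigmoid(lc), a_f = sigmoid(lf), a_w = aw)
}

#' Compute the four ODC attention factor sets
#'
#' @param x Feature map (H, W, C, N) with `C` matching the layer.
#' @param layer An ODC layer from [new_odconv()].
#' @return List with per-sample factor matrices `a_s` (N x kh*kw), `a_c`
#'   (N x in_channels), `a_f` (N x out_channels), `a_w` (N x n); all values
#'   lie strictly in (0, 1) for the sigmoid gates.
#' @export
odc_attentions <- function(x, layer) {
  d <- dim(x)
  if (d[3] != layer$cfg$in_channels)
    stop("channel mismatch: ODC expects ", layer$cfg$in_channels,
         " channels, got ", d[3])
  t <- odc_trunk(layer, x)
  t[c("a_s", "a_c", "a_f", "a_w")]
}

odc_kernel_slice <- function(layer, t) {
  array(layer$W[, , , , t, drop = FALSE], dim(layer$W)[1:4])
}

odc_effective_kernel <- function(layer, a_s, a_c, a_f, a_w) {
  cfg <- layer$cfg
  A <- outer(matrix(a_s, layer$kh, layer$kw), a_c) # (kh,kw,Cin)
  Wbar <- array(0, dim(layer$W)[1:4])
  for (t in seq_len(cfg$num_kernels)) Wbar <- Wbar + a_w[t] * odc_kernel_slice(layer, t)
  Weff <- Wbar * as.vector(A)                       # broadcast over Cout
  sweep(Weff, 4L, a_f, "*")
}

#' Omni-dimensional dynamic convolution forward pass
#'
#' Per sample, the effective kernel is
#' `sum_i a_w[i] * (a_f x a_c x a_s) * W_i` (elementwise modulation with
#' broadcasting along the matching kernel dimension) followed by a single
#' convolution.
#'
#' @param x Feature map (H, W, C, N).
#' @param layer An ODC layer from [new_odconv()].
#' @param factors Optional precomputed factors from [odc_attentions()]
#'   (recycled per sample); when `NULL` they are computed from `x`.
#' @return Output feature map.
#' @export
odc_forward <- function(x, layer, factors = NULL) {
  d <- dim(x)
  if (d[3] != layer$cfg$in_channels)
    stop("channel mismatch: ODC expects ", layer$cfg$in_channels,
         " channels, got ", d[3])
  if (is.null(factors)) factors <- odc_attentions(x, layer)
  N <- d[4]
  Ho <- conv_out_dim(d[1], layer$kh, 1L, layer$pad[1])
  Wo <- conv_out_dim(d[2], layer$kw, 1L, layer$pad[2])
  y <- array(0, c(Ho, Wo, layer$cfg$out_channels, N))
  for (n in seq_len(N)) {
    Weff <- odc_effective_kernel(layer, factors$a_s[n, ], factors$a_c[n, ],
                                 factors$a_f[n, ], factors$a_w[n, ])
    cn <- im2col_cpp(x[, , , n], d[1], d[2], layer$cfg$in_channels,
                     layer$kh, layer$kw, 1L, 1L, layer$pad[1], layer$pad[2])
    y[, , , n] <- sweep(crossprod(cn, matrix(Weff, ncol = layer$cfg$out_channels)),
                        2L, layer$b, "+")
  }
  y
}

odc_trunk_tok <- function(layer, x, meta) {
  N <- meta$N; L <- meta$H * meta$W
  g <- rowsum(x, rep(seq_len(N), each = L), reorder = FALSE) / L
  z0 <- sweep(g %*% layer$fc1_W, 2L, layer$fc1_b, "+")
  z <- pmax(z0, 0)
  aw <- sweep(z %*% layer$hw_W, 2L, layer$hw_b, "+")
  aw <- if (layer$cfg$kernel_attn == "softmax")
    softmax_rows(matrix(aw, N, layer$cfg$num_kernels)) else sigmoid(aw)
  list(g = g, z0 = z0, z = z,
       a_s = sigmoid(sweep(z %*% layer$hs_W, 2L, layer$hs_b, "+")),
       a_c = sigmoid(sweep(z %*% layer$hc_W, 2L, layer$hc_b, "+")),
       a_f = sigmoid(sweep(z %*% layer$hf_W, 2L, layer$hf_b, "+")),
       a_w = aw)
}

# token-mode fast path for pointwise (1x1) kernels: the convolution is a
# per-sample linear map, so no image-layout conversion is needed
odc_forward_tok <- function(layer, x, meta, training) {
  cfg <- layer$cfg
  N <- meta$N; L <- meta$H * meta$W
  tr <- odc_trunk_tok(layer, x, meta)
  Wm <- matrix(layer$W, cfg$in_channels * cfg$out_channels, cfg$num_kernels)
  y <- matrix(0, N * L, cfg$out_channels)
  for (n in seq_len(N)) {
    rows <- ((n - 1L) * L + 1L):(n * L)
    Wbar <- matrix(Wm %*% tr$a_w[n, ], cfg$in_channels, cfg$out_channels)
    Weff <- tr$a_s[n, 1] * (tr$a_c[n, ] * Wbar) *
      rep(tr$a_f[n, ], each = cfg$in_channels)
    y[rows, ] <- x[rows, , drop = FALSE] %*% Weff
  }
  y <- sweep(y, 2L, layer$b, "+")
  list(y = y, meta = meta, cache = list(x = x, tr = tr, L = L, N = N))
}

odc_backward_tok <- function(layer, cache, dy) {
  cfg <- layer$cfg
  tr <- cache$tr; N <- cache$N; L <- cache$L
  nk <- cfg$num_kernels
  Wm <- matrix(layer$W, cfg$in_channels * cfg$out_channels, nk)
  dWm <- matrix(0, nrow(Wm), nk)
  da_s <- matrix(0, N, 1); da_c <- matrix(0, N, cfg$in_channels)
  da_f <- matrix(0, N, cfg$out_channels); da_w <- matrix(0, N, nk)
  dx <- matrix(0, N * L, cfg$in_channels)
  for (n in seq_len(N)) {
    rows <- ((n - 1L) * L + 1L):(n * L)
    xs <- cache$x[rows, , drop = FALSE]
    dys <- dy[rows, , drop = FALSE]
    G <- crossprod(xs, dys)                     # Cin x Cout, d/dWeff
    Wbar <- matrix(Wm %*% tr$a_w[n, ], cfg$in_channels, cfg$out_channels)
    A <- tr$a_s[n, 1] * outer(tr$a_c[n, ], tr$a_f[n, ])
    AG <- A * G
    for (t in seq_len(nk)) {
      dWm[, t] <- dWm[, t] + tr$a_w[n, t] * as.vector(AG)
      da_w[n, t] <- sum(AG * matrix(Wm[, t], cfg$in_channels, cfg$out_channels))
    }
    P <- G * Wbar                               # d/dA
    da_s[n, 1] <- sum(P * outer(tr$a_c[n, ], tr$a_f[n, ]))
    da_c[n, ] <- tr$a_s[n, 1] * as.vector(P %*% tr$a_f[n, ])
    da_f[n, ] <- tr$a_s[n, 1] * as.vector(crossprod(P, tr$a_c[n, ]))
    Weff <- A * Wbar
    dx[rows, ] <- tcrossprod(dys, Weff)
  }
  dls <- da_s * tr$a_s * (1 - tr$a_s)
  dlc <- da_c * tr$a_c * (1 - tr$a_c)
  dlf <- da_f * tr$a_f * (1 - tr$a_f)
  dlw <- if (cfg$kernel_attn == "softmax") softmax_rows_bwd(tr$a_w, da_w)
         else da_w * tr$a_w * (1 - tr$a_w)
  dz <- tcrossprod(dls, layer$hs_W) + tcrossprod(dlc, layer$hc_W) +
    tcrossprod(dlf, layer$hf_W) + tcrossprod(dlw, layer$hw_W)
  dz0 <- dz * (tr$z0 > 0)
  dg <- tcrossprod(dz0, layer$fc1_W)
  dx <- dx + (dg / L)[rep(seq_len(N), each = L), , drop = FALSE]
  list(dx = dx,
       grads = list(W = array(dWm, dim(layer$W)), b = colSums(dy),
                    fc1_W = crossprod(tr$g, dz0), fc1_b = colSums(dz0),
                    hs_W = crossprod(tr$z, dls), hs_b = colSums(dls),
                    hc_W = crossprod(tr$z, dlc), hc_b = colSums(dlc),
                    hf_W = crossprod(tr$z, dlf), hf_b = colSums(dlf),
                    hw_W = crossprod(tr$z, dlw), hw_b = colSums(dlw)))
}

#' @exportS3Method
nn_forward.nn_odconv <- function(layer, x, meta, training = FALSE) {
  if (is.matrix(x)) {
    stopifnot(layer$kh == 1L, layer$kw == 1L)
    return(odc_forward_tok(layer, x, meta, training))
  }
  d <- dim(x); N <- d[4]
  tr <- odc_trunk(layer, x)
  cfg <- layer$cfg
  Ho <- conv_out_dim(d[1], layer$kh, 1L, layer$pad[1])
  Wo <- conv_out_dim(d[2], layer$kw, 1L, layer$pad[2])
  y <- array(0, c(Ho, Wo, cfg$out_channels, N))
  cols <- vector("list", N)
  for (n in seq_len(N)) {
    Weff <- odc_effective_kernel(layer, tr$a_s[n, ], tr$a_c[n, ],
                                 tr$a_f[n, ], tr$a_w[n, ])
    cn <- im2col_cpp(x[, , , n], d[1], d[2], cfg$in_channels,
                     layer$kh, layer$kw, 1L, 1L, layer$pad[1], layer$pad[2])
    cols[[n]] <- cn
    y[, , , n] <- sweep(crossprod(cn, matrix(Weff, ncol = cfg$out_channels)),
                        2L, layer$b, "+")
  }
  list(y = y, meta = list(N = N, H = Ho, W = Wo),
       cache = list(cols = cols, tr = tr, H = d[1], W = d[2]))
}

#' @exportS3Method
nn_backward.nn_odconv <- function(layer, cache, dy) {
  if (is.matrix(dy)) return(odc_backward_tok(layer, cache, dy))
  cfg <- layer$cfg
  d <- dim(dy); N <- d[4]
  tr <- cache$tr
  nk <- cfg$num_kernels
  dW <- array(0, dim(layer$W)); db <- numeric(cfg$out_channels)
  da_s <- matrix(0, N, layer$kh * layer$kw)
  da_c <- matrix(0, N, cfg$in_channels)
  da_f <- matrix(0, N, cfg$out_channels)
  da_w <- matrix(0, N, nk)
  dx <- array(0, c(cache$H, cache$W, cfg$in_channels, N))
  HW <- cache$H * cache$W
  dg <- matrix(0, N, cfg$in_channels)
  for (n in seq_len(N)) {
    a_s <- tr$a_s[n, ]; a_c <- tr$a_c[n, ]; a_f <- tr$a_f[n, ]; a_w <- tr$a_w[n, ]
    dyn <- matrix(dy[, , , n], ncol = cfg$out_channels)
    db <- db + colSums(dyn)
    G <- array(cache$cols[[n]] %*% dyn, dim(layer$W)[1:4])   # d/dWeff
    A <- outer(matrix(a_s, layer$kh, layer$kw), a_c)
    Wbar <- array(0, dim(layer$W)[1:4])
    for (t in seq_len(nk)) Wbar <- Wbar + a_w[t] * odc_kernel_slice(layer, t)
    Gf <- sweep(G, 4L, a_f, "*")                              # G * a_f
    AGf <- Gf * as.vector(A)                                  # (A x a_f) * G
    for (t in seq_len(nk)) {
      dW[, , , , t] <- array(dW[, , , , t, drop = FALSE], dim(AGf)) + a_w[t] * AGf
      da_w[n, t] <- sum(AGf * odc_kernel_slice(layer, t))
    }
    P <- Gf * Wbar                                            # d/dA before outer split
    dA <- array(rowSums(matrix(P, ncol = cfg$out_channels)),
                c(layer$kh, layer$kw, cfg$in_channels))
    dAm <- matrix(dA, layer$kh * layer$kw, cfg$in_channels)
    da_s[n, ] <- as.vector(dAm %*% a_c)
    da_c[n, ] <- as.vector(crossprod(dAm, a_s))
    da_f[n, ] <- colSums(matrix(G * Wbar * as.vector(A), ncol = cfg$out_channels))
    Weff <- sweep(Wbar * as.vector(A), 4L, a_f, "*")
    dx[, , , n] <- col2im_cpp(matrix(Weff, ncol = cfg$out_channels) %*% t(dyn),
                              cache$H, cache$W, cfg$in_channels,
                              layer$kh, layer$kw, 1L, 1L,
                              layer$pad[1], layer$pad[2])
  }
  # gates
  dls <- da_s * tr$a_s * (1 - tr$a_s)
  dlc <- da_c * tr$a_c * (1 - tr$a_c)
  dlf <- da_f * tr$a_f * (1 - tr$a_f)
  dlw <- if (cfg$kernel_attn == "softmax") softmax_rows_bwd(tr$a_w, da_w)
         else da_w * tr$a_w * (1 - tr$a_w)
  dz <- tcrossprod(dls, layer$hs_W) + tcrossprod(dlc, layer$hc_W) +
    tcrossprod(dlf, layer$hf_W) + tcrossprod(dlw, layer$hw_W)
  dz0 <- dz * (cache$tr$z0 > 0)
  dg <- dg + tcrossprod(dz0, layer$fc1_W)
  for (n in seq_len(N))
    dx[, , , n] <- dx[, , , n] + rep(dg[n, ] / HW, each = HW)
  list(dx = dx,
       grads = list(W = dW, b = db,
                    fc1_W = crossprod(tr$g, dz0), fc1_b = colSums(dz0),
                    hs_W = crossprod(tr$z, dls), hs_b = colSums(dls),
                    hc_W = crossprod(tr$z, dlc), hc_b = colSums(dlc),
                    hf_W = crossprod(tr$z, dlf), hf_b = colSums(dlf),
                    hw_W = crossprod(tr$z, dlw), hw_b = colSums(dlw)))
}

#' @exportS3Method
nn_flops.nn_odconv <- function(layer, meta) {
  cfg <- layer$cfg
  Ho <- conv_out_dim(meta$H, layer$kh, 1L, layer$pad[1])
  Wo <- conv_out_dim(meta$W, layer$kw, 1L, layer$pad[2])
  conv <- meta$N * Ho * Wo * cfg$out_channels * cfg$in_channels * layer$kh * layer$kw
  attn <- meta$N * (cfg$in_channels * layer$hidden +
                    layer$hidden * (layer$kh * layer$kw + cfg$in_channels +
                                    cfg$out_channels + cfg$num_kernels))
  list(flops = conv + attn, meta = list(N = meta$N, H = Ho, W = Wo))
}
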