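# Dynamic Inception Convolution (DIC) stem: a dynamic (K-kernel) strided
# projection followed by a four-branch Inception-style depthwise mixer
# (small square kernel, two orthogonal band kernels, identity).

#' Configuration for the Dynamic Inception Convolution stem
#'
#' @param in_channels Number of input channels (3 for RGB microscopy images).
#' @param embed_dim Stem output channels.
#' @param num_kernels Number of parallel candidate kernels `K` aggregated by
#'   the kernel attention.
#' @param small_kernel Odd size of the small square depthwise kernel.
#' @param band_kernel Odd size of the asymmetric band kernels (1 x kb and
#'   kb x 1); a pair of band kernels approximates a large square receptive
#'   field at a fraction of the cost.
#' @param branch_ratios Four non-negative channel fractions (square band,
#'   horizontal band, vertical band, identity) summing to 1.
#' @param stem_stride Spatial downsampling factor of the projection.
#' @param attn_reduction Bottleneck ratio of the kernel-attention subnet.
#' @param proj_kernel Kernel size of the dynamic projection convolution.
#' @return A `dic_config` list.
#' @export
dic_config <- function(in_channels = 3L, embed_dim = 96L, num_kernels = 4L,
                       small_kernel = 3L, band_kernel = 11L,
                       branch_ratios = c(1 / 8, 1 / 8, 1 / 8, 5 / 8),
                       stem_stride = 4L, attn_reduction = 4L, proj_kernel = 3L) {
  stopifnot(in_channels >= 1, embed_dim >= 1, num_kernels >= 1,
            small_kernel %% 2 == 1, band_kernel %% 2 == 1,
            small_kernel <= band_kernel, stem_stride >= 1)
  if (length(branch_ratios) != 4L || any(branch_ratios < 0) ||
      abs(sum(branch_ratios) - 1) > 1e-8)
    stop("branch_ratios must be four non-negative fractions summing to 1")
  ch <- branch_ratios * embed_dim
  if (any(abs(ch - round(ch)) > 1e-8))
    stop("indivisible channel split: branch_ratios times ", embed_dim,
         " channels must be integers (got ", paste(signif(ch, 4), collapse = ", "), ")")
  ch <- round(ch)
  structure(list(in_channels = as.integer(in_channels),
                 embed_dim = as.integer(embed_dim),
                 num_kernels = as.integer(num_kernels),
                 small_kernel = as.integer(small_kernel),
                 band_kernel = as.integer(band_kernel),
                 branch_ratios = branch_ratios,
                 branch_channels = as.integer(ch),
                 stem_stride = as.integer(stem_stride),
                 attn_reduction = as.integer(attn_reduction),
                 proj_kernel = as.integer(proj_kernel)),
            class = "dic_config")
}

#' Create a dynamic kernel bank (K parallel kernels + attention subnet)
#'
#' The bank holds `K` convolution kernels of identical shape and a two-layer
#' affine attention subnet applied after global average pooling; a softmax
#' over the subnet output yields per-sample mixing weights for the kernels.
#'
#' @param c_in,c_out Input/output channels of each kernel.
#' @param kernel Square kernel size.
#' @param K Number of candidate kernels.
#' @param stride Convolution stride.
#' @param attn_reduction Bottleneck ratio of the attention subnet.
#' @return A layer object usable with [kernel_attention()] and
#'   [aggregate_and_convolve()].
#' @export
dynamic_kernel_bank <- function(c_in, c_out, kernel = 3L, K = 4L, stride = 1L,
                                attn_reduction = 4L) {
  hidden <- max(8L, c_in %/% attn_reduction)
  l <- new_layer("nn_dynconv2d",
                 list(kh = kernel, kw = kernel, c_in = c_in, c_out = c_out,
                      K = as.integer(K), stride = as.integer(stride),
                      pad = c(kernel %/% 2L, kernel %/% 2L), hidden = hidden),
                 params = c("kernels", "b", "fc1_W", "fc1_b", "fc2_W", "fc2_b"))
  fan_in <- kernel * kernel * c_in
  l$kernels <- array(stats::rnorm(fan_in * c_out * K, 0, sqrt(2 / fan_in)),
                     c(kernel, kernel, c_in, c_out, K))
  l$b <- numeric(c_out)
  l$fc1_W <- matrix(trunc_normal(c_in * hidden), c_in, hidden)
  l$fc1_b <- numeric(hidden)
  l$fc2_W <- matrix(trunc_normal(hidden * K), hidden, K)
  l$fc2_b <- numeric(K)
  l
}

#' Per-sample attention weights over the kernels of a dynamic kernel bank
#'
#' Global average pooling over space, two affine maps, then a softmax over
#' the `K` candidate kernels. Weights are non-negative and sum to 1 per
#' sample.
#'
#' @param x Feature map, an (H, W, C, N) array.
#' @param bank A [dynamic_kernel_bank()].
#' @return N x K matrix of softmax weights.
#' @export
kernel_attention <- function(x, bank) {
  d <- dim(x)
  if (d[3] != bank$c_in)
    stop("channel mismatch: bank expects ", bank$c_in, " channels, got ", d[3])
  N <- d[4]
  g <- gap_hw(x)
  z <- sweep(g %*% bank$fc1_W, 2L, bank$fc1_b, "+")
  logit <- sweep(z %*% bank$fc2_W, 2L, bank$fc2_b, "+")
  softmax_rows(matrix(logit, N, bank$K))
}

#' Convolve with the per-sample attention-blended kernel
#'
#' For each sample the effective kernel is the weight-blended sum over the
#' bank's `K` kernels; by linearity this equals the same weighting applied to
#' `K` separate convolutions.
#'
#' @param x Feature map (H, W, C, N).
#' @param bank A [dynamic_kernel_bank()].
#' @param weights N x K weight matrix, typically from [kernel_attention()].
#' @return Output feature map.
#' @export
aggregate_and_convolve <- function(x, bank, weights) {
  d <- dim(x); N <- d[4]
  Ho <- conv_out_dim(d[1], bank$kh, bank$stride, bank$pad[1])
  Wo <- conv_out_dim(d[2], bank$kw, bank$stride, bank$pad[2])
  y <- array(0, c(Ho, Wo, bank$c_out, N))
  kflat <- matrix(bank$kernels, ncol = bank$K)
  for (n in seq_len(N)) {
    Wn <- matrix(kflat %*% weights[n, ], ncol = bank$c_out)
    cn <- im2col_cpp(x[, , , n], d[1], d[2], bank$c_in, bank$kh, bank$kw,
                     bank$stride, bank$stride, bank$pad[1], bank$pad[2])
    y[, , , n] <- sweep(crossprod(cn, Wn), 2L, bank$b, "+")
  }
  y
}

#' @exportS3Method
nn_forward.nn_dynconv2d <- function(layer, x, meta, training = FALSE) {
  d <- dim(x); N <- d[4]
  g <- gap_hw(x)
  z <- sweep(g %*% layer$fc1_W, 2L, layer$fc1_b, "+")
  logit <- sweep(z %*% layer$fc2_W, 2L, layer$fc2_b, "+")
  wts <- softmax_rows(matrix(logit, N, layer$K))
  Ho <- conv_out_dim(d[1], layer$kh, layer$stride, layer$pad[1])
  Wo <- conv_out_dim(d[2], layer$kw, layer$stride, layer$pad[2])
  kflat <- matrix(layer$kernels, ncol = layer$K)
  y <- array(0, c(Ho, Wo, layer$c_out, N))
  cols <- vector("list", N)
  for (n in seq_len(N)) {
    Wn <- matrix(kflat %*% wts[n, ], ncol = layer$c_out)
    cn <- im2col_cpp(x[, , , n], d[1], d[2], layer$c_in, layer$kh, layer$kw,
                     layer$stride, layer$stride, layer$pad[1], layer$pad[2])
    cols[[n]] <- cn
    y[, , , n] <- sweep(crossprod(cn, Wn), 2L, layer$b, "+")
  }
  list(y = y, meta = list(N = N, H = Ho, W = Wo),
       cache = list(cols = cols, wts = wts, g = g, z = z, H = d[1], W = d[2]))
}

#' @exportS3Method
nn_backward.nn_dynconv2d <- function(layer, cache, dy) {
  d <- dim(dy); N <- d[4]
  kflat <- matrix(layer$kernels, ncol = layer$K)
  dkern <- matrix(0, nrow(kflat), layer$K)
  db <- numeric(layer$c_out)
  dwts <- matrix(0, N, layer$K)
  dx <- array(0, c(cache$H, cache$W, layer$c_in, N))
  HW <- cache$H * cache$W
  for (n in seq_len(N)) {
    dyn <- matrix(dy[, , , n], ncol = layer$c_out)
    dWb <- cache$cols[[n]] %*% dyn                       # (khkwCin) x Cout
    db <- db + colSums(dyn)
    dWbf <- as.vector(dWb)
    dkern <- dkern + tcrossprod(dWbf, cache$wts[n, ])
    dwts[n, ] <- as.vector(crossprod(kflat, dWbf))
    Wn <- matrix(kflat %*% cache$wts[n, ], ncol = layer$c_out)
    dx[, , , n] <- col2im_cpp(Wn %*% t(dyn), cache$H, cache$W, layer$c_in,
                              layer$kh, layer$kw, layer$stride, layer$stride,
                              layer$pad[1], layer$pad[2])
  }
  dlogit <- softmax_rows_bwd(cache$wts, dwts)
  dfc2_W <- crossprod(cache$z, dlogit)
  dfc2_b <- colSums(dlogit)
  dz <- tcrossprod(dlogit, layer$fc2_W)
  dfc1_W <- crossprod(cache$g, dz)
  dfc1_b <- colSums(dz)
  dg <- tcrossprod(dz, layer$fc1_W)                      # N x Cin
  for (n in seq_len(N))
    dx[, , , n] <- dx[, , , n] + rep(dg[n, ] / HW, each = HW)
  list(dx = dx,
       grads = list(kernels = array(dkern, dim(layer$kernels)), b = db,
                    fc1_W = dfc1_W, fc1_b = dfc1_b,
                    fc2_W = dfc2_W, fc2_b = dfc2_b))
}

#' @exportS3Method
nn_flops.nn_dynconv2d <- function(layer, meta) {
  Ho <- conv_out_dim(meta$H, layer$kh, layer$stride, layer$pad[1])
  Wo <- conv_out_dim(meta$W, layer$kw, layer$stride, layer$pad[2])
  conv <- meta$N * Ho * Wo * layer$c_out * layer$c_in * layer$kh * layer$kw
  attn <- meta$N * (layer$c_in * layer$hidden + layer$hidden * layer$K)
  list(flops = conv + attn, meta = list(N = meta$N, H = Ho, W = Wo))
}

# ---- Inception-style depthwise mixer ------------------------------------

new_inception_mixer <- function(cfg) {
  ch <- cfg$branch_channels
  l <- new_layer("nn_inception_mix",
                 list(channels = ch, C = cfg$embed_dim,
                      ks = cfg$small_kernel, kb = cfg$band_kernel))
  l$hw <- nn_dwconv2d(cfg$small_kernel, cfg$small_kernel, ch[1])
  l$w <- nn_dwconv2d(1L, cfg$band_kernel, ch[2])
  l$h <- nn_dwconv2d(cfg$band_kernel, 1L, ch[3])
  l$child_names <- c("hw", "w", "h")
  l
}

#' Four-branch Inception-style depthwise mixing
#'
#' Splits channels into four groups processed by a small square depthwise
#' convolution, two orthogonal band depthwise convolutions (1 x kb and
#' kb x 1) and an identity mapping, then concatenates; channel count and
#' spatial dimensions are preserved.
#'
#' @param x Feature map (H, W, C, N) with `C` equal to the mixer's channels.
#' @param mixer A mixer from `new_inception_mixer()` (or a full
#'   [dic_config()], in which case a freshly initialized mixer is created).
#' @return Feature map of identical shape.
#' @export
inception_mix <- function(x, mixer) {
  if (inherits(mixer, "dic_config")) mixer <- new_inception_mixer(mixer)
  d <- dim(x)
  if (d[3] != mixer$C)
    stop("channel mismatch: mixer expects ", mixer$C, " channels, got ", d[3])
  nn_forward(mixer, x, list(N = d[4], H = d[1], W = d[2]))$y
}

#' @exportS3Method
nn_forward.nn_inception_mix <- function(layer, x, meta, training = FALSE) {
  ch <- layer$channels
  e <- cumsum(ch); s <- c(1L, e[1:3] + 1L)
  caches <- list()
  y <- x
  parts <- list(layer$hw, layer$w, layer$h)
  for (i in 1:3) {
    if (ch[i] == 0L) next
    f <- nn_forward(parts[[i]], x[, , s[i]:e[i], , drop = FALSE], meta, training)
    y[, , s[i]:e[i], ] <- f$y
    caches[[i]] <- f$cache
  }
  list(y = y, meta = meta, cache = list(caches = caches, s = s, e = e))
}

#' @exportS3Method
nn_backward.nn_inception_mix <- function(layer, cache, dy) {
  ch <- layer$channels
  dx <- dy
  grads <- list()
  parts <- c("hw", "w", "h")
  for (i in 1:3) {
    if (ch[i] == 0L) next
    bw <- nn_backward(layer[[parts[i]]], cache$caches[[i]],
                      dy[, , cache$s[i]:cache$e[i], , drop = FALSE])
    dx[, , cache$s[i]:cache$e[i], ] <- bw$dx
    for (g in names(bw$grads)) grads[[paste0(parts[i], ".", g)]] <- bw$grads[[g]]
  }
  list(dx = dx, grads = grads)
}

#' @exportS3Method
nn_flops.nn_inception_mix <- function(layer, meta) {
  ch <- layer$channels
  f <- meta$N * meta$H * meta$W *
    (ch[1] * layer$ks^2 + ch[2] * layer$kb + ch[3] * layer$kb)
  list(flops = f, meta = meta)
}

# ---- full stem -----------------------------------------------------------

#' Build the DIC stem layer
#'
#' Dynamic strided projection to `embed_dim` channels followed by the
#' Inception-style depthwise mixer. From a 224 x 224 input with the default
#' stride 4 the output grid is 56 x 56.
#'
#' @param cfg A [dic_config()].
#' @return A stem layer; apply with [dic_stem()] or `nn_forward()`.
#' @export
new_dic_stem <- function(cfg = dic_config()) {
  l <- new_layer("nn_dic_stem", list(cfg = cfg))
  l$proj <- dynamic_kernel_bank(cfg$in_channels, cfg$embed_dim,
                                kernel = cfg$proj_kernel, K = cfg$num_kernels,
                                stride = cfg$stem_stride,
                                attn_reduction = cfg$attn_reduction)
  l$mix <- new_inception_mixer(cfg)
  l$child_names <- c("proj", "mix")
  l
}

#' Apply the DIC stem to an image batch
#'
#' @param x Normalized image batch (H, W, 3, N) with spatial dimensions
#'   divisible by the stem stride.
#' @param stem A stem from [new_dic_stem()].
#' @return Feature map (H/stride, W/stride, embed_dim, N).
#' @export
dic_stem <- function(x, stem) {
  d <- dim(x)
  if (d[1] %% stem$cfg$stem_stride != 0 || d[2] %% stem$cfg$stem_stride != 0)
    stop("input spatial dims (", d[1], "x", d[2],
         ") not divisible by stem stride ", stem$cfg$stem_stride)
  nn_forward(stem, x, list(N = d[4], H = d[1], W = d[2]))$y
}

#' @exportS3Method
nn_forward.nn_dic_stem <- function(layer, x, meta, training = FALSE) {
  f1 <- nn_forward(layer$proj, x, meta, training)
  f2 <- nn_forward(layer$mix, f1$y, f1$meta, training)
  list(y = f2$y, meta = f2$meta, cache = list(c1 = f1$cache, c2 = f2$cache))
}

#' @exportS3Method
nn_backward.nn_dic_stem <- function(layer, cache, dy) {
  b2 <- nn_backward(layer$mix, cache$c2, dy)
  b1 <- nn_backward(layer$proj, cache$c1, b2$dx)
  grads <- c(stats::setNames(b1$grads, paste0("proj.", names(b1$grads))),
             stats::setNames(b2$grads, paste0("mix.", names(b2$grads))))
  list(dx = b1$dx, grads = grads)
}

#' @exportS3Method
nn_flops.nn_dic_stem <- function(layer, meta) {
  f1 <- nn_flops(layer$proj, meta)
  f2 <- nn_flops(layer$mix, f1$meta)
  list(flops = f1$flops + f2$flops, meta = f2$meta)
}
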