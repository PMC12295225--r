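# Model assembly: the COKA block (contrastive norm -> ODC -> gated linear
# attention -> contrastive norm -> KAN, with two residual paths) and the
# ablation ladder from the pooling-attention baseline to the full model.
#
# Ladder (each variant adds one substitution):
#   baseline  conv stem + pooling softmax attention + MLP + LayerNorm
#   V0        DIC stem
#   V1        activation-gated linear attention
#   V2        ODC inserted before attention in every block
#   V3        contrastive normalization around attention and at the tail
#   V4        KAN replacing the MLP + quantized tail (full model)

variant_flags <- function(variant) {
  base <- list(stem = "conv", attn = "softmax", odc = FALSE,
               contra = FALSE, ffn = "mlp", quant = FALSE)
  switch(variant,
         baseline = base,
         V0 = modifyList(base, list(stem = "dic")),
         V1 = modifyList(base, list(stem = "dic", attn = "linear")),
         V2 = modifyList(base, list(stem = "dic", attn = "linear", odc = TRUE)),
         V3 = modifyList(base, list(stem = "dic", attn = "linear", odc = TRUE,
                                    contra = TRUE)),
         V4 = modifyList(base, list(stem = "dic", attn = "linear", odc = TRUE,
                                    contra = TRUE, ffn = "kan", quant = TRUE)),
         stop("unknown variant '", variant,
              "'; valid: baseline, V0, V1, V2, V3, V4"))
}

#' Model configuration for the ablation ladder
#'
#' The default geometry is the 10-block profile: stage depths (1, 2, 5, 2),
#' embedding dims doubling 96 -> 768, per-stage heads (1, 2, 4, 8), stem
#' stride 4. The packaged default KAN and MLP widths are the calibrated
#' values of the shipped profile (see `inst/profiles/ilvit-default.yaml`).
#'
#' @param variant One of `"baseline"`, `"V0"` ... `"V4"` (`"V4"` is the full
#'   model).
#' @param num_classes Number of output classes.
#' @param image_size Input image side length.
#' @param stage_depths Blocks per stage; their sum is the stack depth N.
#' @param embed_dims Per-stage embedding dimensions.
#' @param stage_heads Per-stage attention head counts.
#' @param mlp_hidden_ratio MLP hidden width as a multiple of the block input
#'   dim (baseline .. V3).
#' @param kan_grid,kan_order KAN grid size and spline order.
#' @param kan_width_normal Per-stage KAN bottleneck width for non-transition
#'   blocks.
#' @param kan_width_trans KAN bottleneck width at the three stage
#'   transitions.
#' @param odc_num_kernels,odc_kernel_size,odc_reduction In-block ODC
#'   settings.
#' @param kv_strides Per-stage key/value pooling strides of the baseline
#'   pooling attention.
#' @param contra_scale Dispersal strength of contrastive normalization.
#' @param quant_bits Bit width of the quantized tail layers.
#' @param dic A [dic_config()] for the stem (variants V0+).
#' @param stem_kernel Kernel size of the baseline's dense stem convolution.
#' @param qkv_bias Whether Q/K/V projections carry biases.
#' @return A `model_config` list.
#' @export
model_config <- function(variant = "V4", num_classes = 4L, image_size = 224L,
                         stage_depths = c(1L, 2L, 5L, 2L),
                         embed_dims = c(96L, 192L, 384L, 768L),
                         stage_heads = c(1L, 2L, 4L, 8L),
                         mlp_hidden_ratio = 5.55,
                         kan_grid = 4L, kan_order = 3L,
                         kan_width_normal = c(16L, 28L, 28L, 40L),
                         kan_width_trans = c(32L, 32L, 32L),
                         odc_num_kernels = 1L, odc_kernel_size = 1L,
                         odc_reduction = 16L,
                         kv_strides = c(4L, 2L, 1L, 1L),
                         contra_scale = 0.1, quant_bits = 8L,
                         dic = NULL, stem_kernel = 7L, qkv_bias = TRUE) {
  flags <- variant_flags(variant)
  stopifnot(length(stage_depths) == length(embed_dims),
            length(embed_dims) == length(stage_heads),
            num_classes >= 2)
  if (is.null(dic)) dic <- dic_config(embed_dim = embed_dims[1])
  stopifnot(image_size %% dic$stem_stride == 0)
  structure(list(variant = variant, flags = flags,
                 num_classes = as.integer(num_classes),
                 image_size = as.integer(image_size),
                 stage_depths = as.integer(stage_depths),
                 embed_dims = as.integer(embed_dims),
                 stage_heads = as.integer(stage_heads),
                 mlp_hidden_ratio = mlp_hidden_ratio,
                 kan_grid = as.integer(kan_grid),
                 kan_order = as.integer(kan_order),
                 kan_width_normal = as.integer(kan_width_normal),
                 kan_width_trans = as.integer(kan_width_trans),
                 odc_num_kernels = as.integer(odc_num_kernels),
                 odc_kernel_size = as.integer(odc_kernel_size),
                 odc_reduction = as.integer(odc_reduction),
                 kv_strides = as.integer(kv_strides),
                 contra_scale = contra_scale,
                 quant_bits = as.integer(quant_bits),
                 dic = dic, stem_kernel = as.integer(stem_kernel),
                 qkv_bias = qkv_bias),
            class = "model_config")
}

new_norm <- function(d, contra, scale) {
  if (contra) new_contranorm(d, scale) else nn_layernorm(d)
}

new_block <- function(cfg, stage, trans, width_trans_index = 0L) {
  f <- cfg$flags
  d <- cfg$embed_dims[stage]
  d_in <- if (trans) cfg$embed_dims[stage - 1L] else d
  l <- new_layer("nn_block",
                 list(trans = trans, d_in = d_in, d = d, ffn = f$ffn,
                      odc_on = f$odc))
  children <- "norm1"
  l$norm1 <- new_norm(d_in, f$contra, cfg$contra_scale)
  l$pre_conv_on <- FALSE
  if (f$odc) {
    l$odc <- new_odconv(odc_config(d_in, d_in,
                                   kernel_size = cfg$odc_kernel_size,
                                   num_kernels = cfg$odc_num_kernels,
                                   reduction = cfg$odc_reduction))
    children <- c(children, "odc")
  } else if (f$attn == "linear") {
    # the plain convolutional layer preceding linear attention, which the
    # omni-dimensional dynamic convolution later substitutes (V1 -> V2)
    l$pre_conv_on <- TRUE
    l$pre_conv <- nn_dwconv2d(3L, 3L, d_in)
    children <- c(children, "pre_conv")
  }
  l$attn <- new_mha(d_in, d, cfg$stage_heads[stage], mode = f$attn,
                    q_stride = if (trans) 2L else 1L,
                    kv_stride = cfg$kv_strides[stage],
                    qkv_bias = cfg$qkv_bias,
                    quant_bits = if (f$quant && f$attn == "linear") cfg$quant_bits else 0L)
  children <- c(children, "attn")
  if (trans) {
    l$short <- nn_linear(d_in, d)
    children <- c(children, "short")
  }
  l$norm2 <- new_norm(d, f$contra, cfg$contra_scale)
  children <- c(children, "norm2")
  if (f$ffn == "mlp") {
    h <- as.integer(round(cfg$mlp_hidden_ratio * d_in))
    l$fc1 <- nn_linear(d, h); l$act <- nn_act("gelu"); l$fc2 <- nn_linear(h, d)
    children <- c(children, "fc1", "fc2")
  } else {
    w <- if (trans) cfg$kan_width_trans[width_trans_index] else cfg$kan_width_normal[stage]
    l$kan1 <- new_kan_layer(kan_config(d, w, cfg$kan_grid, cfg$kan_order))
    l$kan2 <- new_kan_layer(kan_config(w, d, cfg$kan_grid, cfg$kan_order))
    children <- c(children, "kan1", "kan2")
  }
  l$child_names <- children
  l
}

#' @exportS3Method
nn_forward.nn_block <- function(layer, x, meta, training = FALSE) {
  cache <- list(meta_in = meta)
  f1 <- nn_forward(layer$norm1, x, meta, training); cache$norm1 <- f1$cache
  h <- f1$y
  if (layer$odc_on) {
    if (layer$odc$kh == 1L) {
      fo <- nn_forward(layer$odc, h, meta, training); cache$odc <- fo$cache
      h <- fo$y
    } else {
      fmh <- tokens_to_fm(h, meta$H, meta$W, meta$N)
      fo <- nn_forward(layer$odc, fmh, meta, training); cache$odc <- fo$cache
      h <- fm_to_tokens(fo$y)
    }
  } else if (layer$pre_conv_on) {
    fmh <- tokens_to_fm(h, meta$H, meta$W, meta$N)
    fo <- nn_forward(layer$pre_conv, fmh, meta, training); cache$pre_conv <- fo$cache
    h <- fm_to_tokens(fo$y)
  }
  fa <- nn_forward(layer$attn, h, meta, training); cache$attn <- fa$cache
  mo <- fa$meta
  if (layer$trans) {
    fmx <- tokens_to_fm(x, meta$H, meta$W, meta$N)
    xp <- fm_to_tokens(avgpool2_fwd(fmx))
    fs <- nn_forward(layer$short, xp, mo, training); cache$short <- fs$cache
    xr <- fs$y
  } else xr <- x
  x2 <- xr + fa$y
  f2 <- nn_forward(layer$norm2, x2, mo, training); cache$norm2 <- f2$cache
  if (layer$ffn == "mlp") {
    g1 <- nn_forward(layer$fc1, f2$y, mo, training); cache$fc1 <- g1$cache
    ga <- nn_forward(layer$act, g1$y, mo, training); cache$act <- ga$cache
    g2 <- nn_forward(layer$fc2, ga$y, mo, training); cache$fc2 <- g2$cache
    ff <- g2$y
  } else {
    g1 <- nn_forward(layer$kan1, f2$y, mo, training); cache$kan1 <- g1$cache
    g2 <- nn_forward(layer$kan2, g1$y, mo, training); cache$kan2 <- g2$cache
    ff <- g2$y
  }
  list(y = x2 + ff, meta = mo, cache = cache)
}

#' @exportS3Method
nn_backward.nn_block <- function(layer, cache, dy) {
  grads <- list()
  pg <- function(bw, nm) {
    for (g in names(bw$grads)) grads[[paste0(nm, ".", g)]] <<- bw$grads[[g]]
    bw$dx
  }
  dx2 <- dy
  if (layer$ffn == "mlp") {
    dff <- pg(nn_backward(layer$fc2, cache$fc2, dy), "fc2")
    dff <- nn_backward(layer$act, cache$act, dff)$dx
    dff <- pg(nn_backward(layer$fc1, cache$fc1, dff), "fc1")
  } else {
    dff <- pg(nn_backward(layer$kan2, cache$kan2, dy), "kan2")
    dff <- pg(nn_backward(layer$kan1, cache$kan1, dff), "kan1")
  }
  dx2 <- dx2 + pg(nn_backward(layer$norm2, cache$norm2, dff), "norm2")
  da <- pg(nn_backward(layer$attn, cache$attn, dx2), "attn")
  meta <- cache$meta_in
  if (layer$trans) {
    ds <- pg(nn_backward(layer$short, cache$short, dx2), "short")
    dfm <- avgpool2_bwd(tokens_to_fm(ds, meta$H %/% 2L, meta$W %/% 2L, meta$N),
                        meta$H, meta$W)
    dx <- fm_to_tokens(dfm)
  } else dx <- dx2
  if (layer$odc_on) {
    if (layer$odc$kh == 1L) {
      da <- pg(nn_backward(layer$odc, cache$odc, da), "odc")
    } else {
      dfm <- tokens_to_fm(da, meta$H, meta$W, meta$N)
      da <- fm_to_tokens(pg(nn_backward(layer$odc, cache$odc, dfm), "odc"))
    }
  } else if (layer$pre_conv_on) {
    dfm <- tokens_to_fm(da, meta$H, meta$W, meta$N)
    da <- fm_to_tokens(pg(nn_backward(layer$pre_conv, cache$pre_conv, dfm), "pre_conv"))
  }
  dn <- pg(nn_backward(layer$norm1, cache$norm1, da), "norm1")
  list(dx = dx + dn, grads = grads)
}

#' @exportS3Method
nn_flops.nn_block <- function(layer, meta) {
  f <- 0
  if (layer$odc_on) f <- f + nn_flops(layer$odc, meta)$flops
  if (layer$pre_conv_on) f <- f + nn_flops(layer$pre_conv, meta)$flops
  fa <- nn_flops(layer$attn, meta)
  f <- f + fa$flops
  mo <- fa$meta
  if (layer$trans) f <- f + nn_flops(layer$short, mo)$flops
  if (layer$ffn == "mlp") {
    f <- f + nn_flops(layer$fc1, mo)$flops + nn_flops(layer$fc2, mo)$flops
  } else {
    f <- f + nn_flops(layer$kan1, mo)$flops + nn_flops(layer$kan2, mo)$flops
  }
  list(flops = f, meta = mo)
}

#' Apply one COKA block to a token sequence
#'
#' Computes `x' = x + MHLA(ODC(ContraNorm(x)))` then
#' `y = x' + KAN(ContraNorm(x'))`, both residual paths preserved (layer
#' choices follow the block's configuration; the baseline block substitutes
#' softmax pooling attention, plain layer normalization and an MLP).
#'
#' @param x Token matrix ((N*L) x d, sample-major rows).
#' @param block A block layer (see [build_model()]; `model$blocks[[i]]`).
#' @param H,W Token grid so the ODC convolution can operate on the 2-D
#'   layout.
#' @return Token matrix of the block output.
#' @export
coka_block <- function(x, block, H, W) {
  N <- nrow(x) / (H * W)
  stopifnot(N == round(N))
  nn_forward(block, x, list(N = as.integer(N), H = as.integer(H),
                            W = as.integer(W)))$y
}

# ---- full model ----------------------------------------------------------

#' Build a model variant
#'
#' Constructs the model graph for the requested ablation variant. With the
#' same configuration and seed the construction is deterministic
#' (parameter-wise identical models).
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return A model layer object.
#' @export
build_model <- function(cfg = model_config(), seed = 0L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  f <- cfg$flags
  m <- new_layer("nn_model", list(cfg = cfg))
  if (f$stem == "conv") {
    m$stem <- nn_conv2d(cfg$stem_kernel, cfg$stem_kernel, 3L,
                        cfg$embed_dims[1], stride = cfg$dic$stem_stride)
  } else {
    m$stem <- new_dic_stem(cfg$dic)
  }
  children <- "stem"
  ti <- 0L
  bi <- 0L
  for (s in seq_along(cfg$stage_depths)) for (b in seq_len(cfg$stage_depths[s])) {
    trans <- (s > 1L && b == 1L)
    if (trans) ti <- ti + 1L
    bi <- bi + 1L
    nm <- paste0("block", bi)
    m[[nm]] <- new_block(cfg, s, trans, ti)
    children <- c(children, nm)
  }
  m$n_blocks <- bi
  d_f <- cfg$embed_dims[length(cfg$embed_dims)]
  m$norm_f <- new_norm(d_f, f$contra, cfg$contra_scale)
  children <- c(children, "norm_f")
  if (f$quant) {
    m$qact <- new_qact(cfg$quant_bits)
    m$head <- new_qlinear(d_f, cfg$num_classes, cfg$quant_bits)
  } else {
    m$head <- nn_linear(d_f, cfg$num_classes)
  }
  children <- c(children, if (f$quant) "qact", "head")
  m$child_names <- children
  m
}

#' Model forward pass
#'
#' @param model A model from [build_model()].
#' @param x Image batch as an (H, W, 3, N) array (normalized).
#' @param training Training-mode flag (enables quantizer range tracking).
#' @return List with `logits` (N x num_classes) and, invisibly reusable,
#'   `cache` for [model_backward()].
#' @export
model_forward <- function(model, x, training = FALSE) {
  d <- dim(x)
  meta <- list(N = d[4], H = d[1], W = d[2])
  cache <- list()
  fs <- nn_forward(model$stem, x, meta, training)
  cache$stem <- fs$cache
  tok <- if (length(dim(fs$y)) == 4L) fm_to_tokens(fs$y) else fs$y
  meta <- fs$meta
  for (i in seq_len(model$n_blocks)) {
    nm <- paste0("block", i)
    fb <- nn_forward(model[[nm]], tok, meta, training)
    cache[[nm]] <- fb$cache
    tok <- fb$y; meta <- fb$meta
  }
  fn <- nn_forward(model$norm_f, tok, meta, training)
  cache$norm_f <- fn$cache
  L <- meta$H * meta$W
  pooled <- rowsum(fn$y, rep(seq_len(meta$N), each = L), reorder = FALSE) / L
  hm <- list(N = meta$N, H = 1L, W = 1L)
  h <- pooled
  if (!is.null(model$qact)) {
    fqa <- nn_forward(model$qact, h, hm, training)
    cache$qact <- fqa$cache
    h <- fqa$y
  }
  fh <- nn_forward(model$head, h, hm, training)
  cache$head <- fh$cache
  list(logits = fh$y, cache = cache, meta = meta)
}

#' Model backward pass
#'
#' @param model A model from [build_model()].
#' @param fwd The result of [model_forward()] (with `training = TRUE`).
#' @param dlogits Gradient of the loss with respect to the logits.
#' @return Named list of parameter gradients matching the model's parameter
#'   names.
#' @export
model_backward <- function(model, fwd, dlogits) {
  cache <- fwd$cache
  meta <- fwd$meta
  grads <- list()
  pg <- function(bw, nm) {
    for (g in names(bw$grads)) grads[[paste0(nm, ".", g)]] <<- bw$grads[[g]]
    bw$dx
  }
  dh <- pg(nn_backward(model$head, cache$head, dlogits), "head")
  if (!is.null(model$qact)) dh <- nn_backward(model$qact, cache$qact, dh)$dx
  L <- meta$H * meta$W
  N <- meta$N
  dtok <- matrix(0, N * L, ncol(dh))
  for (n in seq_len(N))
    dtok[((n - 1L) * L + 1L):(n * L), ] <- matrix(dh[n, ] / L, L, ncol(dh), byrow = TRUE)
  dtok <- pg(nn_backward(model$norm_f, cache$norm_f, dtok), "norm_f")
  for (i in rev(seq_len(model$n_blocks))) {
    nm <- paste0("block", i)
    dtok <- pg(nn_backward(model[[nm]], cache[[nm]], dtok), nm)
  }
  dstem_out <- dtok
  if (inherits(model$stem, "nn_conv2d") || inherits(model$stem, "nn_dic_stem")) {
    sm <- stem_out_meta(model, fwd)
    dstem_out <- tokens_to_fm(dtok, sm$H, sm$W, sm$N)
  }
  pg(nn_backward(model$stem, cache$stem, dstem_out), "stem")
  grads
}

stem_out_meta <- function(model, fwd) {
  cfg <- model$cfg
  s <- cfg$image_size %/% 4L
  b1 <- fwd$cache$block1
  list(N = b1$meta_in$N, H = b1$meta_in$H, W = b1$meta_in$W)
}

#' Predict class probabilities or labels
#'
#' @param model A model from [build_model()].
#' @param x Image batch (H, W, 3, N).
#' @param type `"prob"` or `"class"`.
#' @return N x C probability matrix or integer class labels (1-based).
#' @export
model_predict <- function(model, x, type = c("prob", "class")) {
  type <- match.arg(type)
  logits <- model_forward(model, x, training = FALSE)$logits
  p <- softmax_rows(logits)
  if (type == "prob") p else max.col(p, ties.method = "first")
}
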