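# Parameter and FLOP profiling.
#
# FLOP convention: one multiply-accumulate (MAC) = 1 FLOP, counted for
# convolutions and affine maps only (qkv projections, shortcut projections,
# MLP layers, KAN coefficient contractions including the base path, dynamic
# and omni-dimensional convolutions, pooling convolutions, attention-subnet
# FCs once per sample, and the classification head). Excluded: the
# attention score/value products, contrastive-normalization similarity
# products, normalizations, elementwise nonlinearities and the per-sample
# kernel-assembly sums of the dynamic convolutions. This is the convention
# under which the printed efficiency budgets of the model family are
# reproduced; it is switchable via `include_attention_products`.

#' Count forward-pass FLOPs
#'
#' @param model A model from [build_model()].
#' @param input_shape Input shape as `c(channels, height, width)`; batch
#'   size 1.
#' @param include_attention_products Also count the score/value matrix
#'   products of attention and the key-value summaries (off by default; see
#'   convention above).
#' @return Total multiply-accumulate count for one forward pass.
#' @export
count_flops <- function(model, input_shape = c(3L, 224L, 224L),
                        include_attention_products = FALSE) {
  sum(profile_model(model, input_shape, include_attention_products)$flops)
}

attention_product_flops <- function(layer, meta_in, meta_out, meta_kv) {
  Lq <- meta_out$H * meta_out$W
  Lkv <- meta_kv$H * meta_kv$W
  dk <- layer$d_k; h <- layer$heads
  n <- meta_in$N
  if (layer$mode == "linear") {
    n * h * (Lkv * dk * dk + Lq * dk * dk)     # summary + query product
  } else {
    n * h * (Lq * Lkv * dk * 2)                # scores + value mix
  }
}

#' Per-module parameter and FLOP breakdown
#'
#' @inheritParams count_flops
#' @return Data frame with one row per module (stem, each block, tail) and
#'   columns `module`, `params`, `flops`; rows sum to the model totals.
#' @export
profile_model <- function(model, input_shape = c(3L, 224L, 224L),
                          include_attention_products = FALSE) {
  meta <- list(N = 1L, H = as.integer(input_shape[2]), W = as.integer(input_shape[3]))
  mods <- character(); pars <- numeric(); fl <- numeric()
  add <- function(nm, p, f) {
    mods <<- c(mods, nm); pars <<- c(pars, p); fl <<- c(fl, f)
  }
  np <- function(l) {
    refs <- nn_collect(l)
    sum(vapply(refs, function(r) length(r$env[[r$field]]), numeric(1)))
  }
  fs <- nn_flops(model$stem, meta)
  add("stem", np(model$stem), fs$flops)
  meta <- fs$meta
  for (i in seq_len(model$n_blocks)) {
    blk <- model[[paste0("block", i)]]
    fb <- nn_flops(blk, meta)
    f <- fb$flops
    if (include_attention_products) {
      mkv <- if (blk$attn$mode == "softmax")
        list(H = conv_out_dim(meta$H, 3L, blk$attn$kv_stride, 1L),
             W = conv_out_dim(meta$W, 3L, blk$attn$kv_stride, 1L))
      else meta
      f <- f + attention_product_flops(blk$attn, meta, fb$meta, mkv)
    }
    add(paste0("block", i), np(blk), f)
    meta <- fb$meta
  }
  d_f <- model$cfg$embed_dims[length(model$cfg$embed_dims)]
  tailp <- np(model$norm_f) + np(model$head)
  tailf <- meta$N * d_f * model$cfg$num_classes
  add("tail", tailp, tailf)
  data.frame(module = mods, params = pars, flops = fl)
}

#' Profile one or more variants in the style of an efficiency table
#'
#' Builds each variant at the given configuration, counts parameters and
#' forward FLOPs at the stated input, and reports them in millions / G.
#'
#' @param variants Character vector of variant names.
#' @param num_classes Classification head width.
#' @param input_shape `c(channels, height, width)`.
#' @param seed Construction seed.
#' @param ... Further arguments passed to [model_config()].
#' @return Data frame with columns `variant`, `params_M`, `flops_G`.
#' @export
profile_variants <- function(variants = c("baseline", "V0", "V1", "V2", "V3", "V4"),
                             num_classes = 4L, input_shape = c(3L, 224L, 224L),
                             seed = 0L, ...) {
  rows <- lapply(variants, function(v) {
    m <- build_model(model_config(variant = v, num_classes = num_classes, ...),
                     seed = seed)
    data.frame(variant = v,
               params_M = count_parameters(m) / 1e6,
               flops_G = count_flops(m, input_shape) / 1e9)
  })
  do.call(rbind, rows)
}
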