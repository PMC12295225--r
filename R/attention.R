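# Activation-gated linear attention and the multi-head attention layer.
#
# Linear attention:  out = sigmoid(Q) (sigmoid(K^T) softmax(V)) / sqrt(d_k),
# evaluated right-to-left so the key-value summary is a d_k x d_k matrix and
# cost is linear in token count. The softmax over V acts along the feature
# axis of each token (a token-axis softmax would reinstate the quadratic
# evaluation order); the axis is switchable. The baseline variant uses
# conventional softmax attention with strided depthwise pooling on Q/K/V
# (pooling attention).

#' Attention configuration
#'
#' @param embed_dim Embedding dimension of the block.
#' @param num_heads Number of attention heads; must divide `embed_dim`.
#' @param qkv_bias Whether the Q/K/V projection carries a bias.
#' @param softmax_axis Axis of the softmax over V in linear attention:
#'   `"feature"` (per token, the default) or `"token"`.
#' @return An `attention_config` list with `head_dim = embed_dim/num_heads`.
#' @export
attention_config <- function(embed_dim, num_heads = 8L, qkv_bias = TRUE,
                             softmax_axis = c("feature", "token")) {
  softmax_axis <- match.arg(softmax_axis)
  if (embed_dim %% num_heads != 0)
    stop("embed_dim (", embed_dim, ") not divisible by num_heads (", num_heads, ")")
  structure(list(embed_dim = as.integer(embed_dim),
                 num_heads = as.integer(num_heads),
                 head_dim = as.integer(embed_dim %/% num_heads),
                 qkv_bias = qkv_bias, softmax_axis = softmax_axis),
            class = "attention_config")
}

softmax_axis_fwd <- function(V, axis) {
  if (axis == "feature") softmax_rows(V) else t(softmax_rows(t(V)))
}

softmax_axis_bwd <- function(p, dp, axis) {
  if (axis == "feature") softmax_rows_bwd(p, dp)
  else t(softmax_rows_bwd(t(p), t(dp)))
}

#' Activation-gated linear attention for one head
#'
#' Computes `sigmoid(Q) (sigmoid(K^T) softmax(V)) / sqrt(d_k)`: the
#' key-value summary `sigmoid(K^T) softmax(V)` is aggregated first, so the
#' multiply-accumulate count grows linearly in token count (2 L d_k^2
#' instead of the quadratic form's L^2 d_k).
#'
#' @param Q Query tokens (L_q x d_k).
#' @param K,V Key/value tokens (L_kv x d_k); K and V must agree in token
#'   count.
#' @param d_k Scaling dimension (defaults to `ncol(Q)`).
#' @param softmax_axis Softmax axis over V (see [attention_config()]).
#' @return (L_q x d_k) output tokens.
#' @export
linear_attention <- function(Q, K, V, d_k = ncol(Q),
                             softmax_axis = c("feature", "token")) {
  softmax_axis <- match.arg(softmax_axis)
  if (nrow(K) != nrow(V))
    stop("token-count mismatch: K has ", nrow(K), " tokens, V has ", nrow(V))
  S <- crossprod(sigmoid(K), softmax_axis_fwd(V, softmax_axis))
  (sigmoid(Q) %*% S) / sqrt(d_k)
}

# ---- multi-head attention layer -----------------------------------------

# mode "linear": gated linear attention; Q pooled only at stage
#   transitions. mode "softmax": baseline pooling attention with depthwise
#   pooling convolutions on Q, K and V in every block.
new_mha <- function(d_in, d_att, heads, mode = c("linear", "softmax"),
                    q_stride = 1L, kv_stride = 1L, qkv_bias = TRUE,
                    softmax_axis = "feature", quant_bits = 0L) {
  mode <- match.arg(mode)
  stopifnot(d_att %% heads == 0)
  l <- new_layer("nn_mha",
                 list(d_in = d_in, d_att = d_att, heads = as.integer(heads),
                      d_k = as.integer(d_att %/% heads), mode = mode,
                      q_stride = as.integer(q_stride),
                      kv_stride = as.integer(kv_stride),
                      softmax_axis = softmax_axis,
                      quant_bits = as.integer(quant_bits)))
  l$qkv <- nn_linear(d_in, 3L * d_att, bias = qkv_bias)
  l$child_names <- "qkv"
  if (mode == "softmax") {
    l$q_pool <- nn_dwconv2d(3L, 3L, d_att, stride = q_stride)
    l$k_pool <- nn_dwconv2d(3L, 3L, d_att, stride = kv_stride)
    l$v_pool <- nn_dwconv2d(3L, 3L, d_att, stride = kv_stride)
    l$child_names <- c("qkv", "q_pool", "k_pool", "v_pool")
  } else if (q_stride > 1L) {
    l$q_pool <- nn_dwconv2d(3L, 3L, d_att, stride = q_stride)
    l$child_names <- c("qkv", "q_pool")
  }
  l
}

mha_pool <- function(layer, pool_name, x, meta, training) {
  if (is.null(layer[[pool_name]])) return(list(y = x, meta = meta, cache = NULL))
  fm <- tokens_to_fm(x, meta$H, meta$W, meta$N)
  f <- nn_forward(layer[[pool_name]], fm, meta, training)
  list(y = fm_to_tokens(f$y), meta = f$meta, cache = f$cache)
}

mha_unpool <- function(layer, pool_name, cache, dtok, meta_out, meta_in, grads, prefix) {
  if (is.null(layer[[pool_name]])) return(list(dx = dtok, grads = grads))
  dfm <- tokens_to_fm(dtok, meta_out$H, meta_out$W, meta_out$N)
  bw <- nn_backward(layer[[pool_name]], cache, dfm)
  for (g in names(bw$grads)) grads[[paste0(prefix, ".", g)]] <- bw$grads[[g]]
  list(dx = fm_to_tokens(bw$dx), grads = grads)
}

#' @exportS3Method
nn_forward.nn_mha <- function(layer, x, meta, training = FALSE) {
  fq <- nn_forward(layer$qkv, x, meta, training)
  da <- layer$d_att
  Q <- fq$y[, 1:da, drop = FALSE]
  K <- fq$y[, (da + 1):(2 * da), drop = FALSE]
  V <- fq$y[, (2 * da + 1):(3 * da), drop = FALSE]
  pq <- mha_pool(layer, "q_pool", Q, meta, training)
  pk <- mha_pool(layer, "k_pool", K, meta, training)
  pv <- mha_pool(layer, "v_pool", V, meta, training)
  mo <- pq$meta; mkv <- pk$meta
  Lq <- mo$H * mo$W; Lkv <- mkv$H * mkv$W
  N <- meta$N; h <- layer$heads; dk <- layer$d_k
  out <- matrix(0, N * Lq, da)
  if (layer$mode == "linear") {
    sigQ <- sigmoid(pq$y)
    sigK <- sigmoid(pk$y)
    smV <- matrix(0, N * Lkv, da)
    for (j in seq_len(h)) {
      cols <- ((j - 1L) * dk + 1L):(j * dk)
      Vh <- pv$y[, cols, drop = FALSE]
      if (layer$softmax_axis == "feature") {
        smV[, cols] <- softmax_rows(Vh)     # rows are tokens for all samples
      } else {
        for (n in seq_len(N)) {
          rkv <- ((n - 1L) * Lkv + 1L):(n * Lkv)
          smV[rkv, cols] <- softmax_axis_fwd(Vh[rkv, , drop = FALSE], "token")
        }
      }
    }
    smVq <- if (layer$quant_bits > 0L) fake_quant_log2(smV, layer$quant_bits) else smV
    Ss <- vector("list", h)
    for (j in seq_len(h)) {
      cols <- ((j - 1L) * dk + 1L):(j * dk)
      Ss[[j]] <- vector("list", N)
      for (n in seq_len(N)) {
        rq <- ((n - 1L) * Lq + 1L):(n * Lq)
        rkv <- ((n - 1L) * Lkv + 1L):(n * Lkv)
        S <- crossprod(sigK[rkv, cols, drop = FALSE], smVq[rkv, cols, drop = FALSE])
        Ss[[j]][[n]] <- S
        out[rq, cols] <- (sigQ[rq, cols, drop = FALSE] %*% S) / sqrt(dk)
      }
    }
    hc <- list(sigQ = sigQ, sigK = sigK, smV = smV, smVq = smVq, Ss = Ss)
  } else {
    hc <- vector("list", N)
    for (n in seq_len(N)) {
      rq <- ((n - 1L) * Lq + 1L):(n * Lq)
      rkv <- ((n - 1L) * Lkv + 1L):(n * Lkv)
      hc[[n]] <- vector("list", h)
      for (j in seq_len(h)) {
        cols <- ((j - 1L) * dk + 1L):(j * dk)
        Qh <- pq$y[rq, cols, drop = FALSE]
        Kh <- pk$y[rkv, cols, drop = FALSE]
        Vh <- pv$y[rkv, cols, drop = FALSE]
        A <- softmax_rows(tcrossprod(Qh, Kh) / sqrt(dk))
        out[rq, cols] <- A %*% Vh
        hc[[n]][[j]] <- list(A = A, Qh = Qh, Kh = Kh, Vh = Vh)
      }
    }
  }
  list(y = out, meta = mo,
       cache = list(fq = fq$cache, pq = pq, pk = pk, pv = pv, hc = hc,
                    meta_in = meta, mo = mo, mkv = mkv))
}

#' @exportS3Method
nn_backward.nn_mha <- function(layer, cache, dy) {
  da <- layer$d_att; h <- layer$heads; dk <- layer$d_k
  mo <- cache$mo; mkv <- cache$mkv
  Lq <- mo$H * mo$W; Lkv <- mkv$H * mkv$W
  N <- cache$meta_in$N
  dQ <- matrix(0, N * Lq, da)
  dK <- matrix(0, N * Lkv, da)
  dV <- matrix(0, N * Lkv, da)
  if (layer$mode == "linear") {
    cch <- cache$hc
    dsmV <- matrix(0, N * Lkv, da)
    for (j in seq_len(h)) {
      cols <- ((j - 1L) * dk + 1L):(j * dk)
      for (n in seq_len(N)) {
        rq <- ((n - 1L) * Lq + 1L):(n * Lq)
        rkv <- ((n - 1L) * Lkv + 1L):(n * Lkv)
        S <- cch$Ss[[j]][[n]]
        dout <- dy[rq, cols, drop = FALSE]
        dQ[rq, cols] <- tcrossprod(dout, S) / sqrt(dk)
        dS <- crossprod(cch$sigQ[rq, cols, drop = FALSE], dout) / sqrt(dk)
        dK[rkv, cols] <- cch$smVq[rkv, cols, drop = FALSE] %*% t(dS)
        dsmV[rkv, cols] <- cch$sigK[rkv, cols, drop = FALSE] %*% dS
      }
    }
    dQ <- dQ * cch$sigQ * (1 - cch$sigQ)
    dK <- dK * cch$sigK * (1 - cch$sigK)
    # straight-through across the log2 quantizer
    for (j in seq_len(h)) {
      cols <- ((j - 1L) * dk + 1L):(j * dk)
      if (layer$softmax_axis == "feature") {
        dV[, cols] <- softmax_rows_bwd(cch$smV[, cols, drop = FALSE],
                                       dsmV[, cols, drop = FALSE])
      } else {
        for (n in seq_len(N)) {
          rkv <- ((n - 1L) * Lkv + 1L):(n * Lkv)
          dV[rkv, cols] <- softmax_axis_bwd(cch$smV[rkv, cols, drop = FALSE],
                                            dsmV[rkv, cols, drop = FALSE], "token")
        }
      }
    }
  } else {
    for (n in seq_len(N)) {
      rq <- ((n - 1L) * Lq + 1L):(n * Lq)
      rkv <- ((n - 1L) * Lkv + 1L):(n * Lkv)
      for (j in seq_len(h)) {
        cols <- ((j - 1L) * dk + 1L):(j * dk)
        cch <- cache$hc[[n]][[j]]
        dout <- dy[rq, cols, drop = FALSE]
        dA <- tcrossprod(dout, cch$Vh)
        dV[rkv, cols] <- crossprod(cch$A, dout)
        dsc <- softmax_rows_bwd(cch$A, dA) / sqrt(dk)
        dQ[rq, cols] <- dsc %*% cch$Kh
        dK[rkv, cols] <- crossprod(dsc, cch$Qh)
      }
    }
  }
  grads <- list()
  uq <- mha_unpool(layer, "q_pool", cache$pq$cache, dQ, mo, cache$meta_in, grads, "q_pool")
  grads <- uq$grads
  uk <- mha_unpool(layer, "k_pool", cache$pk$cache, dK, mkv, cache$meta_in, grads, "k_pool")
  grads <- uk$grads
  uv <- mha_unpool(layer, "v_pool", cache$pv$cache, dV, mkv, cache$meta_in, grads, "v_pool")
  grads <- uv$grads
  dqkv <- cbind(uq$dx, uk$dx, uv$dx)
  bq <- nn_backward(layer$qkv, cache$fq, dqkv)
  for (g in names(bq$grads)) grads[[paste0("qkv.", g)]] <- bq$grads[[g]]
  list(dx = bq$dx, grads = grads)
}

# Convention: only the qkv projection and pooling convolutions count; the
# gated score/value products are excluded (see vignette).
#' @exportS3Method
nn_flops.nn_mha <- function(layer, meta) {
  f <- nn_flops(layer$qkv, meta)$flops
  mo <- meta
  if (!is.null(layer$q_pool)) {
    pq <- nn_flops(layer$q_pool, meta); mo <- pq$meta; f <- f + pq$flops
  }
  if (layer$mode == "softmax") {
    f <- f + nn_flops(layer$k_pool, meta)$flops + nn_flops(layer$v_pool, meta)$flops
  }
  list(flops = f, meta = mo)
}

#' Multi-head attention over a token sequence
#'
#' Per-head linear Q/K/V projections, gated linear attention (or baseline
#' pooling softmax attention) per head, and concatenation of head outputs.
#'
#' @param x Token matrix ((N*L) x d, rows sample-major) or (L x d) for a
#'   single sample.
#' @param layer A layer from `new_mha()`.
#' @param H,W Spatial grid of the tokens (`H * W = L`); defaults to a single
#'   row of tokens.
#' @return Token matrix of attention outputs.
#' @export
multi_head_attention <- function(x, layer, H = 1L, W = nrow(x)) {
  N <- nrow(x) / (H * W)
  stopifnot(N == round(N))
  if (ncol(x) != layer$d_in)
    stop("embed_dim mismatch: expected ", layer$d_in, ", got ", ncol(x))
  nn_forward(layer, x, list(N = as.integer(N), H = as.integer(H), W = as.integer(W)))$y
}
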