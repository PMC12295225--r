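# Shared fixtures: tiny layer/model configurations and a finite-difference
# gradient checker used across the gradient tests.

tiny_meta <- function(N = 2L, H = 4L, W = 4L) list(N = N, H = H, W = W)

# Small model geometry used wherever a full model is needed quickly.
tiny_model_config <- function(variant = "V4", ...) {
  model_config(variant = variant, num_classes = 4L, image_size = 32L,
               stage_depths = c(1L, 1L, 1L, 1L),
               embed_dims = c(8L, 16L, 32L, 64L),
               stage_heads = c(1L, 2L, 4L, 8L),
               kan_width_normal = c(4L, 4L, 4L, 4L),
               kan_width_trans = c(4L, 4L, 4L),
               kv_strides = c(2L, 2L, 1L, 1L),
               odc_reduction = 4L, ...)
}

# Geometry of the training smoke tests: two stages exercise every ladder
# substitution (DIC stem, pooling vs linear attention, ODC, contrastive
# norm, KAN, quantized tail) including one stage transition.
smoke_model_config <- function(variant) {
  model_config(variant = variant, num_classes = 4L, image_size = 32L,
               stage_depths = c(1L, 1L), embed_dims = c(24L, 48L),
               stage_heads = c(2L, 4L), kan_width_normal = c(8L, 8L),
               kan_width_trans = 8L, kv_strides = c(2L, 1L),
               odc_reduction = 4L)
}

smoke_dataset <- function(per_class = 16L, size = 32L, seed = 11L) {
  ds <- generate_synthetic(synthetic_spec(per_class_count = per_class,
                                          image_size = size, seed = seed))
  dataset_to_batch(ds, size = size, train = FALSE)
}

# central finite differences of sum(forward(x) * dy) against analytic grads
fd_gradient_check <- function(layer, x, meta, n_input = 5L, n_param = 3L,
                              eps = 1e-5) {
  fwd <- ilvit:::nn_forward(layer, x, meta, training = TRUE)
  dy <- fwd$y
  dy[] <- stats::rnorm(length(dy))
  bw <- ilvit:::nn_backward(layer, fwd$cache, dy)
  loss <- function(xx) sum(ilvit:::nn_forward(layer, xx, meta, training = TRUE)$y * dy)
  worst <- 0
  for (ii in sample(length(x), min(n_input, length(x)))) {
    x2 <- x
    x2[ii] <- x2[ii] + eps; l1 <- loss(x2)
    x2[ii] <- x2[ii] - 2 * eps; l0 <- loss(x2)
    worst <- max(worst, abs((l1 - l0) / (2 * eps) - bw$dx[ii]))
  }
  for (p in layer$param_names) {
    w <- layer[[p]]
    for (ii in sample(length(w), min(n_param, length(w)))) {
      w0 <- w[ii]
      layer[[p]][ii] <- w0 + eps; l1 <- loss(x)
      layer[[p]][ii] <- w0 - eps; l0 <- loss(x)
      layer[[p]][ii] <- w0
      worst <- max(worst, abs((l1 - l0) / (2 * eps) - bw$grads[[p]][ii]))
    }
  }
  worst
}
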