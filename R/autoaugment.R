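# AutoAugment (ImageNet policy): 25 sub-policies of two (op, probability,
# magnitude) stages; one sub-policy is drawn per image. Geometric ops use a
# bilinear affine warp filled with the border median; photometric ops follow
# the PIL enhancement semantics on the \[0, 1\] scale.

border_fill <- function(img) {
  S1 <- dim(img)[1]; S2 <- dim(img)[2]
  vapply(1:3, function(ch)
    stats::median(c(img[1, , ch], img[S1, , ch], img[, 1, ch], img[, S2, ch])),
    numeric(1))
}

# Bilinear affine warp: output pixel p maps to A (p - c) + c + t in the input.
warp_affine <- function(img, A, t = c(0, 0)) {
  H <- dim(img)[1]; W <- dim(img)[2]
  fill <- border_fill(img)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gy <- matrix(seq_len(H), H, W) - cy
  gx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  sy <- A[1, 1] * gy + A[1, 2] * gx + cy + t[1]
  sx <- A[2, 1] * gy + A[2, 2] * gx + cx + t[2]
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  inb <- function(yy, xx) yy >= 1 & yy <= H & xx >= 1 & xx <= W
  out <- array(0, dim(img))
  idx <- function(yy, xx) cbind(as.vector(pmin(pmax(yy, 1), H)),
                                as.vector(pmin(pmax(xx, 1), W)))
  for (ch in 1:3) {
    pl <- img[, , ch]
    v00 <- matrix(pl[idx(y0, x0)], H, W)
    v01 <- matrix(pl[idx(y0, x0 + 1)], H, W)
    v10 <- matrix(pl[idx(y0 + 1, x0)], H, W)
    v11 <- matrix(pl[idx(y0 + 1, x0 + 1)], H, W)
    v <- v00 * (1 - fy) * (1 - fx) + v01 * (1 - fy) * fx +
      v10 * fy * (1 - fx) + v11 * fy * fx
    v[!inb(sy, sx)] <- fill[ch]
    out[, , ch] <- v
  }
  out
}

warp_rotate <- function(img, angle_deg) {
  th <- angle_deg * pi / 180
  warp_affine(img, matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2))
}

gray_of <- function(img) {
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  array(rep(g, 3), dim(img))
}

blend <- function(a, b, f) pmin(pmax(b + f * (a - b), 0), 1)

aa_equalize <- function(img) {
  for (ch in 1:3) {
    v <- round(img[, , ch] * 255)
    h <- tabulate(v + 1, 256)
    nz <- h[h > 0]
    if (length(nz) <= 1) next
    step <- (sum(nz) - nz[length(nz)]) / 255
    if (step == 0) next
    lut <- pmin(255, (cumsum(h) - h / 2) / step)
    img[, , ch] <- matrix(lut[v + 1], dim(img)[1], dim(img)[2]) / 255
  }
  img
}

aa_autocontrast <- function(img) {
  for (ch in 1:3) {
    lo <- min(img[, , ch]); hi <- max(img[, , ch])
    if (hi > lo) img[, , ch] <- (img[, , ch] - lo) / (hi - lo)
  }
  img
}

aa_sharpness <- function(img, factor) {
  k <- matrix(c(1, 1, 1, 1, 5, 1, 1, 1, 1) / 13, 3, 3)
  sm <- img
  H <- dim(img)[1]; W <- dim(img)[2]
  for (ch in 1:3) {
    sm[, , ch] <- dwconv_fwd_cpp(array(img[, , ch], c(H, W, 1)),
                                 array(k, c(3, 3, 1)), H, W, 1L,
                                 3L, 3L, 1L, 1L, 1L, 1L)[, , 1]
  }
  # keep the original border (the smoothing kernel is not defined there)
  sm[c(1, H), , ] <- img[c(1, H), , ]; sm[, c(1, W), ] <- img[, c(1, W), ]
  blend(img, sm, factor)
}

apply_aa_op <- function(img, op, mag_idx) {
  m9 <- function(maxv) mag_idx / 9 * maxv
  signed <- function(v) if (stats::runif(1) < 0.5) -v else v
  S <- dim(img)[1]
  switch(op,
    ShearX = warp_affine(img, matrix(c(1, 0, signed(m9(0.3)), 1), 2, 2)),
    ShearY = warp_affine(img, matrix(c(1, signed(m9(0.3)), 0, 1), 2, 2)),
    TranslateX = warp_affine(img, diag(2), c(0, signed(m9(150 / 331) * S))),
    TranslateY = warp_affine(img, diag(2), c(signed(m9(150 / 331) * S), 0)),
    Rotate = warp_rotate(img, signed(m9(30))),
    Color = blend(img, gray_of(img), 1 + signed(m9(0.9))),
    Contrast = blend(img, array(mean(gray_of(img)), dim(img)), 1 + signed(m9(0.9))),
    Brightness = blend(img, array(0, dim(img)), 1 + signed(m9(0.9))),
    Sharpness = aa_sharpness(img, 1 + signed(m9(0.9))),
    Posterize = {
      bits <- 8 - round(m9(4))
      q <- 2^(8 - bits)
      (floor(img * 255 / q) * q) / 255
    },
    Solarize = {
      thr <- (255 - m9(255)) / 255
      ifelse(img >= thr, 1 - img, img)
    },
    AutoContrast = aa_autocontrast(img),
    Equalize = aa_equalize(img),
    Invert = 1 - img,
    stop("unknown AutoAugment op ", op))
}

imagenet_policy <- function() {
  list(
    list(c("Posterize", 0.4, 8), c("Rotate", 0.6, 9)),
    list(c("Solarize", 0.6, 5), c("AutoContrast", 0.6, 5)),
    list(c("Equalize", 0.8, 8), c("Equalize", 0.6, 3)),
    list(c("Posterize", 0.6, 7), c("Posterize", 0.6, 6)),
    list(c("Equalize", 0.4, 7), c("Solarize", 0.2, 4)),
    list(c("Equalize", 0.4, 4), c("Rotate", 0.8, 8)),
    list(c("Solarize", 0.6, 3), c("Equalize", 0.6, 7)),
    list(c("Posterize", 0.8, 5), c("Equalize", 1.0, 2)),
    list(c("Rotate", 0.2, 3), c("Solarize", 0.6, 8)),
    list(c("Equalize", 0.6, 8), c("Posterize", 0.4, 6)),
    list(c("Rotate", 0.8, 8), c("Color", 0.4, 0)),
    list(c("Rotate", 0.4, 9), c("Equalize", 0.6, 2)),
    list(c("Equalize", 0.0, 7), c("Equalize", 0.8, 8)),
    list(c("Invert", 0.6, 4), c("Equalize", 1.0, 8)),
    list(c("Color", 0.6, 4), c("Contrast", 1.0, 8)),
    list(c("Rotate", 0.8, 8), c("Color", 1.0, 2)),
    list(c("Color", 0.8, 8), c("Solarize", 0.8, 7)),
    list(c("Sharpness", 0.4, 7), c("Invert", 0.6, 8)),
    list(c("ShearX", 0.6, 5), c("Equalize", 1.0, 9)),
    list(c("Color", 0.4, 0), c("Equalize", 0.6, 3)),
    list(c("Equalize", 0.4, 7), c("Solarize", 0.2, 4)),
    list(c("Solarize", 0.6, 5), c("AutoContrast", 0.6, 5)),
    list(c("Invert", 0.6, 4), c("Equalize", 1.0, 8)),
    list(c("Color", 0.6, 4), c("Contrast", 1.0, 8)),
    list(c("Equalize", 0.8, 8), c("Equalize", 0.6, 3)))
}

#' Apply one randomly drawn ImageNet AutoAugment sub-policy
#'
#' @param img RGB (H, W, 3) array in \[0, 1\].
#' @return Augmented image. Uses the current RNG stream (seed it for
#'   determinism, e.g. via [train_transform()]).
#' @export
autoaugment_imagenet <- function(img) {
  pol <- imagenet_policy()
  sp <- pol[[sample.int(length(pol), 1)]]
  for (stage in sp) {
    if (stats::runif(1) < as.numeric(stage[2])) {
      img <- apply_aa_op(img, stage[1], as.numeric(stage[3]))
    }
  }
  img
}
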