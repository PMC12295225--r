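---
title: "ILViT: model, design choices and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ILViT: model, design choices and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ilvit)
```

## The model

ILViT is a lightweight hierarchical vision transformer for microscopic cell
classification. Images enter through a **Dynamic Inception Convolution
(DIC)** stem and then pass through four stages of **Contrastive
Omni-Kolmogorov Attention (COKA)** blocks whose embedding dimension doubles
at each stage (96, 192, 384, 768 in the default profile, ten blocks in
total, spatial grid halving at each stage transition). A final contrastive
normalization, global average pooling, a quantized activation and a
quantized linear layer produce the class logits.

### DIC stem

The stem composes two ideas. First, a *dynamic convolution*: the projection
holds `K = 4` candidate kernels of identical shape; a small subnet (global
average pool, two affine maps, softmax) produces a per-sample weight vector
over the kernels, and the input is convolved once with the weight-blended
kernel. Because convolution is linear in the kernel, this equals the same
weighting applied to `K` separate convolutions — a property the tests
exploit as an oracle. Second, an *Inception-style depthwise mixer*: the
projected channels split into four groups processed by a small square
depthwise kernel (3), two orthogonal band kernels (1x11 and 11x1), and an
identity mapping, then concatenate. The branch channel shares default to
(1/8, 1/8, 1/8, 5/8), the Inception-convolution convention. A pair of band
kernels spans a large receptive field at a fraction of a dense kernel's
parameters, which is how the stem undercuts a dense large-kernel front end.

Two open points were settled as follows: the dynamic (K-kernel) aggregation
wraps only the strided projection, not the depthwise branches (exposed as a
structural choice, the projection being where the large-kernel budget
lives), and the projection is a 3x3, stride-4 convolution to the first-stage
width, mirroring the patch-embedding role of the convolutional front end it
replaces.

### COKA block

Each block computes, in pre-norm residual style,

    x' = x  + MHLA(ODC(ContraNorm(x)))
    y  = x' + KAN(ContraNorm(x'))

**ODC** (omni-dimensional dynamic convolution) holds `n` candidate kernels
and modulates them along four axes — spatial position, input channel,
output channel (filter) and kernel index — with per-sample factors from a
shared GAP -> FC -> ReLU trunk with four sigmoid heads. All four gates use a
sigmoid, following the block's pseudo-code convention; a softmax over the
kernel axis is available as a switch. The gate biases initialize at +3
(gates ~0.95) so the modulated kernel starts close to a plain convolution:
with zero-initialized biases the four 0.5-gates attenuate the path
sixteen-fold and visibly starve the early optimization. In the packaged
profile the in-block ODC is a single-kernel pointwise convolution (`n = 1`,
1x1, trunk reduction 16); the module itself implements the general form
(`n = 4`, 3x3 by default).

**Linear attention** gates the projections with sigmoids and reorders the
computation:

    out = sigmoid(Q) (sigmoid(K)^T softmax(V)) / sqrt(d_k)

The key-value summary is a `d_k x d_k` matrix, so the cost is linear in the
token count (2 L d_k^2 multiply-accumulates against L^2 d_k for the
quadratic form). The softmax over `V` runs along the **feature axis** of
each token: a token-axis softmax would couple all tokens and reinstate the
quadratic evaluation order, defeating the construction's purpose; the axis
is nevertheless switchable for comparison. The 1/sqrt(d_k) division is
applied once, to the final product. Head counts follow the multiscale
convention of per-stage doubling (1, 2, 4, 8 in the default profile; the
published training table quotes 8 heads, which matches the final stage).
Head outputs are concatenated directly
onto the residual — there is **no output projection**, exactly as in the
block's pseudo-code; this detail is also what makes the printed parameter
budgets attainable (see *Calibration* below). Stage transitions keep the
baseline's pooling mechanism: a strided depthwise convolution halves the
query grid while the channel width doubles inside the Q/K/V projection.

**ContraNorm** disperses token representations before normalizing:

    x <- (1 + s) x - s softmax(x x^T) x,   then LayerNorm(x)

with `s = 0.1` by default. At `s = 0` this is exactly plain layer
normalization (the V3 substitution is therefore parameter-neutral). The
dispersal counteracts dimensional collapse — tokens that crowd together are
pushed apart by subtracting their similarity-weighted mixture.

**KAN** replaces the MLP: every edge carries a trainable univariate
function, `phi_ij(x) = w_b silu(x) + sum_m c_ijm B_m(x)`, where `B_m` is a
B-spline basis (Cox-de Boor recursion) on a static uniform grid over
[-1, 1]; outputs are `out_j = sum_i phi_ij(x_i)`. Inputs beyond the grid
range extrapolate linearly from the boundary basis values, keeping
gradients defined everywhere; the grid is static for determinism. The
packaged profile uses a bottleneck of two KAN layers (d -> w -> d) with
grid 4 and order 3; a single full-edge d -> d layer (the module default,
grid 5) costs at least `(G + k + 1) d^2` parameters per block and cannot
meet the full model's parameter budget, so the profile trades edge count
for width.

### Quantized tail

Training stays in full precision; quantization is simulated in the forward
pass (fake-quant) so gradients exist, with straight-through estimators.
Three pieces: an 8-bit uniform activation quantizer after global pooling
(asymmetric, calibrated from the running activation range), an 8-bit
uniformly weight-quantized final linear layer, and log2 quantization of the
post-softmax activations inside linear attention
(`code = round(-log2 p)`, dequantized as `2^-code`). A second-order
polynomial approximation of the exponential (`0.3585 (x + 1.353)^2 + 0.344`
on [-ln 2, 0], with range reduction `e^x = 2^-z e^r`) is provided for
integer-friendly softmax evaluation and verified against the true softmax
to 2e-2.

## The ablation ladder

Six variants build up the full model; each adds one substitution:

| variant  | change |
|----------|--------|
| baseline | conv stem, pooling softmax attention, MLP, LayerNorm |
| V0       | DIC stem |
| V1       | activation-gated linear attention (+ a plain depthwise conv before attention) |
| V2       | that conv becomes ODC |
| V3       | LayerNorm becomes ContraNorm (around attention and at the tail) |
| V4       | MLP becomes KAN; quantized tail (full model) |

V1 carries a depthwise 3x3 convolution in front of its attention: the V2
description replaces "the convolutional layer preceding the linear
attention" with ODC, so that layer must already exist in V1.

## Calibration of the default profile

The profile file (`inst/profiles/ilvit-default.yaml`) documents the two
widths calibrated once against the family's printed efficiency budgets and
then frozen. In brief: with stage dims (96, 192, 384, 768), depths
(1, 2, 5, 2) and dim expansion inside the transition attention, block
parameters are dominated by `c . d^2` terms with
`sum(d^2) = 1.23e6` over normal blocks and `0.19e6` over transitions.
The baseline budget (23.33 M) and the full-model budget (8.98 M) cannot be
met simultaneously with an attention output projection or with a
conventional MLP ratio: the non-MLP share of a V2 block must fit inside the
V4 budget, which forces the projection-free attention (as the pseudo-code
writes it) and an MLP hidden ratio of 5.55. Given that skeleton, the KAN
bottleneck widths (16, 28, 28, 40; 32 at transitions, grid 4, order 3)
place V4 at 8.96 M / 1.91 G, the baseline at 23.31 M / 3.97 G, and the
intermediate rungs and their relative reductions fall out correctly without
further tuning (V2 = V3 = 24.90 M / 4.20 G; 52%/61% reductions vs the
baseline, 54.7%/64% vs V3).

### FLOP convention

`count_flops()` counts multiply-accumulates (1 MAC = 1 FLOP) of
convolutions and affine maps only: Q/K/V projections, shortcut projections,
MLP layers, KAN coefficient contractions including the base path
(`(G + k + 1)` MACs per edge per token), DIC/ODC convolutions, pooling
convolutions, the attention-subnet FCs (once per sample) and the head.
Excluded: attention score/value products, the ContraNorm similarity
products, normalizations, elementwise nonlinearities and the per-sample
kernel-assembly sums. This is the convention under which the printed
budgets of the model family are reproduced; `include_attention_products =
TRUE` switches the score/value products back in.

## Synthetic data

`generate_synthetic()` emulates four cell-culture morphologies on a
bright-field canvas (violet-tinted cells on a light background, Gaussian
background noise with sd 0.05 on the [0, 1] scale): *fusiform* — locally
aligned bundles of thin spindles (axis ratio 5, orientation jitter pi/10);
*epithelioid* — sparse rounded cells; *cobblestone* — a dense jittered
polygonal tessellation with dark borders between bright cell bodies;
*mixed* — the field of view partitioned by a random straight boundary into
two regions of different pure morphologies. Everything is deterministic
given the spec's seed.

What it does and does not show: the generator reproduces the *geometry* of
the four classes well enough that they are learnably distinct (a linear
probe on 8x8 downsampled pixels exceeds 60% held-out accuracy), but it has
none of the photometric complexity of real micrographs — no illumination
gradients, focus variation, staining variability, debris or class
imbalance. Passing the training smoke tests therefore demonstrates that
every architectural variant can optimize and fit visually distinct
morphologies, not that it reaches any particular accuracy on real data.

## Training protocol

`train_config()` defaults to the published protocol: AdamW (lr 1e-4, eps
1e-8, betas 0.9/0.999, weight decay 1e-4), batch size 32, cosine decay to
1e-6 with linear warmup starting at 1e-6. The warmup length is not part of
the published table; the package defaults to 20 epochs. One integer seeds
initialization, data order and augmentation independently. The `steps`
argument caps the number of optimizer steps while the cosine schedule keeps
spanning the full `epochs` horizon, so a short run sits on the early,
near-peak part of the schedule exactly as those steps would in a full run.

The training transform follows the published augmentation protocol: random
rotation in [-15, 15] degrees, one randomly drawn sub-policy of the
standard ImageNet AutoAugment table (25 sub-policies; geometric ops via a
bilinear affine warp filled with the border median, photometric ops with
PIL enhancement semantics), bilinear resize to 224 and channel
standardization with means (0.485, 0.456, 0.406) and sds (0.229, 0.224,
0.225). Test-time: resize and standardize only. The robustness
perturbation adds Gaussian noise with sigma = 0.05 on the [0, 1] intensity
scale (after resize, before standardization) and clips.

## Problem sizes used by the test suite

The efficiency checks build the full-size profiles (they only require
construction, no forward pass). The training smoke tests use a scaled-down
geometry chosen as the package's own desk-scale setting: 64 images (4
classes x 16) at 64 x 64, a two-stage ladder with dims (64, 128), one block
per stage, stem stride 8 with a covering 9x9 kernel, warmup 20 epochs and a
500-epoch schedule horizon, 300 optimizer steps. Training accuracy over the
full 64-image set is evaluated every 25 steps and the run stops once it
reaches 95%.

## Numerical choices

* Initialization: truncated normal (sd 0.02) for affine maps, He-normal for
  convolution kernels, unit gains for normalizations, open gates (+3 bias)
  for the ODC attention heads, kernel-attention softmax at temperature 1.
* "Same" padding everywhere; odd kernels preserve spatial dims at stride 1.
* Ties in argmax predictions resolve to the first class.
* Degenerate inputs: the quantizer guards against zero calibration ranges;
  log2 quantization rejects non-positive inputs; cross-entropy clamps
  probabilities at 1e-12; B-spline evaluation outside the knot span clamps
  to the boundary interval and extrapolates linearly.
* Per-class reports define class accuracy as the within-class hit rate
  (equal to recall), the convention of per-class performance tables; micro
  accuracy is trace/total, which coincides with micro recall and micro F1.
  The literal `sum(TP) / sum(TP + FP + FN)` form, whose denominator counts
  every error twice, is available behind `literal = TRUE`.

## Known limitations

* The training loop is plain R plus BLAS; it is meant for desk-scale
  verification, not for 500-epoch runs on real datasets.
* ODC supports `groups = 1` only.
* Quantization is simulated (fake-quant); there are no integer-only
  inference kernels.
* The baseline reproduces the 10-block pooling-attention profile's budget,
  not its exact published implementation details (relative positional
  embeddings and hybrid window attention are out of scope).
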