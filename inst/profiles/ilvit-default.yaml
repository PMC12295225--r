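# ilvit-default profile: the packaged geometry of the model family.
#
# Derivation notes. The 10-block skeleton (stage depths 1-2-5-2, dims
# 96->192->384->768, heads 1-2-4-8, stride-4 stem, dim expansion inside the
# stage-transition attention, no attention output projection — the block
# pseudo-code concatenates heads straight onto the residual) was fixed first.
# Two widths were then calibrated once against the family's printed
# efficiency budgets and frozen:
#   * mlp_hidden_ratio = 5.55 (hidden width of the baseline..V3 MLP as a
#     multiple of the block input dim): places the baseline at 23.31 M
#     parameters / 3.97 GFLOPs (budget: 23.33 M / 4.00 G).
#   * KAN bottleneck widths (16, 28, 28, 40) per stage and 32 at the three
#     transitions, with grid 4 and order 3: places the full model (V4) at
#     8.96 M parameters / 1.91 GFLOPs (budget: 8.98 M / 1.91 G).
# The in-block ODC uses a single candidate pointwise kernel with trunk
# reduction 16, which reproduces the V1 -> V2 increment (+1.70 M / +0.29 G).
# FLOPs follow the package's MAC convention (see the profiling vignette
# section): convolution and affine-map MACs only.

variant: V4
num_classes: 4
image_size: 224
stage_depths: [1, 2, 5, 2]
embed_dims: [96, 192, 384, 768]
stage_heads: [1, 2, 4, 8]
mlp_hidden_ratio: 5.55
kan_grid: 4
kan_order: 3
kan_width_normal: [16, 28, 28, 40]
kan_width_trans: [32, 32, 32]
odc_num_kernels: 1
odc_kernel_size: 1
odc_reduction: 16
kv_strides: [4, 2, 1, 1]
contra_scale: 0.1
quant_bits: 8
stem_kernel: 7
qkv_bias: true
dic:
  in_channels: 3
  embed_dim: 96
  num_kernels: 4
  small_kernel: 3
  band_kernel: 11
  branch_ratios: [0.125, 0.125, 0.125, 0.625]
  stem_stride: 4
  attn_reduction: 4
  proj_kernel: 3
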