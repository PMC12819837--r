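---
title: "SEAFEC: model, design choices, and what the desk-scale tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SEAFEC: model, design choices, and what the desk-scale tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The operator

Agricultural imagery — leaf-disease photographs and crop/weed field scenes
— confronts convolutional networks with two coupled difficulties: lesion
and weed structures span a wide range of scales, and their boundaries are
often diffuse (blurred halos, overlapping leaves, lighting interference).
SEAFEC is a drop-in replacement for a standard `k x k` convolution that
addresses both at once with two parallel branches fused by a learnable
gate:

\[
Y \;=\; \alpha\, F_{\mathrm{SCARF}}(X) \;+\; (1-\alpha)\, F_{\mathrm{MEFE}}(X),
\qquad \alpha = \sigma(a) \in (0,1),
\]

where `a` is a single learnable logit per operator instance.

**SCARF** (spatial–channel adaptive receptive-field attention) replaces the
static kernel with position-specific weights. For an input
\(X \in \mathbb{R}^{B\times C\times H\times W}\):

1. *Attention path.* A local average pooling (window `k`, the module
   stride, valid-tap border averaging) summarizes context; a grouped 1×1
   convolution expands `C` to `C·k²` logits; a softmax over the `k²`
   receptive-field axis yields the attention tensor
   \(A_{rf} \in \mathbb{R}^{B\times C\times k^2\times H'\times W'}\), which
   is nonnegative and sums to one over the `k²` axis at every position.
2. *Feature path.* A depthwise `k x k` convolution (groups = `C`) expands
   each channel into its `k²` receptive-field samples, followed by batch
   normalization, a ReLU, and efficient channel attention (ECA): global
   average pooling, a 1-D cross-channel convolution whose odd kernel size
   adapts to the channel count (`t = floor(|log2(C)/γ + b/γ|)`, bumped to
   the next odd, minimum 3, with γ = 2, b = 1), and a sigmoid gate.
3. *Fusion.* The attention tensor multiplies the features elementwise; the
   `k²` samples of each position are laid out as a row-major `k·H' × k·W'`
   mosaic (sample `u·k+v` of position `(i,j)` at `(i·k+u, j·k+v)`); a
   `k x k` convolution with stride `k` reads exactly one mosaic cell per
   output position and maps `C` to `C_out`.

**MEFE** (multi-scale edge feature enhancement) strengthens boundary cues
without edge annotations. For each pyramid size `s_i`: adaptive average
pooling to `s_i × s_i`, a 1×1 reduction to `C/r` channels, a
depthwise-separable 3×3 convolution, and a bilinear upsample back to
`(H, W)` give the branch features `F_i`. The edge response is a learnable
high-pass step built from a fixed difference,
\(E_i = F_i - \mathrm{AvgPool}_{3\times3}(F_i)\),
refined by a bias-free depthwise-separable stack φ and added back:
\(\hat F_i = F_i + \phi(E_i)\). All \(\hat F_i\) are concatenated and
fused by a 1×1 convolution to `C_out`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `kernel_size` | 3 | SCARF receptive-field extent `k` (odd) |
| `stride` | 1 | shared subsampling of both branches |
| `attention_groups` | `C` | grouping of the 1×1 attention expansion |
| `pool_sizes` | (20, 18, 8) | MEFE pyramid target sizes (classification); (18, 14, 8) detection; (20, 15, 8) segmentation |
| `reduction_ratio` | 4 | MEFE channel shrink `r` (must divide `C`) |
| `refinement_depth` | 2 | depthwise-separable layers in φ |
| `alpha_init` | 0.6 / 0.5 / 0.4 | initial fusion weight per task (classification / detection / segmentation) |

`alpha_init` is stored as the inverse sigmoid of the requested value, so
the initial gate is exact (`alpha_init = 0.6` gives a logit of
`log(0.6/0.4) ≈ 0.405`). Pool sizes larger than the running feature map are
clamped to the map size with a one-time warning per operator instance.

## Design choices at genuinely open points

Several aspects of the operator admit more than one reading; the package
fixes them as follows and treats them as part of the design.

- **Softmax axis.** Attention normalizes over the `k²` receptive-field
  axis, not over space: each position distributes unit mass over its own
  `k²` samples, which is what "relative importance of each receptive-field
  location" requires.
- **Mosaic semantics.** The `k²` axis unfolds row-major
  (`u·k+v → (i·k+u, j·k+v)`), so the stride-`k` fusion convolution sees
  exactly the `k²` weighted samples of one position. The test suite checks
  this against an enumeration oracle that never rearranges anything.
- **Grouping.** The feature expansion uses groups = `C` (each channel
  yields its own `k²` samples), matching the `C → C·k²` bookkeeping; the
  attention expansion's grouping is configurable with a depthwise default.
- **Channel mapping.** When the replaced convolution has `C_in ≠ C_out`,
  the mapping happens in each branch's final convolution (SCARF's stride-k
  fusion, MEFE's 1×1 fusion); a stride > 1 is realized by the pooling /
  strided stages inside the branches so both branches always agree on
  output shape.
- **Border handling.** All averaging steps (attention pooling, the 3×3
  smoothing inside the edge response, MEFE's output down-pool) divide by
  the number of valid taps, and MEFE's depthwise convolutions use
  replicate padding. Consequently a spatially constant map passes through
  the smoothing unchanged, the edge response of a constant map is exactly
  zero everywhere including borders (the high-pass is computed in
  difference form, so this holds to the last bit), and a constant input
  with bias-free convolutions produces a constant output.
- **α granularity.** One scalar logit per operator instance (not
  per-channel, not shared across instances).
- **Activation.** The feature-path nonlinearity defaults to ReLU;
  `identity` is available.
- **Biases.** Final fusion convolutions and the depthwise/ECA convolutions
  are bias-free (they feed normalization or gates); MEFE's reduction and
  pointwise convolutions keep biases; φ is bias-free so the edge path
  cannot inject a DC offset.
- **Initialization.** Fan-in-scaled Gaussian weights, zero biases, drawn
  from a private RNG stream seeded per layer (default seed 42), so two
  constructions with the same seed are bit-identical.

## Backbone surgery and complexity accounting

`build_seafec_resnet18()` replaces the first 3×3 convolution of each of
the eight residual blocks (matching channels and stride; exactly eight
replacements). `build_seafec_deeplabv3()` replaces the three 3×3
convolutions of the final (dilated) bottleneck stage of a
DeepLabV3-ResNet50 without auxiliary head. A generic `replace_convs()`
hook applies any factory to any path-selected convolutions and refuses to
touch a layer that is not a plain convolution, so accidentally re-applying
a surgery fails loudly.

Parameter counts enumerate learnable scalars; MAC counts propagate shapes
through convolution and linear layers only (normalization, pooling and
activations excluded), one MAC per multiply–add. Under this convention the
1000-class ResNet-18 baseline measures 11.69M parameters and 1.81G MACs at
224², and the 21-class no-aux DeepLabV3-ResNet50 measures 39.64M
parameters; these are the conventions the complexity report states in its
header. Replacing convolutions yields a small parameter increase for
SCARF, a large decrease for MEFE (reduced-channel depthwise pyramids are
much cheaper than dense 3×3 kernels), and the largest configuration for
the dual-branch SEAFEC — the orderings the accounting is expected to
reproduce on ResNet-18. On DeepLabV3, the same substitution arithmetic
makes the MEFE variant *smaller* than the baseline (three 2.36M-parameter
convolutions are replaced by ~0.9M-parameter branches); the package
reports what the construction actually counts.

## The synthetic fixtures

The generators emulate the structural regimes the operator targets, not
the photometric statistics of any real dataset:

- *Classification:* near-circular brown spots vs. elongated strips on a
  textured leaf-green background (optionally with blurred halos). Lesions
  are warm-toned (R > G) so lesion pixels are recoverable by threshold;
  under the defaults spot images carry a smaller lesion-pixel share than
  strip images.
- *Segmentation:* broad crop leaves over soil with thin weed blades drawn
  on top until a target weed share is met — three classes with
  intertwined boundaries, rendered to black/red/green pseudo-color masks
  that round-trip exactly.
- *Detection:* dense (≥ 10 small, possibly overlapping) vs. sparse (≤ 3
  large) half-open boxes with lesions drawn inside.

Augmentation draws one operation per copy from {right-angle or ±15°
rotation, 80–100% crop, 0.8–1.2× scale, Gaussian blur σ ∈ [0.5, 1.5],
Gaussian noise σ = 8/255} — values chosen once as field-typical — and
transforms masks and boxes consistently; `copies_per_image = 1` doubles
every class exactly. Everything is bit-reproducible from a seed, with
per-sample streams so subsets are stable.

Because the fixtures are synthetic and small, a passing suite shows that
the operators compute the stated algebra, that every variant can learn,
and that the accounting is exact — it does not show that the operator
improves accuracy on real field imagery.

## Training harness and problem sizes

`smoke_train()` minimizes softmax cross-entropy with Adam (lr 1e-3, batch
32), stopping once training accuracy reaches 100%. The learning check
trains all four ResNet-18 variants on a 200-sample spot-vs-strip fixture
at 32×32 — a size chosen so the full dual-branch network still executes
every code path (all eight replaced blocks, pool clamping, stride
handling) while the whole suite stays a desk-scale computation. The
property checks run the enumeration oracle on instances up to
`B = 2, C = 4, H = W = 6` at tolerance 1e-5, and attention normalization
at 1e-5.

## Numerical notes and limitations

- Batch normalization uses biased batch variance in the normalizer and
  unbiased running updates (momentum 0.1, eps 1e-5); evaluation mode uses
  the running statistics.
- Softmax subtracts the per-position maximum before exponentiation.
- Bilinear resizing uses half-pixel centers without corner alignment.
- Adaptive pooling uses floor/ceil bin edges, so bins may overlap when the
  output size does not divide the input.
- The stack is CPU-only double precision; it is built for correctness and
  desk-scale experiments, not for large-scale training. No pretrained
  weights ship with the package, and no claim is made about reproducing
  published accuracies on external datasets.
- Detection integration into a full one-stage detector is provided only
  through `replace_convs()` on a user-supplied model; no detector
  architecture ships with the package.
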