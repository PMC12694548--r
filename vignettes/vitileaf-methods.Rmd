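---
title: "vitileaf: models, budgets and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vitileaf: models, budgets and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitileaf)
```

## The problem

Identifying grape cultivars from leaf photographs taken in working vineyards
is a fine-grained recognition task: the eleven cultivars handled here differ
in subtle silhouette traits (lobe count, serration pattern, vein geometry)
while the images carry heavy nuisance variation — mixed soil/grass/trunk
backgrounds, varying light and pose, and partial occlusion of the leaf. A
practical field tool must also run on phones and edge devices, which turns
the parameter and multiply-accumulate (MAC) budget into a first-class design
constraint alongside accuracy.

`vitileaf` implements a family of lightweight classifiers around a
MobileNetV3-Small backbone and audits every assembly against its published
budget before a single image is processed.

## Model family

The backbone is the canonical 11-row MobileNetV3-Small stage table
(`mnv3_small_rows()`): a stride-2 stem to 16 channels, eleven
inverted-residual bottlenecks (expansion 1x1 convolution, depthwise 3x3/5x5,
optional attention on the expanded features, linear 1x1 compression, residual
connection when stride is 1 and widths match), a 1x1 head expansion to 576
channels, global average pooling, and a two-layer classifier. The table is
data, not logic: every variant is derived from it.

Four interchangeable attention blocks gate the expanded features
(`attention_block()`):

* **SE** — squeeze (global average pool) and excitation (two 1x1 layers,
  reduction 4 with 8-divisible rounding, hard-sigmoid gate);
* **ECA** — a single adaptive-width 1-D convolution across the pooled channel
  descriptor; essentially parameter-free;
* **CBAM** — channel attention (shared two-layer bottleneck over average- and
  max-pooled descriptors) followed by spatial attention (7x7 convolution over
  the channel-wise mean and max maps);
* **CA (coordinate attention)** — pooling along each spatial axis separately,
  a shared bottleneck 1x1 convolution (hard-swish), then per-axis gates, so
  the attention map encodes *where* along each axis the informative structure
  sits. This suits leaves, whose diagnostic serrations and veins are
  spatially structured.

All four preserve shape, emit gates strictly inside (0, 1), and reduce to the
identity at unit gates — properties the test suite asserts directly.

The fusion variants add an Inception-style multi-branch stage
(`ics_inception_block()`): parallel 1x1 convolution branches — one linear
(conv + batch norm), one ReLU6-activated — plus a stride-1 3x3 max-pooling
branch, filter concatenation, and CBAM dual attention over the concatenation.
The stage is instantiated at two scales in the `ICS-MS` assembly:

* a **micro** block directly after the stem (112x112 resolution at the
  standard input): branches of 128 channels each (pool branch projected),
  concatenation of 384, CBAM, then a linear 1x1 compression back to 16
  channels. Sitting at full stem resolution, this block carries the extra
  multi-scale computation that raises the model's MAC count while adding
  only ~32 k parameters — high-resolution processing is where micro-texture
  (vein and serration detail) is still visible;
* a **macro** block replacing the 96-to-576 head convolution at 7x7: linear
  and ReLU6 branches of 240 channels plus the 96-channel pooling pass-through
  concatenate to exactly 576, so the classifier's input width is unchanged.

Fusion variants use a 480-wide classifier hidden layer (the non-fusion
variants keep the canonical 1024); the joint-loss assembly adds an affine
576-to-85 center-feature projection and an 11x85 class-center matrix.

## Budget pinning

The published table prints whole-model budgets but not the internal widths,
so the free constants were pinned once, by grid search, to reproduce every
printed number exactly, and are frozen in the package
(`R/architectures.R`):

| constant | value | pinned by |
|---|---|---|
| CA reduction ratio | 9 | MS-CA = 1.37 M |
| CBAM in-bottleneck reduction | 4 | MS-CBAM = 1.52 M |
| micro-branch width | 128 | ICS-MS MACs = 0.21 G |
| macro-branch width | 240 | concat = 576 |
| classifier hidden (fusion) | 480 | ICS-MS (CE) = 1.12 M |
| center dimension | 85 | ICS-MS joint = 1.17 M |

```{r audit}
audit_budgets()
```

Checks worth spelling out:

* `count_parameters()` counts every trainable scalar (conv/linear weights and
  biases, batch-norm affine pairs, attention weights, the center projection
  and center matrix); batch-norm running statistics are buffers and are not
  counted. The descriptor-table counts are verified against the instantiated
  models' actual weight arrays in the tests — two independent routes.
* `count_macs()` counts one multiply-accumulate per multiply-add for
  convolution and linear layers at 224x224x3. Budget tables conventionally
  label this quantity "FLOPs(G)"; the printed 0.06 G for the baseline matches
  the MAC convention, not 2x it, so that is what the counter reports.
* The ECA variant honestly counts 1.07 M — an attention mechanism whose whole
  point is to be parameter-free cannot add the ~0.45 M that the published
  1.52 M figure implies, so that single figure is not reproduced and the
  audit's default target table excludes it.
* The derived reductions are computed from the printed (rounded) values:
  (1.53 − 1.37)/1.53 ≈ 10.4 % for the CA swap and (1.53 − 1.17)/1.53 ≈
  23.5 % overall.

## Joint supervision

Training minimises `L = L_CE + lambda * L_center`, with cross-entropy as the
batch mean of the negative log-softmax and the center loss as the batch sum
`0.5 * sum_i ||f(x_i) - mu_{y_i}||^2` on the projected center features
(the standard discriminative-feature-learning formulation; `lambda` absorbs
the mean/sum scale difference). Network weights are optimised by Adam
(learning rate 1e-4 at full scale); the class centers are updated by plain
SGD with the canonical mini-batch rule
`mu_j <- mu_j - alpha * sum_{i: y_i = j}(mu_j - f_i) / (1 + n_j)`, rate
`alpha = 0.5`. The center machinery is exactly inert at `lambda = 0`: a
joint run with zero weight is bit-identical to a plain cross-entropy run,
which the acceptance suite asserts.

The sweep grid for `lambda` is {0, 0.01, 0.05, 0.1, 0.2} with 0.01 as the
shipped default (the grid's argmax at full scale).

## Data pipeline

Splitting is stratified: validation and test each receive
`ceiling(ratio * N)` images allocated across classes by largest remainder
(ties toward larger classes), training takes the per-class residual. On the
published per-class counts this reproduces the 4839/606/606 partition
exactly, with every class within one image of 80/10/10. Five-fold assignment
is stratified the same way (per-class fold sizes within one).

Training-set augmentation follows the field recipe: horizontal flip
(p = 0.5), rotation in ±15° (bilinear, reflect padding), independent
multiplicative brightness/contrast factors in [0.9, 1.1], and 3x3 Gaussian
blur with p = 0.3. The blur sigma is drawn from [0.1, 2] — only the kernel
size is pinned by the protocol, so a range covering near-identity to clearly
soft was chosen once. Normalisation is (x − 0.5)/0.5 per channel, with
ImageNet statistics selectable. Validation and test images pass through
resize and normalisation only.

## The synthetic benchmark

Real vineyard photographs are large and external; the package instead ships
a procedural generator (`generate_leaf_dataset()`) that emulates the
*statistical structure* the models must cope with:

* eleven classes, separable by construction: polar lobed silhouettes
  (3/5/7 lobes) with sinusoidal serration (distinct frequency/amplitude per
  class), vein skeletons at class-specific branching angles, and
  class-specific hue/saturation/size; per-image jitter (±10 % serration and
  scale, small hue shifts) provides intra-class variation;
* backgrounds composed from 2–4 procedural natural-element textures (soil,
  grass, trunk palettes over value noise) — no photographic assets;
* occlusion by elongated grass/twig-shaped occluders drawn until the
  occluded fraction of the ground-truth leaf mask falls inside a declared
  band: none (< 15 %), slight (15–30 %), moderate (30–40 %), mixed
  65/25/10 across the dataset by largest-remainder apportionment;
* the "published" preset uses the published per-class counts (total 6051); the
  "tiny" preset (20 per class) is the continuous-testing scale.

A nearest-centroid classifier on oracle shape descriptors measured from the
rendered masks (dominant low/high angular frequencies of the radial profile,
mean radius) separates the classes essentially perfectly, certifying that
the benchmark is learnable from shape alone. What passing tests on this
benchmark do *not* show: robustness to real photographic nuisance (specular
light, camera noise, true botanical variation); the generator makes no
attempt at photorealism.

## Numerical engine and reproducibility

No deep-learning runtime is assumed: the package carries its own small
reverse-mode engine in base R. Feature maps are stored as (position x
channel) matrices so that 1x1 convolutions — the bulk of the arithmetic in
this architecture family — are single BLAS GEMM calls; depthwise
convolutions are vectorised shift-and-add over kernel taps; batch-norm
backward uses the standard train-mode formula. Every layer's analytic
gradient is verified against central-difference numerical differentiation in
the test suite (relative error ~1e-9). All randomness (weight
initialisation, shuffling, augmentation, dropout) flows from one R RNG seed;
two runs with the same seed produce bit-identical histories. Weight files
embed an audit manifest (variant, class count, parameter count) and loading
refuses a mismatched architecture.

Degenerate inputs: batch-norm guards singleton batches by merging trailing
one-image batches into their predecessor; max-pool padding uses negative
infinity so padded positions never win; attention gates use saturating
hard-sigmoid/sigmoid forms, and a non-finite loss aborts training with the
offending epoch and settings.

## Scaled-down study sizes

The full protocol (224x224 inputs, batch 64, 200 epochs, 5-fold
cross-validation on 6051 images) is far beyond a test suite's budget. The
models are fully convolutional down to the global pool, so the package's
continuous tests run the identical architectures at reduced input sizes.
These sizes were fixed up front as the package's CI scale:

* **learnability benchmark** — tiny preset (220 images), 48x48 inputs,
  batch 16, Adam 1e-3, 20 epochs, `lambda = 0.01`; the fitted training-set
  accuracy must exceed five times the 1/11 chance rate;
* **memorisation smoke test** — two cultivars x 25 images, 48x48, batch 8,
  plain cross-entropy, up to 50 epochs, to 100 % training accuracy;
* **center-loss geometry** — tiny preset at 32x32, 12 epochs, three matched
  seeds x {0, 0.01}: compactness is compared on unit-normalised pooled
  features, since raw intra-class distances confound compactness with the
  overall feature scale, which differs between runs;
* the learning rate 1e-3 (rather than the full-scale 1e-4) compensates for
  the ~100x fewer optimisation steps at this scale.

Parameter counts are resolution-independent and the MAC audit always runs at
the standard 224.

## Known limitations

* The baseline zoo (ResNet50, MobileNetV2, MobileNetV3-Large, ShuffleNetV2)
  exists as exact layer tables for budget auditing; those architectures are
  not instantiated for training.
* The engine is CPU-only and double-precision; it is built for correctness
  and test-scale training, not production throughput.
* The published MS-ECA parameter figure is not reproducible by any faithful
  ECA construction (see above) and is excluded from the audit targets.
* The exact internal widths of the fusion stage are reconstructions pinned
  by the printed budgets; other width allocations could meet the same
  budgets. The audit manifest records the chosen ones.
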