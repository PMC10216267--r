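---
title: "Modular network growth and encoder-decoder segmentation: methods and design"
author: "GraMNet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular network growth and encoder-decoder segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GraMNet)
```

# Scope

GraMNet implements two connected pieces of machinery for liver CT image
analysis, exercisable entirely on synthetic phantoms:

1. **Gradational modular networks (GraMNet)** — convolutional classifiers
   grown incrementally from small building blocks ("SubNets"), where at
   every growth stage the existing network is frozen and only the newest
   SubNet plus a fresh classification head are trained.
2. **En-DeNet** — a U-Net-style encoder-decoder for binary liver/tumor
   segmentation, trained with a compound binary cross-entropy + Dice
   loss, followed by threshold binarization and connected-component
   fragment clearing.

No deep-learning framework is used: the package carries its own
convolutional engine (im2col convolution with C++ kernels, spatial batch
normalization, 2x2 max pooling, Adam, full backpropagation). This is a
deliberate design choice, not a workaround: the staged freezing protocol
is a statement about *which parameters receive gradient updates*, and
owning the engine makes that contract auditable — frozen tensors are
bit-identical before and after training, which the test suite verifies
by cryptographic hash.

# The SubNet and its composition algebra

A SubNet is an ordered stack of layer groups, each
convolution → batch norm → ReLU → (optional) 2x2 max pool. Five presets
("A"–"E") ship with the package; A and C are narrow 8/16/32-filter
stacks (3x3 and 1x1 kernels respectively), B and D are 64/128/256-filter
3x3 stacks, and E uses asymmetric 1x3 / 3x1 / 1x3 kernels. The
classification head global-average-pools the final feature map and
applies one fully connected layer with softmax, so every output row is a
probability vector over the classes.

Networks compose in two ways:

* **Series (A+B)**: SubNet B's first convolution consumes the final
  feature maps of the frozen network A. With $L_A$ and $L_B$ convolution
  layers, the combined classifier has $L_A + L_B$ convolution layers
  plus one fully connected layer.
* **Parallel (A||B)**: both branches receive the identical raw input;
  their final feature maps are spatially aligned and concatenated along
  depth before a fresh joint head.

**Spatial alignment at parallel joins.** Branches that pooled a
different number of times disagree in spatial size. We align to the
*smaller* (deeper-pooled) map by adaptive average pooling of the larger
one, then concatenate along depth. Averaging preserves scale and is the
block-mean adjoint of nearest-neighbor expansion, keeping backward
passes exact. Aligning upward (expanding the smaller map) would
replicate values without adding information and multiply the head's
input size; we chose downward alignment once and apply it everywhere.

**Head input.** The final feature map is global-average-pooled to a
depth-length vector before the fully connected layer. A lexicographic
flattening would also work, but pooling keeps the head size independent
of input resolution, which matters when the same SubNet presets are
attached at different depths of the composition tree.

**Frozen batch norm.** Frozen SubNets run in inference mode: their
batch-norm layers use stored running statistics, and those statistics
are treated as parameters for the purpose of the freezing contract.
Allowing running statistics to drift would make "frozen" false in a way
that hash checks catch immediately.

# Staged training

The canonical growth sequence is A, A+B, A+B||C, A+B||C+D,
(A+B||C+D)||E: B and D attach in series, C and E in parallel. At stage
4, SubNet D consumes the depth-concatenated (A+B || C) features in
series; at stage 5, SubNet E reads the raw input, mirroring C. Each
stage gets a **fresh** classification head: heads are cheap (a few
hundred parameters here), and re-initialization avoids anchoring a new,
larger feature space to the previous head's decision boundary.

Each stage minimizes the empirical cross-entropy risk
$$R = -\frac{1}{M} \sum_{n=1}^{N}\sum_{m=1}^{M} y_{n,m}\,\log \hat y_{n,m},$$
normalized by the class count $M$ (kept literal; a flag switches to the
more common $1/N$). Optimization is Adam with initial learning rate
0.001 (the schedule is specified, the starting rate follows the
segmentation protocol and the common Adam default), dropped by a factor
of 0.1 once half of the scheduled epochs are complete. Validation runs
every 50 iterations; training stops early once the validation loss has
exceeded its running minimum for 50 consecutive checks ("validation
patience"). L2 regularization of $10^{-4}$ applies to the trainable
weight tensors only — frozen parameters receive no decay because they
receive no updates at all. An alternative protocol (batch 16, learning
rate $10^{-4}$, 500 iterations, 0.1 drop after 20 iterations) ships as
the preset `stageTrainPreset("section4")`.

Pooling flags of a preset are adapted to the feature-map size a SubNet
actually sees (`adaptSpecToInput`): a 2x2 pool is dropped when the map
is already a single pixel. This keeps the Table-of-presets filter banks
intact while making deep series attachment well-defined.

# The segmentation model and loss

En-DeNet is a 5-stage encoder-decoder. Each encoder stage is two 3x3
conv + BN + ReLU layers followed by 2x2 max pooling, with the pre-pool
features skipped across to the matching decoder block. The decoder has
5 blocks of two 3x3 convolutions at channel counts (256, 128, 64, 32,
16), nearest-neighbor upsampling and skip concatenation; a 1x1
convolution and sigmoid produce the per-pixel foreground probability.
Two encoders are provided behind one interface: `"tiny5"` (8, 16, 32,
64, 64 channels) and `"effnet-b3-style"` (24, 32, 48, 96, 136), plus
explicit channel overrides; neither uses pretrained weights — transfer
learning is out of scope, and the solvability tests show the phantom
tasks do not need it.

The loss is
$$\mathcal{L} = \mathrm{BCE}(p, y) + \alpha \, (1 - \mathrm{DC}(p, y)),
\qquad \alpha = 0.2,$$
with BCE the negative mean cross-entropy and DC the soft Dice
coefficient $(2\sum p y + s)/(\sum p + \sum y + s)$, smoothing
$s = 10^{-6}$. Two printed-form ambiguities are resolved deliberately:

* A cross-entropy without the leading minus and mean diverges to
  $-\infty$ for good predictions; the standard negative-mean form is the
  only reading consistent with "binary cross-entropy", and it is what we
  implement.
* Adding the Dice *similarity* to a loss would reward bad masks. The
  default Dice term is therefore $1 - \mathrm{DC}$; the literal additive
  similarity is available via `lossConfig(diceAsLoss = FALSE)` for
  comparison.

Soft (probability-valued) Dice is used inside the loss; hard Dice on
binarized masks is used for evaluation.

Training uses Adam (learning rate 0.001, weight decay $10^{-8}$), batch
16, at most 200 epochs, and a plateau scheduler: when the validation
loss has not improved for 5 consecutive epochs the rate is multiplied by
0.1; training stops once the rate falls below $10^{-6}$. A Hausdorff
distance is available as an optional evaluation metric (`hd95`) but is
*not* part of the loss: no formulation or weight for a Hausdorff loss
term is specified anywhere, so we do not invent one.

# Post-processing

Probability maps are binarized at 0.5, with the tie (exactly 0.5)
mapping to foreground — a convention we fixed because *some* rule is
needed and ≥ is the common one. Fragments are then removed: 8-connected
components (4-connectivity splits diagonal bridges that visual
inspection treats as one lesion) with area strictly below 1024 pixels
are dropped, and a component of exactly 1024 pixels is retained. The
1024 threshold is defined at the native 512x512 resolution; working at
a 0.25 resize scales areas by 1/16, so the matching threshold there is
64 pixels — the package leaves `minArea` explicit rather than guessing
the caller's resolution.

# Evaluation metrics

`segmentationMetrics` reports Jaccard $|A \cap B| / |A \cup B|$ and Dice
$2|A \cap B| / (|A| + |B|)$; `classificationMetrics` reports ACC, PRE,
REC, SPE and F1 from confusion counts, and `aucScore` computes AUC as
the normalized Mann-Whitney U statistic (equal to the trapezoidal area
under the ROC curve). Three conventions worth stating:

* The Jaccard index is implemented in its standard form. A reciprocal
  $|A \cup B| / |A \cap B|$ would exceed 1 and would contradict the
  universally reported ordering JSI ≤ DC.
* Recall is the standard sensitivity TP/(TP+FN).
* Degenerate ratios (0/0) are reported as `NA` with a warning rather
  than forced to 0 or 1, so means over many records are not biased by
  empty-mask edge cases. Per-image metrics are computed and then
  averaged (rather than pooling pixels across images); this is the
  package default and is what `writeEvaluationReport` aggregates.

# The phantom generator

`generatePhantom` draws a 2-D slice: a rotated elliptical "liver" at
intensity 0.55 on a 0.15 background, zero or more disk "tumors" inside
the liver whose intensity offset is drawn from a signed contrast range
(negative = hypodense, darker; positive = hyperdense, brighter), plus
clipped additive Gaussian noise (SD 0.02 by default). The tumor mask is
nested inside the liver mask by construction, and a sample is labelled
malignant exactly when its tumor mask is nonempty — an explicit artifact
convention, since no label-derivation rule for binary classification is
otherwise specified. A second channel, when requested, is a smoothed
contrast-stretched copy of the slice; it is a stand-in for a perfusion
map whose actual computation is not specified anywhere, and we make no
claim that it reproduces one.

The generator enforces |contrast| > 2·noise SD so tumor and parenchyma
intensities are statistically separable — this is what makes the
downstream learning tasks solvable by design, and the property suite
verifies ≥95% threshold separability over 100 samples. Phantoms are
2-D because the whole pipeline operates on 2-D slices; the default side
is 128 pixels for desk-scale speed with 512 reachable through the
config. Determinism is per (seed, index), so datasets regenerate
byte-identically.

**What the phantoms do not emulate** — CT physics, Hounsfield units,
organ texture, 3-D anatomy, inter-patient variability, annotation
noise. Passing the solvability tests therefore demonstrates that the
training mechanics work (gradients flow where they should, freezing
holds, the architecture can fit a separable task); it says nothing
about clinical segmentation accuracy, and the package makes no such
claim.

# Numerical choices

* Convolution weights use He initialization; heads use small Gaussian
  weights (SD 0.01) and zero biases. All initialization is
  seed-deterministic, and per-call seeds are derived from a base seed
  with a fixed integer recurrence kept below $2^{31}$.
* Batch norm uses eps $10^{-5}$ and running-statistic momentum 0.1.
* Predicted probabilities are clamped to $[10^{-12}, 1 - 10^{-12}]$
  inside logarithms, so losses are always finite.
* Max-pool ties resolve to the first (top-left) element scanned, which
  keeps the backward pass deterministic.
* Adam uses $\beta_1 = 0.9$, $\beta_2 = 0.999$, eps $10^{-8}$; L2 decay
  is added to weight-tensor gradients only (never biases, BN scalars or
  running statistics).
* Class-prediction ties break toward the lower class index.

# Problem sizes used by the tests

The suite trains the full A–E sequence on 400 phantoms at 32x32
(72/8/20 split) and expects ≥95% test accuracy, and trains a
narrow-channel En-DeNet (`tinySegConfig()`: encoder 4–64, decoder 64–4
channels) on 200 phantoms at 128x128 for 8 epochs at learning rate
0.003, expecting mean liver Dice ≥ 0.8. These sizes were chosen once as
the smallest configurations on which the two tasks are comfortably
solvable; the learning-rate bump for the tiny model simply compensates
for its reduced width. Oracle-equivalence suites run 100 random
instances per operation against brute-force reimplementations
(enumeration, naive convolution loops, flood fill).

# Known limitations

* CPU-only and desk-scale; no attempt at GPU or large-image throughput.
* The DICOM reader supports explicit-VR little-endian single-frame
  files only, and the NIfTI loader does per-slice min-max
  normalization; both are thin conveniences, untested against clinical
  archives.
* Composition trees are binary nestings of series/parallel joins;
  arbitrary DAG topologies and architecture search are out of scope.
* The per-preset parameter totals quoted for SubNets A, C and E in the
  originating material cannot be reconciled with their printed filter
  banks under any standard counting convention (their implied input
  channel counts are unstated); only the SubNet-B figure (0.390 M)
  matches convolution arithmetic, and that is the one the acceptance
  check asserts. `countParameters`/`countMAdd` use the standard
  conventions stated in their documentation.
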