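---
title: "Binocular fundus classification: model, preprocessing and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binocular fundus classification: model, preprocessing and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bfpcnet)
```

## The problem

A patient's two fundus photographs (left and right eye) jointly determine a
multi-label diagnosis over eight ODIR-style categories: normal (N),
diabetes (D), glaucoma (G), cataract (C), age-related macular degeneration
(A), hypertension (H), pathological myopia (M) and other (O). Diseases
develop independently per eye, so a patient-level classifier must combine
evidence from both images; categories are not mutually exclusive, so the
task is multi-label rather than multi-class.

This package implements a complete binocular pipeline: weighted Gaussian
enhancement, a residual convolutional backbone carrying channel+spatial
residual attention blocks, a shared-weight two-branch architecture with a
feature-fusion head, a label-smoothed cross-entropy loss, and the
surrounding data machinery (manifests, stratified 4/1 splitting,
augmentation-driven balancing, per-class confusion metrics). Because no
deep-learning framework is assumed, the network — convolutions via im2col
and BLAS GEMM, batch normalisation, attention, Adam, full backpropagation —
is implemented in base R with two small compiled kernels (`src/conv.cpp`,
`src/bn.cpp`) for the memory-bound inner loops. Backpropagation is verified
against finite differences in the test-suite.

## Preprocessing: the weighted enhancement

Every image is resized to a square and enhanced per colour channel as

$$I_{weight} = \alpha\, I_{org} + \beta\, (I_{org} * K_{h\times w}) + \gamma,$$

with defaults $\alpha = 4$, $\beta = -4$, $\gamma = 128$ and a
$63 \times 63$ Gaussian kernel $K$ with $\sigma = 10$ pixels in both
directions. Since $\beta = -\alpha$, the operation subtracts the
low-frequency background and re-centres the residual at mid-grey: uneven
illumination is flattened and vessels and lesions are amplified. A constant
image maps exactly to uniform 128, which the tests exploit as an analytic
anchor.

Numerical choices the formula itself leaves open:

* **Output range** — the affine combination can exceed 8-bit range; the
  result is clipped to $[0, 255]$. With $\gamma = 128$ centring the
  residuals, clipping only affects the strongest edges.
* **Border handling** — the blur uses reflective (symmetric, edge-repeated)
  padding, implemented with exact dense banded operators so the separable
  blur has a closed linear form. Reflection avoids the dark halo at the
  fundus rim that zero padding would create, and commutes exactly with
  horizontal/vertical flips, which the tests assert on the interior.
* **Resampling** — downscaling uses pixel-area averaging (at integer
  factors, exact block averaging; oracled against brute-force block means),
  upscaling is bilinear. Plain bilinear subsampling would alias the
  high-frequency content that the enhancement then amplifies, so the area
  kernel is the deliberate choice for shrinking.

Augmentation is restricted to the pixel-exact group: rotations by
90/180/270 degrees and horizontal/vertical flips. This keeps every
augmented image free of interpolation artefacts, makes the ops invertible
(useful for testing), and leaves labels untouched. Both eyes of a cloned
patient receive the same op so pairing semantics survive balancing. The
angle set for "rotation" augmentation is a design choice; arbitrary-angle
rotation is excluded on purpose.

## The residual attention block

A block maps a feature tensor $F \in \mathbb{R}^{C\times H\times W}$ to
$M = \mathrm{ReLU}(U' + F)$:

1. **Pre-convolutions.** `n_pre_convs` (default 3) channel-preserving
   $3\times3$ conv+BN+ReLU layers produce $F'$, capturing non-linear
   channel interactions.
2. **Channel attention.** Global average pooling turns $F'$ into a
   $C$-vector; two *independently parameterised* bottleneck dense maps
   ($C \to C/r \to C$, reduction $r = 16$ by default) are applied to that
   one pooled descriptor, summed, and rectified. The printed formula shows
   two identical-looking terms; two independent parameter sets is the
   reading that makes the sum non-trivial. The activation is ReLU — not the
   CBAM sigmoid — so the attention vector is an unbounded non-negative
   gain, and the rescaled map is $U = s \odot F'$.
3. **Spatial attention.** The channel-wise mean collapses $U$ to a
   $1\times H\times W$ map; a stride-1 $3\times3$ spatial max pool is
   applied on top ("superimposed pooling"); a single $7\times7$, 1-to-1
   channel convolution (dimension-preserving padding, CBAM's kernel
   convention) produces an attention map which is multiplied elementwise
   with the pooled map and broadcast across all $C$ channels. This is the
   only reading of the pooling composition consistent with an output of
   shape $C\times H\times W$, which the residual merge requires.
4. **Residual merge.** $M = \mathrm{ReLU}(U' + F)$, with $F$ the block
   *input* — the attention path is a learned additive refinement on top of
   an identity shortcut. (A block output of shape $1\times H\times W$ would
   make this sum ill-formed, so the $C\times H\times W$ contract is applied
   throughout.)

**Initialisation.** Because the attention activations are ReLU rather than
sigmoid, a zero-centred initialisation frequently starts with the whole
attention vector at exactly zero, which gates the block off and — since the
gate's own gradient then vanishes — keeps it off permanently. The two dense
maps therefore start with small positive output biases (0.5 each, so the
initial gain is 1, mirroring a batch-norm gamma of one) and inner biases of
0.1. The tests assert that gradient reaches every trainable parameter on a
synthetic batch.

## Backbone, fusion, head

Two variants are provided behind one configuration surface:

* `resnet50` — the standard 4-stage bottleneck layout (3/4/6/3 blocks,
  widths 256/512/1024/2048), $7\times7$ stride-2 stem with max pooling,
  attention blocks inserted after every stage by default (configurable).
  Pre-trained weights can be warm-started from a saved parameter tree; no
  download is ever attempted.
* `tiny` — a two-stage residual net (stride-2 stem $3\to16$, stages
  $16\to32\to64$, all stride 2, attention after each stage, embedding 64)
  sized so that a
  full forward pass on a 64×64 image takes well under a second on one CPU.
  It exists so that the complete pipeline — including training — runs at
  desk scale; it is architecturally a faithful miniature, not a mock.

Both branches share weights (halving parameters and enforcing left/right
symmetry: swapping the two images of a patient provably leaves the output
unchanged under symmetric fusion weights, which is tested). Per-branch
embeddings come from global average pooling.

The fusion head implements $p = \tfrac1T \sum_i w_i y_i$ with $T = 2$ and
default weights $(0.5, 0.5)$, *literally*: identical inputs therefore fuse
to half their value, because the $1/T$ and the already-normalised weights
both divide. Three modes are provided because the source material is
ambiguous about what $y_i$ is:

* `feature_average` (default) — average the branch embeddings, then one
  shared head (ReLU → dropout → dense → activation). The following dense
  layer absorbs the overall scale, so the halving is harmless here.
* `prediction_average` — apply the head per eye and average the predicted
  probabilities. Note that with the literal $1/T$ the fused probabilities
  cannot exceed 0.5 under default weights; this mode reproduces the printed
  formula faithfully rather than usefully.
* `feature_concat` — concatenate embeddings and let the head reduce.

The head activation defaults to sigmoid with per-class binary cross-entropy
on label-smoothed targets — the statistically correct pairing for
independent multi-label targets, and the loss the training recipe names.
The softmax head with the literal smoothed categorical cross-entropy
$-\sum_k y'_k \lg \hat y_k$ is available (`lg` is read as the natural
logarithm; the base only rescales the loss and is configurable).
Label smoothing is $y'_k = (1 - v)\, y_k + v/K$ with $v = 0.1$, $K = 8$,
so positives become 0.9125 and negatives 0.0125. Probabilities are clamped
at $10^{-7}$ inside the losses.

Training defaults are the published recipe: Adam, learning rate $10^{-3}$,
100 epochs, batch size 32, input 256×256. A validation fraction
(default 10%) is carved out of the training records for curve tracking and
best-epoch checkpointing; no early stopping is enabled by default. The
multi-label decision threshold is 0.5 on the per-class probability.

## Data handling

Manifests are CSV files with header
`id,left_image,right_image,N,D,G,C,A,H,M,O`; labels are patient-level (both
eyes share the row's vector — whether the benchmark's tallies count eyes or
patients is not stated, so the patient reading is used consistently).
Malformed rows (non-binary labels, missing files) are soft-collected into a
validation report rather than aborting the read; a malformed header is
fatal.

The 4/1 train/test split works per class: a pool of $n$ records yields
`round(n/5)` test records (nearest integer; R's ties-to-even, though no
half-integers occur in practice). This nearest-integer rule is the unique
simple rounding that reproduces all eight published train/test tallies
(574.6 → 575 rounds up, 151.2 → 151 rounds down), which the test-suite
checks as a full-table regression. Because records are multi-label, classes
are processed rarest-first and a record assigned through one class keeps
its side — no patient ever appears in both train and test.

Balancing tops up under-represented classes by cloning seeded-random
members with random augmentation ops until the target count is reached;
originals are never dropped unless an explicit downsample target is given.
The published tallies shrink one class (D, 1608 → 1539) without stating a
rule; the package exposes a generic seeded downsample option and makes no
claim that it reproduces the original reduction.

## The synthetic generator

Real ODIR data cannot be redistributed, so the package ships a
deterministic generator that emulates the *layout* and provides learnable
class structure: per patient, two square RGB images (bright circular disc
on dark background) and a multi-hot label. Each active disease adds one
documented motif, chosen to be mutually distinct in both colour and
spatial frequency so that the signal survives the background-subtracting
enhancement:

| label | motif |
|---|---|
| D | 4–7 small bright yellow blobs |
| G | enlarged pale inner disc with a crisp white rim |
| C | global milky haze plus fine white granules over the whole frame |
| A | 3–5 large dark spots |
| H | two crossing bright red lines |
| M | dark crescent at the disc rim |
| O | bright cyan pixel speckle inside the disc |
| N | no motif; set exactly when no disease bit is active |

Disease bits are drawn per eye (default rate 0.10 per disease) and the
patient label is the union of the two eyes, as in real paired data; eyes
can be forced to share one draw with `per_eye_independence = FALSE`.
Rendering is a pure function of (spec, patient index): each patient uses an
RNG stream seeded by an integer mix of dataset seed and index, so patient
*i* is reproducible regardless of how many patients are generated, and
datasets are byte-identical across runs of the same seed.

What the generator does *not* emulate: real lesion morphology, vessel
trees, camera vignetting, inter-grader label noise, and the severe class
imbalance of clinical data. Passing the end-to-end tests therefore
demonstrates that the pipeline is implemented correctly and can extract
genuinely present image signal — it says nothing about clinical
performance, which requires the real benchmark at full scale.

## Problem sizes and the capacity check

The end-to-end capacity check trains the tiny backbone on 200 synthetic
patients at 64×64 until training accuracy reaches 99%+ (at most 30 epochs,
batch size 8, learning rate $5\times10^{-3}$ with cosine decay, no dropout,
no validation carve-out — the check deliberately *wants* the model to overfit its
training set, since its purpose is to demonstrate optimisation capacity,
not generalisation). Evaluated on its own training set, the fitted model
must reach micro-F1 ≥ 0.99. A separate small run (same seed twice) asserts
bit-for-bit reproducibility of the whole training loop. These sizes are the
package's chosen desk-scale study conditions; the published headline
metrics (94.23% accuracy etc.) require the external ODIR dataset at
256×256 and are expressly out of scope.

## Known limitations

* Batch-norm statistics are tracked with momentum 0.9; on very small
  datasets the train-mode/eval-mode gap can be visible. The capacity check
  evaluates at a scale where the running statistics have converged.
* The literal $1/T$ in prediction-averaging halves fused probabilities;
  use the default feature averaging unless reproducing the printed formula
  is the point.
* `resnet50` at 256×256 runs forward on CPU in seconds but is not intended
  to be *trained* in this environment; the tiny variant is the trainable
  stand-in.
* The Adam implementation is single-threaded deterministic; reproducibility
  claims assume one BLAS thread.
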