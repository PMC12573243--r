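---
title: "Embedding neural networks in weight space: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embedding neural networks in weight space: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Two small autoencoders trained on image patches and on spectrogram
windows end up with visibly different filters, because the second-order
statistics of their training data differ: natural image patches are
approximately translation-invariant 2-D textures, while spectrogram
windows have strong structure along the time axis and harmonic structure
across frequency rows. `metanet` asks whether that difference is
recoverable *from the weights alone*: it embeds a population of
first-order networks into a low-dimensional "meta-representation" space
by autoencoding their weight matrices, and then checks with a
k-nearest-neighbour classifier whether a network's training modality and
category can be read off its embedding.

## The model

**First-order networks.** Each network is the encoder of a linear
autoencoder $x \in [0,1]^{256} \mapsto W^\top x \in \mathbb{R}^{16}$,
with an untied linear decoder (with bias) used only during training.
The encoder has no bias, so the object of study is exactly the
$256 \times 16$ matrix $W$. Training: Glorot-uniform initialization, MSE
reconstruction loss, Adam (lr $10^{-3}$), one epoch over the dataset's
patch matrix in shuffled order, batch size 256. The single epoch is
deliberate: the zoo is meant to sample the distribution of
weakly-converged solutions, not a single optimum, and replicate-to-
replicate variation is what the validation split measures. The decoder's
form (untied, with bias) is a design choice; only the encoder feeds the
meta-stage, so the decoder affects results only through training
dynamics.

**Unitwise stage.** Column $j$ of $W$ is a *filter*: a 256-vector
viewable as a $16 \times 16$ receptive field (row-major reshape). A
convolutional autoencoder compresses each filter independently to a
3-d latent: three 3x3 same-padding conv layers of 8, 16 and 32 channels,
each followed by batch normalization, ReLU and 2x2 max pooling
($16 \to 8 \to 4 \to 2$ spatial), then fully connected $128 \to 32 \to
3$; the decoder mirrors this with nearest-neighbour upsampling and a
linear output layer. MSE, Adam, 50 epochs, batch 128. The channel
widths, kernel size and FC widths are design choices recorded here and
in the parameter objects; the stated architecture family (3 conv +
BN + max-pool, 2 FC, 3-d bottleneck, mirrored decoder, ReLU except the
linear output) is fixed.

**Filter sorting.** The 16 hidden units of a first-order network have no
canonical order — permuting the columns of $W$ leaves the function
unchanged — so the 16 filter latents are treated as a set. They are
canonicalized by sorting ascending on the first latent coordinate, with
ties broken by the second and then third coordinate. Given tie-free
first coordinates this makes the downstream embedding exactly
permutation invariant, which the acceptance suite checks bit-for-bit.
An alternative reading ("sort raw filters by their first weight
element") was considered and rejected: sorting happens after the
unitwise stage precisely because the learned latent is a more stable
sort key than a single raw weight.

**Interunit stage.** The sorted $16 \times 3$ latent block is flattened
filter-major to 48 values and compressed by a purely linear autoencoder
$48 \to 16 \to 48$ (bias terms, MSE, Adam, 50 epochs). The 16-d code is
the network's meta-representation. The two stages are trained in
sequence — the sort key must exist before stage 2's inputs can be
formed.

**Meta-classifier.** A kNN classifier ($k = 10$, Euclidean distance)
over the meta-representations of the training-split nets, labelled by
dataset id. Vote ties are broken by smallest mean neighbour distance,
then lexicographically smallest label; the rule is documented because
accuracy depends on it, and the implementation is checked exactly
against a brute-force distance-sort oracle. Modality prediction is the
dataset prediction coarsened through a dataset-to-modality map, so
modality accuracy can never fall below category accuracy.

## Synthetic data: what it emulates and what it does not

The replication-scale corpora (20 Pascal VOC classes, 10 UrbanSound8k
and 11 IRMAS classes, a million patches each) cannot be bundled or
downloaded here, so the package generates two synthetic patch families
that reproduce the *modality-level second-order contrast* the pipeline
is supposed to detect:

* **Vision-like (modality A):** stationary Gaussian random fields on the
  16x16 grid with squared-exponential covariance. Categories differ by
  correlation length (defaults 1, 2.5, 4 pixels) and optionally an
  anisotropic elongation (default fourth category: length 2, ratio 2
  along the horizontal axis). This mimics textures with different
  spatial scales, translation-invariant by construction.
* **Audio-like (modality B):** 16 frequency rows x 16 time columns with
  energy on the harmonic rows $f_0 \cdot (1, 2, \dots)$ of a fundamental
  (defaults $f_0 \in \{1, 2, 3, 5\}$ with 4, 3, 2, 3 harmonics),
  amplitude $1/h$ per harmonic, modulated by a stationary AR(1) temporal
  envelope (smoothness 0.80-0.90) bounded away from zero, plus white
  noise (sd 0.05 on both modalities).

Defaults were chosen once, to be what a texture/audio modeller would
call a moderate, realistic contrast — categories within a modality
overlap substantially (correlation lengths a factor ~2 apart, shared
harmonics between $f_0 = 1, 2$), while the between-modality contrast
(isotropic 2-D correlation vs. time-smooth harmonic stacks) is
qualitative. A brute-force anisotropy statistic (|lag-1 correlation
along time minus along rows|) separates the two modalities with no
overlap under the defaults; that separation is a stated precondition of
the test world, not a result.

Every patch is min-max rescaled to $[0,1]$ per patch, with a zero-range
guard mapping constant patches to 0.5 — the same guard used for uniform
images and silent audio in the real-data path.

What a green test does **not** establish: that the pipeline reaches the
publication-scale accuracies on the real corpora. Marginal pixel
statistics of photographs, the mel frequency warp, class imbalance and
the 41-dataset breadth are all absent from the synthetic world. The
desk-scale suite (8 datasets, 60 nets each) measures that the method
*recovers a known planted contrast*, with effect sizes chosen a priori.

## Numerical choices

* **Input standardization of both meta-stages.** Raw encoder filters live
  at Glorot scale (sd about 0.085), while a batch-normalized conv decoder
  naturally emits outputs of order 1: trained on raw filters, the
  unitwise stage spends its entire 50-epoch budget shrinking its output
  scale and ends up reconstructing less variance than a rank-3 PCA — it
  has effectively learned only the mean. The filter pool is therefore
  z-scored with a scalar mean/sd computed on the training split (stored
  in the parameter object and reapplied at embedding time). The sorted
  filter latents similarly carry large rank-dependent offsets, so the
  interunit stage z-scores its 48 input coordinates the same way. This
  is optimizer plumbing: the architecture, losses and training schedule
  are unchanged, and all downstream invariants (permutation invariance,
  determinism) are unaffected because the transform is fixed after
  training.
* **Interunit batch size scales with the zoo.** The full protocol trains
  the linear stage on 10,000 nets with batch 128 (about 78 optimizer
  steps per epoch). A desk-scale zoo of 400 training nets with the same
  batch would see only 4 steps per epoch — demonstrably undertrained for
  even a linear autoencoder. The default batch is therefore
  `ceiling(128 * n / 10000)`: exactly 128 at full scale, 6 at desk
  scale, holding steps-per-epoch constant rather than batch size. The
  first-order and unitwise stages keep their fixed batches (256, 128);
  their step counts already sit in the full-scale regime.

* **Determinism.** Every stochastic step draws from a stream derived
  with a 31-bit mixing hash from (base seed, stage name, dataset id,
  replicate index), so zoo training is order-independent and two runs
  from one config are bit-identical (acceptance criterion). The caller's
  RNG state is saved and restored around every internal draw.
* **Batch normalization** uses batch statistics (biased variance) during
  training and running averages (momentum 0.1, unbiased correction) at
  embedding time, so an embedding never depends on what else is in the
  batch. Embedding processes each filter as its own forward pass, which
  additionally makes batched and single-filter embeddings identical to
  the last bit — that is what lets the permutation-invariance criterion
  demand `identical()` rather than a tolerance.
* **Max-pool ties** route the gradient to the first maximum in scan
  order; **sort ties** fall through coordinates 2 and 3; **kNN vote
  ties** use mean neighbour distance then the lexicographic label. All
  three rules exist to keep results reproducible rather than to improve
  them.
* **MSE measurement** for the "loss decreases" properties is computed
  over the full training set in training-statistics mode (chunked), at
  initialization and after the final epoch, so the comparison is not
  confounded by running-average warm-up.
* **Degenerate inputs**: constant patches, silence, infinite correlation
  length and single-crop images all have defined outputs (0.5-filled
  patches, single shared draw) and are covered by tests.
* **Serialization** is plain text (JSON + CSV) with `%.17g` formatting;
  IEEE doubles round-trip exactly, which the zoo round-trip test
  asserts with `identical()`.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| patches per dataset | 20,000 | enough for one stable epoch of the first-order AE; paper scale ($10^6$) is a config change |
| nets per dataset | 60 (50/10) | smallest population where kNN with k = 10 has headroom; paper scale is 600 (500/100) |
| meta epochs | 50 | the stated training length for both meta-stages |
| k | 10 | the stated neighbour count |
| batch sizes | 256 (first-order), 128 (unitwise), auto (interunit) | unstated upstream; recorded in the config and params |
| Adam lr | 1e-3 | framework default, unstated upstream |
| t-SNE perplexity | 30 (paper scale), 20 (desk) | 80 validation nets violate N > 3·30, so the desk config lowers it; validation enforces the bound |

## Known limitations

* The conv architecture details beyond the stated family (channel
  widths, upsampling flavour) are package choices; a replication against
  the original code could legitimately differ in the learned latents
  while preserving every property tested here.
* Filter sorting canonicalizes only unit order. Sign flips and rotations
  of the encoder subspace are other symmetries of the first-order
  model that the method inherits from the original design and does not
  quotient out.
* The raw-weight baseline at desk scale is informative but noisy: with
  80 validation nets, one net is 1.25 accuracy points. The acceptance
  criterion therefore compares meta vs. baseline as an inequality, not
  by value.
* Exact t-SNE is $O(N^2)$ per iteration; it is meant for the validation
  sets of a few hundred points, not for embedding the full paper-scale
  zoo (24,600 nets).
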