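---
title: "Positional multi-length mutual-attention networks for EEG seizure classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional multi-length mutual-attention networks for EEG seizure classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmmnet)
```

## The problem

Epileptic seizures leave characteristic signatures in the
electroencephalogram (EEG): high-amplitude, low-frequency spike-wave
discharges that stand out against background activity. Automated seizure
detection from single-channel EEG segments is a time-series classification
problem in which both very local morphology (the sharp transients) and long
temporal context (the rhythmic organisation of a discharge) are
informative. `pmmnet` implements a positional multi-length and
mutual-attention (PMM) network for this task, together with the data
handling, synthetic benchmark, and cross-validated evaluation protocol
needed to study it end to end on a CPU.

## The model

A labeled segment $s \in \mathbb{R}^{1\times L}$ passes through four stages.

**Positional feature encoding.** Each encoding block computes

$$F_o = \sigma(F_e)\odot \mathrm{conv}_2(\mathrm{RReLU}(\mathrm{conv}_1(F_e))) + F_e,$$

a residual convolution block whose non-identity branch is gated elementwise
by a logistic sigmoid of the block input — positions with strong input
activity let more of the refined feature through. The randomized leaky ReLU
uses a negative slope drawn per element from $U(p, q)$ during training
($p = 1/8$, $q = 1/3$, the usual convention) and the deterministic midpoint
$(p+q)/2$ in evaluation. Each block is followed by a non-overlapping
max-pool of width 2. When a block widens the channel count, a learned 1x1
convolution of the input supplies the gate and residual term in the new
width; with matched widths the residual is the raw input. The default
encoder stacks three blocks of 16, 32 and 64 channels with kernel width 3.
Block count, widths, kernels and pool windows are configuration, not claims
about one canonical architecture.

**Multi-length feature learning.** The encoded sequence feeds a stack of
residual dilated LSTM (RDLSTM) layers with dilation rates 1, 2 and 4. A
layer with dilation $d$ connects time $t$ to its own states at $t-d$:

$$c'_t = f'_t \odot c_{t-d} + i'_t \odot z'_t, \qquad
  h'_t = o'_t \odot\big(\tanh(c'_t) + h^{(l-1)}_t\big),$$

with the block input and all three gates driven by the layer-below hidden
state $h^{(l-1)}_t$ and the dilated recurrent state $h'_{t-d}$. The
shortcut inside the output gate passes the layer-below feature straight
through, which keeps gradients alive in deep stacks; the dilations give the
stack an exponentially growing temporal receptive field. Two reading
choices were open here: the recurrent drive of the block input is taken as
the layer's *own* dilated hidden state (reading one equation's unprimed
symbol as a typo, consistent with the gate equations), and states at
$t \le d$ are zero vectors. A consequence of the shortcut is that the
layer-below feature must live in the hidden dimension, so every RDLSTM
stack begins with a learned linear embedding of the encoder channels into
the hidden size (64 by default); plain-LSTM ablation variants instead
consume the encoder features directly through rectangular input weights.
Dilation structure is exactly equivalent to running $d$ independent
unit-dilation chains over the interleaved subsequences — the test suite
uses this as an oracle.

**Mutual-attention feature reinforcement.** The three per-layer hidden
sequences $F_q, F_k, F_v$ (one per dilation rate) are batch-normalized per
feature, linearly projected to $Q, K, V$, and combined by three mutual
scaled-dot attentions

$$A_{qk} = \mathrm{softmax}\!\left(\tfrac{QK^\top}{S}\right)V,\quad
  A_{qv} = \mathrm{softmax}\!\left(\tfrac{QV^\top}{S}\right)K,\quad
  A_{vk} = \mathrm{softmax}\!\left(\tfrac{VK^\top}{S}\right)Q,$$

where rows index time positions (positions attend over positions; the
attention axis was an open choice and this is the standard one). The
second combination aggregates the *key* stream under query-value scores —
unusual, but implemented exactly as specified. Each attention runs $T$
heads over disjoint feature slices ($T = 4$ by default; $S$ defaults to
$\sqrt{\text{hidden}/T}$); head outputs are concatenated and mixed by a
per-pair linear map, the three streams are concatenated and fused by a
width-1 convolution, and the fused map is averaged over time to give a
fixed-size feature vector (the pooling choice is ours; a dense layer needs
a fixed-size input).

**Classification.** A dense softmax layer yields
$P(y=c\mid s) \propto \exp(\theta_c^\top s)$, trained under mean
categorical cross-entropy. The loss as printed in the source formulation
mixes a binary-CE term into the multi-class sum; standard categorical
cross-entropy is used, with predicted probabilities clipped at $10^{-12}$.

## Training

Adam (beta 0.9/0.999, eps 1e-8) with initial learning rate 3e-4 and a
multiplicative per-epoch decay $\eta_e = \eta_0 (1-0.001)^{e-1}$ — "decayed
by a factor of 0.001" is ambiguous between multiplicative and divisive
semantics; the multiplicative reading is used and exposed in the
configuration. Batch size defaults to 64 and epochs to 100 (both
unstated upstream and freely configurable). All weights are scaled-uniform
fan-in initialized except the classifier, which starts at zero so an
untrained model predicts uniform probabilities. Every source of
randomness (initialization, shuffling, RReLU slopes) runs through R's RNG
from a single seed, so training traces are bit-reproducible.

Because no deep-learning framework is involved, the package carries its own
reverse-mode differentiation: each forward pass builds a tape of nodes
(convolution, RReLU, max-pool, batch-norm, fused RDLSTM layer, fused
multi-head attention, pooling, dense/cross-entropy), and one reverse sweep
yields all parameter gradients. The recurrence and attention kernels are
implemented in C++ (RcppArmadillo) with pure-R reference implementations
kept in the package; the tests require exact agreement between the two and
agreement of every backward kernel with central finite differences
(relative error below 1e-4 in double precision, checked end to end through
the assembled micro network).

## Ablation variants

The component study maps onto four flags: `use_pfe` (positional gate +
residual in the encoder), `use_rdlstm` (residual dilated cell vs plain
LSTM), `use_mfl` (three-layer stack vs a single recurrent layer) and
`use_attention` (mutual-attention reinforcement vs time-averaging the last
hidden sequence). `pmm_variant()` builds the named variants; "original" is
the plain conv encoder + single LSTM + softmax baseline. Mutual attention
needs three taps, so the attention variant implies the multi-layer stack.
The six variants have pairwise distinct parameter counts, which makes the
constructibility property checkable mechanically.

## Data handling

`read_bonn_set()` reads the Bonn layout (per-set directories of 100
plain-text recordings, 4097 samples each); `make_task()` builds the
hyphenated class-combination tasks ("A-E", "AB-CD-E", ...), windowing each
recording into $\lfloor 4097/178\rfloor = 23$ non-overlapping segments.
The segment length mirrors the UCI chunking convention; whole-recording
segments are available via `window_len = 4097`. The unspecified
pre-processing stage is implemented as per-window z-scoring (configurable:
none, z-score, min-max; constant windows map to zero under an epsilon
guard). `read_uci_csv()` reads the 178-sample UCI dialect and emits the
binary seizure-vs-rest label. Windows retain their source `recording_id`,
and cross-validation is group-aware by default: all windows of one
recording share a fold, preventing train/test leakage from autocorrelated
windows — the upstream protocol does not say which level it stratified at,
so the leak-proof reading is the default.

## The synthetic study

`synth_eeg()` generates labeled segments as background noise (white, 1/f,
or AR(1); pink by default) plus class-profiled oscillatory bursts: a
sharpened sinusoid $\mathrm{sign}(\sin)\,|\sin|^{1/\text{sharpness}}$
placed at seeded random offsets until a duty fraction of the segment is
covered. The sharpening mimics the pointed transients of spike-wave
morphology; nothing quantitative hangs on the exact waveform, and segments
are grouped into pseudo-recordings of 23 windows so group-aware
cross-validation is exercised. The `"binary"` preset (burst amplitude 5
vs 0 on unit-variance noise, 200 segments per class, length 178) is an
easily separable control: a model that cannot reach high held-out accuracy
there is broken. The `"null"` preset draws both classes from the same
distribution, so held-out accuracy must sit at chance — this guards
against information leaking through the protocol rather than the signal.
What these studies *cannot* show is performance on real ictal EEG:
amplitude-separable synthetic bursts are far easier than clinical data,
where class differences are subtler and non-stationary.

The reduced configuration used for CPU-scale studies
(`pmm_reduced_config()`: encoder widths 8/16/32, hidden 32, 20 epochs,
batch 32, learning rate 2e-3) narrows every stage proportionally; the
higher learning rate compensates for the short schedule. With it, a 3-seed,
5-fold cross-validation of the binary study (400 segments) runs in a few
minutes on one core, and `scripts/acceptance.R` re-derives those numbers
from scratch.

## Numerical choices and limitations

* Convolution is cross-correlation with zero "same" padding (odd kernels);
  max-pool windows that do not divide the length drop the tail samples.
* Batch-norm uses eps 1e-5 and running-statistic momentum 0.1; evaluation
  mode uses the running averages.
* Argmax ties in prediction resolve to the lowest class index;
  zero-denominator metrics report 0 with a `degenerate` flag rather than
  NaN.
* The multi-class metric aggregation is unweighted one-vs-rest macro
  averaging; the upstream tables report single values without defining the
  aggregation, so this is a package choice.
* Sequences are processed unidirectionally; multi-channel montages, GPU
  paths and the published comparison baselines are out of scope.
* Training the full-size default configuration on all 11,500 UCI segments
  is CPU-feasible but slow (hours, not minutes); the reduced configuration
  is the intended vehicle for experimentation.
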