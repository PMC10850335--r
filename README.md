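# pmmnet

Classification of epileptic-seizure EEG with a positional multi-length and
mutual-attention (PMM) network, implemented natively in R.

Scalp and intracranial EEG during a seizure shows high-amplitude
spike-wave discharges whose detection requires both local waveform detail
and long temporal context. `pmmnet` provides, for researchers working with
single-channel EEG segments (the Bonn sets A–E and the UCI
seizure-recognition chunking are the reference formats):

* **Positional feature encoding** — residual 1D-convolution blocks whose
  refinement branch is gated elementwise by a sigmoid of the block input
  (`F_o = σ(F_e) ⊙ conv₂(RReLU(conv₁(F_e))) + F_e`), each followed by
  max-pooling.
* **Multi-length feature learning** — hierarchically stacked residual
  dilated LSTMs with dilation rates 1, 2, 4
  (`c'_t = f' ⊙ c_{t−d} + i' ⊙ z'`, `h'_t = o' ⊙ (tanh(c'_t) + h_below)`),
  giving an exponentially growing temporal receptive field.
* **Mutual-attention feature reinforcement** — the three dilated feature
  streams are normalized, projected to Q/K/V, combined by the three mutual
  scaled-dot attentions `softmax(QKᵀ/S)V`, `softmax(QVᵀ/S)K`,
  `softmax(VKᵀ/S)Q` with `T` heads, and fused by a width-1 convolution.
* **Softmax classification** trained with Adam under categorical
  cross-entropy (lr 3e-4, multiplicative per-epoch decay 0.001).
* Readers for the Bonn ASCII and UCI CSV formats, hyphenated
  class-combination tasks ("A-E", "AB-CD-E", …), a seeded spike-wave EEG
  simulator with controllable class separability, stratified/group-aware
  k-fold cross-validation, and the standard confusion-matrix metrics
  (accuracy, precision, sensitivity, specificity, F1).

Gradients come from a built-in tape-based reverse-mode differentiation
core; the recurrent and attention kernels are compiled (RcppArmadillo)
with pure-R reference implementations kept alongside, and every backward
pass is verified against central finite differences in the test suite.

## Worked example

Train the reduced network on the separable synthetic study (seizure-like
bursts of amplitude 5 against pure background noise) and cross-validate:

```r
library(pmmnet)

d   <- synth_preset("binary", n_per_class = 200, seed = 0)
cfg <- pmm_reduced_config(n_classes = 2)

fit <- pmm_train(cfg, d, seed = 1, epochs = 3, verbose = TRUE)
#> epoch   1  loss 0.4088  acc 0.940  lr 2.00e-03
#> epoch   2  loss 0.0096  acc 0.998  lr 2.00e-03
#> epoch   3  loss 0.0014  acc 1.000  lr 2.00e-03
```

The loss falls from near `log 2` (the uniform-prediction value for two
classes) to essentially zero: the power difference between the two classes
is easy to learn. Held-out performance under group-aware 5-fold
cross-validation:

```r
cv <- pmm_cross_validate(d, cfg, k = 5, seed = 1)
cv$summary
#> # A tibble: 1 × 5
#>   accuracy precision sensitivity specificity    f1
#>      <dbl>     <dbl>       <dbl>       <dbl> <dbl>
#> 1        1         1           1           1     1
```

Metrics come from confusion counts exactly as defined — for example
`classification_metrics(list(tp = 40, fn = 10, tn = 45, fp = 5))` returns
accuracy 0.85, precision 0.889, sensitivity 0.80, specificity 0.90 and
F1 0.842. On the `"null"` preset (identical class distributions) the same
protocol stays at chance accuracy, confirming the pipeline leaks no label
information. `tidy()`, `glance()` and `autoplot()` methods expose training
histories and per-fold metrics as tibbles and ggplots.

With a local copy of the Bonn dataset, tasks are built and evaluated the
same way:

```r
recs <- dplyr::bind_rows(read_bonn_set("bonn/A", "A"), read_bonn_set("bonn/E", "E"))
task <- make_task(recs, "A-E", window_len = 178)     # 23 windows/recording
pmm_cross_validate(task, pmm_config(n_classes = 2), k = 10, seed = 1)
```

A thin CLI over the same functions lives in `inst/scripts/pmm.R`
(`synth`, `train`, `eval`, `cv` subcommands).

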