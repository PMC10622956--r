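---
title: "Learnable EEG channel selection with channel attention: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learnable EEG channel selection with channel attention: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecaselect)
```

## The problem

Motor-imagery brain-computer interfaces decode which movement a person is
imagining from multichannel EEG. Recording montages routinely carry more
electrodes than the task needs: redundant channels add preparation time,
computation and noise. *Channel selection* asks which small subset of
electrodes preserves classification accuracy. This package implements an
*embedded* selection method: a channel-attention layer inside the
classifier itself learns, during ordinary training, how much each
electrode contributes, and the learned weights induce an importance
ranking from which a subset of any size is read off as a prefix.

## The attention model

An efficient-channel-attention (ECA) module summarizes a feature block
$X \in \mathbb{R}^{W \times H \times C}$ by channel-wise global average
pooling, $y_c = \frac{1}{WH}\sum_{i,j} X_{i,j,c}$, and produces one gate
per channel. Between convolutional stages the gate is a shared 1-D
convolution across the channel axis,

$$w = \sigma(\mathrm{Conv1d}_k(y) + b),$$

whose kernel size adapts to the channel dimension,
$k = \psi(C) = \left|\tfrac{\log_2 C}{2} + \tfrac12\right|_{odd}$ (the
nearest odd integer; an exact tie, which occurs when the expression is an
even integer, resolves to the larger odd number — the choice forced by the
published parameter counts of the third and fourth modules, 6 = 5 taps +
bias at $C = 128$ and $C = 256$). The module carries $k$ taps plus one
bias.

At the network input, locality across an arbitrary electrode ordering is
meaningless — homologous electrodes on opposite hemispheres interact — so
the input-facing instance (the *CA layer*) replaces the small shared
convolution with a full linear map,

$$w_{CA} = \sigma(W_{CA}\, y + b), \qquad W_{CA} \in \mathbb{R}^{C \times C},$$

with $C^2 + C$ parameters and no dimensionality reduction, preserving the
one-to-one correspondence between electrodes and weights. In both forms
the block is recalibrated channel-wise, $Y_c = w_c X_c$, leaving shapes
untouched; because the gate is a sigmoid, every weight lies strictly in
$(0,1)$.

The attention vector is *input-dependent*: $w$ is a function of each
sample's pooled descriptor. The per-electrode importance used for ranking
is therefore the expectation of the attention over a dataset — the
elementwise mean of the per-sample CA vectors. An alternative static
summary (the L2 norm of each electrode's row of $W_{CA}$) is available
behind `extract_channel_weights(method = "weight_norm")` but is not the
default, since the averaged attention is what the gate actually applies
to the data.

## The network

`build_eca_deepnet()` assembles the deep convolutional architecture the
attention is embedded in: a CA layer on the raw electrodes; a temporal
convolution (32 filters, kernel 10) followed by a spatial convolution
across all electrodes (kernel $1 \times C$), the factorized first stage
that suits oscillatory EEG; then three further convolution blocks (64,
128, 256 filters, kernel 10), each convolution followed by batch
normalization, an ELU activation ($x$ for $x>0$, $e^x - 1$ otherwise),
max-pooling of width/stride 3, an ECA module, and dropout (after blocks
1–3 only); finally a convolutional classifier spanning the remaining
temporal extent with a log-softmax head. For the default
$22 \times 1000$ input the symbolic shape trace runs
$991 \to 330 \to 321 \to 107 \to 98 \to 32 \to 23 \to 7$ along time.

Bookkeeping choices are pinned down by the published per-layer parameter
counts rather than prose: block convolutions carry *no* bias (their counts
are exactly filters × kernel × input maps), the classifier carries one,
batch normalization contributes two scalars per feature map, the CA layer
$C^2+C$, each ECA module $k+1$.

Where the architecture's source is silent we chose standard values and
state them here: Glorot-uniform initialization with zero biases; batchnorm
$\varepsilon = 10^{-5}$, momentum 0.1; maximum 200 epochs with early
stopping on validation loss (patience 30), both configurable; accuracy
reported per crop by default with an optional per-trial majority vote.
Default hyperparameters (dropout 0.5, AdamW, learning rate $10^{-3}$,
batch 16, weight decay $10^{-4}$) are the modal values of the shipped
per-subject tuning presets (`subject_presets`); the full search space is
validated by `hyperparameters()`. Training is fully deterministic given
the seed (default 20200220), which drives initialization, shuffling,
dropout and the validation split.

The forward/backward engine is authored in the package (R with three
compiled convolution kernels); its gradients are validated against
central-difference numerical differentiation in the test suite, so the
training loop rests on verified machinery rather than on an external
autodiff framework.

## The selection loop

1. Train the full-montage model on a subject's data (`train_model()`).
2. Extract the expected CA attention per electrode
   (`extract_channel_weights()`).
3. Rank electrodes by descending weight (`rank_channels()`); ties keep
   montage order.
4. Take the first $N_c$ entries (`select_subset()`), restrict the data
   (`restrict_to_subset()`), rebuild the network for $N_c$ electrodes
   (spatial kernel $1 \times N_c$, CA layer $N_c^2 + N_c$) and retrain
   from scratch with the same seed (`channel_sweep()`).

Retraining, rather than masking the dropped electrodes, matches the
intended deployment (a smaller montage) and the published practice of
re-tuning hyperparameters after selection; masking without retraining is
available only as a diagnostic by evaluating the restricted data on the
full model. At $N_c = C$ the sweep reuses the full model directly — the
selection is a no-op — so the full-subset row reproduces the direct
train/evaluate result exactly. Subsets are recorded in ranking order;
consumers needing montage order can re-sort from the ranking file. The
sweep's prediction time is wall-clock and hardware-dependent, and is
deliberately untested.

## The synthetic benchmark

Real four-class motor-imagery data (22 electrodes, 250 Hz, 288 trials of
4 s cued imagery per session) requires a download and hours of training,
so the package ships a generator whose *defaults reproduce that session
geometry*: 72 trials per class, 4.5 s trials (0.5 s pre-cue baseline +
4 s task), 2 s inter-trial rest so that the standardizer's statistics
settle between trials.

Each channel carries $1/f$ pink noise (10 µV RMS), white sensor noise
(1 µV RMS) and a mu rhythm synthesized as 8–13 Hz band-limited noise
(15 µV RMS by default) rather than a pure sinusoid, so no trivial phase
cue separates classes. During the task window of a class-$k$ trial the
rhythm amplitude on that class's *informative channels* is multiplied by
$1 - d$ (event-related desynchronization, ERD); band power therefore
drops by $(1-d)^2$, a contract the tests verify by periodogram. The
default class-to-channel map mimics contralateral sensorimotor
organization on the standard 22-name montage: left hand → C4, right hand
→ C3, feet → Cz, tongue → FCz. Defaults use $d = 0.5$, a strong but
physiological desynchronization.

The generator emulates the *geometry and the spectral signature* of
motor-imagery EEG, not its physiology: there is no volume conduction, no
cross-channel correlation of backgrounds, no artifacts (EOG/EMG), and
exactly one informative electrode per class. Passing the recovery tests
therefore demonstrates that the selection loop finds channels that carry
class information under realistic noise spectra — not that it would rank
electrodes identically on a particular human subject.

## The preprocessing pipeline

`preprocess_recording()` chains the three stages in their stated order:
a 4th-order Butterworth band-pass, 1–40 Hz, applied forward-backward for
zero phase (the realization is our choice; only the band is prescribed);
exponential-moving-average standardization per channel with decay 0.999
($m_t = 0.999\,m_{t-1} + 0.001\,x_t$, likewise for the residual variance,
output $(x_t - m_t)/\max(\sqrt{v_t}, 10^{-4})$, initialized at
$m_0 = x_1$, $v_0 = 1$); and sliding-window cropping of the cue-relative
segment $[-0.5\,\mathrm{s}, 4\,\mathrm{s})$ into 1000-sample windows.
The published sample count (864 crops from 288 trials, 216 per class)
fixes three crops per trial but not their placement; the 125-sample slack
with stride 62 places them at offsets 0, 62 and 124, and the stride is an
exposed parameter. Crops never straddle trials, and the validation split
inside `train_model()` is drawn trial-wise so sibling crops cannot leak
across the split.

## Numerical and degenerate-input choices

- ECA convolution boundary: zero padding of $(k-1)/2$ per side
  (length-preserving); kernels longer than $2C$ are rejected.
- Ranking ties break by original channel index, making the ranking a
  deterministic permutation.
- Pooling drops a trailing remainder shorter than 3; argmax gradients go
  to the first maximum in a tied window.
- Batch variance is floored at 0 before the $\varepsilon$-guarded square
  root; a non-finite training loss aborts with the epoch named rather
  than continuing silently.
- Empty sample sets, mismatched channel counts, out-of-range subset
  sizes and unknown configuration keys all fail fast with the offending
  quantity named; trials whose crop segment leaves the recording are
  skipped with a warning.

## Problem sizes used by the tests

The structural checks (parameter table, shape trace, crop arithmetic) run
at the full published geometry — they are instantaneous. Training-based
checks run the full architecture (≈460k parameters) on reduced sessions,
chosen so the whole suite stays desk-scale: smoke tests use a few trials
per class and 2–6 epochs; the planted-channel recovery benchmark uses the
high-SNR configuration ($d = 0.8$, rhythm 25 µV) with 24 trials per
class, and a training recipe of 6 epochs, batch 16, weight decay
$10^{-2}$, AdamW at $10^{-3}$, and no validation holdout. Two properties
of that benchmark are worth recording. First, recovery tracks
generalization: runs that memorize the background noise instead of the
ERD signature do not move attention toward the informative electrodes, so
the benchmark recipe leans on data volume and weight decay rather than
long schedules. Second, attention contrast at these scales is small in
absolute terms (weights separate by ~0.01 around 0.5) — the *ordering*,
not the magnitude, carries the signal, which is exactly what the ranking
consumes.

## Known limitations

- The importance ranking is a per-subject, per-training artifact; no
  cross-subject transfer is attempted.
- Greedy prefix selection inherits the attention's blind spot for
  redundancy: two equally informative, highly correlated electrodes both
  rank high even though one would suffice.
- The generator's independence across channels understates the spatial
  correlation of real EEG, which makes selection *easier* here than in
  practice.
- Hyperparameter search (the tuning that produced `subject_presets`) is
  out of scope; a hook exists in that every command accepts explicit
  hyperparameters.
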