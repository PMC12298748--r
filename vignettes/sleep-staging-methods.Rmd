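---
title: "Gated cross-channel attention for sleep staging: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gated cross-channel attention for sleep staging: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcafnet)
```

## The problem

Clinical sleep scoring assigns one of five stages — wake (W), light sleep
(N1), intermediate sleep (N2), deep slow-wave sleep (N3) and REM — to each
30 s epoch of an overnight polysomnography (PSG) recording. The stages have
well-known spectral and transient signatures: alpha rhythm (8–12 Hz) in
relaxed wake, theta (4–7 Hz) in N1, sleep spindles (12–14 Hz bursts) and
K-complexes in N2, high-amplitude 0.5–2 Hz slow waves in N3, and
low-amplitude mixed-frequency EEG with rapid eye movements in REM. Because
some of these cues live in different channels (eye movements in the EOG,
slow waves in the EEG), classifiers that fuse channels outperform
single-channel ones — but naive concatenation underuses cross-channel
structure. `mcafnet` implements a compact classifier whose fusion step is a
*dynamically gated multi-head cross-channel attention* mechanism, together
with everything needed to train and evaluate it.

The model is strictly one-to-one: each epoch is classified independently,
with no neighbouring-epoch context.

## From signal to tensor

Each epoch is a `[3 x 3000]` matrix (two EEG derivations and one horizontal
EOG at 100 Hz). `stft_log_power()` frames each channel with a 2 s periodic
Hamming window hopping by 1 s (50% overlap, no edge padding), zero-pads
frames to 256 points and takes the natural log of one-sided power plus a
floor of `1e-10`. With these defaults a 3000-sample channel produces
exactly `T = floor((3000 - 200)/100) + 1 = 29` frames of 129 bins.
`reduce_bins()` drops one bin — the Nyquist bin by default — to reach the
power-of-two feature dimension `F = 128`; which bin is dropped is
configurable (`"drop_dc"`) because either convention is defensible and the
choice is immaterial after standardization. `standardize()` then centres
and scales each channel's `T x F` matrix to zero mean and unit *population*
variance. Standardization is per epoch and per channel by default; a
per-recording scope is available in `preprocess_epochs(scope =
"recording")` for users who prefer recording-level normalization. The
power spectrum deliberately omits window-energy normalization: any affine
constant is removed by the standardization that follows.

## The network

Let `X` be the `[B x C x L x D]` batch tensor (`C = 3` channels, `L = 29`
frames, `D = 128` features).

**Per-channel temporal convolution.** Each channel has its own parameter
set (channels never mix here). Along the time axis a depthwise 1-D
convolution (kernel 3, zero padding 1, groups equal to `D`, channel
multiplier 2) widens the features to `2D`, a GELU (exact, error-function
form) adds nonlinearity, and a 1x1 convolution projects back to `D`.
Sequence length is preserved for every `L`, including `L = 1`. A dense
(non-grouped) widening convolution is available behind
`model_config(dense_conv = TRUE)` for the heavier literal reading of the
two-layer description; the depthwise form is the default configuration.
No normalization layers are used anywhere in the network.

**Gated cross-channel fusion.** Each fusion layer (there are `N_A = 2`)
performs, with projections *shared* across channels and positions:

1. A position-wise affine map to `3D` features, split into queries, keys
   and values and reshaped into `H = 4` heads of `d_h = D/H`.
2. For every head and ordered channel pair `(i, j)`:
   `A = Q_i K_j' / sqrt(d_h)`, softmax over *key positions only*, and a
   partial output `W V_j`. The output for query channel `i` is the plain
   sum over all key channels `j` (including `j = i`); no `1/C` normalizer
   is applied, following the defining sum literally. The
   joint-softmax-over-(channel, position) variant is deliberately not
   implemented.
3. Heads are concatenated and mapped by a learnable `D x D` output
   projection.
4. A scalar gate per sample: the layer input is averaged over channels and
   time to a `D`-vector, mapped through a linear layer and a sigmoid,
   giving `G in (0, 1)`.
5. Residual update `Y = X + G * O'`.

Each layer owns independent parameters, including its own gate, and the
gate reads the same tensor that feeds the residual. Because the softmax is
per channel pair, every query position receives total attention mass `C`
rather than 1; the aggregated attention maps in `aggregate_attention()`
should be read with that convention in mind. No positional encoding is
used: the temporal convolution is the only source of position information.

**Classifier.** The fused `[B x C x L x D]` tensor is reduced over time —
the mean by default; `"last"` and `"max"` are selectable since the
reduction is not otherwise pinned down — flattened to `C*D = 384`
features, passed through a 512-unit ReLU layer with dropout 0.5, and a
final affine map with softmax over the five stages, ordered
`W, N1, N2, N3, REM` everywhere. Training consumes logits through a
numerically stable log-softmax cross-entropy; the softmax probabilities
are for reporting.

`count_parameters()` reports 433,799 trainable scalars for the default
configuration (101,760 temporal-conv, 132,354 fusion, 199,685 classifier).
The dense-conv variant has roughly 0.74M. Published descriptions of this
architecture family quote ~0.63M, which matches neither closed form; the
function reports the honest count rather than forcing agreement.

## Training protocol

`train_model()` uses mini-batches of 64 with a fresh shuffle each pass
(epochs are independent; no sequence context), cross-entropy loss, and
AdamW with decoupled weight decay:

```
p <- p - lr * wd * p - lr * m_hat / (sqrt(v_hat) + eps)
```

Defaults are the reference protocol: learning rate `5e-6`, weight decay
`1e-2`, betas `(0.9, 0.999)` and `eps = 1e-2` — an unusually large epsilon,
kept because it is part of the stated protocol and left configurable.
Early stopping monitors validation accuracy with patience 20 and *strict*
improvement; ties keep the earliest pass, and the returned model is the
one with the best recorded validation accuracy. A hard bound of 200 passes
backstops the patience rule. All randomness (shuffling, dropout) flows
from `train_config(seed = )`, so a fixed seed reproduces the trajectory
bit-for-bit on one machine.

`split_subjects_kfold()` partitions *subjects*, never epochs: group `f` is
the test set, the cyclically next group is validation (equal subject
counts when group sizes divide evenly, matching the protocol's
equal-sized validation requirement), the rest train. The gradient
implementation is hand-written and verified in the test suite against
central finite differences for every parameter group (agreement ~5e-10).

## Synthetic polysomnography

`generate_dataset()` produces stage-conditioned 3-channel epochs so the
whole pipeline runs without any data download. Oscillatory components are
narrowband-filtered Gaussian noise (2nd-order Butterworth band-pass run
forward-backward, scaled to the target amplitude) rather than pure
sinusoids, which gives realistically fluctuating rhythms; transient events
(spindle bursts, K-complexes, saccade-like EOG deflections, slow eye
movements) are placed by Poisson counts at uniform positions,
rejection-resampled so no event is truncated at an epoch border. Default
amplitudes are physiological (tens of microvolts, slow waves ~90 µV,
broadband noise 10 µV) — the absolute scale is irrelevant after
standardization but is kept meaningful for EDF export. Each synthetic
subject receives a log-normal amplitude multiplier (sd 0.1) and a Gaussian
centre-frequency offset (sd 0.3 Hz), so subject-wise splits are
non-trivial. Stage labels follow exact quota allocation, guaranteeing the
target mix.

What the generator does *not* emulate matters for interpreting results:
there is no sleep architecture (epochs are independent draws, matching the
one-to-one model), no artifacts, no inter-night variability, and class
signatures are cleaner than real PSG. Synthetic results therefore
demonstrate that the implementation can learn and exploit cross-channel
spectral structure; they say nothing about accuracy on real recordings,
which requires the Sleep-EDF accession through `load_recording()`.

## Problem sizes and numerical choices

The packaged experiments use a reduced model — `D = 32` (frequency bins
pooled in groups of four), `H = 2`, one fusion layer, 128 hidden units —
with an elevated learning rate of `1e-3`, chosen so that the desk-scale
studies complete in minutes on one CPU:

* *Separability study*: 1000 balanced epochs over 10 subjects, 800
  training / 200 held-out by subject, at most 25 passes.
* *Fusion-advantage study*: 600 epochs over 6 subjects where N1 and REM
  share identical EEG signatures and differ only in the EOG channel; a
  fused 3-channel model is compared against a single-EEG-channel model on
  REM F1. Both thresholds used in the tests (95% training accuracy, 80%
  held-out) were fixed from a calibration run before being frozen.

Other numerical decisions: softmax rows are max-shifted before
exponentiation; probabilities are floored at `1e-300` inside the loss;
degenerate confusion-matrix classes use the 0/0 → 0 convention and are
flagged rather than dropped; checkpoints embed the full configuration and
a format-version string, and loading verifies every field against an
expected configuration when one is supplied.

## Evaluation

`metrics_from_confusion()` derives per-class precision/recall/F1, overall
accuracy, Cohen's kappa, macro-F1, macro-averaged sensitivity (mean
recall) and macro-averaged specificity (one-vs-rest TN/(TN+FP), macro
averaged — the convention adopted since "Sens/Spec" is otherwise
underdetermined for five classes). Metrics are stored as fractions and
rendered as percentages only in reports; any rounding for comparison with
published tables is half-up to one decimal and applied at comparison time
only. The package bundles reference confusion matrices from the Sleep-EDF
benchmark (`reference_confusion()`) and the test suite reproduces every
per-class value printed alongside them at one-decimal precision; the two
published macro-F1 values differ from the recomputation by exactly one
unit in the last digit (truncation versus rounding), and the tests compare
at that precision.

## Ablations

All published ablation variants are constructible from configuration
alone: single-channel models (`c_channels = 1` with the corresponding
channel slice), naive concatenation without fusion
(`use_fusion = FALSE` — the flattened per-channel features are simply
concatenated for the classifier), and removal of the temporal convolution
(`use_temporal_conv = FALSE`).

## Known limitations

* Training is CPU-bound R; the full-size configuration trains at desk
  scale but a full Sleep-EDF cross-validation is a long-running job.
* The EDF reader targets EDF/EDF+C with a single annotation track — the
  subset needed for Sleep-EDF-style recordings and this package's own
  exports.
* Attention maps are retained only when requested
  (`keep_attention = TRUE`), since a full map stack is `B x H x C x C x L
  x L` and grows quickly with batch size.
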