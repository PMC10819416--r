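---
title: "Methods: synthetic EEG cohorts and Chebyshev graph-convolutional fatigue staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic EEG cohorts and Chebyshev graph-convolutional fatigue staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why:
the model and its assumptions, the parameters that matter, what the
synthetic cohort generator does and does not emulate, the numerical
choices, and the limitations we know about.

## The model

EEG drowsiness staging rests on a robust spectral observation: as
fatigue deepens, theta-band (4–8 Hz) power rises and beta-band
(13–30 Hz) power falls, with a milder rise in alpha. The classifier
treats the four fatigue-sensitive channels P4, C3, O1, O2 as the nodes
of a graph whose edges are functional connectivity — the absolute
Pearson correlation between channel time series — and learns a
spectral graph filter over that graph.

A Chebyshev graph-convolution layer computes
\[
H' = \sigma\Big(\sum_{k=0}^{K-1} T_k(\tilde L)\, H\, W_k + b\Big),
\qquad T_k(x) = 2xT_{k-1}(x) - T_{k-2}(x),
\]
with $\tilde L = (2/\lambda_{\max}) L - I$ the rescaled symmetric
normalized Laplacian, $H$ the per-node feature matrix, and $K$ the
Chebyshev order (the filter's hop radius). Five such layers (Leaky-ReLU
activations, batch normalization after each activation) shrink the
per-node feature width along the chain
2920 → 2920 → 1460 → 730 → 365 → 180 in the full-width replica; the node
count never changes — there is no graph coarsening, so all dimension
halving acts on feature widths. Dropout, flattening
(4 × 180 = 720) and a fully connected softmax head complete the model.
`count_parameters()` gives the analytic per-layer accounting
($C_k \cdot \text{in} \cdot \text{out}$ weights per layer,
$\text{out}$ biases, $2\,\text{out}$ batch-norm parameters,
$720 \times n_\text{classes}$ head weights), and the test suite verifies
it against brute-force enumeration of the instantiated arrays.

Classification is evaluated over four nested cases of the five ordinal
stages: case I = {normal, full-fatigue}, case II adds fatigue, case III
adds semi-fatigue, case IV uses all five. The nesting (anchored by the
stated two-class case I and the 2/3/4/5-class ladder) is a design
choice exposed in `define_case()`; other compositions are one line away.

## Signal conditioning

The offline chain is: 50 Hz notch, 0.02–50 Hz band-pass, terminal
windowing, per-channel min–max normalization.

* **Notch**: a second-order bandstop biquad (standard constrained
  direct form), quality factor $Q = 30$ by default (bandwidth
  $\approx f_0/Q \approx 1.7$ Hz at 250 Hz sampling). $Q$ is
  configurable; only "second order" is prescribed by the method.
* **Band-pass**: "second-order Butterworth, 0.02–50 Hz" is realized as
  a cascade of a second-order high-pass at 0.02 Hz and a second-order
  low-pass at 50 Hz. The cascade's magnitude is exactly the product of
  the two Butterworth factors (after bilinear prewarping), which makes
  the closed-form response testable to near machine precision.
* **Zero phase**: all offline filters are applied forward–backward.
  Phase handling is unspecified in the method; zero-phase avoids group
  delay on 5-s windows at the cost of squaring the magnitude response.
* **Order of operations**: the 0.02 Hz high-pass has a ~50 s period, so
  it is meaningful only on full recordings; filter before extracting
  the terminal window. On windows shorter than a minute the high-pass
  edge is effectively inert.
* **Min–max**: per channel, per window, applied after augmentation
  (matching the stated processing order); a constant channel cannot be
  rescaled and maps to zeros with a warning. Whether normalization
  statistics should be per-window or per-recording is unstated; we
  chose per-window and expose the chain so either is scriptable.

## The synthetic cohort generator

No recordings are distributed with the method, so the cohort generator
is first-class, tested code — it defines the study conditions for every
learning experiment in the package.

Each class is specified by relative band powers over delta/theta/
alpha/beta and a white-noise floor (µV). The default five-class
gradient is monotone — theta 0.4 → 1.8 rising, beta 1.0 → 0.4 falling,
alpha mildly rising, delta mildly rising — chosen once as a plausible
drowsiness gradient; the absolute scale (`amplitude = 10` µV per
unit-RMS band mixture, noise floor 3 µV) makes raw windows span roughly
±50 µV, cosmetic realism only. Within each band a window is a mixture
of five sinusoids on a fixed, evenly spaced frequency comb over the
band interior, with phases drawn uniformly at random per window and
channel. Randomizing phases rather than frequencies keeps each class's
spectral support stable across windows, which is what makes the cohort
learnable from band content; the comb is exactly band-limited by
construction. Channels blend a shared latent band process with an
independent one (amplitude weight 0.5, renormalized to unit RMS), so
the expected inter-channel correlation is strictly between 0 and 1 —
the graph-construction stage needs non-degenerate correlations. With
the default noise floor the pooled |r| lands near 0.42–0.48.

Two artifact injections complete the emulation: a 50 Hz mains tone
(amplitude 10 µV by default, random phase per channel) for the notch
stage to remove, and `add_white_noise_snr()`, which rescales each noise
realization so the *empirical* SNR equals the requested dB value
exactly (used by the robustness sweep).

What the generator deliberately does **not** emulate: 1/f background
spectra, waveform morphology (spindles, K-complexes, eye blinks),
nonstationary band-power drift within a window, volume-conduction
topography beyond a single shared latent process, and any ECG/EMG/
respiration structure. Passing tests therefore certify the pipeline's
mechanics and the learnability of band-power structure — not
performance on real recordings.

## Training and data hygiene

* **Splits**: stratified 70/20/10 per class,
  floor-then-largest-remainder (2920 → 2044/584/292). The partition is
  a pure function of the seed and the windows' provenance ids, so a
  permuted input yields the same partition.
* **Leakage guards**: the channel graph is estimated from the training
  split only and frozen; GAN augmentation is fitted per class on the
  training split only. `run_pipeline()` refuses configurations that
  request augmentation on any other split, and the test suite
  constructs the violation deliberately.
* **Optimizer**: Adamax, learning rate $10^{-4}$, weight decay
  $4 \times 10^{-4}$ (applied to weight matrices only), batch 16,
  cross-entropy, 150 epochs — the tuned full-scale values are the
  `gcn_control()` defaults. Model selection keeps the best validation
  accuracy, ties broken by lower validation loss, then earlier epoch.
  "Iterations" is read as epochs.
* **GAN**: non-saturating binary cross-entropy loss (none is named by
  the method), latent dimension 100, discriminator widths
  512/256/128/1 with first-layer dropout 0.3, Adam (β₁ = 0.5) at
  learning rate 0.001, 500 iterations, batch 10; one GAN per class.
  The generator's sigmoid output keeps synthetic windows in [0, 1],
  matching normalized real windows (we normalize first, then augment).
  The per-class count target (e.g. 2920) and the classifier's node
  feature length are independent parameters: the former is a window
  count, the latter a per-node width, and the full-width replica
  (2920-wide features) exists for parameter accounting rather than as
  a physically realizable window length.

## Numerical choices

* Chebyshev bases use the stable three-term recursion; the suite checks
  it against eigendecomposition spectral filtering to $10^{-8}$ on
  random graphs (n ≤ 8, K ≤ 6) and checks the edgeless-graph collapse
  (an edgeless graph has $L = I$, $\lambda_{\max} = 1$, $\tilde L = I$,
  so a ChebConv layer degenerates to a per-node dense layer with weight
  $\sum_k W_k$).
* $\lambda_{\max}$ is computed exactly (trivial at n = 4); the common
  approximation $\lambda_{\max} = 2$ is available as a mode.
* Sparsification keeps surviving weights (binarization is a flag); the
  default cutoff 0.5 on |r| sits at a knife edge for the default
  cohort, whose pooled correlations concentrate just below 0.5, so the
  pipeline default is 0.4 and `channel_graph()` warns whenever the
  thresholded graph is disconnected. With the default Chebyshev orders
  $C_k = 1$ (the accuracy-maximizing setting) only $T_0 = I$ is used
  and the classifier is graph-independent; the graph machinery is
  exercised by higher-order configurations and its own tests.
* Batch normalization follows the activation (the stated layer order),
  normalizes each feature over nodes × batch, and uses running
  statistics (momentum 0.1) at inference; dropout is inverted and
  disabled at inference, so prediction is deterministic.
* First-layer initialization defaults to `"spectral"`: the order-0
  block is filled with quadrature sinusoid probes at evenly spaced
  frequencies (in cycles per window). For oscillatory node features
  this starts the network at frequency-selective projections whose
  rectified outputs give deeper layers direct access to band
  envelopes; plain Glorot is available and is used wherever tests need
  init-agnostic behavior.
* All randomness flows through per-stage seeds derived from one master
  seed (kept below $2^{31}$); every generator output is a pure
  function of its spec and seed.

## Desk-scale study conditions

The reduced benchmark (`smoke_learning_run()`) fixes: the default
two-class cohort (normal vs full-fatigue) or the full five-class
cohort, 100 windows per class, 0.5-s windows at 128 Hz (64 samples, the
reduced architecture's input width; the sampling rate must stay above
twice the highest band edge), the conditioning chain, a 70/20/10 split,
the reduced chain 64 → 64 → 32 → 16 → 8 → 8, and 30 Adamax epochs at
learning rate $10^{-2}$, weight decay $10^{-1}$, batch 16 — stronger
regularization and a larger step than the full-scale defaults, as
appropriate for 140 training windows. The acceptance checks run this
benchmark over three seeds for cases I and IV, and the robustness sweep
corrupts a fresh 50-windows-per-class labeled cohort at 20/10/0/−10 dB.

## Known limitations

* With random phases, the class signal lives entirely in quadratic
  (band-power) statistics of the samples; a rectifier network must
  *learn* that invariance, which is sample-hungry. At the desk scale
  (70 training windows per class) the two-class validation accuracy
  typically lands in the 0.75–0.9 range rather than at the
  full-data regime, and it rises with cohort size; the five-class case
  at the same budget sits far lower. The band-power linear baseline
  (`band_power_features()` + LDA), by contrast, separates class 0 from
  class 4 essentially perfectly — the information is present, and the
  gap is the network's sample efficiency, not the generator's
  separability.
* The desk-scale GAN (a few hundred iterations on tens of windows)
  reproduces coarse spectral shape — its windows beat white noise on
  periodogram distance — but is not class-faithful enough to improve
  the classifier at this scale; count-augmentation is therefore tested
  for its bookkeeping and spectra, not claimed as an accuracy booster.
* Multiclass specificity/precision use one-vs-rest macro averaging; the
  aggregation behind any externally reported multiclass scalars is
  unknowable without the original data, so no equivalence is claimed.
* EDF input/output is out of scope here; cohorts are exchanged as plain
  CSV channel matrices with a manifest and JSON header
  (`write_cohort_csv()` / `read_cohort_csv()`).
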