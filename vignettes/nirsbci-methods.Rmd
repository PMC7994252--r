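---
title: "Subject-independent fNIRS classification: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subject-independent fNIRS classification: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsbci)
```

## The problem

Functional near-infrared spectroscopy (fNIRS) measures cortical hemodynamics
optically: task-evoked neural activity raises oxy-hemoglobin (HbO) and lowers
deoxy-hemoglobin (HbR) concentration. A binary fNIRS brain–computer interface
discriminates a mental-arithmetic task (MA) from an idle state (IS) from short
signal epochs. Because fNIRS signals are strongly subject-specific, a
classifier is normally calibrated per user; *subject-independent* operation —
training only on other people's data, evaluated by leave-one-subject-out
cross-validation (LOSO-CV) — removes that calibration session. This package
implements the full pipeline: hemoglobin conversion, band-pass filtering,
epoching, four classifiers (shrinkage LDA, a bagged ensemble of regularized
LDAs, a compact CNN known as EEGNet, and a 1-D CNN with EvoNorm
normalization-activation layers), LOSO evaluation, a pseudo-online
calibration-size simulation, and a synthetic data generator so that everything
runs without any recording hardware or external download.

## Preprocessing

**Hemoglobin conversion.** Optical-density changes at 780, 805 and 830 nm map
linearly to concentration changes (modified Beer–Lambert law):

$$
\begin{pmatrix}\Delta HbR\\ \Delta HbO\end{pmatrix} =
\begin{pmatrix} 1.8545 & -0.2394 & -1.0947\\
               -1.4887 & \phantom{-}0.5970 & \phantom{-}1.4847\end{pmatrix}
\begin{pmatrix}\Delta OD_{780}\\ \Delta OD_{805}\\ \Delta OD_{830}\end{pmatrix}
\quad (\mathrm{mM\cdot cm}).
$$

The coefficients are fixed constants (`mbll_matrix()`); the operation is exact
and linear, and `make_od_fixture()` provides its Moore–Penrose right-inverse
so conversion can be exercised from simulated hemoglobin data. Raw-intensity
SNIRF input is converted to optical density as $-\log_{10}(I/\bar I)$ with
$\bar I$ the channel's temporal mean.

**Filtering.** Physiological nuisance rhythms (Mayer waves near 0.1 Hz,
respiration near 0.25 Hz, cardiac pulsation near 1 Hz) are removed with a
6th-order Butterworth band-pass at 0.01–0.09 Hz applied forward and backward
(`signal::filtfilt`), i.e. zero phase with an effective 12th-order magnitude
response. Each series is demeaned before filtering; the offset lies outside
the pass band and removing it first conditions the narrow-band IIR better.
`bandpass_gain()` exposes the theoretical forward–backward response, which the
tests compare against measured attenuation (0.05 Hz passes within 5%; 1 Hz is
attenuated by more than 40 dB).

**Epoching.** The sampling rate of the reference montage is printed as
13.3 Hz; a $[0, 15]$ s epoch inclusive of both endpoints with exactly 201
samples forces the exact rational rate $40/3$ Hz, which the package uses
throughout. Baseline correction subtracts the per-channel mean over
$[-1, 0)$ s — the onset sample belongs to the epoch, not the baseline. Events
too close to a record boundary are dropped and counted, so epochs plus drops
always equal events. The flattened 32-wide signal axis is a package constant:
HbO channels 1–16 first, then HbR channels 1–16 (nothing in the science pins
this order; it only has to be consistent everywhere, and it is asserted by a
sentinel-channel test).

**Normalization.** Networks receive per-trial, per-signal z-scores over the
time axis, using the population standard deviation (divisor $n$) with an
epsilon guard ($10^{-12}$) that maps constant signals to zero instead of NaN.
Normalizing twice is a contract error: the flag records that the operation is
applied exactly once, per fold, after the train/test split (it is a per-trial
operation, so no statistics leak between folds either way).

## Classifiers

**Shrinkage LDA.** Features are temporal mean amplitudes in the 0–5, 5–10 and
10–15 s windows for every channel and chromophore (16 × 2 × 3 = 96,
window-major order). The pooled within-class covariance $S$ is shrunk toward
a scaled identity, $S_\gamma = (1-\gamma) S + \gamma \nu I$ with
$\nu = \mathrm{tr}(S)/p$, and the discriminant is
$w = S_\gamma^{-1}(\mu_{MA} - \mu_{IS})$ with the boundary midway between the
class means. With `shrinkage = "analytic"` the intensity is the Ledoit–Wolf
estimate (the standard choice in the BCI literature when "shrinkage LDA" is
named without a formula); it was verified against scikit-learn's
implementation to seven digits during development and is tested for its
limiting behaviors. Class encoding is fixed (IS = 0, MA = 1; positive score =
MA) to remove sign ambiguity, and exact-zero scores resolve to IS and are
counted.

**Bagged regularized LDA.** Fifty weak learners, each a fixed-shrinkage LDA
($\gamma = 0.1$) trained on a full-size bootstrap resample; majority vote with
a deterministic tie-break by mean decision score. A resample that misses a
class is redrawn (and the redraw counted). The original study used MATLAB's
`fitcensemble`; only configuration-level equivalence (50 learners / 100%
resampling / $\gamma = 0.1$) is claimed, not weight-level equivalence.

**Proposed 1-D CNN.** Input (201 time samples × 32 signals), then: EvoNorm →
dropout 0.5 → conv(32 filters, kernel 13, stride 9, valid) → EvoNorm →
dropout → conv(32, 6, 4, valid) → EvoNorm → dropout → flatten(128) → dense(2,
softmax). Shapes are frozen by tests: (201,32) → (21,32) → (4,32) → 128 → 2,
and the parameter count (20,066) is asserted once so the architecture cannot
drift. Weights are He-Normal; forward and backward passes are implemented in
base R and verified against finite differences.

**EvoNorm.** The normalization-activation layer is the S0 (sample-based)
variant: $y = x\,\sigma(v x)\,/\,\mathrm{std}_{group}(x)\cdot\gamma + \beta$
with learnable per-channel $\gamma, \beta, v$ and 8 groups over the 32-wide
channel axis. S0 was chosen over the batch-based B0 because it behaves
identically in training and inference and tolerates small datasets; 8 groups
is the common default that divides 32. The published layer is 2-D; the 1-D
adaptation here treats time as the spatial axis and groups only channels. At
$v = 0, \gamma = 1, \beta = 0$, one group, the layer reduces to
$0.5\,x/\mathrm{std}(x)$, which is tested. An ablation flag
(`cnn_config(norm = "batchnorm_relu")`) swaps every EvoNorm for BatchNorm +
ReLU, and both variants build and train.

**EEGNet.** The compact reference CNN: temporal convolution (8 filters,
kernel (1,6) — half the sampling rate — same padding, no bias), BatchNorm;
depthwise spatial convolution over all 32 rows (depth 2, max-norm 1),
BatchNorm, ELU, average pool (1,4), dropout 0.25; separable convolution (16
filters, kernel (1,2), same padding), BatchNorm, ELU, average pool (1,8),
dropout; flatten (96) → dense(2, softmax). Two source ambiguities were
resolved as follows: the separable kernel is printed (1, 2) in the
architecture table but (2, 1) in the text — only (1, 2) (temporal) makes the
table's shape arithmetic work, so (1, 2) it is; and "$F_1$, $F_1$, and $D$
were set to 8, 16, and 2" is read as $F_1 = 8$, $F_2 = 16$, $D = 2$ (the only
assignment consistent with the table). The dense-layer max-norm of the
original EEGNet is not mentioned in the source configuration and defaults to
off. Convolution weights are Glorot-uniform, the reference default for this
architecture.

**Trainer.** Both networks train with Adamax (learning rate 0.0005, legacy
per-update decay $lr_t = lr/(1 + 5\times10^{-8} t)$ — the convention of the
Keras generation of tools), batch size 100, categorical cross-entropy, a
stratified random 10% validation split (stratified rather than a tail split
because trials are time-ordered and a tail split would confound with session
fatigue), early stopping on validation loss with patience 20, and
best-validation-weight restoration (the conservative reading of "early
stopping with patience"). All randomness — split, shuffling, dropout —
derives from one seed, so training is bit-reproducible. Training sets smaller
than the batch size train as a single smaller batch (logged, not an error).

## Evaluation

`run_loso()` fits a classifier per fold on the other subjects' trials only —
normalization is per-trial and the validation split is drawn inside the fold —
and predicts the held-out subject. A trial-fingerprint audit asserts that no
test trial entered training. Per-subject accuracy (matching balanced test
sets) is the primary aggregate: the report carries the per-subject vector,
mean, SD and SE, plus pooled predictions so the pooled-vs-mean decomposition
can be checked. `run_pseudo_online()` implements the subject-dependent
learning curve: for each subject, train a shrinkage LDA on the
chronologically first $N$ trials of each class ("first" meaning acquisition
order within class) and test on the remaining $30 - N$; no other subject's
data are touched. `wilcoxon_signed_rank()` is the paired two-sided test with
zero differences dropped and mid-ranks for ties; for $n \le 25$ the p-value is
exact, by dynamic programming over the doubled-rank distribution (doubling
makes mid-ranks integral), which removes the exact-vs-approximate knob at the
study's $n = 18$; the implementation agrees with `stats::wilcox.test` on
tie-free data and with full $2^n$ enumeration oracles.

## The synthetic generator

`simulate_subject()` emulates the experimental paradigm: a 2 s instruction, a
10 s task block, a randomized 16–18 s inter-trial rest; 30 MA and 30 IS trials
in seeded random order; 16 channels at 40/3 Hz. MA trials add an
HRF-convolved 10 s boxcar to HbO and $-1/3$ of it to HbR (anti-correlated, as
hemodynamics demand; the ratio is a knob, not a claim); IS trials add nothing.
The HRF is the canonical double-gamma (peak 6 s, undershoot 16 s, ratio 1/6) —
the community default, since the source assumes but never parameterizes the
hemodynamic response. Noise is a sum of Mayer (~0.1 Hz), respiratory
(~0.25 Hz) and cardiac (~1.1 Hz) sinusoids with per-subject frequency and
phase jitter, a random-walk drift, and white noise; subjects differ by a
log-normal response gain (sdlog 0.35) and additive spatial-topography jitter.

The default effect amplitude (0.005 mM·cm peak HbO) is a one-time convenience
calibration: it places shrinkage-LDA LOSO accuracy on the full default
dataset (18 subjects × 30 trials/class) at 70.7% ± 8.1 — inside the 60–75%
regime realistic for this paradigm — and is *not* a reproduction of any
published number. What the generator does **not** emulate: motion artifacts,
optode-coupling changes, photon-transport geometry, session nonstationarity,
or real inter-subject covariance structure. Tests passing on synthetic data
therefore certify the pipeline's statistical mechanics (chance level on null
data, high accuracy on strong effects, no leakage), not field performance on
real recordings.

## Numerical choices and problem sizes

Fixed conventions, all tested: population-SD z-scoring with a $10^{-12}$
guard; EvoNorm $\epsilon = 10^{-5}$; BatchNorm $\epsilon = 10^{-3}$ with
momentum 0.99; vote ties break on mean decision score; zero LDA scores
resolve to IS; window endpoints of the feature extractor are inclusive;
baseline interval is half-open. The statistical sanity suite runs at desk
scale: zero-effect (5 subjects × 20 trials/class) and strong-effect
(4 subjects × 24 trials/class at 30× the calibrated amplitude, homogeneous
subjects) datasets are simulated at 5 Hz — the hemodynamic signal lives below
0.1 Hz, so the rate only sets tensor sizes; the 40/3 Hz geometry (201
samples, 96 features, layer shapes) is pinned by its own exact tests. Network
training in these runs uses batch size 16, so the optimizer takes a sensible
number of steps per epoch on small training sets, with epoch caps of 25
(zero effect: there is nothing to learn), 60 (CNN) and 150 (EEGNet).

## Known limitations

* The public deposit of the original recordings is not bundled and no loader
  for it is shipped: its internal layout is undocumented and could not be
  validated offline. SNIRF import (`read_snirf()`) is the supported path for
  real data; it delegates HDF5 access to a bundled Python helper using h5py.
* Training the networks in base R is orders of magnitude slower than a GPU
  framework; the reference configurations train fine, but at dataset sizes of
  the original study expect minutes per fold, and the published headline
  accuracies (71.20% CNN vs 65.74% sLDA, etc.) can only be approached with
  the real data and longer training budgets.
* The exact EvoNorm variant and group count of the original model are not
  stated in the source; S0 with 8 groups is this package's documented choice.
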