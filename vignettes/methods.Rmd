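---
title: "Methods: GASF encoding, conditional-GAN augmentation, and the evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GASF encoding, conditional-GAN augmentation, and the evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Ternary classification of motor tasks — right-hand finger tapping (RHT),
left-hand finger tapping (LHT) and foot tapping (FT) — from multichannel
fNIRS recordings of oxygenated and deoxygenated hemoglobin concentration
changes (ΔHbO, ΔHbR). Deep classifiers overfit badly at the sample sizes
typical of fNIRS experiments (tens of trials per class), so the pipeline
augments the training set with class-conditional synthetic images from a
conditional generative adversarial network (CGAN) and measures how
classification accuracy responds as the generated fraction grows from 0%
to 110% of the real training set.

The pipeline is: band-pass filtering → trial epoching and baseline
correction → (features/kernel PCA for channel ranking) → Gramian Angular
Summation Field (GASF) image encoding of one selected channel → CGAN
training and synthesis → CNN classification → augmentation-fraction sweep.

# Signal preprocessing

**Filtering.** A third-order Butterworth band-pass with a 0.01–0.1 Hz
passband, applied forward and backward (zero phase). The passband keeps the
slow task-evoked hemodynamic response; cardiac pulsation (1–1.5 Hz),
respiration (0.2–0.5 Hz), Mayer waves (~0.1 Hz), drift and DC offset are
rejected. The forward–backward pass squares the magnitude response and
cancels phase lag, so event timing is preserved — we read the published
"zero-order filter implemented by the third-order Butterworth" as
zero-*phase* filtering, the standard practice. The implementation mirrors
the textbook scheme (odd-reflection padding plus steady-state initial
conditions, with the recursion in compiled code) because the `signal`
package's `filtfilt` leaves large edge transients on low-frequency designs;
`signal::butter` still supplies the filter design itself.

**Epoching.** Epochs span −2 s to +28 s around each task onset, half-open
at the right edge, so a 10 Hz recording yields exactly 300 samples. Events
too close to the recording edges are skipped with a logged message.
Baseline correction subtracts the per-channel mean of the −1–0 s reference
interval. Sample windows are half-open `[start, end)` everywhere — the
onset sample belongs to the post-onset side and the 0–5/5–10/10–15 s
feature windows never double-count a sample.

**Features.** Window means of ΔHbO and ΔHbR over 0–5, 5–10 and 10–15 s for
each channel: 20 × 2 × 3 = 120 features per epoch, ordered channel-major,
then chromophore, then window. Standardization uses the population
(divide-by-*n*) standard deviation so worked examples are exact, is fitted
on training rows only, and is applied unchanged to test rows — the source
protocol does not state this split hygiene, we impose it to prevent
leakage. Constant features have their standard deviation floored at 1e-8
with a warning.

**Kernel PCA.** Centered-kernel eigendecomposition (RBF kernel by default,
width 1/features, at most 20 components — none of these values are given
in the source, all are configurable). Components are ordered by descending
eigenvalue with a deterministic sign convention: the largest-magnitude
loading of each component is positive. With a linear kernel the scores
equal classical PCA scores, which the tests exploit as an oracle.

**Channel selection.** The published procedure ranks channels by the
"feature importance" of an unspecified baseline classifier; that is not
reproducible, so the package substitutes a model-free score: the one-way
F statistic of each channel's window-mean ΔHbO features across the three
classes, summed over the three windows, with ties broken toward the lowest
channel index. Both encode paths are exposed: the default encodes the
selected channel's series, `encode_source = "kpca1"` encodes the epoch's
first principal-component time course across channels.

# GASF encoding

A 1-D series is PAA-downsampled to 28 points (piecewise-aggregate means;
downsampling *before* the Gramian construction is the convention in the
GAF literature and avoids resampling artifacts), min–max rescaled to
[−1, 1], mapped to polar angles φ = arccos(x̃), and expanded into the
matrix G<sub>ij</sub> = cos(φ<sub>i</sub> + φ<sub>j</sub>) =
x̃<sub>i</sub>x̃<sub>j</sub> − √(1−x̃<sub>i</sub>²)√(1−x̃<sub>j</sub>²).
The image is the affine map (G+1)/2 into [0, 1]. Only the post-onset
0–28 s portion is encoded; the pre-onset baseline is reference only.
A constant (degenerate) series is mapped to all zeros by convention, which
propagates to a uniform all-black image.

Two intrinsic properties of this encoding shape everything downstream:

* **Scale is lost.** The min–max rescale removes absolute amplitude, so a
  weak and a strong response of the same shape give the same image.
* **Sign is lost.** G is invariant under x̃ → −x̃ (φ → π − φ leaves
  cos(φ<sub>i</sub>+φ<sub>j</sub>) unchanged), so an inverted response
  gives *exactly* the same image.

Consequently class identity on a single encoded channel can only be
carried by the *temporal signature* (latency, width, within-window shape)
of the response. This is a mathematical property of the encoding, not an
implementation choice, and it dictates the design of the synthetic
generator below.

# The synthetic generator

The generator emulates the statistical structure the pipeline assumes, so
every stage is testable without external recordings:

* 20 channels (first ten tagged left hemisphere, last ten right), 10 Hz
  sampling — the sampling rate is not printed in the source; 10 Hz
  satisfies Nyquist for cardiac noise and keeps a 30 s epoch at 300
  samples. Trials arrive every 30 s on average, jittered uniformly ±5 s,
  in randomized class order, 10 s of tapping each.
* Evoked responses are canonical double-gamma kernels (peak 6 s,
  undershoot ratio 1/6 — community defaults; the source never specifies a
  waveform) convolved with the task boxcar. Hand taps raise ΔHbO
  contralaterally (amplitude 1, arbitrary micromolar-scaled units) with a
  weaker (0.45×), delayed (2.5 s) and broadened (1.8×) ipsilateral
  response; ΔHbR mirrors with a third of the amplitude. Foot taps lower
  ΔHbO and raise ΔHbR bilaterally with a brisker, narrower time course
  (0.55× width).
* Because the GASF discards sign and scale, these three *temporal*
  signatures — canonical, delayed/broad, brisk/narrow — are what make the
  classes separable on one channel; the amplitude and sign pattern still
  reproduces the published topography (contralateral HbO increase for hand
  taps, bilateral HbO decrease for foot taps) and is what the laterality
  and feature tests assert.
* Noise: sinusoids with per-channel random phase at 1.2 Hz (cardiac),
  0.3 Hz (respiration) and 0.1 Hz (Mayer), plus a per-channel DC offset,
  a slow linear drift and white noise; default amplitudes 0.2 / 0.15 /
  0.25 / 0.2 / 0.1 against an evoked amplitude of 1. Per-channel
  multiplicative gains in [0.8, 1.2] emulate optode-coupling variation.
* `generate_recording()` is a pure function of its configuration,
  including the seed: identical configurations give bit-identical output.

What the generator does **not** emulate: motion artifacts,
subject-to-subject anatomical variability, optode-level light propagation,
serial correlations of real physiological noise, or the modified
Beer–Lambert conversion from optical densities. Passing tests on this
benchmark therefore demonstrate that the pipeline's machinery is correct
and that augmentation does not corrupt a learnable problem — they do not
certify accuracy on any real dataset.

# The conditional GAN

The generator maps a 100-dimensional standard-normal latent vector plus a
class label to a 28×28 image in (−1, 1): dense layer to a 7×7×128 grid,
then three 4×4 transposed-convolution layers (7→14→28 via two stride-2
layers plus one stride-1 refinement layer), batch normalization and ReLU
on every layer except the tanh output. The discriminator is a small
strided convolutional stack (two 4×4 stride-2 layers, leaky ReLU, dense
sigmoid head). Conditioning concatenates three constant one-hot label
planes to the inputs of both networks — the original conditional-GAN
scheme. A learned label-embedding channel was tried first and abandoned:
at the few hundred optimization steps a CPU budget allows it leaves
generated classes at chance fidelity, whereas one-hot planes plus a
*matching-aware* discriminator batch (real images paired with wrong
labels, scored as fake at half weight) reach requested-class fidelity of
1.0 under a pixel nearest-centroid oracle.

Training alternates a discriminator step (real batch → target 1, generated
batch → target 0, mismatched-label batch → target 0) with a
non-saturating generator step, batch 32, adaptive-moment optimizer at
learning rate 2e-4 with first-moment decay 0.5 (the stable convention for
small image GANs; the source states no optimizer for the GAN). The
per-step history records both discriminator loss halves — their sum is
the negated empirical value function of the minimax objective, an identity
the tests assert — plus the generator loss and the discriminator's
balanced-batch accuracy, which at equilibrium should hover near 1/2.
Synthesis draws `round(fraction × n_real)` images split equally across the
three classes (remainder round-robin by class code), maps pixels to
[0, 1], and tags provenance `generated`. A mean pairwise MS-SSIM above
0.98 within any generated class raises a mode-collapse warning.

Layer sizes beyond the mandated 7×7×128 grid (32/16 generator filters,
16/32 discriminator filters) and the 400-step default were chosen once as
the smallest stack that conditions reliably on a single CPU; all are
configurable.

# The CNN classifier

Eighteen counted layers: input, four blocks of (convolution → batch
normalization → 2×2 max-pool) with 16/32/64/128 3×3 filters (28→14→7→3→1),
two fully connected layers (128, 64) each followed by dropout, and a
3-way softmax. Published counting of "18 layers" is ambiguous; this
enumeration is fixed in the configuration docs. Training uses categorical
cross-entropy plus an l2 kernel penalty of strength 0.5 initially
(applied to every convolution and hidden dense kernel; the output layer is
exempt so heavy shrinkage cannot pin the logits at uniform), batches of
four, RMSprop, learning-rate halving after 4 epochs without validation
improvement, early stopping after 8, and restoration of the
best-validation weights. Dropout (0.3 default) is applied to the fully
connected layers. Validation and test sets must contain only real images;
every entry point asserts this.

Across the augmentation sweep the regularization is relaxed linearly with
the fraction — l2 from 0.5 at fraction 0 down to 0.01 at the top of the
grid, dropout from 0.4 to 0.2 — implementing the published "initially
strict, periodically relaxed" schedule with a declared, logged map.
`random_search()` samples dropout, optimizer, kernel size and dense widths
uniformly with a fixed seed and returns the highest-validation-accuracy
configuration (ties to the earlier trial).

# Evaluation

Accuracy is 100 × trace/total of the 3×3 confusion matrix — the
multi-class reduction of the binary (TP+TN)/(TP+FP+TN+FN) definition,
validated against both published example matrices. Precision is
column-wise (predicted-positive denominator); the published per-class
table for the fully augmented model matches this convention. One-vs-rest
AUROC is the rank (Mann–Whitney) statistic with ties counted one half,
macro-averaged without weights. MS-SSIM uses the standard five-scale
weight vector with an 11×11 Gaussian window (σ 1.5); scales whose side
would drop below the window are truncated and the remaining weights
renormalized, so 28×28 images use two scales; contrast-structure terms are
floored at zero before the geometric combination.

`augmentation_sweep()` trains the CGAN once, then per fraction synthesizes,
trains the classifier on real ∪ generated with the step's relaxed
regularization, and evaluates on the untouched real test set; a failed
step records a failure row and the sweep continues. Every stage derives
its seed deterministically from the master seed.

# Problem sizes and numerical choices

The packaged benchmark uses 40 trials per class (120 epochs → 90 training
and 30 test images, 10 per class, mirroring the published test-set
geometry), 400 GAN steps, and at most 25 classifier epochs per sweep step;
the full 12-fraction sweep then completes in a few minutes on one CPU and
is the configuration the acceptance script reruns. Degenerate inputs are
handled by declared conventions (constant series → zero vector; constant
feature → floored sd; class never predicted → NaN precision with a
warning). Epoch discretization snaps onsets to the sample grid. All
stochastic stages are seeded; reported results are pure functions of
(data, configuration, seed). Numerical tolerances in the tests: 1e-12 for
closed-form identities (GASF, value-function bookkeeping), 1e-6 for
eigendecomposition-based comparisons, finite-difference gradient checks at
1e-5–1e-6.

# Known limitations

* The synthetic benchmark is far easier than real multi-subject fNIRS;
  accuracies here say nothing quantitative about real data.
* Single-channel GASF encoding discards sign, scale and all cross-channel
  structure; multi-channel fusion is not implemented.
* The GAN is small and CPU-sized; no Wasserstein/gradient-penalty variants,
  no inception-based scores (MS-SSIM is the implemented diagnostic).
* The channel-importance score is a model-free F statistic, not a
  reproduction of the unspecified baseline-classifier importance.
* Training the classifier purely on generated data is possible via the
  API (train on a generated set, validate on real) but is not a supported
  headline mode.
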