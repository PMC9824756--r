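---
title: "Methods: the bag-of-hybrid-deep-features EEG pipeline"
author: "bohdf authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the bag-of-hybrid-deep-features EEG pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`bohdf` classifies labeled multi-channel EEG trials into emotion classes by
turning each channel into a time-frequency image and describing that image
with two complementary feature families:

1. **Preprocessing.** Each channel is band-pass filtered to 4–45 Hz with an
   order-4 Butterworth filter applied forward-backward (zero phase). This
   removes baseline drift, muscle/line-noise energy, and keeps the theta
   through low-gamma rhythms that carry affective signatures.
2. **Spectrogram.** The filtered channel is short-time Fourier transformed:
   frame $m$ covers $L$ samples starting at $m \cdot \mathrm{hop}$,
   $S(m,k) = \sum_i E(i + m\,\mathrm{hop}) \, w(i) \, e^{-j 2\pi i k / L}$,
   and the amplitude surface is $A(m,k) = |S(m,k)|^2 / L$, so each frame's
   amplitudes sum exactly to the windowed segment's energy (a Parseval
   identity the test suite asserts to 1e-9 relative error). The amplitude
   matrix is log-compressed, min–max normalized, oriented frequency-up, and
   bilinearly resized to a 224×224 image.
3. **Texture half (OMTLBP_SMC, 600 features).** A rotation-invariant local
   binary pattern variant: around every interior pixel, 8-point rings are
   sampled at radii 1, 2, 3; the radius-2 and radius-3 rings average 5 and 7
   sub-samples per direction (22.5° and 15° apart), overlapping adjacent
   octants. Adjacent radii are averaged into three fused structures
   ($U_1 = P^1$, $U_2 = (P^1+P^2)/2$, $U_3 = (P^2+P^3)/2$). Per structure,
   local differences against the center split into sign and magnitude
   (LDSMT); each is encoded with the rotation-invariant-uniform (riu2)
   scheme and joined with a one-bit center code into a 10×10×2 joint
   histogram. Three structures × 200 bins = 600 features.
4. **Deep half (1000 features).** The rendered image is fed to a pluggable
   deep backend; the reference configuration is a pretrained
   ImageNet-architecture GoogLeNet's final 1000-way fully connected layer
   (pre-softmax). The package ships a deterministic mock backend for
   dependency-free operation (below).
5. **Bag of words.** The concatenated 1600-dim per-channel vectors are
   z-scored (statistics fitted on training data only) and clustered with
   k-means *within each class* (k = 8 words per class by default); a trial
   is encoded as the histogram of nearest-word assignments of its channels.
6. **Classification.** Inverse-distance-weighted KNN (default, 10
   neighbors) or an SVM (RBF / cubic kernel) on the encoded histograms,
   evaluated by stratified 5-fold cross-validation in which scaler,
   vocabulary and classifier are rebuilt inside every fold.

# Parameters that matter

| parameter | default | meaning / why |
|---|---|---|
| `filter_spec(low_cut, high_cut)` | 4, 45 Hz | the conventional affective-EEG analysis band |
| `filter_spec(order)` | 4 | order-4 Butterworth; forward-backward doubles the effective roll-off |
| `stft_config(window_len)` | 1 s of samples | 1 Hz bin spacing; balances time/frequency resolution at EEG rates |
| `stft_config(hop)` | L/2 | 50% overlap, standard practice |
| `stft_config(window_shape)` | hamming | any of hamming/hann/gaussian/rectangular; the Parseval identity holds for all |
| `stft_config(band)` | 4–45 Hz | out-of-band rows are near-zero after filtering and would waste image dynamic range |
| `stft_config(image_size)` | 224 | the common CNN input size |
| `omtlbp_describe(r1_mode)` | "circle" | radius-1 ring at exact radius 1.0 (diagonals interpolated); "integer8" snaps to the 8-connected neighbors |
| `pipeline_config(k_per_class)` | 8 | the cluster size the evaluation sweep (k ∈ {8, 10, 12}) selects |
| `pipeline_config(classifier)` | knn_weighted | weighted KNN with K = 10; SVM variants available |
| `pipeline_config(n_folds)` | 5 | stratified cross-validation folds |

# Design decisions where the design was open

* **Window family and length.** Candidate window shapes are named but not
  fixed upstream of this package; we default to a Hamming window of one
  second with 50% overlap, all configurable, because that is standard EEG
  spectrogram practice.
* **The innermost fused structure.** The multi-scale fusion rule averages
  adjacent radii, which leaves the innermost structure without a partner;
  we define $U_1$ as the unfused radius-1 ring, yielding exactly three
  topological structures.
* **Magnitude threshold scope.** The magnitude code thresholds against
  $\rho_m$, "the average magnitude"; per-patch and per-image readings are
  both defensible. We use the image-level mean per structure, the
  convention of sign/magnitude/center LBP variants, which keeps codes
  comparable across pixels.
* **Deep feature dimension.** Reported FC dimensions conflict (1024 vs
  1000); only 1000 is consistent with the stated 1600-dim fusion, so every
  backend defaults to 1000 features (backends may declare other lengths;
  the fusion layer reads the declaration).
* **Per-class vocabulary.** Cluster centroids are described per class, so
  the canonical vocabulary is per-class k-means (8·C words for C classes);
  a single global k-means is available as `vocab_mode = "global"`.
* **Evaluation protocol.** A "70/30 split with 5-fold cross-validation" is
  self-contradictory; we treat stratified 5-fold CV as canonical and
  provide the stratified 70/30 holdout as a secondary mode. Both rebuild
  the scaler/vocabulary inside the training portion only.
* **One raw feature per channel.** What constitutes one bag-of-words token
  is unstated for multi-channel trials; we produce one 1600-dim vector per
  channel per trial and let the trial histogram aggregate channels, which
  is what makes multi-channel combination meaningful.
* **Count normalization.** Whether bag counts are normalized before
  classification is unstated; both modes exist, default L1-normalized.
* **Pre-softmax activations.** Whether FC features are taken before or
  after softmax is unstated; pre-softmax is the default for its richer
  dynamic range.

# Numerical choices

* **Butterworth design.** No DSP package is assumed: the band-pass is
  designed via the analog prototype → band-pass transform → bilinear
  transform route and matches reference `butter()` coefficients to 1e-12
  (frozen in the test suite). Zero-phase application squares the magnitude
  response; the analytic response check gives ≥ 40 dB attenuation at 1 Hz
  and ≤ 1 dB ripple at 25 Hz for the default design at fs = 200 Hz.
* **Edge handling.** Odd-reflection padding of 3 × (filter length − 1)
  samples at both ends before forward-backward filtering — slightly longer
  than the minimal one filter length, which measurably reduces the IIR
  start-up transient on 2 s trials.
* **Image normalization degenerate case.** A constant amplitude surface
  (e.g. an all-zero signal) renders as uniform mid-gray 0.5 rather than
  dividing by a zero range.
* **Sampling geometry.** Ring angles are measured counter-clockwise from
  the +column axis; sub-pixel samples are bilinearly interpolated, with
  near-integer coordinates snapped (tolerance 1e-9) so axis-aligned samples
  hit pixels exactly. Interior pixels exclude a 3-pixel border so the
  radius-3 ring stays in bounds.
* **Ties.** Nearest-word assignment and KNN/SVM votes break ties toward the
  lowest index; the sign of a zero local difference is +1; η(x, x) = 1.
  All deterministic and asserted in tests.
* **k-means.** Greedy farthest-point seeding from a seeded RNG; stop at
  relative centroid movement < 1e-6 or 300 iterations; empty clusters are
  re-seeded with the worst-represented point. The objective trace is
  exposed and tested to be non-increasing.
* **Seeds.** Every stochastic step (trial synthesis, k-means init, fold
  shuffling, SVM working-pair choice) derives from explicit integer seeds;
  two runs from one config are byte-identical, which is itself a test.

# The synthetic generator: what it emulates, what it does not

`synthetic_spec()` produces trials whose channels are 1/f^α Gaussian noise
(frequency-domain shaped, α = 1 by default, unit RMS) plus, per class, an
amplitude-modulated sinusoid with per-channel random carrier inside the
class's band, random phase, and a slow (0.1–0.5 Hz) burst envelope at
relative amplitude 1.5. The default three classes occupy well-separated
theta (5–7 Hz), alpha (10–13 Hz) and beta (22–30 Hz) bands; optional 50 Hz
line noise and 0.3 Hz drift exercise the band-pass stage. The default test
geometry is 8 channels × 10 s at 200 Hz; a `"deap_like"` preset mirrors a
32-channel, 128 Hz, 63 s benchmark layout.

This emulates exactly one property of affective EEG — class-conditional
band-power structure over a pink noise floor — and none of the rest: no
volume conduction or inter-channel correlation, no real artifact
morphology, no non-stationarity beyond the burst envelope, no
subject-level variability. A green end-to-end test therefore establishes
that the pipeline *recovers class-discriminative spectral structure when it
exists*, with no leakage and deterministically; it does not establish any
accuracy level on real DEAP/SEED recordings, which are gated downloads and
out of scope here.

# Known limitations

* The reference CNN backend requires an external deep-learning runtime and
  pretrained weights; without them it raises an explicit error and the
  deterministic mock projection stands in. Mock features are linear in the
  image, so they are informative but far weaker than real CNN features.
* The in-package SVM is a minimal SMO implementation (features are
  internally z-scored before the kernel), sufficient for the encoded
  histograms at this scale; KNN is the headline classifier.
* The descriptor is O(interior pixels × 104 interpolations) per image
  (~0.15 s at 224²); large datasets should cache feature tables
  (`cmd_extract`) rather than recompute.
* MATLAB-container dataset adapters (`deap_mat`, `seed_mat`) need an
  external `.mat` reader and are interface stubs here; native text and EDF
  containers are fully supported.
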