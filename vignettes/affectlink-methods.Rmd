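---
title: "Cross-modal affective correlation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal affective correlation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(affectlink)
```

`affectlink` quantifies how low-level audio-visual properties of an
emotional film stimulus co-vary with a viewer's EEG and facial
expressions, and how both relate to self-reported valence, arousal and
emotion category. This vignette is the package's own account of the
models it implements, the tunable parameters that matter, what the
synthetic data generator does and does not emulate, and the places where
the design was genuinely open.

## 1. The analysis chain

For each stimulus clip the recording is cut into **15 s windows advanced
by 1 s** (`windowEpochs()`, `windowCount()`): a clip of `T` whole seconds
yields `floor((T - 15)/1) + 1` windows. Windowing is the unit of analysis
throughout; windows are keyed by `(subject, clip, window_start_s)` so
their heavy overlap stays visible to downstream inference.

Per window, four cue families are computed:

* **Visual (11 cues)** — `extractVisualCues()`: visual excitement, shot
  count and mean shot duration, lighting-key median, shadow proportion,
  color energy, GLCM contrast/correlation/energy/homogeneity, and the
  proportion of saturated pixels.
* **Audio (19 cues)** — `extractAudioCues()`: MFCC 1–13, gated loudness
  and loudness range, voice probability, key clarity, mode, harmonic
  flux.
* **EEG (96 + 496 cues)** — `bandPSD()` and
  `conditionalEntropyMatrix()` after `cleanEEG()`.
* **Face (30 cues)** — `computeFaceCues()` on per-window mean landmarks
  (or on the frame nearest to the wavelet-fused face image).

Modality pairs are then related by regularized CCA (`ccaFit()`), cue
importance is read from structure correlations (`topLoadings()`),
first-component projections are correlated with valence/arousal
(`projectAndCorrelate()`) and regressed on the 12-category emotion
vocabulary (`regressEmotions()`), and band coefficients are compared
across subjects with paired t-tests (`pairedBandTTest()`). An optional
final stage compares layer representations of two small convolutional
networks fed EEG topographic images and face images
(`similarityMatrix()`).

## 2. Visual cues

Frames are RGB arrays in $[0,1]$. Defaults, with the reasoning:

* **GLCM** (`glcmFeatures()`): luminance (`0.299R + 0.587G + 0.114B`)
  quantized to **8 equal-width levels on the fixed [0, 1] range**,
  symmetric normalized co-occurrence matrix, offsets $(0,1)$ and $(1,0)$
  averaged, then the standard contrast $\sum p_{ij}(i-j)^2$, energy
  $\sum p_{ij}^2$, homogeneity $\sum p_{ij}/(1+|i-j|)$ and correlation
  (normalized covariance of $(i,j)$). Eight levels keep exhaustive
  pair-enumeration oracles tractable; fixed-range quantization (rather
  than per-frame min/max) makes the descriptors respond to absolute
  luminance spread, which the synthetic texture knob relies on. A
  zero-variance matrix (constant frame) returns the correlation sentinel
  0 with a warning.
* **Lighting key** (`lightingKey()`): CIE L* per pixel (the lightness
  channel shared by Luv and Lab, computed from linearized sRGB with the
  matrix-consistent D65 white), median per frame, and the fraction of
  pixels with $L^* < 0.2$ as shadow. The 0.2 threshold mirrors the
  saturation convention below.
* **Color energy** (`colorEnergy()`): per frame
  `mean(V*S) * sd(V*S)` in HSV — raw energy times color contrast. This
  operationalizes "product of raw energy and color contrast" with one
  interpretable term for each factor.
* **Saturation proportion**: fraction of pixels with HSV saturation
  above **0.2**.
* **Visual excitement** (`visualExcitement()`): fraction of pixels whose
  CIE-Lab distance between consecutive frames exceeds **ΔE = 10** (a
  clearly supra-threshold perceptual difference), frames wider than 128
  px column-subsampled first.
* **Shot detection** (`detectShots()`): 16-bin per-channel HSV histogram
  difference, normalized to $[0,1]$; a cut needs score $> 0.3$ and at
  least **0.6 s** since the previous cut. `n_shots = cuts + 1`.
* Sequences faster than **8 fps** are uniformly subsampled before cue
  computation (cost control; the cues are frame averages).

## 3. Audio cues

Mono, $f_s \ge 8$ kHz. **MFCC**: 25 ms frames, 10 ms hop, Hann taper, 40
triangular mel filters to Nyquist, log energies floored at $10^{-10}$,
orthonormal DCT-II, coefficients 1–13 (the 0th is energy and is
excluded — digital silence therefore gives exactly zero). **Loudness**:
a simplified two-stage K-style weighting (2nd-order 38 Hz high-pass plus
a +4 dB shelf above 1.5 kHz, applied causally), 400 ms blocks at 100 ms
hop, absolute gate at −70; loudness is the power mean of gated block
levels, range the 95th−10th percentile spread. Levels are meaningful
relatively, not as absolute broadcast units. **Voice probability**: per
40 ms frame, `harmonicity * (1 - flatness) * sqrt(modulation)` with
harmonicity the peak normalized autocorrelation in the 85–300 Hz
fundamental range, flatness the spectral geometric/arithmetic mean
ratio, and modulation the clip-level 2–8 Hz energy-envelope fraction;
frames scoring above 0.25 count as voiced. The score is monotone in each
component and is exposed as a pluggable `scoreFun` so a trained detector
can replace it. **Pitch**: 100 ms chroma frames (55–2000 Hz), Krumhansl
major/minor profiles as the 24 key templates; key clarity is the best
template correlation (clamped to $[0,1]$), mode the best-major minus
best-minor difference, harmonic flux the mean Euclidean change of the
L2-normalized spectrum. Silence returns the sentinel (0, 0, 0). All
clip- or window-level audio values are means over frames; frame-level
features are computed once per clip and re-aggregated per window, which
is exactly equal to direct window extraction for frame-mean cues.

## 4. EEG features

* **Cleaning** (`cleanEEG()`): 0.5 Hz high-pass, then a simplified
  artifact-subspace method: the calibration covariance is the entrywise
  median of 0.5 s block covariances; each 50%-overlapping block is
  eigendecomposed and components whose variance exceeds $k^2 = 25$ times
  the calibration variance along the same direction are zeroed; blocks
  are recombined by triangular overlap-add. On artifact-free synthetic
  EEG the output correlates with the input above 0.999 per channel;
  planted 500 µV bursts are attenuated by more than 80% of peak
  amplitude. Full artifact subspace reconstruction (calibration-segment
  selection, channel-wise consensus) is deliberately out of scope; the
  cleaner is a pluggable default.
* **Band PSD** (`bandPSD()`): Welch averaged periodogram, 2 s Hann
  segments, 50% overlap; band value = mean density over bins in
  $[4,7)$, $[7,13)$, $[13,30)$ Hz; output is channel-major,
  band-minor — a frozen order on which loading interpretation depends.
  The gamma band is deliberately excluded. Because windows start on
  segment-hop boundaries, the pipeline computes segment periodograms
  once per clip and window-averages them; this path is exactly equal to
  per-window Welch.
* **Conditional entropy** (`conditionalEntropy()`): each series
  discretized into **16 equal-width bins over its own range**,
  $H(X|Y) = H(X,Y) - H(Y)$ from the joint histogram, in **bits**
  (both choices configurable). The feature vector is the lower triangle
  ($i > j$, row-major) of the 32×32 pair matrix: 496 one-way values.

## 5. Facial features

The 49-point layout is: eyebrows 2×5, nose 9 (bridge 11–14, base
15–19), eyes 2×6, outer lip 12, inner lip 6. `faceCueTable()` is the
frozen, versioned definition of all 30 features — name, kind
(horizontal/W, vertical/H, area/(W·H)) and landmark indices — and
includes every feature the analysis names (eye heights and widths,
eyebrow–eye and eyebrow–lip distances, lip width and height, inner-mouth
and nose areas, nose width and height); the remainder (eye areas, brow
widths and arches, interocular distance, eye–nose and mouth–eye
distances, …) were chosen to cover the same facial regions
symmetrically. Polygon areas use the shoelace formula. Normalization by
the face box makes the vector exactly similarity-invariant. The 50×50 px
minimum face size is a detection-time filter (`detectFace()`, together
with the image-margin exclusion), not a class invariant, so normalized
unit-box fixtures remain representable. Frame fusion
(`fuseFrames()`) uses an orthonormal Haar 4-level decomposition with the
max-absolute-detail / mean-approximation rule; orthonormal Haar gives
exact single-image reconstruction, which anchors the fusion tests.
Window features default to per-window **mean landmarks**; the
fused-image path (features from the frame nearest the fused
representation) is provided for real video, where per-frame landmark
noise is not independent of appearance.

## 6. Canonical correlation analysis

`ccaFit()` solves the symmetric form of
$(C_{xx}+\lambda I)^{-1} C_{xy} (C_{yy}+\lambda I)^{-1} C_{yx}$,
clamps correlations to $[0,1]$, fixes weight signs (largest $|w_x|$
entry positive) and reports structure correlations against the realized
variates. Defaults: ridge $\lambda = 10^{-3}$ on standardized cues (the
496-dimensional entropy block against a few hundred windows per subject
is otherwise singular); ridge 0 is reserved for oracle comparisons and
errors informatively on rank-deficient input. Fitting is **per subject**
by default, aggregated across subjects by mean absolute loading;
`grouping = "pooled"` fits all windows jointly and is the right choice
when subjects share one generative model (as the synthetic data do).
Ties in $|loading|$ break by frozen column order. "Projecting back the
joint space" is operationalized as first-component variate scores plus
structure-correlation attribution; the projection must use the same
standardized matrices the fit saw. Because 1 s-hop windows overlap
heavily, correlation p-values at window level are nominal only;
`blockPermutePValue()` permutes labels at clip level for honest
inference.

## 7. Representational similarity

`eegToTopoImage()` interpolates the three band-power maps onto a 32×32
grid by inverse-distance-squared weighting over the electrodes — exact
at electrode pixels and constant-preserving — with R/G/B = theta/alpha/
beta, joint [0, 1] scaling per image, zero outside the unit scalp disk.
(Scattered linear-in-hull interpolation has no in-scope implementation;
inverse-distance weighting satisfies the same contract points.)
`buildNetwork()` builds a width-reduced VGG-style stack — 3×3
convolutions in five blocks of repeats 2,2,3,3,3 with 8–32 filters,
2×2 max pooling, two dense layers — giving 15 probe layers, matching
the probed layers of the full 16-layer architecture with its classifier
discarded. Weights are He-initialized and seeded; no training is
performed: random-weight networks preserve input-geometry structure,
which is what the representational comparison measures at this scale
(reproducing a trained network's specific layer correlation pattern is a
non-goal). `layerRDM()` is $1 -$ Pearson correlation of flattened
activations (sentinel dissimilarity 1 for zero-variance vectors);
`similarityMatrix()` compares RDM upper triangles by Spearman
correlation, the standard choice when the dissimilarity scale is not
meaningful. Activations are capped at 4096 values per layer with a
seeded mask.

## 8. The synthetic data generator

`genDataset()` emulates the structure of a film-viewing affect study:
subjects × clips, one latent affect pair
$(z_\mathrm{val}, z_\mathrm{ar}) \sim N(0, I)$ per trial, all modalities
driven by that latent, labels
`clip(round(5 + 2z), 1, 9)` per axis plus a 12-tag emotion from the
quadrant × intensity map (`emotionTagTable()`; tiers at latent radius 1
and 2). Each driven cue family observes $z + N(0, 1/\mathrm{snr}^2)$;
the default SNR is 2 and the audio families run at half that SNR,
making texture the dominant stimulus channel, mirroring the finding the
pipeline is designed to detect. Default geometry follows the study
scale (tens of clips, 35–117 s durations, 32-channel 256 Hz EEG, 1–9
labels); frame size (32 px), frame rate (2 fps) and audio rate (8 kHz)
are chosen for desk-scale runtimes.

The **planted linkages** and their knobs:

* *Arousal → GLCM homogeneity.* The texture knob is calibrated in
  homogeneity units: a measured (amplitude × edge-style) → homogeneity
  surface is inverted so that mean homogeneity is **linear** in the
  latent (slope 0.075 per scaled-latent unit over ±1.1, with a small
  leak outside so the effect is strictly monotone). Each clip draws an
  independent *texture style* nuisance — a sparse strong two-level edge
  field — which moves contrast, energy and correlation at fixed
  homogeneity, so the planted cue is identifiable among its co-moving
  GLCM siblings. Per-frame grain has fixed absolute amplitude so visual
  excitement does not track the knob.
* *Arousal → central beta.* Beta-band amplitude at C3/Cz/C4 scales as
  the square root of a tanh-bounded linear map, so beta **power** (what
  the PSD measures) is linear in the latent, again with a strict-
  monotonicity leak.
* *Valence → lighting; valence → pitch; arousal → loudness; arousal →
  eye opening; valence → nose scale* — all smooth monotone (tanh) maps.

What the generator does **not** emulate: volume-conduction-realistic
EEG topographies, photorealistic faces, real soundtracks, inter-subject
variability (all synthetic subjects share one generative model — hence
pooled fitting in the benchmark), label response styles, or genuinely
nonstationary artifacts beyond injectable bursts. Passing tests
therefore demonstrate correctness of the measurement and inference
chain under a known ground truth, not performance on human data.

## 9. The end-to-end benchmark

`plantedLinkageRun()` freezes the package's recovery benchmark: 5
subjects × 15 clips × 34 s at SNR 2 → 1500 windows; visual+audio cues
against the 96 band-PSD features; pooled CCA, ridge $10^{-3}$;
detection means the top AV loading is `glcm_homogeneity` and the top
EEG loading a central-channel beta feature. The entropy block is off
(the planted signal is spectral; 496 extra dimensions add cost, not
information here) and the cleaner is off (no artifacts are injected;
its pass-through and attenuation behavior are tested separately). The
geometry balances three pressures: 1500 windows as the augmented sample
size, enough independent clips (75) that the 30-dimensional AV block
cannot interpolate the clip-level latent structure, and total synthetic
content (~2550 s per run) small enough for routine re-runs. The
acceptance suite requires detection in at least 18 of 20 seeds.

## 10. Numerical choices and degenerate inputs

Documented sentinels: GLCM correlation 0 on zero-variance matrices
(warned); silence → zero MFCCs, floor loudness (−100, range 0), pitch
(0,0,0); zero-variance activation vectors → RDM dissimilarity 1;
zero-variance paired differences → $t = 0, p = 1$ (or ±∞, 0 for a
nonzero constant difference); constant cue columns are dropped with a
warning naming them. Entropy uses $0 \log 0 = 0$ and clamps tiny
negative rounding to 0. Canonical correlations clamp to $[0,1]$;
eigenvector signs are fixed deterministically. `withSeed()` isolates
all generator randomness from the caller's RNG state, and every
stochastic helper takes an explicit seed, so equal seeds give
bit-identical objects.

## 11. Known limitations

Loadings from per-subject fits with few clips are unstable when the
feature dimension approaches the number of independent clips — pooled
fitting or more clips is the remedy, and the benchmark does both. The
simplified cleaner is not full artifact subspace reconstruction and
will not repair sustained artifacts. Absolute loudness is not
broadcast-calibrated. The conditional-entropy estimator is biased for
small windows (binned plug-in); its role here is comparative. The
similarity stage uses untrained networks by design and says nothing
about learned feature hierarchies.
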