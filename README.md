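# affectlink

Cross-modal correlation analysis of affective multimedia, EEG and facial
expressions.

When people watch emotionally charged movie clips, low-level properties of
the stimulus — the texture and lighting of the image, the pitch and
loudness of the soundtrack — leave measurable traces in the viewer's
physiology. `affectlink` implements the full analysis chain for relating
three concurrent recordings of such an experiment:

* **Audio-visual cues** of the stimulus itself: 11 video cues (visual
  excitement, shot count and duration, lighting key and shadow proportion,
  color energy, four gray-level co-occurrence (GLCM) texture descriptors,
  saturated-pixel proportion) and 19 audio cues (13 MFCCs, gated loudness
  and loudness range, voice probability, key clarity, mode, harmonic
  flux) — 30 cues per 15 s window.
* **EEG cues** from a 32-channel, 256 Hz recording: band power spectral
  density in theta (4–7 Hz), alpha (7–13 Hz) and beta (13–30 Hz) per
  channel (96 features) and one-way conditional entropy for each channel
  pair (lower triangle, 496 features), after subspace artifact cleaning.
* **Facial-expression cues**: 30 normalized distance/area features from a
  49-point landmark layout (eye opening, eyebrow-to-eye and -to-lip
  distances, lip and nose geometry, mouth/nose/eye areas), with wavelet
  max-fusion of face frames into one representative image.

The modalities are related by regularized **canonical correlation
analysis** (CCA). For cue matrices $X \in \mathbb{R}^{n\times p}$ and
$Y \in \mathbb{R}^{n\times q}$ it solves

$$(C_{xx} + \lambda I)^{-1} C_{xy} (C_{yy} + \lambda I)^{-1} C_{yx}\, w_x = \rho^2\, w_x,$$

reports canonical correlations $\rho_k$, weights, and structure
correlations ("loadings", the correlation of each original cue with its
canonical variate), ranks cues by absolute loading, correlates
first-component projections with self-reported valence/arousal (1–9) and
regresses them on a 12-category emotion vocabulary. A final stage converts
EEG windows to RGB topographic images (R/G/B = theta/alpha/beta), feeds
them and fused face images through two small VGG-style convolutional
networks, and compares all 15 probe layers of one network against the
other by representational similarity analysis (Spearman correlation of
representational dissimilarity matrix upper triangles).

Because the human dataset that motivates this pipeline is access
restricted, the package ships a first-class **synthetic data generator**
(`genDataset()`): every trial draws a latent affect vector
$(z_\mathrm{val}, z_\mathrm{ar})$ that drives frame texture (GLCM
homogeneity, via a calibrated texture knob), lighting, audio pitch and
loudness, central-channel beta amplitude, eye opening and nose scale, plus
the behavior labels — so every downstream stage can be tested against
ground truth.

## Worked example

```r
library(affectlink)

cfg <- defaultConfig(seed = 7, nSubjects = 4, nClips = 12, clipSeconds = 34,
                     grouping = "pooled", entropy = FALSE, clean = FALSE)
res <- runAll(cfg)   # ~1-2 min

res$manifest$nWindows
#> [1] 960

round(res$cca[["AV-EEG"]]$meanCor, 3)
#> [1] 0.952

round(head(sort(res$cca[["AV-EEG"]]$loadingsX, decreasing = TRUE), 3), 4)
#> glcm_homogeneity    glcm_contrast      glcm_energy
#>           0.7959           0.7836           0.7301

subset(res$behavior[["AV-EEG"]], label == "arousal")[, c("side", "r", "top_cue")]
#>   side          r          top_cue
#> 2    x -0.7882699 glcm_homogeneity
#> 4    y -0.7555316          C4_beta
```

48 clips of 34 s yield 960 overlapping 15 s windows (1 s hop). The AV–EEG
canonical correlation is high because the synthetic arousal latent drives
both sides; the top audio-visual loading is GLCM homogeneity, and the
arousal-label correlation is carried by homogeneity on the stimulus side
and central beta power (`C4_beta`) on the EEG side — the planted linkage,
recovered end to end. Signs are negative because higher arousal lowers
homogeneity. Windows within a clip share one label, so treat nominal
p-values with care and use `blockPermutePValue()` for honest inference.

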