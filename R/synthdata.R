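#' Linkage configuration for the synthetic generator
#'
#' Describes how the two latent affect axes drive the observable cue
#' channels. The arousal latent drives frame texture amplitude (lowering
#' GLCM homogeneity, raising contrast), beta-band EEG amplitude at the
#' central channels, audio loudness and eye opening; the valence latent
#' drives lighting level, audio pitch and nose scale. \code{snr} is the
#' ratio of latent to noise scale: each driven family sees
#' \code{z + N(0, 1/snr^2)}, and labels see the same corruption, so
#' \code{snr = Inf} is the zero-noise setting.
#'
#' @param snr positive signal-to-noise ratio (may be \code{Inf}).
#' @param textureGain,betaGain,loudnessGain,pitchGain,lightingGain,
#'   eyeGain,noseGain per-family coupling strengths.
#' @param audioSnrFactor multiplier on \code{snr} for the audio families;
#'   the default 0.5 makes audio a secondary (noisier) channel of the
#'   latent, mirroring the primacy of the texture linkage.
#' @return list of class \code{"linkageConfig"}.
#' @export
linkageConfig <- function(snr = 2, textureGain = 0.5, betaGain = 0.5,
                          loudnessGain = 0.15, pitchGain = 0.15,
                          lightingGain = 0.12, eyeGain = 0.3,
                          noseGain = 0.2, audioSnrFactor = 0.5) {
  if (snr <= 0) stop("snr must be positive")
  structure(list(snr = snr, textureGain = textureGain, betaGain = betaGain,
                 loudnessGain = loudnessGain, pitchGain = pitchGain,
                 lightingGain = lightingGain, eyeGain = eyeGain,
                 noseGain = noseGain, audioSnrFactor = audioSnrFactor),
            class = "linkageConfig")
}

#' The 12-category emotion vocabulary
#'
#' Tags are arranged as the four valence/arousal quadrants of the circumplex
#' times three intensity tiers (distance of the latent from the origin:
#' below 1, 1 to 2, above 2).
#'
#' @return data.frame with columns \code{quadrant}, \code{tier}, \code{tag}.
#' @export
emotionTagTable <- function() {
  data.frame(
    quadrant = rep(c("V+A+", "V-A+", "V-A-", "V+A-"), each = 3),
    tier = rep(1:3, times = 4),
    tag = c("contentment", "joy", "excitement",
            "anxiety", "fear", "anger",
            "boredom", "sadness", "disgust",
            "neutral", "calm", "serenity"),
    stringsAsFactors = FALSE)
}

#' Map a latent affect vector to behavior labels
#'
#' Valence and arousal labels are \code{clip(round(5 + 2 z), 1, 9)} on each
#' axis; the emotion tag is chosen by latent quadrant and intensity tier
#' (see \code{\link{emotionTagTable}}).
#'
#' @param zv,za latent valence and arousal (possibly noise-corrupted).
#' @return list with \code{valence}, \code{arousal} (integers 1..9) and
#'   \code{emotion} (character tag).
#' @export
latentToLabels <- function(zv, za) {
  clip9 <- function(z) as.integer(min(9, max(1, round(5 + 2 * z))))
  quad <- if (zv >= 0 && za >= 0) "V+A+" else if (zv < 0 && za >= 0) "V-A+"
    else if (zv < 0) "V-A-" else "V+A-"
  r <- sqrt(zv^2 + za^2)
  tier <- if (r < 1) 1L else if (r < 2) 2L else 3L
  tab <- emotionTagTable()
  list(valence = clip9(zv), arousal = clip9(za),
       emotion = tab$tag[tab$quadrant == quad & tab$tier == tier])
}

# Band-limited Gaussian noise, unit RMS per column, for several disjoint
# bands at once: one white-noise spectrum per column is masked per band
# (disjoint frequency supports make the band components independent).
# Returns a list of n x nCols matrices, one per band.
bandNoiseSet <- function(n, nCols, fs, bands) {
  sp <- stats::mvfft(matrix(stats::rnorm(n * nCols), n, nCols))
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                     # two-sided frequency axis
  lapply(bands, function(b) {
    spb <- sp
    spb[f < b[1] | f > b[2], ] <- 0
    y <- Re(stats::mvfft(spb, inverse = TRUE)) / n
    rms <- sqrt(colMeans(y^2))
    rms[rms == 0] <- 1
    sweep(y, 2, rms, `/`)
  })
}

#' Generate a synthetic EEG epoch
#'
#' Each channel is a sum of band-limited Gaussian noise in the theta, alpha
#' and beta bands plus a small broadband floor. The beta-band amplitude at
#' the central channels (C3, Cz, C4) scales as \code{exp(betaGain * z_arousal)},
#' so central beta power is strictly monotone in the arousal latent for a
#' fixed seed. Optional high-amplitude artifact bursts can be injected for
#' cleaner tests.
#'
#' @param latent named numeric with \code{z_valence}, \code{z_arousal}.
#' @param nChannels number of channels (32 for the default montage).
#' @param fs sampling rate in Hz, at least 64 (the beta band must be
#'   resolvable).
#' @param seconds epoch duration.
#' @param seed integer seed; fixed seed gives a bit-identical epoch.
#' @param betaGain coupling of \code{z_arousal} to central beta amplitude.
#' @param artifacts logical; inject burst artifacts.
#' @param burstAmp burst peak amplitude in microvolts.
#' @param nBursts number of bursts when \code{artifacts} is \code{TRUE}.
#' @return an \code{\link{EEGRecording}}.
#' @export
genEEG <- function(latent, nChannels = 32, fs = 256, seconds = 15,
                   seed = 1, betaGain = 0.5, artifacts = FALSE,
                   burstAmp = 500, nBursts = 3) {
  if (fs < 64) stop("fs must be >= 64 Hz to resolve the beta band")
  n <- round(seconds * fs)
  if (n < 2 * fs) stop("epoch shorter than one PSD segment")
  mon <- standardMontage()
  if (nChannels != nrow(mon))
    stop("the default montage has 32 channels")
  withSeed(seed, function() {
    central <- mon$name %in% centralChannels()
    ampTheta <- rep(6, nChannels)
    ampAlpha <- rep(8, nChannels)
    # planted arousal linkage: central beta POWER is linear in the latent
    # over the working range (amplitude enters the PSD squared), with a
    # small leak outside the tanh bound keeping the effect strictly
    # monotone
    ampBeta <- rep(4, nChannels)
    u <- tanh(1.2 * betaGain * latent[["z_arousal"]])
    u <- u + 0.02 * (1.2 * betaGain * latent[["z_arousal"]] - u)
    ampBeta[central] <- ampBeta[central] * sqrt(pmax(1 + 0.85 * u, 0.05))
    bn <- bandNoiseSet(n, nChannels, fs, eegBands())
    x <- bn$theta %*% diag(ampTheta) + bn$alpha %*% diag(ampAlpha) +
      bn$beta %*% diag(ampBeta) +
      matrix(stats::rnorm(n * nChannels, sd = 1), n, nChannels)
    data <- t(x)
    if (artifacts) {
      burstLen <- round(0.2 * fs)
      pulse <- hannWindow(burstLen) * burstAmp
      for (k in seq_len(nBursts)) {
        ch <- sample.int(nChannels, 1)
        t0 <- sample.int(n - burstLen, 1)
        data[ch, t0:(t0 + burstLen - 1)] <-
          data[ch, t0:(t0 + burstLen - 1)] + pulse * sample(c(-1, 1), 1)
      }
    }
    EEGRecording(data, fs = fs, channelNames = mon$name,
                 channelXY = as.matrix(mon[, c("x", "y")]))
  })
}

# Texture-knob calibration: mean GLCM homogeneity (8 levels, the default
# offsets) of the synthetic frame model as a function of the static-
# pattern amplitude (rows) and the texture-style mixing weight w (columns;
# w is the fine-grain fraction of the pattern). Measured once over the
# reference pattern statistics. The generator drives the amplitude through
# the inverse of this surface, so the planted homogeneity is linear in the
# latent whatever texture style a clip draws — the other GLCM descriptors
# then carry independent style variance.
textureCalibration <- function() {
  H <- rbind(
    c(0.80870, 0.74084, 0.74148, 0.72776),
    c(0.79726, 0.74208, 0.73518, 0.72050),
    c(0.78242, 0.74394, 0.72856, 0.71386),
    c(0.77032, 0.74270, 0.72215, 0.70462),
    c(0.75587, 0.73731, 0.71309, 0.70037),
    c(0.74222, 0.72806, 0.70397, 0.68717),
    c(0.73299, 0.71501, 0.69285, 0.67656),
    c(0.71065, 0.69829, 0.67632, 0.66069),
    c(0.68895, 0.67653, 0.65860, 0.64250),
    c(0.66781, 0.65914, 0.63870, 0.62888),
    c(0.64606, 0.64201, 0.62454, 0.61321),
    c(0.62818, 0.62246, 0.60966, 0.60059),
    c(0.61072, 0.60699, 0.59724, 0.59282),
    c(0.59656, 0.59544, 0.58603, 0.57934),
    c(0.58407, 0.58076, 0.57545, 0.57220),
    c(0.57214, 0.56965, 0.56727, 0.56638),
    c(0.56331, 0.56573, 0.56178, 0.56241),
    c(0.55571, 0.55802, 0.55659, 0.55708),
    c(0.55316, 0.54852, 0.55032, 0.55648))
  list(amps = c(seq(0.02, 0.20, 0.03), seq(0.25, 0.80, 0.05)),
       es = c(0, 0.05, 0.10, 0.15), H = H)
}

# Amplitude achieving a target mean homogeneity at edge amplitude e:
# monotone interpolation of the inverted calibration surface (columns
# forced decreasing; where the surface is flat the choice of amplitude is
# immaterial for homogeneity), linear blend between the bracketing edge
# columns.
ampForHomogeneity <- function(h, e) {
  cal <- textureCalibration()
  e <- min(max(e, min(cal$es)), max(cal$es))
  j <- findInterval(e, cal$es, rightmost.closed = TRUE)
  j2 <- min(j + 1L, length(cal$es))
  invCol <- function(col) {
    col <- cummin(col) - 1e-6 * seq_along(col)   # enforce strict decrease
    hh <- min(max(h, min(col) + 1e-4), max(col) - 1e-4)
    stats::approx(rev(col), rev(cal$amps), xout = hh)$y
  }
  a1 <- invCol(cal$H[, j]); a2 <- invCol(cal$H[, j2])
  t <- if (j2 == j) 0 else (e - cal$es[j]) / (cal$es[j2] - cal$es[j])
  (1 - t) * a1 + t * a2
}

# Planted homogeneity target: linear in the scaled latent u over the
# central range, with a small leak slope outside so the effect stays
# strictly monotone.
homogeneityTarget <- function(u) {
  v <- pmin(pmax(u, -1.1), 1.1)
  v <- v + 0.03 * (u - v)
  0.64 - 0.075 * v
}

# Sparse two-level blob field: sign of a heavily smoothed noise field
# (large blobs, little perimeter).
edgeBlobs <- function(height, width) {
  m <- matrix(stats::rnorm(height * width), height)
  for (i in 1:4) m <- smooth3(m)
  sign(m)
}

# Smooth a matrix with a 3x3 box kernel (replicated edges).
smooth3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- m[c(1, seq_len(nr - 1)), ]; dn <- m[c(seq_len(nr - 1) + 1, nr), ]
  acc <- m + up + dn
  left <- acc[, c(1, seq_len(nc - 1))]; right <- acc[, c(seq_len(nc - 1) + 1, nc)]
  (acc + left + right) / 9
}

# One textured RGB frame. `textureAmp` controls the static-pattern
# luminance amplitude (GLCM homogeneity knob); `edgeField` is a sparse
# strong two-level field (the texture-style nuisance, constant within a
# shot, NOT scaled by the knob); `baseLum` the global level (lighting
# key); `hueField` a smooth field shifting R against B (color energy and
# saturation). The per-frame grain has a fixed absolute amplitude so that
# frame-to-frame change (visual excitement) does not track the texture
# knob.
synthFrame <- function(pattern, hueField, textureAmp, baseLum, satAmp,
                       grainSd = 0.05, edgeField = 0) {
  lum <- baseLum + textureAmp * pattern + edgeField +
    grainSd * matrix(stats::rnorm(length(pattern)), nrow(pattern))
  r <- lum + satAmp * hueField
  g <- lum
  b <- lum - satAmp * hueField
  arr <- array(0, c(nrow(pattern), ncol(pattern), 3))
  arr[, , 1] <- pmin(pmax(r, 0), 1)
  arr[, , 2] <- pmin(pmax(g, 0), 1)
  arr[, , 3] <- pmin(pmax(b, 0), 1)
  arr
}

#' Generate a synthetic frame sequence
#'
#' Textured noise fields with one dedicated knob per visual cue: texture
#' amplitude (GLCM contrast up, homogeneity down) scales as
#' \code{exp(textureGain * z_arousal)}; the global luminance level (lighting
#' key) rises with \code{z_valence}; a smooth hue field provides color
#' energy and saturated pixels; scheduled abrupt pattern switches emulate
#' shot cuts.
#'
#' @param latent named numeric with \code{z_valence}, \code{z_arousal}.
#' @param width,height frame size in pixels.
#' @param fps frame rate.
#' @param seconds clip duration.
#' @param seed integer seed.
#' @param textureGain,lightingGain latent couplings.
#' @param cutTimes seconds at which a shot cut (pattern switch) occurs.
#' @param satAmp amplitude of the hue field.
#' @return a \code{\link{FrameSequence}}.
#' @export
genFrames <- function(latent, width = 32, height = 32, fps = 2, seconds = 15,
                      seed = 1, textureGain = 0.4, lightingGain = 0.12,
                      cutTimes = numeric(0), satAmp = 0.15) {
  nFrames <- max(2L, round(seconds * fps))
  withSeed(seed, function() {
    # texture-style nuisance: sparse strong edge blobs, drawn per clip and
    # independent of the latent
    edgeAmp <- stats::runif(1, 0, 0.15)
    textureAmp <- ampForHomogeneity(
      homogeneityTarget(textureGain * latent[["z_arousal"]]), edgeAmp)
    baseLum <- 0.45 + lightingGain * tanh(latent[["z_valence"]])
    times <- (seq_len(nFrames) - 1) / fps
    shotId <- findInterval(times, sort(cutTimes)) + 1L
    patterns <- list(); hues <- list(); edges <- list()
    for (s in unique(shotId)) {
      patterns[[s]] <- smooth3(matrix(stats::rnorm(height * width), height))
      edges[[s]] <- edgeAmp * edgeBlobs(height, width)
      hues[[s]] <- smooth3(smooth3(matrix(stats::rnorm(height * width), height)))
    }
    frames <- lapply(seq_len(nFrames), function(i)
      synthFrame(patterns[[shotId[i]]], hues[[shotId[i]]],
                 textureAmp, baseLum, satAmp,
                 edgeField = edges[[shotId[i]]]))
    FrameSequence(frames, fps = fps)
  })
}

#' Generate a synthetic audio clip
#'
#' A harmonic tone stack whose fundamental follows \code{z_valence} (pitch
#' knob) and whose overall level follows \code{z_arousal} (loudness knob),
#' with a slow amplitude envelope providing a nonzero loudness range, plus
#' an optional 4 Hz amplitude-modulated voiced-like segment.
#'
#' @param latent named numeric with \code{z_valence}, \code{z_arousal}.
#' @param fs sampling rate (Hz, >= 8000).
#' @param seconds clip duration.
#' @param seed integer seed.
#' @param pitchGain,loudnessGain latent couplings (loudness in dB per
#'   latent unit is \code{20 * loudnessGain / log(10) * ...}; level scales
#'   as \code{exp(loudnessGain * z_arousal)}).
#' @param voicedFraction fraction of the clip occupied by a voiced-like
#'   120 Hz amplitude-modulated segment.
#' @return an \code{\link{AudioClip}}.
#' @export
genAudio <- function(latent, fs = 8000, seconds = 15, seed = 1,
                     pitchGain = 0.25, loudnessGain = 0.3,
                     voicedFraction = 0) {
  n <- round(seconds * fs)
  withSeed(seed, function() {
    t <- (seq_len(n) - 1) / fs
    f0 <- 220 * 2^(pitchGain * latent[["z_valence"]])
    amp <- 0.08 * exp(loudnessGain * latent[["z_arousal"]])
    x <- numeric(n)
    for (h in 1:5) x <- x + sin(2 * pi * h * f0 * t + stats::runif(1, 0, 2 * pi)) / h
    # major-triad partners for key structure
    for (ratio in c(5 / 4, 3 / 2))
      x <- x + 0.5 * sin(2 * pi * ratio * f0 * t + stats::runif(1, 0, 2 * pi))
    env <- 1 + 0.5 * sin(2 * pi * 0.2 * t + stats::runif(1, 0, 2 * pi))
    x <- amp * env * x / max(abs(x))
    if (voicedFraction > 0) {
      nv <- round(voicedFraction * n)
      v <- numeric(nv); tv <- (seq_len(nv) - 1) / fs
      for (h in 1:8) v <- v + sin(2 * pi * h * 120 * tv) / h
      v <- v * (1 + 0.5 * sin(2 * pi * 4 * tv))
      x[seq_len(nv)] <- x[seq_len(nv)] + amp * v / max(abs(v))
    }
    x <- x + 1e-4 * stats::rnorm(n)
    AudioClip(x, fs = fs)
  })
}

#' Canonical 49-point face template
#'
#' Landmarks in a 100 x 100 face box, image convention (y grows downward):
#' points 1-5 left eyebrow, 6-10 right eyebrow, 11-14 nose bridge (top to
#' tip), 15-19 nose base (left to right, 17 at the bottom center), 20-25
#' left eye, 26-31 right eye, 32-43 outer lip, 44-49 inner lip.
#'
#' @param eyeOpen eye-opening factor (1 = neutral); half-opening of each
#'   eye is \code{2 * eyeOpen} pixels.
#' @param noseScale nose size factor (1 = neutral), scaling points 11-19
#'   about the nose center.
#' @param lipRaise vertical raise of the mouth corners in pixels.
#' @return 49 x 2 matrix of (x, y) coordinates.
#' @export
faceTemplate <- function(eyeOpen = 1, noseScale = 1, lipRaise = 0) {
  e <- 2 * eyeOpen
  pts <- rbind(
    # left eyebrow 1-5 (outer to inner)
    c(18, 30), c(24, 28), c(30, 27), c(36, 28), c(42, 30),
    # right eyebrow 6-10 (inner to outer)
    c(58, 30), c(64, 28), c(70, 27), c(76, 28), c(82, 30),
    # nose bridge 11-14
    c(50, 40), c(50, 46), c(50, 52), c(50, 57),
    # nose base 15-19
    c(42, 62), c(46, 64), c(50, 65), c(54, 64), c(58, 62),
    # left eye 20-25: outer, top x2, inner, bottom x2
    c(22, 42), c(27, 42 - e), c(33, 42 - e), c(38, 42), c(33, 42 + e),
    c(27, 42 + e),
    # right eye 26-31: inner, top x2, outer, bottom x2
    c(62, 42), c(67, 42 - e), c(73, 42 - e), c(78, 42), c(73, 42 + e),
    c(67, 42 + e),
    # outer lip 32-43: corner L, upper arc, corner R, lower arc
    c(35, 72 - lipRaise), c(40, 70), c(45, 69), c(50, 68.5), c(55, 69),
    c(60, 70), c(65, 72 - lipRaise), c(60, 75), c(55, 76), c(50, 76.5),
    c(45, 76), c(40, 75),
    # inner lip 44-49: corner L, upper x2, corner R, lower x2
    c(40, 72), c(46, 71), c(54, 71), c(60, 72), c(54, 73.5), c(46, 73.5))
  if (noseScale != 1) {
    idx <- 11:19
    ctr <- c(50, 55)
    pts[idx, ] <- sweep(sweep(pts[idx, ], 2, ctr) * noseScale, 2, ctr, `+`)
  }
  pts
}

#' Generate synthetic landmark trajectories
#'
#' The canonical template with eye opening driven by \code{z_arousal} and
#' nose scale by \code{z_valence}, plus small per-frame positional jitter.
#'
#' @param latent named numeric with \code{z_valence}, \code{z_arousal}.
#' @param nFrames number of frames.
#' @param seed integer seed.
#' @param eyeGain,noseGain latent couplings.
#' @param jitterSd per-frame coordinate jitter (pixels).
#' @return list with \code{points} (49 x 2 x nFrames array), \code{faceBox}
#'   (x, y, W, H), and the realized \code{eyeOpen}, \code{noseScale}
#'   parameters.
#' @export
genLandmarks <- function(latent, nFrames = 30, seed = 1, eyeGain = 0.3,
                         noseGain = 0.2, jitterSd = 0.15) {
  withSeed(seed, function() {
    eyeOpen <- 1 + eyeGain * tanh(latent[["z_arousal"]])
    noseScale <- 1 + noseGain * tanh(latent[["z_valence"]])
    base <- faceTemplate(eyeOpen = eyeOpen, noseScale = noseScale)
    arr <- array(rep(base, nFrames), c(49, 2, nFrames))
    arr <- arr + array(stats::rnorm(length(arr), sd = jitterSd), dim(arr))
    list(points = arr, faceBox = c(0, 0, 100, 100),
         eyeOpen = eyeOpen, noseScale = noseScale)
  })
}

#' Rasterize a simple synthetic face image
#'
#' Draws a grayscale face (light background, elliptical head, dark brows,
#' eye and mouth ellipses sized from the landmark geometry, nose polygon)
#' from a landmark set, for the fusion and detection paths. The image is
#' rendered supersampled and box-averaged down, so sub-pixel geometry
#' changes (eye opening, nose scale) appear as intensity changes. Values
#' in [0, 1].
#'
#' @param lm a \code{\link{LandmarkSet}} or 49 x 2 matrix in the canonical
#'   100 x 100 box.
#' @param side output image side in pixels.
#' @param margin background margin (output pixels) around the face box.
#' @param supersample rendering oversampling factor (default 4).
#' @return side x side numeric matrix.
#' @export
rasterizeFace <- function(lm, side = 64, margin = 8, supersample = 4) {
  pts <- if (is(lm, "LandmarkSet")) lm@points else lm
  ss <- as.integer(supersample)
  big <- side * ss
  m <- margin * ss
  img <- matrix(0.95, big, big)
  sc <- (big - 2 * m) / 100
  px <- m + pts[, 1] * sc
  py <- m + pts[, 2] * sc
  xs <- matrix(rep(seq_len(big), each = big), big)    # column index
  ys <- matrix(rep(seq_len(big), times = big), big)   # row index
  ellipse <- function(cx, cy, rx, ry, val) {
    sel <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
    img[sel] <<- val
  }
  ellipse(m + 50 * sc, m + 50 * sc, 52 * sc, 58 * sc, 0.72)
  # brows: stamps along the brow landmarks
  for (i in 1:10) ellipse(px[i], py[i], 2 * sc, 1.2 * sc, 0.3)
  # eyes: ellipses spanning the eye landmarks (height = eye opening)
  for (eye in list(20:25, 26:31)) {
    exs <- px[eye]; eys <- py[eye]
    ellipse(mean(exs), mean(eys), diff(range(exs)) / 2,
            max(diff(range(eys)) / 2, 0.2 * sc), 0.2)
  }
  # nose: quadrilateral via stamps along bridge and base plus tip ellipse
  for (i in 11:19) ellipse(px[i], py[i], 1.4 * sc, 1.4 * sc, 0.5)
  ellipse(px[13], py[13],
          (max(px[15:19]) - min(px[15:19])) / 2.6,
          (py[17] - py[11]) / 2.6, 0.5)
  # mouth: ellipse spanning the outer lip
  ellipse(mean(px[32:43]), mean(py[32:43]),
          diff(range(px[32:43])) / 2, diff(range(py[32:43])) / 2, 0.33)
  # box-average down to the output side
  out <- matrix(0, side, side)
  for (i in seq_len(ss)) {
    for (j in seq_len(ss)) {
      out <- out + img[seq(i, big, by = ss), seq(j, big, by = ss)]
    }
  }
  out / ss^2
}

#' Generate a full synthetic multimodal dataset
#'
#' Produces \code{nSubjects * nClips} trials. Per trial one latent affect
#' pair is drawn i.i.d. standard normal; each driven cue family observes
#' the latent corrupted by \code{N(0, 1/snr^2)} noise (the linkage), and
#' the behavior labels are \code{clip(round(5 + 2 z), 1, 9)} per axis with
#' the emotion tag from the quadrant x intensity map.
#'
#' @param nSubjects,nClips positive counts.
#' @param clipSeconds clip duration (>= 15 s).
#' @param linkage a \code{\link{linkageConfig}}.
#' @param seed integer master seed; all trial streams derive from it.
#' @param fps,audioFs,eegFs modality sampling rates.
#' @param frameSide frame width/height in pixels.
#' @param nCuts number of scheduled shot cuts per clip; the default scales
#'   with the clip duration (one cut per ~12 s).
#' @return list of \code{\link{SynthTrial}} objects.
#' @export
genDataset <- function(nSubjects, nClips, clipSeconds = 35,
                       linkage = linkageConfig(), seed = 1,
                       fps = 2, audioFs = 8000, eegFs = 256,
                       frameSide = 32, nCuts = NULL) {
  if (is.null(nCuts)) nCuts <- max(1, round(clipSeconds / 12))
  if (nSubjects <= 0 || nClips <= 0) stop("counts must be positive")
  if (clipSeconds < 15) stop("clipSeconds must be >= 15")
  trials <- vector("list", nSubjects * nClips)
  k <- 0L
  noiseSd <- if (is.finite(linkage$snr)) 1 / linkage$snr else 0
  for (s in seq_len(nSubjects)) {
    for (c in seq_len(nClips)) {
      k <- k + 1L
      tseed <- childSeed(seed, s, c)
      trial <- withSeed(tseed, function() {
        z <- c(z_valence = stats::rnorm(1), z_arousal = stats::rnorm(1))
        eff <- function(zv) zv + stats::rnorm(1, sd = noiseSd)
        zTex <- c(z_valence = eff(z[["z_valence"]]),
                  z_arousal = eff(z[["z_arousal"]]))
        zEeg <- c(z_valence = eff(z[["z_valence"]]),
                  z_arousal = eff(z[["z_arousal"]]))
        effAud <- function(zv) zv + stats::rnorm(1, sd = noiseSd /
                                                   linkage$audioSnrFactor)
        zAud <- c(z_valence = effAud(z[["z_valence"]]),
                  z_arousal = effAud(z[["z_arousal"]]))
        zFace <- c(z_valence = eff(z[["z_valence"]]),
                   z_arousal = eff(z[["z_arousal"]]))
        zLab <- c(eff(z[["z_valence"]]), eff(z[["z_arousal"]]))
        cutTimes <- if (nCuts > 0)
          sort(stats::runif(nCuts, 2, clipSeconds - 2)) else numeric(0)
        list(z = z, zTex = zTex, zEeg = zEeg, zAud = zAud, zFace = zFace,
             zLab = zLab, cutTimes = cutTimes)
      })
      labels <- latentToLabels(trial$zLab[1], trial$zLab[2])
      frames <- genFrames(trial$zTex, width = frameSide, height = frameSide,
                          fps = fps, seconds = clipSeconds,
                          seed = childSeed(tseed, 11),
                          textureGain = linkage$textureGain,
                          lightingGain = linkage$lightingGain,
                          cutTimes = trial$cutTimes)
      audio <- genAudio(trial$zAud, fs = audioFs, seconds = clipSeconds,
                        seed = childSeed(tseed, 12),
                        pitchGain = linkage$pitchGain,
                        loudnessGain = linkage$loudnessGain)
      eeg <- genEEG(trial$zEeg, fs = eegFs, seconds = clipSeconds,
                    seed = childSeed(tseed, 13),
                    betaGain = linkage$betaGain)
      lms <- genLandmarks(trial$zFace, nFrames = round(clipSeconds * fps),
                          seed = childSeed(tseed, 14),
                          eyeGain = linkage$eyeGain,
                          noseGain = linkage$noseGain)
      trials[[k]] <- new("SynthTrial", audio = audio, frames = frames,
                         eeg = eeg, landmarks = lms$points,
                         faceBox = lms$faceBox, labels = labels,
                         latent = trial$z, subject = s, clip = c,
                         seed = tseed)
    }
  }
  trials
}
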