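# Nineteen audio cues: 13 clip-level MFCCs, gated loudness and loudness
# range, voice probability, and three pitch features (keyclarity, mode,
# harmonic flux). All clip-level values are means over analysis frames.

hz2mel <- function(f) 2595 * log10(1 + f / 700)
mel2hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel filterbank matrix
#'
#' Triangular filters equally spaced on the mel scale between 0 Hz and
#' Nyquist (HTK convention).
#'
#' @param nMels number of filters.
#' @param nfft FFT length.
#' @param fs sampling rate (Hz).
#' @return nMels x (nfft/2 + 1) matrix.
#' @export
melFilterbank <- function(nMels, nfft, fs) {
  half <- nfft %/% 2 + 1L
  freqs <- (seq_len(half) - 1) * fs / nfft
  edges <- mel2hz(seq(hz2mel(0), hz2mel(fs / 2), length.out = nMels + 2))
  fb <- matrix(0, nMels, half)
  for (m in seq_len(nMels)) {
    lo <- edges[m]; ctr <- edges[m + 1]; hi <- edges[m + 2]
    up <- (freqs - lo) / (ctr - lo)
    down <- (hi - freqs) / (hi - ctr)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II matrix rows k = 1..nCoef (0th row excluded).
dctMatrix <- function(nCoef, n) {
  k <- seq_len(nCoef)
  m <- sqrt(2 / n) * cos(outer(k, (seq_len(n) - 0.5), function(kk, nn)
    pi * kk * nn / n))
  m
}

#' Mel-frequency cepstral coefficients
#'
#' Standard mel-filterbank log-energy plus DCT per frame; the clip-level
#' value of each coefficient is the mean over frames. Coefficients 1-13
#' (the 0th energy coefficient is excluded), so digital silence, whose
#' log-mel vector is constant at the floor, gives exactly zero for every
#' returned coefficient.
#'
#' @param clip an \code{\link{AudioClip}}.
#' @param nCoeffs number of coefficients (default 13).
#' @param frameMs,hopMs frame length and hop in milliseconds (25 / 10).
#' @param nMels mel bands (default 40).
#' @param floor log-energy floor (default 1e-10).
#' @return named numeric mfcc_1 .. mfcc_nCoeffs.
#' @export
mfcc <- function(clip, nCoeffs = 13, frameMs = 25, hopMs = 10, nMels = 40,
                 floor = 1e-10) {
  m <- mfccFrames(clip, nCoeffs, frameMs, hopMs, nMels, floor)
  if (ncol(m$coef) == 0) stop("clip shorter than one frame")
  stats::setNames(rowMeans(m$coef), paste0("mfcc_", seq_len(nCoeffs)))
}

# Frame-level MFCCs: list(coef = nCoeffs x nFrames, times = frame centers).
mfccFrames <- function(clip, nCoeffs = 13, frameMs = 25, hopMs = 10,
                       nMels = 40, floor = 1e-10) {
  fs <- clip@fs
  frameLen <- round(frameMs / 1000 * fs)
  hop <- round(hopMs / 1000 * fs)
  nfft <- 2^ceiling(log2(frameLen))
  fr <- frameSignal(clip@samples, frameLen, hop)
  if (ncol(fr) == 0)
    return(list(coef = matrix(numeric(0), nCoeffs, 0), times = numeric(0)))
  p <- framePowerSpectra(fr, nfft, fs)
  fb <- melFilterbank(nMels, nfft, fs)
  logE <- log(pmax(fb %*% p, floor))
  coef <- dctMatrix(nCoeffs, nMels) %*% logE
  times <- ((seq_len(ncol(fr)) - 1) * hop + frameLen / 2) / fs
  list(coef = coef, times = times)
}

# Simplified two-stage K-style weighting (causal): a 2nd-order 38 Hz
# high-pass removing inaudible rumble, then a +4 dB first-order high shelf
# above ~1.5 kHz approximating head-related emphasis.
kWeight <- function(x, fs) {
  hp <- signal::butter(2, 38 / (fs / 2), type = "high")
  y <- as.numeric(signal::filter(hp, x))
  sh <- signal::butter(1, 1500 / (fs / 2), type = "high")
  hi <- as.numeric(signal::filter(sh, y))
  y + (10^(4 / 20) - 1) * hi
}

# Block loudness: 400 ms blocks, 100 ms hop, levels in dB-like LU units.
# Block mean squares come from a cumulative sum (one O(n) pass).
loudnessBlocks <- function(clip, blockMs = 400, hopMs = 100) {
  fs <- clip@fs
  z <- kWeight(clip@samples, fs)
  blockN <- round(blockMs / 1000 * fs)
  hopN <- round(hopMs / 1000 * fs)
  cs <- c(0, cumsum(z^2))
  n <- length(z)
  if (n < blockN) {
    ms <- mean(z^2)
    times <- n / (2 * fs)
  } else {
    starts <- seq(1L, n - blockN + 1L, by = hopN)
    ms <- (cs[starts + blockN] - cs[starts]) / blockN
    times <- (starts - 1L + blockN / 2) / fs
  }
  list(level = -0.691 + 10 * log10(pmax(ms, 1e-12)), times = times)
}

loudnessFromBlocks <- function(lev, gate = -70, floorLevel = -100) {
  keep <- lev > gate
  if (!any(keep))
    return(c(loudness = floorLevel, loudness_range = 0))
  g <- lev[keep]
  mean_ms <- mean(10^((g + 0.691) / 10))
  c(loudness = -0.691 + 10 * log10(mean_ms),
    loudness_range = unname(stats::quantile(g, 0.95) -
                              stats::quantile(g, 0.10)))
}

#' Gated loudness and loudness range
#'
#' EBU-style gated block measurement with a simplified two-stage
#' K-weighting filter: block level over 400 ms blocks (100 ms hop) of the
#' weighted signal in dB-like LU units, absolute-gated at -70; loudness is
#' the power mean of gated block levels and the range is the 95th minus the
#' 10th percentile of the gated block levels. An all-silent clip returns
#' the floor level (-100) with range 0.
#'
#' @param clip an \code{\link{AudioClip}} (>= 3 s for a meaningful range).
#' @return named numeric: loudness, loudness_range.
#' @export
loudness <- function(clip) {
  lb <- loudnessBlocks(clip)
  loudnessFromBlocks(lb$level)
}

# Frame-level voicing analysis: 40 ms frames, 40 ms hop. Returns per-frame
# score components and the frame times.
voiceFrames <- function(clip) {
  fs <- clip@fs
  frameLen <- round(0.040 * fs)
  hop <- round(0.040 * fs)
  fr <- frameSignal(clip@samples, frameLen, hop)
  if (ncol(fr) == 0) return(NULL)
  nfft <- 2^ceiling(log2(2 * frameLen))
  frz <- rbind(fr, matrix(0, nfft - frameLen, ncol(fr)))
  sp <- stats::mvfft(frz)
  pw <- abs(sp)^2
  ac <- Re(stats::mvfft(pw, inverse = TRUE)) / nfft
  lagLo <- max(2L, floor(fs / 300))
  lagHi <- min(frameLen - 1L, ceiling(fs / 85))
  r0 <- pmax(ac[1, ], 1e-12)
  acl <- ac[(lagLo + 1L):(lagHi + 1L), , drop = FALSE]
  harm <- do.call(pmax, lapply(seq_len(nrow(acl)),
                               function(i) acl[i, ])) / r0
  harm <- pmax(0, pmin(1, harm))
  half <- nfft %/% 2 + 1L
  p <- pw[2:half, , drop = FALSE] + 1e-12
  flat <- exp(colMeans(log(p))) / colMeans(p)
  energy <- colMeans(fr^2)
  times <- ((seq_len(ncol(fr)) - 1) * hop + frameLen / 2) / fs
  list(harm = harm, flat = flat, energy = energy, times = times,
       frameRate = fs / hop)
}

# Fraction of energy-envelope modulation in the 2-8 Hz speech-syllable band
# (DC excluded), in [0, 1].
modulationFactor <- function(energy, frameRate) {
  n <- length(energy)
  if (n < 8) return(0)
  e <- sqrt(energy)
  e <- e - mean(e)
  if (all(e == 0)) return(0)
  sp <- abs(stats::fft(e))^2
  half <- n %/% 2 + 1L
  f <- (seq_len(half) - 1) * frameRate / n
  band <- f >= 2 & f <= 8
  sum(sp[seq_len(half)][band]) / sum(sp[2:half])
}

#' Voice probability
#'
#' Fraction of frames classified voiced-speech-like by a documented score:
#' \code{harmonicity * (1 - spectral flatness) * sqrt(modulation factor)},
#' where harmonicity is the maximum normalized autocorrelation in the
#' 85-300 Hz fundamental range, spectral flatness the geometric-to-
#' arithmetic spectral mean ratio, and the modulation factor the clip-level
#' fraction of energy-envelope power in the 2-8 Hz band. The score is
#' monotone in each component; frames with score above \code{threshold}
#' count as voiced. The scoring is a pluggable interface: pass a different
#' \code{scoreFun} to substitute a trained voice-activity detector.
#'
#' @param clip an \code{\link{AudioClip}}.
#' @param threshold voiced score threshold (default 0.25).
#' @param scoreFun function(harmonicity, flatness, modFactor) -> score.
#' @return scalar in [0, 1].
#' @export
voiceProbability <- function(clip, threshold = 0.25,
                             scoreFun = function(h, f, m) h * (1 - f) * sqrt(m)) {
  vf <- voiceFrames(clip)
  if (is.null(vf)) return(0)
  m <- modulationFactor(vf$energy, vf$frameRate)
  mean(scoreFun(vf$harm, vf$flat, m) > threshold)
}

#' Krumhansl-style key profiles
#'
#' Hard-coded major and minor tonal hierarchies used as the 24 key
#' templates (12 rotations each).
#' @return list with \code{major} and \code{minor} length-12 profiles,
#'   index 1 = the tonic pitch class.
#' @export
keyProfiles <- function() {
  list(major = c(6.35, 2.23, 3.48, 2.33, 4.38, 4.09,
                 2.52, 5.19, 2.39, 3.66, 2.29, 2.88),
       minor = c(6.33, 2.68, 3.52, 5.38, 2.60, 3.53,
                 2.54, 4.75, 3.98, 2.69, 3.34, 3.17))
}

# Frame-level chroma and normalized spectra: 100 ms frames, 100 ms hop.
chromaFrames <- function(clip) {
  fs <- clip@fs
  frameLen <- round(0.100 * fs)
  hop <- round(0.100 * fs)
  nfft <- 2^ceiling(log2(frameLen))
  fr <- frameSignal(clip@samples, frameLen, hop)
  if (ncol(fr) == 0) return(NULL)
  p <- framePowerSpectra(fr, nfft, fs)
  freqs <- (seq_len(nrow(p)) - 1) * fs / nfft
  sel <- freqs >= 55 & freqs <= 2000
  pc <- (round(12 * log2(freqs[sel] / 440)) %% 12) + 1L
  agg <- matrix(0, 12, sum(sel))
  agg[cbind(pc, seq_along(pc))] <- 1
  chroma <- agg %*% p[sel, , drop = FALSE]
  e <- colSums(p)
  norm <- sqrt(colSums(p^2))
  norm[norm == 0] <- 1
  spn <- sweep(p, 2, norm, `/`)
  times <- ((seq_len(ncol(fr)) - 1) * hop + frameLen / 2) / fs
  list(chroma = chroma, spn = spn, energy = e, times = times)
}

# Per-frame keyclarity/mode from chroma columns; silent frames -> 0/0.
keyFrames <- function(chroma, energy, silentThresh = 1e-10) {
  prof <- keyProfiles()
  tmpl <- rbind(
    t(vapply(0:11, function(r) prof$major[((0:11 - r) %% 12) + 1],
             numeric(12))),
    t(vapply(0:11, function(r) prof$minor[((0:11 - r) %% 12) + 1],
             numeric(12))))
  tmplC <- t(scale(t(tmpl)))   # row-standardized templates
  nFr <- ncol(chroma)
  mu <- colMeans(chroma)
  sdv <- sqrt(colMeans(chroma^2) - mu^2) * sqrt(12 / 11)
  ok <- energy >= silentThresh & sdv > 0
  sdv[!ok] <- 1
  z <- sweep(sweep(chroma, 2, mu), 2, sdv, `/`)
  cors <- (tmplC %*% z) / 11
  bestMaj <- apply(cors[1:12, , drop = FALSE], 2, max)
  bestMin <- apply(cors[13:24, , drop = FALSE], 2, max)
  keyclarity <- pmax(0, pmax(bestMaj, bestMin)) * ok
  mode <- pmax(-1, pmin(1, bestMaj - bestMin)) * ok
  list(keyclarity = keyclarity, mode = mode)
}

#' Pitch features: keyclarity, mode, harmonic flux
#'
#' A chromagram (55-2000 Hz, 12 pitch classes) is computed per frame;
#' keyclarity is the maximum correlation of the frame chroma against the
#' 24 rotated major/minor key templates (clamped to [0, 1]), mode is the
#' best-major minus best-minor correlation clamped to [-1, 1], and
#' harmonic flux is the mean frame-to-frame Euclidean change of the
#' L2-normalized power spectrum. Silence yields the documented sentinel
#' (0, 0, 0).
#'
#' @param clip an \code{\link{AudioClip}}.
#' @return named numeric: pitch_keyclarity, pitch_mode,
#'   pitch_harmonic_flux.
#' @export
pitchFeatures <- function(clip) {
  cf <- chromaFrames(clip)
  if (is.null(cf)) stop("clip shorter than one analysis frame")
  kf <- keyFrames(cf$chroma, cf$energy)
  nFr <- ncol(cf$spn)
  flux <- if (nFr >= 2)
    mean(sqrt(colSums((cf$spn[, -1, drop = FALSE] -
                         cf$spn[, -nFr, drop = FALSE])^2))) else 0
  c(pitch_keyclarity = mean(kf$keyclarity), pitch_mode = mean(kf$mode),
    pitch_harmonic_flux = flux)
}

#' Names of the nineteen audio cues (frozen order)
#' @return character vector of length 19.
#' @export
audioCueNames <- function()
  c(paste0("mfcc_", 1:13), "loudness", "loudness_range",
    "voice_probability", "pitch_keyclarity", "pitch_mode",
    "pitch_harmonic_flux")

# Frame-level audio feature bundle for windowed aggregation.
audioFrameFeatures <- function(clip, voicedThreshold = 0.25) {
  mf <- mfccFrames(clip)
  lb <- loudnessBlocks(clip)
  vf <- voiceFrames(clip)
  modF <- if (is.null(vf)) 0 else modulationFactor(vf$energy, vf$frameRate)
  voicedScore <- if (is.null(vf)) numeric(0)
    else vf$harm * (1 - vf$flat) * sqrt(modF)
  cf <- chromaFrames(clip)
  kf <- if (is.null(cf)) NULL else keyFrames(cf$chroma, cf$energy)
  nFr <- if (is.null(cf)) 0 else ncol(cf$spn)
  flux <- if (nFr >= 2)
    sqrt(colSums((cf$spn[, -1, drop = FALSE] -
                    cf$spn[, -nFr, drop = FALSE])^2)) else numeric(0)
  fluxTimes <- if (nFr >= 2) (cf$times[-1] + cf$times[-nFr]) / 2 else numeric(0)
  list(mfcc = mf, loud = lb, voiced = voicedScore > voicedThreshold,
       voicedTimes = if (is.null(vf)) numeric(0) else vf$times,
       key = kf, keyTimes = if (is.null(cf)) numeric(0) else cf$times,
       flux = flux, fluxTimes = fluxTimes)
}

# Aggregate frame-level audio features over the window [t0, t1).
aggregateAudioCues <- function(af, t0, t1) {
  inw <- function(t) t >= t0 & t < t1
  sel <- inw(af$mfcc$times)
  mf <- if (any(sel)) rowMeans(af$mfcc$coef[, sel, drop = FALSE])
    else rep(0, nrow(af$mfcc$coef))
  ld <- loudnessFromBlocks(af$loud$level[inw(af$loud$times)])
  vp <- if (any(inw(af$voicedTimes))) mean(af$voiced[inw(af$voicedTimes)]) else 0
  ks <- inw(af$keyTimes)
  kc <- if (any(ks)) mean(af$key$keyclarity[ks]) else 0
  md <- if (any(ks)) mean(af$key$mode[ks]) else 0
  fx <- if (any(inw(af$fluxTimes))) mean(af$flux[inw(af$fluxTimes)]) else 0
  stats::setNames(c(mf, ld, vp, kc, md, fx), audioCueNames())
}

#' Extract the nineteen audio cues
#'
#' Computes all audio cues of a clip in the frozen column order
#' (\code{\link{audioCueNames}}).
#'
#' @param clip an \code{\link{AudioClip}}.
#' @return named numeric vector of length 19.
#' @export
extractAudioCues <- function(clip) {
  af <- audioFrameFeatures(clip)
  aggregateAudioCues(af, 0, length(clip@samples) / clip@fs + 1)
}
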