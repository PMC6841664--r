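# Eleven video cues: visual excitement, shot count/duration, lighting key,
# shadow proportion, color energy, four GLCM texture descriptors, and the
# proportion of saturated pixels.

#' @keywords internal
frameLuminance <- function(frame)
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]

# n x 3 pixel matrix from an RGB frame
framePixels <- function(frame) cbind(as.vector(frame[, , 1]),
                                     as.vector(frame[, , 2]),
                                     as.vector(frame[, , 3]))

# GLCM of a quantized matrix for one (dr, dc) offset: symmetric, normalized
# to a joint probability.
glcmMatrix <- function(q, levels, dr, dc) {
  nr <- nrow(q); nc <- ncol(q)
  r1 <- seq_len(nr - dr); c1 <- seq_len(nc - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  counts <- matrix(tabulate(as.vector(a) * levels + as.vector(b) + 1L,
                            nbins = levels * levels),
                   levels, levels, byrow = TRUE)
  counts <- counts + t(counts)              # symmetric
  counts / sum(counts)
}

glcmDescriptors <- function(p) {
  levels <- nrow(p)
  i <- matrix(rep(seq_len(levels) - 1L, levels), levels)
  j <- t(i)
  contrast <- sum(p * (i - j)^2)
  energy <- sum(p^2)
  homogeneity <- sum(p / (1 + abs(i - j)))
  pi_ <- rowSums(p); pj <- colSums(p)
  mui <- sum((seq_len(levels) - 1L) * pi_)
  muj <- sum((seq_len(levels) - 1L) * pj)
  vi <- sum(((seq_len(levels) - 1L) - mui)^2 * pi_)
  vj <- sum(((seq_len(levels) - 1L) - muj)^2 * pj)
  correlation <- if (vi <= 0 || vj <= 0) {
    warning("zero-variance GLCM; correlation sentinel 0")
    0
  } else sum(p * (i - mui) * (j - muj)) / sqrt(vi * vj)
  c(contrast = contrast, correlation = correlation,
    energy = energy, homogeneity = homogeneity)
}

#' GLCM texture features of a frame sequence
#'
#' Per frame, the luminance image is quantized to \code{levels} equal-width
#' gray levels on the fixed [0, 1] range, a symmetric normalized gray-level
#' co-occurrence matrix is formed for each offset, and the standard
#' contrast, correlation, energy and homogeneity descriptors are computed,
#' averaged over offsets and then over frames. A zero-variance GLCM (e.g. a
#' constant frame) yields the documented correlation sentinel 0 with a
#' warning.
#'
#' @param frames a \code{\link{FrameSequence}}.
#' @param levels number of gray levels (>= 2; default 8).
#' @param offsets list of (row, col) displacement vectors; default
#'   \code{list(c(0, 1), c(1, 0))}.
#' @return named numeric: contrast, correlation, energy, homogeneity.
#' @export
glcmFeatures <- function(frames, levels = 8,
                         offsets = list(c(0, 1), c(1, 0))) {
  if (levels < 2) stop("levels must be >= 2")
  per <- vapply(frames@frames, function(f)
    glcmFrame(frameLuminance(f), levels, offsets), numeric(4))
  rowMeans(per)
}

glcmFrame <- function(g, levels, offsets) {
  q <- pmin(floor(pmin(pmax(g, 0), 1) * levels), levels - 1L)
  storage.mode(q) <- "integer"
  per <- vapply(offsets, function(off)
    glcmDescriptors(glcmMatrix(q, levels, off[1], off[2])), numeric(4))
  rowMeans(per)
}

#' Lighting key of a frame sequence
#'
#' Frames are converted to the Luv color space; per frame the median of the
#' lightness channel (scaled to [0, 1]) and the fraction of pixels below the
#' shadow threshold are taken, then averaged over frames.
#'
#' @param frames a \code{\link{FrameSequence}}.
#' @param shadowThreshold lightness below which a pixel counts as shadow
#'   (default 0.2).
#' @return named numeric: lighting_key_median, shadow_proportion.
#' @export
lightingKey <- function(frames, shadowThreshold = 0.2) {
  per <- vapply(frames@frames, function(f) {
    L <- frameLightness(f)
    c(stats::median(L), mean(L < shadowThreshold))
  }, numeric(2))
  c(lighting_key_median = mean(per[1, ]), shadow_proportion = mean(per[2, ]))
}

# sRGB (gamma-encoded, [0,1]) -> CIE XYZ (D65), vectorized.
srgbToXYZ <- function(px) {
  lin <- ifelse(px <= 0.04045, px / 12.92, ((px + 0.055) / 1.055)^2.4)
  cbind(X = as.vector(lin %*% c(0.4124564, 0.3575761, 0.1804375)),
        Y = as.vector(lin %*% c(0.2126729, 0.7151522, 0.0721750)),
        Z = as.vector(lin %*% c(0.0193339, 0.1191920, 0.9503041)))
}

labF <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3),
                           t / (3 * (6 / 29)^2) + 4 / 29)

# D65 white point implied by the sRGB matrix rows (so white maps exactly
# to L* = 100).
.whiteXYZ <- c(X = 0.4124564 + 0.3575761 + 0.1804375,
               Y = 0.2126729 + 0.7151522 + 0.0721750,
               Z = 0.0193339 + 0.1191920 + 0.9503041)

# CIE L* of every pixel, scaled to [0, 1]. The lightness channel is shared
# by the Luv and Lab spaces, so the lighting key needs nothing else.
frameLightness <- function(frame) {
  Y <- srgbToXYZ(framePixels(frame))[, "Y"] / .whiteXYZ[["Y"]]
  (116 * labF(Y) - 16) / 100
}

# CIE Lab coordinates of every pixel (D65 white).
rgbToLab <- function(px) {
  xyz <- srgbToXYZ(px)
  fx <- labF(xyz[, "X"] / .whiteXYZ[["X"]])
  fy <- labF(xyz[, "Y"] / .whiteXYZ[["Y"]])
  fz <- labF(xyz[, "Z"] / .whiteXYZ[["Z"]])
  cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

#' Color energy of a frame sequence
#'
#' Per frame, raw energy is the mean over pixels of brightness times
#' saturation (HSV), color contrast is the standard deviation of the same
#' product, and the cue is the mean over frames of their product.
#'
#' @param frames a \code{\link{FrameSequence}}.
#' @return scalar, >= 0.
#' @export
colorEnergy <- function(frames) {
  mean(vapply(frames@frames, function(f) colorEnergyFrame(f), numeric(1)))
}

colorEnergyFrame <- function(f) {
  px <- framePixels(f)
  hsv <- grDevices::rgb2hsv(t(px), maxColorValue = 1)
  vs <- hsv["v", ] * hsv["s", ]
  mean(vs) * stats::sd(vs)
}

#' Proportion of saturated pixels
#'
#' Mean over frames of the fraction of pixels whose HSV saturation exceeds
#' the threshold (default 0.2, the normalized-HSV convention).
#'
#' @param frames a \code{\link{FrameSequence}}.
#' @param threshold saturation threshold in [0, 1].
#' @return scalar in [0, 1].
#' @export
saturationProportion <- function(frames, threshold = 0.2) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  mean(vapply(frames@frames, function(f) {
    hsv <- grDevices::rgb2hsv(t(framePixels(f)), maxColorValue = 1)
    mean(hsv["s", ] > threshold)
  }, numeric(1)))
}

# Per-frame CIE-Lab pixel matrix, with optional column subsampling to at
# most maxWidth columns.
frameLab <- function(frame, maxWidth = 128) {
  w <- dim(frame)[2]
  if (w > maxWidth) {
    keep <- round(seq(1, w, length.out = maxWidth))
    frame <- frame[, keep, , drop = FALSE]
  }
  rgbToLab(framePixels(frame))
}

#' Visual excitement
#'
#' Mean over consecutive frame pairs of the fraction of pixels whose
#' perceptual color difference (CIE-Lab Euclidean distance) exceeds a
#' just-noticeable threshold. Frames wider than \code{maxWidth} pixels are
#' column-subsampled first.
#'
#' @param frames a \code{\link{FrameSequence}} with at least 2 frames.
#' @param jnd just-noticeable Lab distance (default 10).
#' @param maxWidth downscaling bound (default 128).
#' @return scalar in [0, 1].
#' @export
visualExcitement <- function(frames, jnd = 10, maxWidth = 128) {
  n <- length(frames@frames)
  if (n < 2) stop("at least two frames required")
  labs <- lapply(frames@frames, frameLab, maxWidth = maxWidth)
  mean(vapply(seq_len(n - 1), function(i) {
    d2 <- rowSums((labs[[i + 1]] - labs[[i]])^2)
    mean(d2 > jnd^2)
  }, numeric(1)))
}

hsvOfFrame <- function(f)
  grDevices::rgb2hsv(t(framePixels(f)), maxColorValue = 1)

hsvHistogram <- function(hsv, nbins) {
  vapply(1:3, function(ch) {
    h <- tabulate(pmin(floor(hsv[ch, ] * nbins), nbins - 1L) + 1L,
                  nbins = nbins)
    h / sum(h)
  }, numeric(nbins))
}

# Normalized per-channel HSV histogram difference between consecutive
# frames: 0.5 * sum |dh| per channel (in [0,1]), averaged over H, S, V.
scoresFromHists <- function(hists) {
  n <- length(hists)
  if (n < 2) return(numeric(0))
  vapply(seq_len(n - 1), function(i)
    mean(colSums(abs(hists[[i + 1]] - hists[[i]])) / 2), numeric(1))
}

shotScores <- function(frames, nbins = 16) {
  hists <- lapply(frames@frames, function(f)
    hsvHistogram(hsvOfFrame(f), nbins))
  scoresFromHists(hists)
}

#' Shot boundary detection
#'
#' A content-change score per frame transition (mean absolute difference of
#' per-channel HSV histograms, normalized to [0, 1]); a cut is declared
#' where the score exceeds \code{threshold} and at least
#' \code{minSceneLen} seconds have elapsed since the previous cut.
#'
#' @param frames a \code{\link{FrameSequence}}.
#' @param threshold normalized score threshold (default 0.3).
#' @param minSceneLen minimum scene length in seconds (default 0.6).
#' @return named numeric: n_shots, avg_shot_duration (seconds).
#' @export
detectShots <- function(frames, threshold = 0.3, minSceneLen = 0.6) {
  scores <- shotScores(frames)
  shotsFromScores(scores, frames@fps, length(frames@frames),
                  threshold, minSceneLen)
}

shotsFromScores <- function(scores, fps, nFrames, threshold = 0.3,
                            minSceneLen = 0.6) {
  minGap <- max(1, round(minSceneLen * fps))
  cuts <- 0L
  last <- -minGap
  for (i in seq_along(scores)) {
    if (scores[i] > threshold && (i - last) >= minGap) {
      cuts <- cuts + 1L
      last <- i
    }
  }
  nShots <- cuts + 1L
  c(n_shots = nShots, avg_shot_duration = (nFrames / fps) / nShots)
}

#' Names of the eleven visual cues (frozen order)
#' @return character vector of length 11.
#' @export
visualCueNames <- function()
  c("visual_excitement", "n_shots", "avg_shot_duration",
    "lighting_key_median", "shadow_proportion", "color_energy",
    "glcm_contrast", "glcm_correlation", "glcm_energy",
    "glcm_homogeneity", "saturation_proportion")

# Per-frame feature table and per-transition scores; the window-level
# aggregation path used by the pipeline so frame work is done once per clip.
visualFrameFeatures <- function(frames, levels = 8,
                                offsets = list(c(0, 1), c(1, 0)),
                                shadowThreshold = 0.2, satThreshold = 0.2,
                                jnd = 10, nbins = 16) {
  n <- length(frames@frames)
  hists <- vector("list", n)
  perFrame <- matrix(0, 8, n,
                     dimnames = list(c("lighting_key_median",
                                       "shadow_proportion", "color_energy",
                                       "saturation_proportion",
                                       "glcm_contrast", "glcm_correlation",
                                       "glcm_energy", "glcm_homogeneity"),
                                     NULL))
  for (i in seq_len(n)) {
    f <- frames@frames[[i]]
    glcm <- glcmFrame(frameLuminance(f), levels, offsets)
    L <- frameLightness(f)
    hsv <- hsvOfFrame(f)
    hists[[i]] <- hsvHistogram(hsv, nbins)
    vs <- hsv["v", ] * hsv["s", ]
    perFrame[, i] <- c(stats::median(L), mean(L < shadowThreshold),
                       mean(vs) * stats::sd(vs),
                       mean(hsv["s", ] > satThreshold),
                       glcm[["contrast"]], glcm[["correlation"]],
                       glcm[["energy"]], glcm[["homogeneity"]])
  }
  labs <- lapply(frames@frames, frameLab)
  excite <- if (n >= 2) vapply(seq_len(n - 1), function(i)
    mean(rowSums((labs[[i + 1]] - labs[[i]])^2) > jnd^2), numeric(1))
    else numeric(0)
  list(perFrame = perFrame, excitement = excite,
       shotScores = scoresFromHists(hists), fps = frames@fps, nFrames = n)
}

# Aggregate frame-level visual features over a frame index range.
aggregateVisualCues <- function(ff, frameIdx, threshold = 0.3,
                                minSceneLen = 0.6) {
  pf <- rowMeans(ff$perFrame[, frameIdx, drop = FALSE])
  trans <- frameIdx[-length(frameIdx)]
  exc <- if (length(trans)) mean(ff$excitement[trans]) else 0
  shots <- shotsFromScores(ff$shotScores[trans], ff$fps, length(frameIdx),
                           threshold, minSceneLen)
  out <- c(visual_excitement = exc, shots,
           pf[c("lighting_key_median", "shadow_proportion", "color_energy")],
           pf[c("glcm_contrast", "glcm_correlation", "glcm_energy",
                "glcm_homogeneity")],
           pf["saturation_proportion"])
  out[visualCueNames()]
}

#' Extract the eleven visual cues
#'
#' Computes all visual cues of a frame sequence in the frozen column order
#' (\code{\link{visualCueNames}}). Sequences faster than \code{maxFps}
#' frames per second are uniformly subsampled first.
#'
#' @param frames a \code{\link{FrameSequence}}.
#' @param levels,offsets GLCM parameters.
#' @param shadowThreshold,satThreshold,jnd thresholds for lighting, saturated
#'   pixels and perceptual change.
#' @param shotThreshold,minSceneLen shot-detector parameters.
#' @param maxFps cue-computation frame-rate cap (default 8).
#' @return named numeric vector of length 11.
#' @export
extractVisualCues <- function(frames, levels = 8,
                              offsets = list(c(0, 1), c(1, 0)),
                              shadowThreshold = 0.2, satThreshold = 0.2,
                              jnd = 10, shotThreshold = 0.3,
                              minSceneLen = 0.6, maxFps = 8) {
  if (frames@fps > maxFps) {
    keep <- unique(round(seq(1, length(frames@frames),
                             by = frames@fps / maxFps)))
    frames <- FrameSequence(frames@frames[keep], fps = maxFps)
  }
  ff <- visualFrameFeatures(frames, levels, offsets, shadowThreshold,
                            satThreshold, jnd)
  aggregateVisualCues(ff, seq_len(ff$nFrames), shotThreshold, minSceneLen)
}
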