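# EEG cleaning, sliding-window epoching, band power spectral density
# (96 features) and pairwise conditional entropy (496 features).

#' Sliding-window epoching
#'
#' Cuts a recording into windows of \code{winS} seconds advanced by
#' \code{hopS} seconds: \code{floor((T - winS)/hopS) + 1} windows, each
#' starting at a multiple of the hop.
#'
#' @param recording an \code{\link{EEGRecording}}.
#' @param winS window length in seconds (default 15).
#' @param hopS hop in seconds (default 1).
#' @return list of \code{\link{EEGRecording}} windows.
#' @export
windowEpochs <- function(recording, winS = 15, hopS = 1) {
  fs <- recording@fs
  n <- ncol(recording@data)
  winN <- round(winS * fs)
  hopN <- round(hopS * fs)
  if (n < winN) stop("recording shorter than one window")
  nWin <- (n - winN) %/% hopN + 1L
  lapply(seq_len(nWin), function(w) {
    i0 <- (w - 1L) * hopN
    new("EEGRecording", data = recording@data[, (i0 + 1L):(i0 + winN),
                                              drop = FALSE],
        fs = fs, channelNames = recording@channelNames,
        channelXY = recording@channelXY)
  })
}

#' Number of sliding windows for a duration
#'
#' @param seconds recording duration (s).
#' @param winS,hopS window and hop (s).
#' @return integer window count.
#' @export
windowCount <- function(seconds, winS = 15, hopS = 1)
  as.integer(floor((seconds - winS) / hopS) + 1)

#' Subspace artifact cleaning
#'
#' A simplified artifact-subspace cleaner: the recording is high-passed at
#' \code{hpHz}; a robust calibration covariance is formed as the
#' entrywise median of block covariances; then within each block the
#' block's own principal components are compared against the calibration
#' variance along the same directions, and components whose variance
#' exceeds \code{k^2} times the calibration bound are zeroed before
#' reconstruction from the retained subspace. Clean data passes through
#' essentially unchanged; high-amplitude transients are strongly
#' attenuated. All-flat channels are flagged, passed through untouched,
#' and reported via a message. The function is a pluggable default: any
#' function with the same signature can stand in for it in the pipeline
#' configuration.
#'
#' @param recording an \code{\link{EEGRecording}} with >= 10 s of data.
#' @param k rejection cutoff in multiples of the calibration baseline
#'   (default 5).
#' @param blockS block length in seconds (default 0.5).
#' @param hpHz high-pass cutoff in Hz (default 0.5).
#' @return an \code{\link{EEGRecording}} of the same shape.
#' @export
cleanEEG <- function(recording, k = 5, blockS = 0.5, hpHz = 0.5) {
  fs <- recording@fs
  x <- recording@data
  if (ncol(x) < 10 * fs) stop("at least 10 s required for calibration")
  flat <- apply(x, 1, stats::sd) == 0
  if (any(flat))
    message("flat channels passed through: ",
            paste(recording@channelNames[flat], collapse = ", "))
  act <- which(!flat)
  hp <- signal::butter(2, hpHz / (fs / 2), type = "high")
  y <- x
  for (ch in act) y[ch, ] <- signal::filtfilt(hp, x[ch, ])
  ya <- y[act, , drop = FALSE]
  blockN <- round(blockS * fs)
  nBlocks <- ncol(ya) %/% blockN
  # robust calibration covariance: median of block covariances entrywise
  covs <- vapply(seq_len(nBlocks), function(b) {
    blk <- ya[, ((b - 1L) * blockN + 1L):(b * blockN), drop = FALSE]
    tcrossprod(blk) / (blockN - 1)
  }, matrix(0, length(act), length(act)))
  c0 <- apply(covs, c(1, 2), stats::median)
  # 50% overlapping blocks (short transients lie fully inside a block),
  # detection always on the original data, triangular overlap-add
  starts <- unique(c(seq(1L, ncol(ya) - blockN + 1L, by = blockN %/% 2L),
                     ncol(ya) - blockN + 1L))
  triang <- pmin(seq_len(blockN), rev(seq_len(blockN)))
  out <- matrix(0, nrow(ya), ncol(ya))
  wsum <- numeric(ncol(ya))
  for (s0 in starts) {
    idx <- s0:(s0 + blockN - 1L)
    blk <- ya[, idx, drop = FALSE]
    eb <- eigen(tcrossprod(blk) / (blockN - 1), symmetric = TRUE)
    # variance bound along each block component from the calibration
    bound <- k^2 * colSums(eb$vectors * (c0 %*% eb$vectors))
    bad <- eb$values > bound
    if (any(bad)) {
      scores <- t(eb$vectors) %*% blk
      scores[bad, ] <- 0
      blk <- eb$vectors %*% scores
    }
    out[, idx] <- out[, idx] + sweep(blk, 2, triang, `*`)
    wsum[idx] <- wsum[idx] + triang
  }
  y[act, ] <- sweep(out, 2, wsum, `/`)
  new("EEGRecording", data = y, fs = fs,
      channelNames = recording@channelNames, channelXY = recording@channelXY)
}

#' Band power spectral density features
#'
#' Averaged-periodogram (Welch) spectral density per channel with
#' Hann-tapered segments; the band value is the mean density over the band
#' bins. Output is ordered channel-major, band-minor over theta, alpha,
#' beta (\code{channel_band} names), 32 channels x 3 bands = 96 features.
#'
#' @param window an \code{\link{EEGRecording}}.
#' @param bands named list of band edges (default \code{\link{eegBands}});
#'   bins are assigned half-open, \code{lo <= f < hi}.
#' @param segS segment length in seconds (default 2).
#' @param overlap fractional segment overlap (default 0.5).
#' @return named numeric vector, channels x bands.
#' @export
bandPSD <- function(window, bands = eegBands(), segS = 2, overlap = 0.5) {
  fs <- window@fs
  hi <- max(unlist(bands))
  if (fs / 2 < hi) stop("fs too low to cover the top band edge")
  segN <- round(segS * fs)
  if (ncol(window@data) < segN) stop("window shorter than one PSD segment")
  hopN <- max(1L, round(segN * (1 - overlap)))
  nCh <- nrow(window@data)
  segs <- lapply(seq_len(nCh), function(ch)
    frameSignal(window@data[ch, ], segN, hopN))
  nSeg <- ncol(segs[[1]])
  big <- do.call(cbind, segs)
  p <- framePowerSpectra(big, segN, fs, density = TRUE)
  freqs <- (seq_len(nrow(p)) - 1) * fs / segN
  out <- numeric(nCh * length(bands))
  nms <- character(nCh * length(bands))
  k <- 0L
  for (ch in seq_len(nCh)) {
    chP <- rowMeans(p[, ((ch - 1L) * nSeg + 1L):(ch * nSeg), drop = FALSE])
    for (b in seq_along(bands)) {
      k <- k + 1L
      sel <- freqs >= bands[[b]][1] & freqs < bands[[b]][2]
      out[k] <- mean(chP[sel])
      nms[k] <- paste(window@channelNames[ch], names(bands)[b], sep = "_")
    }
  }
  stats::setNames(out, nms)
}

# Per-segment band-PSD for a whole recording: one Hann periodogram per
# Welch segment, band means per channel. Because the sliding windows start
# on segment-hop boundaries, the band PSD of a window equals the mean over
# the segments it contains, so segment periodograms are computed once per
# clip instead of once per window.
segmentBandPSD <- function(recording, bands = eegBands(), segS = 2,
                           overlap = 0.5) {
  fs <- recording@fs
  segN <- round(segS * fs)
  hopN <- max(1L, round(segN * (1 - overlap)))
  nCh <- nrow(recording@data)
  segs <- lapply(seq_len(nCh), function(ch)
    frameSignal(recording@data[ch, ], segN, hopN))
  nSeg <- ncol(segs[[1]])
  p <- framePowerSpectra(do.call(cbind, segs), segN, fs, density = TRUE)
  freqs <- (seq_len(nrow(p)) - 1) * fs / segN
  bandSel <- lapply(bands, function(b) freqs >= b[1] & freqs < b[2])
  vals <- matrix(0, nSeg, nCh * length(bands))
  nms <- character(nCh * length(bands))
  k <- 0L
  for (ch in seq_len(nCh)) {
    chP <- p[, ((ch - 1L) * nSeg + 1L):(ch * nSeg), drop = FALSE]
    for (b in seq_along(bands)) {
      k <- k + 1L
      vals[, k] <- colMeans(chP[bandSel[[b]], , drop = FALSE])
      nms[k] <- paste(recording@channelNames[ch], names(bands)[b],
                      sep = "_")
    }
  }
  colnames(vals) <- nms
  list(values = vals, starts = (seq_len(nSeg) - 1) * hopN / fs,
       segS = segS)
}
binIndices <- function(x, bins) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(1L, length(x)))
  i <- floor((x - r[1]) / (r[2] - r[1]) * bins) + 1L
  pmin(i, bins)
}

entropyFromCounts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Conditional entropy between two series
#'
#' Each series is discretized into \code{bins} equal-width bins over its
#' own range; \code{H(X|Y) = H(X,Y) - H(Y)} is estimated from the joint
#' histogram, in bits. Always non-negative; \code{H(X|X) = 0} exactly.
#'
#' @param x,y numeric vectors of equal length.
#' @param bins number of bins per axis (default 16, >= 2).
#' @return conditional entropy in bits.
#' @export
conditionalEntropy <- function(x, y, bins = 16) {
  if (length(x) != length(y)) stop("series must have equal length")
  if (bins < 2) stop("bins must be >= 2")
  ix <- binIndices(x, bins)
  iy <- binIndices(y, bins)
  joint <- tabulate(ix + bins * (iy - 1L), nbins = bins * bins)
  hy <- entropyFromCounts(tabulate(iy, nbins = bins))
  entropyFromCounts(joint) - hy
}

#' Pairwise conditional entropy features
#'
#' \code{H(ch_i | ch_j)} for the lower triangle (i > j) of the channel-pair
#' matrix, row-major, giving \code{choose(32, 2) = 496} one-way values for
#' the default montage. Names are \code{"chi|chj"}.
#'
#' @param window an \code{\link{EEGRecording}}.
#' @param bins bins per channel (default 16).
#' @return named numeric vector of length \code{choose(channels, 2)}.
#' @export
conditionalEntropyMatrix <- function(window, bins = 16) {
  x <- window@data
  nCh <- nrow(x)
  idx <- t(apply(x, 1, binIndices, bins = bins))
  marg <- vapply(seq_len(nCh), function(ch)
    entropyFromCounts(tabulate(idx[ch, ], nbins = bins)), numeric(1))
  out <- numeric(nCh * (nCh - 1L) / 2L)
  nms <- character(length(out))
  k <- 0L
  for (i in 2:nCh) {
    for (j in seq_len(i - 1L)) {
      k <- k + 1L
      joint <- tabulate(idx[i, ] + bins * (idx[j, ] - 1L),
                        nbins = bins * bins)
      out[k] <- entropyFromCounts(joint) - marg[j]
      nms[k] <- paste(window@channelNames[i], window@channelNames[j],
                      sep = "|")
    }
  }
  stats::setNames(pmax(out, 0), nms)
}

#' Extract the EEG cue vector of one window
#'
#' The 96 band-PSD features, optionally followed by the 496 conditional
#' entropy features, in the frozen orders.
#'
#' @param window an \code{\link{EEGRecording}}.
#' @param entropy include the conditional-entropy block (default TRUE).
#' @param bins entropy bins.
#' @return named numeric vector of length 96 or 592.
#' @export
extractEEGCues <- function(window, entropy = TRUE, bins = 16) {
  psd <- bandPSD(window)
  if (!entropy) return(psd)
  c(psd, conditionalEntropyMatrix(window, bins = bins))
}
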