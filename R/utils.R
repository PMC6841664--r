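# Internal helpers shared across modules.

# Hann window (periodic form, as used for averaged periodograms and STFT).
hannWindow <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

# Frame a signal into overlapping columns: frameLen x nFrames matrix.
frameSignal <- function(x, frameLen, hop) {
  n <- length(x)
  nf <- if (n < frameLen) 0L else (n - frameLen) %/% hop + 1L
  if (nf == 0L) return(matrix(numeric(0), nrow = frameLen, ncol = 0))
  idx <- outer(seq_len(frameLen), (seq_len(nf) - 1L) * hop, `+`)
  matrix(x[idx], nrow = frameLen)
}

# One-sided power spectra of framed columns (Hann-tapered periodograms).
# Returns (nfft/2 + 1) x nFrames matrix of |FFT|^2 with taper power
# normalization; `density` scales to PSD units (power per Hz).
framePowerSpectra <- function(frames, nfft, fs, density = FALSE) {
  w <- hannWindow(nrow(frames))
  fw <- frames * w
  if (nrow(fw) < nfft)
    fw <- rbind(fw, matrix(0, nfft - nrow(fw), ncol(fw)))
  sp <- stats::mvfft(fw)
  half <- nfft %/% 2 + 1L
  p <- abs(sp[seq_len(half), , drop = FALSE])^2
  # fold negative frequencies into positive bins (except DC/Nyquist)
  if (half > 2L) p[2:(half - 1L), ] <- 2 * p[2:(half - 1L), ]
  u <- sum(w^2)
  if (density) p / (fs * u) else p / u
}

# Derive a child RNG seed from a base seed and stream labels (stays < 2^31).
childSeed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  for (p in parts) h <- (h * 69069 + as.numeric(p) * 2654435761) %% 2147483629
  as.integer(h)
}

# Run fn() under a local, restored RNG state with the given seed.
withSeed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# Shoelace polygon area for an ordered (x, y) matrix.
polygonArea <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Pearson correlation that returns 0 for zero-variance inputs.
safeCor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}
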