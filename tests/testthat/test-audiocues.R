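test_that("MFCCs of digital silence are exactly zero beyond the DC term", {
  clip <- AudioClip(numeric(4 * 8000), 8000)
  m <- mfcc(clip)
  expect_length(m, 13)
  expect_identical(names(m), paste0("mfcc_", 1:13))
  expect_equal(unname(m), rep(0, 13), tolerance = 1e-10)
})

test_that("MFCC of a pure tone matches an independent filterbank+DCT oracle", {
  fs <- 8000
  t <- (0:(2 * fs - 1)) / fs
  clip <- AudioClip(0.5 * sin(2 * pi * 440 * t), fs)
  mine <- mfcc(clip)
  # independent oracle: frame, Hann periodogram, triangular mel filterbank,
  # log with floor, orthonormal DCT-II, mean over frames
  frameLen <- 200; hop <- 80; nfft <- 256; nMels <- 40
  starts <- seq(1, length(clip@samples) - frameLen + 1, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(frameLen - 1)) / frameLen)
  hz2mel <- function(f) 2595 * log10(1 + f / 700)
  mel2hz <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- mel2hz(seq(0, hz2mel(fs / 2), length.out = nMels + 2))
  freqs <- (0:(nfft / 2)) * fs / nfft
  fb <- t(sapply(seq_len(nMels), function(m)
    pmax(0, pmin((freqs - edges[m]) / (edges[m + 1] - edges[m]),
                 (edges[m + 2] - freqs) / (edges[m + 2] - edges[m + 1])))))
  dct <- sqrt(2 / nMels) *
    cos(outer(1:13, (1:nMels) - 0.5, function(k, n) pi * k * n / nMels))
  coefs <- sapply(starts, function(s) {
    fr <- clip@samples[s:(s + frameLen - 1)] * w
    sp <- abs(fft(c(fr, numeric(nfft - frameLen))))^2
    sp <- sp[1:(nfft / 2 + 1)]
    sp[2:(nfft / 2)] <- 2 * sp[2:(nfft / 2)]
    sp <- sp / sum(w^2)
    dct %*% log(pmax(fb %*% sp, 1e-10))
  })
  expect_equal(unname(mine), unname(rowMeans(coefs)), tolerance = 1e-6)
})

test_that("MFCC shape is invariant to gain away from the floor", {
  set.seed(2)
  fs <- 8000
  x <- rnorm(2 * fs) * 0.2 + sin(2 * pi * 300 * (0:(2 * fs - 1)) / fs)
  m1 <- mfcc(AudioClip(x * 0.05, fs))
  m2 <- mfcc(AudioClip(x * 0.5, fs))
  expect_gt(cor(m1, m2), 0.999)
})

test_that("loudness follows the gated block convention", {
  fs <- 8000
  t8 <- (0:(8 * fs - 1)) / fs
  sine <- AudioClip(0.3 * sin(2 * pi * 440 * t8), fs)
  l1 <- loudness(sine)
  expect_equal(l1[["loudness_range"]], 0, tolerance = 1e-6)
  l2 <- loudness(AudioClip(0.6 * sin(2 * pi * 440 * t8), fs))
  expect_equal(l2[["loudness"]] - l1[["loudness"]], 20 * log10(2),
               tolerance = 0.1)
  expect_equal(l2[["loudness_range"]], l1[["loudness_range"]],
               tolerance = 0.1)
  # all-silent clip: floor level, zero range
  l0 <- loudness(AudioClip(numeric(4 * fs), fs))
  expect_equal(unname(l0), c(-100, 0))
  # two-level amplitude profile matches a direct block-level computation
  amp <- rep(c(0.1, 0.5), each = 4 * fs)
  x <- amp * sin(2 * pi * 440 * (0:(8 * fs - 1)) / fs)
  lb <- affectlink:::loudnessBlocks(AudioClip(x, fs))
  direct <- affectlink:::loudnessFromBlocks(lb$level)
  expect_equal(loudness(AudioClip(x, fs)), direct)
  expect_gt(direct[["loudness_range"]], 10)
})

test_that("voice probability separates noise from voiced harmonics", {
  set.seed(5)
  fs <- 8000
  noise <- AudioClip(0.2 * rnorm(6 * fs), fs)
  expect_lte(voiceProbability(noise), 0.2)
  t <- (0:(6 * fs - 1)) / fs
  v <- 0
  for (h in 1:8) v <- v + sin(2 * pi * h * 120 * t) / h
  v <- v * (1 + 0.5 * sin(2 * pi * 4 * t))
  voiced <- AudioClip(0.2 * v / max(abs(v)), fs)
  expect_gte(voiceProbability(voiced), 0.8)
  for (clip in list(noise, voiced)) {
    p <- voiceProbability(clip)
    expect_true(p >= 0 && p <= 1)
  }
})

test_that("pitch features recognize key structure and harmonic change", {
  fs <- 8000
  t8 <- (0:(8 * fs - 1)) / fs
  triad <- function(freqs, t) {
    x <- 0
    for (f in freqs) x <- x + sin(2 * pi * f * t)
    x
  }
  cmaj <- AudioClip(0.2 * triad(c(261.63, 329.63, 392.0), t8), fs)
  pf <- pitchFeatures(cmaj)
  expect_gt(pf[["pitch_mode"]], 0)
  expect_lt(pf[["pitch_harmonic_flux"]], 0.05)
  set.seed(6)
  noise <- AudioClip(0.2 * rnorm(8 * fs), fs)
  expect_gte(pf[["pitch_keyclarity"]],
             pitchFeatures(noise)[["pitch_keyclarity"]])
  # alternating chords each second raise the flux above the stationary case
  x <- numeric(8 * fs)
  for (s in 0:7) {
    tt <- (0:(fs - 1)) / fs
    f <- if (s %% 2 == 0) c(261.63, 329.63, 392.0) else c(220, 261.63, 329.63)
    x[(s * fs + 1):((s + 1) * fs)] <- 0.2 * triad(f, tt)
  }
  expect_gt(pitchFeatures(AudioClip(x, fs))[["pitch_harmonic_flux"]],
            pf[["pitch_harmonic_flux"]])
  # silence sentinel
  ps <- pitchFeatures(AudioClip(numeric(2 * fs), fs))
  expect_equal(unname(ps), c(0, 0, 0))
})

test_that("the full audio cue vector is complete, deterministic and bounded", {
  z <- zLatent(0.2, -0.3)
  clip <- genAudio(z, seconds = 8, seed = 4, voicedFraction = 0.3)
  a1 <- extractAudioCues(clip)
  expect_length(a1, 19)
  expect_identical(names(a1), audioCueNames())
  expect_identical(a1, extractAudioCues(clip))
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(4 * 8000) * runif(1, 0.01, 0.5)
    a <- extractAudioCues(AudioClip(x, 8000))
    expect_true(all(is.finite(a)))
    expect_true(a[["voice_probability"]] >= 0 && a[["voice_probability"]] <= 1)
    expect_true(a[["pitch_keyclarity"]] >= 0 && a[["pitch_keyclarity"]] <= 1)
    expect_true(a[["pitch_mode"]] >= -1 && a[["pitch_mode"]] <= 1)
    expect_true(a[["pitch_harmonic_flux"]] >= 0)
    expect_true(a[["loudness_range"]] >= 0)
  }
})

test_that("windowed aggregation matches whole-clip extraction", {
  clip <- genAudio(zLatent(0.1, 0.4), seconds = 10, seed = 8)
  af <- affectlink:::audioFrameFeatures(clip)
  whole <- affectlink:::aggregateAudioCues(af, 0, 11)
  expect_equal(whole, extractAudioCues(clip))
})
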