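smallRecording <- function(seconds, fs = 64) {
  n <- round(seconds * fs)
  new("EEGRecording", data = matrix(sin(seq_len(n) / 5), 1), fs = fs,
      channelNames = "ch1", channelXY = matrix(0, 1, 2))
}

test_that("sliding-window epoching follows the count law", {
  expect_length(windowEpochs(smallRecording(35)), 21)
  expect_length(windowEpochs(smallRecording(15)), 1)
  expect_length(windowEpochs(smallRecording(117)), 103)
  expect_error(windowEpochs(smallRecording(10)), "shorter")
  w <- windowEpochs(smallRecording(20))
  expect_identical(ncol(eegData(w[[1]])), 15L * 64L)
  # hop alignment: second window starts one hop later
  r <- smallRecording(17)
  ws <- windowEpochs(r)
  expect_identical(eegData(ws[[2]])[1, 1], eegData(r)[1, 65])
})

test_that("subspace cleaning passes clean data and crushes bursts", {
  e <- genEEG(zLatent(), seconds = 15, seed = 9)
  ec <- cleanEEG(e)
  expect_identical(dim(eegData(ec)), dim(eegData(e)))
  cors <- vapply(1:32, function(ch)
    cor(eegData(e)[ch, ], eegData(ec)[ch, ]), numeric(1))
  expect_gt(min(cors), 0.99)
  eb <- genEEG(zLatent(), seconds = 15, seed = 9, artifacts = TRUE,
               burstAmp = 500)
  ebc <- cleanEEG(eb)
  expect_lte(max(abs(eegData(ebc))), 0.2 * max(abs(eegData(eb))))
})

test_that("flat channels are flagged and passed through", {
  e <- genEEG(zLatent(), seconds = 15, seed = 2)
  d <- eegData(e)
  d[5, ] <- 0
  eFlat <- EEGRecording(d, fs = 256)
  expect_message(ec <- cleanEEG(eFlat), "flat")
  expect_identical(eegData(ec)[5, ], d[5, ])
})

test_that("band PSD concentrates, scales quadratically and sums to variance", {
  fs <- 256
  n <- 15 * fs
  mon <- standardMontage()
  d <- matrix(0, 32, n)
  d[8, ] <- sin(2 * pi * 10 * (0:(n - 1)) / fs)   # C3, 10 Hz
  e <- EEGRecording(d + 1e-6, fs = 256)
  p <- bandPSD(e)
  expect_length(p, 96)
  expect_identical(names(p)[22:24], c("C3_theta", "C3_alpha", "C3_beta"))
  expect_gt(p[["C3_alpha"]], 100 * (p[["C3_theta"]] + p[["C3_beta"]]))
  # quadratic amplitude scaling
  e2 <- EEGRecording(2 * d + 2e-6, fs = 256)
  p2 <- bandPSD(e2)
  expect_equal(p2[["C3_alpha"]] / p[["C3_alpha"]], 4, tolerance = 0.01)
  # Parseval sanity on random signals
  set.seed(3)
  x <- matrix(rnorm(32 * n), 32)
  er <- EEGRecording(x, fs = 256)
  seg <- affectlink:::segmentBandPSD(er, bands = list(full = c(0, 128.01)))
  full <- colMeans(seg$values)
  segN <- 2 * fs
  df <- fs / segN
  nBins <- segN / 2 + 1
  tot <- vapply(1:32, function(ch)
    full[[paste0(standardMontage()$name[ch], "_full")]] * nBins * df,
    numeric(1))
  expect_equal(tot, apply(x, 1, var), tolerance = 0.05)
})

test_that("segment-PSD fast path equals per-window band PSD", {
  e <- genEEG(zLatent(0.2, 0.5), seconds = 20, seed = 2)
  sp <- affectlink:::segmentBandPSD(e)
  w3 <- windowEpochs(e)[[3]]
  sel <- sp$starts >= 2 - 1e-9 & sp$starts + sp$segS <= 17 + 1e-9
  expect_equal(colMeans(sp$values[sel, ]), bandPSD(w3), tolerance = 1e-12)
})

test_that("conditional entropy obeys its identities and calibration", {
  set.seed(4)
  x <- rnorm(2000)
  expect_equal(conditionalEntropy(x, x, 16), 0, tolerance = 1e-12)
  y <- rnorm(2000)
  expect_gte(conditionalEntropy(x, y, 8), 0)
  # conditioning never increases entropy
  hx <- -sum(prop.table(tabulate(affectlink:::binIndices(x, 8), 8)) *
               log2(prop.table(tabulate(affectlink:::binIndices(x, 8), 8))))
  expect_lte(conditionalEntropy(x, y, 8), hx + 1e-12)
  # independent uniforms at 16 bins approach log2(16) bits
  set.seed(5)
  u <- runif(1e5); v <- runif(1e5)
  expect_equal(conditionalEntropy(u, v, 16), 4, tolerance = 0.05)
  expect_error(conditionalEntropy(x, y[-1], 8), "equal length")
  expect_error(conditionalEntropy(x, y, 1), "bins")
})

test_that("conditional entropy matches the brute-force joint histogram", {
  set.seed(6)
  for (i in 1:10) {
    n <- sample(200:1000, 1)
    bins <- sample(2:4, 1)
    x <- rnorm(n); y <- x * runif(1) + rnorm(n)
    expect_equal(conditionalEntropy(x, y, bins), bruteCondEntropy(x, y, bins),
                 tolerance = 1e-12)
  }
})

test_that("the pairwise entropy vector has the frozen order and properties", {
  e <- genEEG(zLatent(), seconds = 15, seed = 7)
  ce <- conditionalEntropyMatrix(e)
  expect_length(ce, 496)
  expect_identical(names(ce)[1], "AF3|Fp1")
  expect_true(all(ce >= 0))
  # duplicated channel pair -> zero entry
  d <- eegData(e)
  d[2, ] <- d[1, ]
  ce2 <- conditionalEntropyMatrix(EEGRecording(d, fs = 256))
  expect_equal(ce2[["AF3|Fp1"]], 0)
  full <- extractEEGCues(e)
  expect_length(full, 96 + 496)
  expect_length(extractEEGCues(e, entropy = FALSE), 96)
})

test_that("high-arousal trials carry more central beta than low-arousal ones", {
  hi <- vapply(1:50, function(i)
    bandPSD(genEEG(zLatent(0, 1.5), seconds = 15,
                   seed = 100 + i))[["Cz_beta"]], numeric(1))
  lo <- vapply(1:50, function(i)
    bandPSD(genEEG(zLatent(0, -1.5), seconds = 15,
                   seed = 200 + i))[["Cz_beta"]], numeric(1))
  tt <- t.test(hi, lo, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})
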