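test_that("GLCM descriptors handle degenerate and hand-enumerable frames", {
  cf <- frameSeq(list(matrix(0.5, 8, 8)))
  w <- capture_warnings(g <- glcmFeatures(cf))   # one warning per offset
  expect_true(all(grepl("sentinel", w)) && length(w) >= 1)
  expect_equal(g[["contrast"]], 0)
  expect_equal(g[["energy"]], 1)
  expect_equal(g[["homogeneity"]], 1)
  expect_equal(g[["correlation"]], 0)
  # 4x4 two-level checkerboard, horizontal offset: all 12 pairs differ by 1
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  g2 <- glcmFeatures(frameSeq(list(cb)), levels = 2, offsets = list(c(0, 1)))
  expect_equal(g2[["contrast"]], 1)
  expect_equal(g2[["homogeneity"]], 0.5)
})

test_that("GLCM agrees with brute-force pair enumeration on small images", {
  set.seed(10)
  for (i in 1:12) {
    side <- sample(3:8, 1)
    levels <- sample(2:4, 1)
    g <- matrix(runif(side * side), side)
    offs <- list(c(0, 1), c(1, 0))
    mine <- glcmFeatures(frameSeq(list(g)), levels = levels, offsets = offs)
    ref <- bruteGLCM(g, levels, offs)
    expect_equal(unname(mine), unname(ref), tolerance = 1e-12)
  }
})

test_that("noise on a constant clip lowers homogeneity and raises contrast", {
  set.seed(4)
  flat <- matrix(0.5, 16, 16)
  noisy <- flat + matrix(rnorm(256, sd = 0.15), 16)
  gFlat <- suppressWarnings(glcmFeatures(frameSeq(list(flat))))
  gNoisy <- glcmFeatures(frameSeq(list(noisy)))
  expect_lt(gNoisy[["homogeneity"]], gFlat[["homogeneity"]])
  expect_gt(gNoisy[["contrast"]], gFlat[["contrast"]])
})

test_that("lighting key separates dark, bright and half-shadow frames", {
  lkB <- lightingKey(frameSeq(list(matrix(0, 8, 8))))
  expect_equal(unname(lkB), c(0, 1))
  lkW <- lightingKey(frameSeq(list(matrix(1, 8, 8))))
  expect_equal(unname(lkW), c(1, 0))
  half <- matrix(0, 8, 8); half[, 1:4] <- 1
  expect_equal(lightingKey(frameSeq(list(half)))[["shadow_proportion"]], 0.5)
})

test_that("color energy and saturation proportion follow their definitions", {
  expect_equal(colorEnergy(frameSeq(list(matrix(0.5, 8, 8)))), 0)
  # uniform saturated frame: zero contrast term
  sat <- array(0, c(8, 8, 3)); sat[, , 1] <- 1
  expect_equal(colorEnergy(FrameSequence(list(sat), 1)), 0)
  expect_equal(saturationProportion(frameSeq(list(matrix(0.3, 8, 8)))), 0)
  expect_equal(saturationProportion(FrameSequence(list(sat), 1)), 1)
  # quarter of pixels at saturation 0.5 (green vs gray), threshold 0.2
  f <- array(0.5, c(4, 4, 3))
  f[1, , 1] <- 0.25; f[1, , 3] <- 0.25   # top row: s = 0.5
  expect_equal(saturationProportion(FrameSequence(list(f), 1)), 0.25)
  # two-tone frame matches the direct mean x sd oracle
  two <- array(0.2, c(4, 4, 3)); two[1:2, , 1] <- 0.9
  px <- cbind(as.vector(two[, , 1]), as.vector(two[, , 2]),
              as.vector(two[, , 3]))
  hsv <- grDevices::rgb2hsv(t(px), maxColorValue = 1)
  vs <- hsv["v", ] * hsv["s", ]
  expect_equal(colorEnergy(FrameSequence(list(two), 1)), mean(vs) * sd(vs))
})

test_that("visual excitement counts perceptually changed pixels", {
  same <- frameSeq(list(matrix(0.5, 8, 8), matrix(0.5, 8, 8)))
  expect_equal(visualExcitement(same), 0)
  alt <- frameSeq(list(matrix(0, 8, 8), matrix(1, 8, 8), matrix(0, 8, 8)))
  expect_equal(visualExcitement(alt), 1)
  # exactly half the pixels flip far beyond threshold each step
  a <- matrix(0.1, 8, 8)
  b <- a; b[1:4, ] <- 0.9
  expect_equal(visualExcitement(frameSeq(list(a, b, a))), 0.5)
  expect_error(visualExcitement(frameSeq(list(a))), "two frames")
})

test_that("shot detection finds planted cuts and respects scene length", {
  st <- frameSeq(rep(list(matrix(0.5, 8, 8)), 10), fps = 2)
  s1 <- detectShots(st)
  expect_equal(unname(s1), c(1, 5))
  sw <- frameSeq(c(rep(list(matrix(0.2, 8, 8)), 5),
                   rep(list(matrix(0.9, 8, 8)), 5)), fps = 2)
  expect_equal(detectShots(sw)[["n_shots"]], 2)
  # 30 s clip with two planted cuts -> 3 shots, 10 s average
  mats <- c(rep(list(matrix(0.2, 8, 8)), 20), rep(list(matrix(0.6, 8, 8)), 20),
            rep(list(matrix(0.95, 8, 8)), 20))
  s3 <- detectShots(frameSeq(mats, fps = 2))
  expect_equal(unname(s3), c(3, 10))
})

test_that("the full visual cue vector is complete, deterministic and bounded", {
  z <- zLatent(0.3, 0.5)
  fr <- genFrames(z, seconds = 15, seed = 6, cutTimes = c(7.2))
  v1 <- extractVisualCues(fr)
  expect_identical(names(v1), visualCueNames())
  expect_length(v1, 11)
  expect_identical(v1, extractVisualCues(fr))
  # static gray clip sentinel values
  stat <- frameSeq(rep(list(matrix(0.5, 8, 8)), 6), fps = 2)
  vs <- suppressWarnings(extractVisualCues(stat))
  expect_equal(vs[["visual_excitement"]], 0)
  expect_equal(vs[["n_shots"]], 1)
  expect_equal(vs[["saturation_proportion"]], 0)
})

test_that("bounded cues respect their ranges on random clips", {
  set.seed(11)
  for (i in 1:100) {
    mats <- replicate(2, matrix(runif(36), 6), simplify = FALSE)
    fr <- FrameSequence(lapply(mats, function(m) {
      a <- array(runif(108), c(6, 6, 3)); a
    }), fps = 2)
    v <- suppressWarnings(extractVisualCues(fr))
    expect_true(all(is.finite(v)))
    expect_true(v[["visual_excitement"]] >= 0 && v[["visual_excitement"]] <= 1)
    expect_true(v[["lighting_key_median"]] >= 0 && v[["lighting_key_median"]] <= 1)
    expect_true(v[["shadow_proportion"]] >= 0 && v[["shadow_proportion"]] <= 1)
    expect_true(v[["saturation_proportion"]] >= 0 && v[["saturation_proportion"]] <= 1)
    expect_true(v[["glcm_correlation"]] >= -1 && v[["glcm_correlation"]] <= 1)
    expect_true(v[["glcm_energy"]] > 0 && v[["glcm_energy"]] <= 1)
    expect_true(v[["glcm_homogeneity"]] > 0 && v[["glcm_homogeneity"]] <= 1)
    expect_true(v[["glcm_contrast"]] >= 0)
    expect_true(v[["color_energy"]] >= 0)
  }
})

test_that("window aggregation path equals direct extraction", {
  z <- zLatent(-0.4, 0.8)
  fr <- genFrames(z, seconds = 16, seed = 9, cutTimes = c(6))
  direct <- extractVisualCues(fr)
  ff <- affectlink:::visualFrameFeatures(fr)
  agg <- affectlink:::aggregateVisualCues(ff, seq_along(fr@frames))
  expect_equal(agg, direct, tolerance = 1e-12)
})
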