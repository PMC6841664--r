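test_that("wavelet fusion reconstructs, idempotes and takes max-abs details", {
  set.seed(1)
  img <- matrix(runif(64 * 64), 64)
  expect_lt(max(abs(fuseFrames(list(img)) - img)), 1e-10)
  expect_lt(max(abs(fuseFrames(list(img, img, img)) - img)), 1e-10)
  # coefficient-level rule: fused detail equals the max-|.| input detail
  img2 <- matrix(runif(64 * 64), 64)
  img2[20:28, 30:40] <- 1   # high-contrast patch
  d1 <- affectlink:::haarDecompose(img, 4)
  d2 <- affectlink:::haarDecompose(img2, 4)
  fused <- affectlink:::haarDecompose(fuseFrames(list(img, img2)), 4)
  for (l in 1:4) {
    for (band in c("LH", "HL", "HH")) {
      a <- d1$details[[l]][[band]]; b <- d2$details[[l]][[band]]
      expected <- ifelse(abs(a) >= abs(b), a, b)
      expect_equal(fused$details[[l]][[band]], expected, tolerance = 1e-10)
    }
  }
  expect_error(fuseFrames(list(img, matrix(0, 8, 8))), "dimensions")
  expect_error(fuseFrames(list()), "at least one")
})

test_that("the 30 facial features match hand computation on the template", {
  pts <- faceTemplate()           # eyeOpen 1 -> lids at 40 / 44
  lm <- LandmarkSet(pts, c(0, 0, 100, 100))
  fc <- computeFaceCues(lm)
  expect_length(fc, 30)
  expect_identical(names(fc), faceCueNames())
  shoelace <- function(m) {
    x <- m[, 1]; y <- m[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  # every feature the analysis names, computed independently by hand
  expect_equal(fc[["eye_height_left"]], 4 / 100)          # |40 - 44|
  expect_equal(fc[["eye_height_right"]], 4 / 100)
  expect_equal(fc[["eye_width_left"]], (38 - 22) / 100)
  expect_equal(fc[["eye_width_right"]], (78 - 62) / 100)
  expect_equal(fc[["brow_eye_left"]], (40 - mean(c(30, 28, 27, 28, 30))) / 100)
  expect_equal(fc[["brow_lip_left"]], (72 - mean(c(30, 28, 27, 28, 30))) / 100)
  expect_equal(fc[["lip_width"]], (65 - 35) / 100)
  expect_equal(fc[["lip_height"]], (76.5 - 68.5) / 100)
  expect_equal(fc[["inner_lip_width"]], (60 - 40) / 100)
  expect_equal(fc[["nose_width"]], (58 - 42) / 100)
  expect_equal(fc[["nose_height"]], (65 - 40) / 100)
  expect_equal(fc[["nose_area"]],
               shoelace(pts[c(11, 15, 17, 19), ]) / 1e4)
  expect_equal(fc[["mouth_area_inner"]], shoelace(pts[44:49, ]) / 1e4)
  expect_equal(fc[["mouth_area_outer"]], shoelace(pts[32:43, ]) / 1e4)
  expect_equal(fc[["eye_area_left"]], shoelace(pts[20:25, ]) / 1e4)
  expect_equal(fc[["interocular"]],
               abs(mean(pts[20:25, 1]) - mean(pts[26:31, 1])) / 100)
  expect_equal(fc[["brow_arch_left"]], (30 - 27) / 100)
  expect_equal(fc[["inner_brow_gap"]], (58 - 42) / 100)
  expect_equal(fc[["nose_lip_gap"]], (68.5 - 65) / 100)
})

test_that("facial features are exactly scale and translation invariant", {
  pts <- faceTemplate(eyeOpen = 1.3, noseScale = 0.9, lipRaise = 1)
  base <- computeFaceCues(LandmarkSet(pts, c(0, 0, 100, 100)))
  scaled <- computeFaceCues(LandmarkSet(pts * 2, c(0, 0, 200, 200)))
  expect_identical(base, scaled)
  shifted <- computeFaceCues(LandmarkSet(pts + 37, c(37, 37, 100, 100)))
  expect_equal(base, shifted, tolerance = 1e-12)
  # unit-box landmarks are representable (detection minimum not a class rule)
  unitFc <- computeFaceCues(LandmarkSet(pts / 100, c(0, 0, 1, 1)))
  expect_equal(base, unitFc, tolerance = 1e-12)
  expect_error(computeFaceCues(LandmarkSet(pts, c(0, 0, 0, 100))))
})

test_that("face detection applies size and margin rejection", {
  lms <- genLandmarks(zLatent(), nFrames = 1, seed = 1)
  img <- rasterizeFace(lms$points[, , 1], side = 128, margin = 12)
  box <- detectFace(img)
  expect_false(is.null(box))
  expect_gte(box[["W"]], 50)
  # 40x40 dark candidate rejected by the minimum-size rule
  small <- matrix(0.95, 128, 128)
  small[40:79, 40:79] <- 0.2
  expect_null(detectFace(small))
  expect_null(detectFace(matrix(0.95, 128, 128)))   # blank image
  # margin-touching candidate rejected
  touch <- matrix(0.95, 128, 128)
  touch[1:70, 1:70] <- 0.2
  expect_null(detectFace(touch))
})

test_that("eye-opening parameter drives the eye-height features", {
  open <- numeric(100); height <- numeric(100)
  for (i in 1:100) {
    z <- zLatent(0, rnorm(1))
    lms <- genLandmarks(z, nFrames = 3, seed = 300 + i)
    open[i] <- lms$eyeOpen
    height[i] <- extractFaceCues(lms$points, lms$faceBox)[["eye_height_left"]]
  }
  expect_gt(cor(open, height), 0.9)
})

test_that("both window-level feature paths work", {
  lms <- genLandmarks(zLatent(0.5, -0.5), nFrames = 6, seed = 2)
  mean_fc <- extractFaceCues(lms$points, lms$faceBox)
  expect_length(mean_fc, 30)
  imgs <- lapply(1:6, function(i) rasterizeFace(lms$points[, , i], side = 64))
  fused_fc <- extractFaceCues(lms$points, lms$faceBox, method = "fused",
                              images = imgs)
  expect_length(fused_fc, 30)
  expect_error(extractFaceCues(lms$points, lms$faceBox, method = "fused"),
               "images")
})
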