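test_that("standardization centers, scales, drops constants, idempotes", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 0, 2))
  s <- standardizeCues(m)
  # sample-sd convention: sd(1,2,3) = 1
  expect_equal(unname(s[, "a"]), c(-1, 0, 1), tolerance = 1e-9)
  expect_equal(unname(colMeans(s)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(s, 2, sd)), c(1, 1), tolerance = 1e-12)
  m2 <- cbind(a = c(1, 2, 3), k = c(7, 7, 7))
  expect_warning(s2 <- standardizeCues(m2), "k")
  expect_identical(colnames(s2), "a")
  expect_equal(standardizeCues(s), s[, , drop = FALSE], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(standardizeCues(m[1, , drop = FALSE]), "2 rows")
})

test_that("identical sets give unit canonical correlations", {
  set.seed(1)
  x <- matrix(rnorm(200 * 4), 200)
  colnames(x) <- paste0("f", 1:4)
  r <- ccaFit(x, x, ridge = 0)
  expect_equal(canonicalCors(r), rep(1, 4), tolerance = 1e-8)
})

test_that("rank deficiency at zero ridge raises an instructive error", {
  set.seed(2)
  x <- matrix(rnorm(50 * 3), 50)
  x <- cbind(x, x[, 1] + x[, 2])   # exactly collinear
  y <- matrix(rnorm(50 * 2), 50)
  expect_error(ccaFit(x, y, ridge = 0), "ridge")
  expect_error(ccaFit(x, y, ridge = -1), ">= 0")
  expect_silent(r <- ccaFit(x, y, ridge = 1e-3))
  expect_error(ccaFit(x[1:40, ], y), "equal row")
  expect_error(ccaFit(x, y, nComponents = 5), "exceeds")
})

test_that("canonical correlations match the generalized-eigenvalue oracle", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(100:500, 1)
    p <- sample(2:6, 1); q <- sample(2:6, 1)
    x <- matrix(rnorm(n * p), n)
    y <- matrix(rnorm(n * q), n)
    y[, 1] <- y[, 1] + runif(1, 0.2, 1) * x[, 1]
    fit <- ccaFit(x, y, ridge = 0)
    expect_equal(canonicalCors(fit), bruteCCA(x, y), tolerance = 1e-8)
    # and an algorithmically different reference: QR-based cancor
    cc <- stats::cancor(scale(x, scale = FALSE), scale(y, scale = FALSE))
    expect_equal(canonicalCors(fit), cc$cor, tolerance = 1e-8)
  }
})

test_that("canonical correlations are invariant to affine recoding", {
  set.seed(4)
  n <- 300
  x <- matrix(rnorm(n * 4), n)
  y <- matrix(rnorm(n * 3), n)
  y[, 2] <- y[, 2] + 0.7 * x[, 3]
  A <- matrix(rnorm(16), 4); while (abs(det(A)) < 0.1) A <- matrix(rnorm(16), 4)
  B <- matrix(rnorm(9), 3); while (abs(det(B)) < 0.1) B <- matrix(rnorm(9), 3)
  f1 <- ccaFit(x, y, ridge = 0)
  f2 <- ccaFit(sweep(x %*% A, 2, c(1, -2, 3, 0.5), `+`),
               sweep(y %*% B, 2, c(2, 0, -1), `+`), ridge = 0)
  expect_equal(canonicalCors(f1), canonicalCors(f2), tolerance = 1e-8)
})

test_that("successive canonical variates are uncorrelated", {
  set.seed(5)
  n <- 400
  x <- matrix(rnorm(n * 5), n)
  y <- matrix(rnorm(n * 5), n)
  f <- ccaFit(x, y, ridge = 0)
  sx <- scale(x, scale = FALSE) %*% ccaWeights(f, "x")
  sy <- scale(y, scale = FALSE) %*% ccaWeights(f, "y")
  cx <- cor(sx); cy <- cor(sy)
  expect_lt(max(abs(cx[upper.tri(cx)])), 1e-6)
  expect_lt(max(abs(cy[upper.tri(cy)])), 1e-6)
})

test_that("a planted shared factor is recovered with its loading on top", {
  set.seed(6)
  n <- 2000
  z <- rnorm(n)
  x <- cbind(p1 = z + 0.5 * rnorm(n), matrix(rnorm(n * 3), n))
  y <- cbind(q1 = z + 0.5 * rnorm(n), matrix(rnorm(n * 3), n))
  colnames(x)[2:4] <- paste0("x", 2:4); colnames(y)[2:4] <- paste0("y", 2:4)
  f <- ccaFit(x, y, ridge = 0)
  expect_gt(canonicalCors(f)[1], 0.75)
  expect_lt(canonicalCors(f)[1], 0.85)
  tl <- topLoadings(f, "x", k = 2)
  expect_identical(tl$table$feature[1], "p1")
  expect_true(tl$weightShare >= 0 && tl$weightShare <= 1)
  # k = feature count returns a permutation of all names
  all4 <- topLoadings(f, "x", k = 4)
  expect_setequal(all4$table$feature, colnames(x))
  expect_error(topLoadings(f, "x", k = 10), "feature count")
})

test_that("independent sets give near-zero first correlation", {
  set.seed(7)
  x <- matrix(rnorm(5000 * 3), 5000)
  y <- matrix(rnorm(5000 * 3), 5000)
  expect_lt(canonicalCors(ccaFit(x, y, ridge = 0))[1], 0.1)
})

test_that("projections correlate with labels as constructed", {
  set.seed(8)
  n <- 1000
  z <- rnorm(n)
  x <- cbind(a = z + 0.1 * rnorm(n), b = rnorm(n))
  y <- cbind(c = z + 0.1 * rnorm(n), d = rnorm(n))
  f <- ccaFit(x, y, ridge = 0)
  v <- scale(x, scale = FALSE) %*% ccaWeights(f, "x")[, 1]
  labAff <- data.frame(valence = as.vector(3 * v + 2), arousal = rnorm(n))
  pc <- projectAndCorrelate(f, x, y, labAff)
  expect_equal(abs(pc$r[pc$side == "x" & pc$label == "valence"]), 1,
               tolerance = 1e-9)
  expect_lt(abs(pc$r[pc$side == "x" & pc$label == "arousal"]), 0.1)
  expect_identical(pc$top_cue[pc$side == "x" & pc$label == "valence"], "a")
  expect_error(projectAndCorrelate(f, x, y, labAff[1:10, ]), "align")
})

test_that("emotion regression returns class-mean deviations", {
  emotions <- rep(c("joy", "fear", "calm"), each = 40)
  scores <- ifelse(emotions == "joy", 1, -1)
  r <- regressEmotions(scores, emotions)
  expect_identical(r$class, "joy")
  grand <- mean(scores)
  expect_equal(r$maxCoef, 1 - grand)
  # frequency-weighted coefficients sum to zero
  counts <- table(emotions)[names(r$coefficients)]
  expect_equal(sum(r$coefficients * as.numeric(counts)), 0, tolerance = 1e-12)
  # classes below 2 trials are excluded with a message
  expect_message(r2 <- regressEmotions(c(scores, 5), c(emotions, "anger")),
                 "anger")
  expect_false("anger" %in% names(r2$coefficients))
  # max coefficient shrinks with n under the null
  set.seed(9)
  nulls <- vapply(c(200, 2000), function(n) {
    em <- sample(emotionTagTable()$tag, n, replace = TRUE)
    mean(replicate(20, abs(regressEmotions(rnorm(n), em)$maxCoef)))
  }, numeric(1))
  expect_lt(nulls[2], nulls[1])
})

test_that("paired band t-test matches the textbook formula", {
  a <- c(2.1, 3.4, 2.8, 3.9, 3.1)
  b <- c(1.5, 2.9, 2.8, 3.0, 2.2)
  res <- pairedBandTTest(cbind(A = a, B = b), "A", "B")
  d <- a - b
  tHand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$t, tHand, tolerance = 1e-9)
  expect_equal(res$p, 2 * pt(-abs(tHand), 4), tolerance = 1e-9)
  same <- pairedBandTTest(cbind(A = a, B = a), "A", "B")
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  # consistent positive differences with tiny jitter -> significant
  set.seed(10)
  aa <- b + 1 + rnorm(5, sd = 1e-3)
  expect_lt(pairedBandTTest(cbind(A = aa, B = b), "A", "B")$p, 0.01)
  expect_error(pairedBandTTest(cbind(A = a[1:2], B = b[1:2]), "A", "B"),
               "3 paired")
})

test_that("block permutation respects clip structure", {
  set.seed(11)
  clip <- rep(1:20, each = 10)
  z <- rnorm(20)[clip]
  lab <- z + rnorm(20, sd = 0.3)[clip]
  sig <- blockPermutePValue(z, lab, clip, nPerm = 99, seed = 1)
  expect_lt(sig$p, 0.05)
  nullLab <- rnorm(20)[clip]
  nul <- blockPermutePValue(z, nullLab, clip, nPerm = 99, seed = 1)
  expect_gt(nul$p, 0.05)
})
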