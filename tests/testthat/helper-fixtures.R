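# Shared fixtures and independent oracles used across the test files.

# Grayscale matrix -> RGB frame array.
grayFrame <- function(m) {
  a <- array(0, c(nrow(m), ncol(m), 3))
  a[, , 1] <- m; a[, , 2] <- m; a[, , 3] <- m
  a
}

frameSeq <- function(mats, fps = 2) FrameSequence(lapply(mats, grayFrame), fps)

# Brute-force GLCM descriptors by explicit pair enumeration (symmetric,
# normalized), independent of the package implementation.
bruteGLCM <- function(g, levels, offsets) {
  q <- pmin(floor(pmin(pmax(g, 0), 1) * levels), levels - 1L)
  perOffset <- sapply(offsets, function(off) {
    dr <- off[1]; dc <- off[2]
    counts <- matrix(0, levels, levels)
    for (i in seq_len(nrow(q) - dr)) {
      for (j in seq_len(ncol(q) - dc)) {
        a <- q[i, j] + 1L; b <- q[i + dr, j + dc] + 1L
        counts[a, b] <- counts[a, b] + 1
        counts[b, a] <- counts[b, a] + 1
      }
    }
    p <- counts / sum(counts)
    lv <- 0:(levels - 1)
    pi_ <- rowSums(p); pj <- colSums(p)
    mui <- sum(lv * pi_); muj <- sum(lv * pj)
    vi <- sum((lv - mui)^2 * pi_); vj <- sum((lv - muj)^2 * pj)
    corr <- 0
    if (vi > 0 && vj > 0) {
      s <- 0
      for (a in seq_len(levels)) for (b in seq_len(levels))
        s <- s + p[a, b] * (lv[a] - mui) * (lv[b] - muj)
      corr <- s / sqrt(vi * vj)
    }
    contrast <- 0; energy <- 0; homog <- 0
    for (a in seq_len(levels)) for (b in seq_len(levels)) {
      contrast <- contrast + p[a, b] * (lv[a] - lv[b])^2
      energy <- energy + p[a, b]^2
      homog <- homog + p[a, b] / (1 + abs(lv[a] - lv[b]))
    }
    c(contrast, corr, energy, homog)
  })
  out <- rowMeans(perOffset)
  names(out) <- c("contrast", "correlation", "energy", "homogeneity")
  out
}

# Brute-force conditional entropy H(X|Y) from an explicit joint table.
bruteCondEntropy <- function(x, y, bins) {
  binify <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) return(rep(1L, length(v)))
    pmin(floor((v - r[1]) / (r[2] - r[1]) * bins) + 1L, bins)
  }
  ix <- binify(x); iy <- binify(y)
  joint <- matrix(0, bins, bins)
  for (k in seq_along(ix)) joint[ix[k], iy[k]] <- joint[ix[k], iy[k]] + 1
  pj <- joint / sum(joint)
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  H(as.vector(pj)) - H(colSums(pj))
}

# Brute-force canonical correlations via the full generalized eigenproblem
# of the block covariance system.
bruteCCA <- function(x, y) {
  p <- ncol(x); q <- ncol(y)
  cxx <- stats::cov(x); cyy <- stats::cov(y); cxy <- stats::cov(x, y)
  A <- rbind(cbind(matrix(0, p, p), cxy), cbind(t(cxy), matrix(0, q, q)))
  B <- rbind(cbind(cxx, matrix(0, p, q)), cbind(matrix(0, q, p), cyy))
  ev <- Re(eigen(solve(B, A), only.values = TRUE)$values)
  sort(ev[ev > 1e-10], decreasing = TRUE)[seq_len(min(p, q))]
}

zLatent <- function(zv = 0, za = 0) c(z_valence = zv, z_arousal = za)
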