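# EEG-to-topographic-image conversion, a width-reduced VGG-style network
# with probe points, and layer x layer representational similarity.

#' Interpolate scattered channel values onto a topographic grid
#'
#' Inverse-distance-squared weighting over the electrodes, evaluated on a
#' square grid covering the unit head disk: exact at electrode pixels,
#' constant-preserving, zero outside the scalp disk.
#'
#' @param values channels x bands matrix of non-negative powers.
#' @param coords channels x 2 electrode coordinates in the unit disk.
#' @param side grid side in pixels (default 32).
#' @return list with \code{img} (side x side x bands array scaled jointly
#'   to [0, 1]) and \code{mapping} (data.frame channel, px, py).
#' @export
topoMap <- function(values, coords, side = 32) {
  if (nrow(coords) < 4) stop("at least 4 electrodes required")
  values <- as.matrix(values)
  gx <- seq(-1, 1, length.out = side)
  gy <- seq(1, -1, length.out = side)   # row 1 = front of the head
  px <- matrix(rep(gx, each = side), side)
  py <- matrix(rep(gy, times = side), side)
  inside <- px^2 + py^2 <= 1
  d2 <- outer(as.vector(px), coords[, 1], `-`)^2 +
    outer(as.vector(py), coords[, 2], `-`)^2
  w <- 1 / pmax(d2, 1e-12)
  # exact hits: give the nearest electrode full weight
  hit <- d2 < 1e-9
  w[rowSums(hit) > 0, ] <- hit[rowSums(hit) > 0, , drop = FALSE]
  interp <- (w %*% values) / rowSums(w)
  rng <- range(interp)
  scaled <- if (rng[2] - rng[1] > 1e-9 * max(abs(rng), 1))
    (interp - rng[1]) / (rng[2] - rng[1])
    else matrix(0.5, nrow(interp), ncol(interp))
  img <- array(0, c(side, side, ncol(values)))
  for (b in seq_len(ncol(values))) {
    m <- matrix(scaled[, b], side)
    m[!inside] <- 0
    img[, , b] <- m
  }
  # nearest grid pixel inside the scalp disk for each electrode
  insideIdx <- which(inside)
  mapping <- data.frame(channel = seq_len(nrow(coords)),
                        px = integer(nrow(coords)), py = integer(nrow(coords)))
  for (ch in seq_len(nrow(coords))) {
    dd <- (px[insideIdx] - coords[ch, 1])^2 + (py[insideIdx] - coords[ch, 2])^2
    best <- insideIdx[which.min(dd)]
    mapping$py[ch] <- (best - 1L) %% side + 1L        # row
    mapping$px[ch] <- (best - 1L) %/% side + 1L       # column
  }
  list(img = img, mapping = mapping)
}

#' Convert an EEG window to an RGB topographic image
#'
#' Band power spectral density per channel is interpolated onto the scalp
#' grid, one band per color plane: R = theta, G = alpha, B = beta, scaled
#' jointly to [0, 1], zero outside the scalp disk.
#'
#' @param window an \code{\link{EEGRecording}}.
#' @param side image side in pixels (default 32).
#' @return list with \code{img} (side x side x 3) and \code{mapping}.
#' @export
eegToTopoImage <- function(window, side = 32) {
  psd <- bandPSD(window)
  powers <- matrix(psd, ncol = 3, byrow = TRUE)   # channel-major ordering
  topoMap(powers, window@channelXY, side = side)
}

#' Default scaled-down VGG-style architecture
#'
#' Five 3x3 convolution blocks with repeats 2, 2, 3, 3, 3 (13 conv layers)
#' and two dense layers: 15 probe points, matching the probed layers of
#' the full-size 16-layer architecture with the classification layer
#' discarded. Widths are reduced for desk-scale use.
#'
#' @param inputSide input image side (default 32).
#' @param filters per-block filter counts.
#' @param repeats per-block conv repeats.
#' @param dense dense layer widths.
#' @return list describing the architecture.
#' @export
defaultArch <- function(inputSide = 32, filters = c(8, 16, 32, 32, 32),
                        repeats = c(2, 2, 3, 3, 3), dense = c(64, 64))
  list(inputSide = inputSide, inputChannels = 3, filters = filters,
       repeats = repeats, dense = dense)

#' Build a seeded VGG-style network
#'
#' Creates the layer stack (3x3 same-padding convolutions with ReLU,
#' 2x2 max pooling between blocks, then dense layers) with He-initialized
#' Gaussian weights; deterministic under the seed.
#'
#' @param arch architecture from \code{\link{defaultArch}}.
#' @param seed integer seed for the initialization.
#' @return list of class \code{"convNet"} with the weights and probe-layer
#'   names.
#' @export
buildNetwork <- function(arch = defaultArch(), seed = 1) {
  nBlocks <- length(arch$filters)
  if (arch$inputSide < 2^nBlocks)
    stop("input side collapses before the last block; use a larger input ",
         "or fewer blocks")
  withSeed(seed, function() {
    layers <- list()
    inC <- arch$inputChannels
    side <- arch$inputSide
    for (b in seq_len(nBlocks)) {
      for (r in seq_len(arch$repeats[b])) {
        fanIn <- 9 * inC
        w <- matrix(stats::rnorm(fanIn * arch$filters[b],
                                 sd = sqrt(2 / fanIn)), fanIn)
        layers[[length(layers) + 1L]] <-
          list(type = "conv", w = w, inC = inC, outC = arch$filters[b],
               name = sprintf("conv%d_%d", b, r), side = side)
        inC <- arch$filters[b]
      }
      layers[[length(layers) + 1L]] <- list(type = "pool",
                                            name = sprintf("pool%d", b))
      side <- side %/% 2L
    }
    nIn <- side * side * inC
    for (d in seq_along(arch$dense)) {
      w <- matrix(stats::rnorm(arch$dense[d] * nIn, sd = sqrt(2 / nIn)),
                  arch$dense[d])
      layers[[length(layers) + 1L]] <-
        list(type = "dense", w = w, name = sprintf("fc%d", d))
      nIn <- arch$dense[d]
    }
    probes <- vapply(Filter(function(l) l$type != "pool", layers),
                     `[[`, character(1), "name")
    structure(list(layers = layers, arch = arch, probes = probes),
              class = "convNet")
  })
}

# 3x3 same-padding convolution of an h x w x c array via shifted slices.
conv3x3 <- function(x, w, outC) {
  h <- dim(x)[1]; wd <- dim(x)[2]; c <- dim(x)[3]
  pad <- array(0, c(h + 2, wd + 2, c))
  pad[2:(h + 1), 2:(wd + 1), ] <- x
  cols <- matrix(0, h * wd, 9 * c)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    sl <- pad[(1 + di):(h + di), (1 + dj):(wd + dj), , drop = FALSE]
    cols[, (k * c + 1):((k + 1) * c)] <- matrix(sl, h * wd)
    k <- k + 1L
  }
  out <- cols %*% w
  array(pmax(out, 0), c(h, wd, outC))
}

maxPool2 <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]
  a <- x[seq(1, h, 2), seq(1, w, 2), , drop = FALSE]
  b <- x[seq(2, h, 2), seq(1, w, 2), , drop = FALSE]
  c2 <- x[seq(1, h, 2), seq(2, w, 2), , drop = FALSE]
  d <- x[seq(2, h, 2), seq(2, w, 2), , drop = FALSE]
  pmax(a, b, c2, d)
}

#' Forward pass with probe-layer activations
#'
#' Runs each input image through the network and records the flattened
#' activation at every probe point (each conv layer and each dense layer).
#' Probe outputs longer than \code{maxFeatures} values are subsampled with
#' a seeded mask shared across inputs.
#'
#' @param net a network from \code{\link{buildNetwork}}.
#' @param images list of side x side x 3 arrays.
#' @param maxFeatures per-layer activation cap (default 4096).
#' @param maskSeed seed of the subsampling masks.
#' @return named list of inputs x features activation matrices, one per
#'   probe layer.
#' @export
forwardActivations <- function(net, images, maxFeatures = 4096,
                               maskSeed = 1) {
  acts <- vector("list", length(net$probes))
  names(acts) <- net$probes
  for (i in seq_along(images)) {
    x <- images[[i]]
    for (l in net$layers) {
      if (l$type == "conv") {
        x <- conv3x3(x, l$w, l$outC)
        acts[[l$name]][[i]] <- as.vector(x)
      } else if (l$type == "pool") {
        x <- maxPool2(x)
      } else {
        x <- pmax(as.vector(l$w %*% as.vector(x)), 0)
        acts[[l$name]][[i]] <- x
      }
    }
  }
  out <- vector("list", length(acts))
  names(out) <- names(acts)
  for (nm in names(acts)) {
    m <- do.call(rbind, acts[[nm]])
    if (ncol(m) > maxFeatures) {
      keep <- withSeed(childSeed(maskSeed, match(nm, names(acts))),
                       function() sample.int(ncol(m), maxFeatures))
      m <- m[, sort(keep), drop = FALSE]
    }
    out[[nm]] <- m
  }
  out
}

#' Representational dissimilarity matrix of one layer
#'
#' Entry (i, j) is one minus the Pearson correlation between the flattened
#' activation vectors of inputs i and j; symmetric with an exactly zero
#' diagonal. Pairs involving a zero-variance activation vector get the
#' documented sentinel dissimilarity 1.
#'
#' @param activations inputs x features matrix (>= 3 inputs).
#' @return inputs x inputs dissimilarity matrix.
#' @export
layerRDM <- function(activations) {
  n <- nrow(activations)
  if (n < 3) stop("at least 3 inputs required")
  sds <- apply(activations, 1, stats::sd)
  cm <- suppressWarnings(stats::cor(t(activations)))
  cm[sds == 0, ] <- 0
  cm[, sds == 0] <- 0
  d <- 1 - cm
  diag(d) <- 0
  d
}

#' Layer x layer representational similarity matrix
#'
#' For two activation lists from the same input trials, entry (i, j) is
#' the Spearman rank correlation between the upper triangles of the
#' layer-i RDM of network A and the layer-j RDM of network B.
#'
#' @param actsA,actsB activation lists from
#'   \code{\link{forwardActivations}} on the same inputs.
#' @return layers x layers matrix with entries in [-1, 1].
#' @export
similarityMatrix <- function(actsA, actsB) {
  nA <- nrow(actsA[[1]])
  if (any(vapply(actsB, nrow, integer(1)) != nA))
    stop("both networks must see the same input trials")
  ut <- function(m) m[upper.tri(m)]
  rdmA <- lapply(actsA, function(a) ut(layerRDM(a)))
  rdmB <- lapply(actsB, function(a) ut(layerRDM(a)))
  out <- matrix(0, length(rdmA), length(rdmB),
                dimnames = list(names(actsA), names(actsB)))
  for (i in seq_along(rdmA)) for (j in seq_along(rdmB))
    out[i, j] <- stats::cor(rdmA[[i]], rdmB[[j]], method = "spearman")
  out
}

#' Generate paired EEG-topo and face image inputs
#'
#' For representational-similarity runs: \code{n} trials with latent
#' affect vectors; each yields an EEG topographic image (from a synthetic
#' EEG window) and a rasterized face image (from synthetic landmarks).
#' With \code{coupled = FALSE} the face images come from independent
#' latents, breaking the cross-modal linkage.
#'
#' @param n number of input trials.
#' @param seed integer seed.
#' @param side image side (default 32).
#' @param coupled share the latent between modalities (default TRUE).
#' @param eegSeconds EEG window length per trial (default 15).
#' @return list with \code{eegImages}, \code{faceImages} (lists of
#'   side x side x 3 arrays) and \code{latents}.
#' @export
rsaInputs <- function(n, seed = 1, side = 32, coupled = TRUE,
                      eegSeconds = 15) {
  zs <- withSeed(childSeed(seed, 71), function()
    matrix(stats::rnorm(2 * n), n, 2,
           dimnames = list(NULL, c("z_valence", "z_arousal"))))
  zFace <- if (coupled) zs else withSeed(childSeed(seed, 72), function()
    matrix(stats::rnorm(2 * n), n, 2,
           dimnames = list(NULL, c("z_valence", "z_arousal"))))
  eegImages <- vector("list", n); faceImages <- vector("list", n)
  for (i in seq_len(n)) {
    z <- stats::setNames(as.numeric(zs[i, ]), c("z_valence", "z_arousal"))
    eeg <- genEEG(z, seconds = eegSeconds, seed = childSeed(seed, 73, i))
    eegImages[[i]] <- eegToTopoImage(eeg, side = side)$img
    zf <- stats::setNames(as.numeric(zFace[i, ]), c("z_valence", "z_arousal"))
    lms <- genLandmarks(zf, nFrames = 1, seed = childSeed(seed, 74, i))
    face <- rasterizeFace(lms$points[, , 1], side = side,
                          margin = max(2, round(side / 16)))
    faceImages[[i]] <- array(rep(face, 3), c(side, side, 3))
  }
  list(eegImages = eegImages, faceImages = faceImages, latents = zs)
}
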