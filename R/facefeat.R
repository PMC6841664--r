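# Face-frame fusion by multilevel 2-D wavelet decomposition, the canonical
# 30 normalized landmark-geometry features, and a pluggable face detector.

# Single-level 2-D orthonormal Haar analysis: list(LL, LH, HL, HH).
haarStep <- function(m) {
  r1 <- m[seq(1, nrow(m), 2), , drop = FALSE]
  r2 <- m[seq(2, nrow(m), 2), , drop = FALSE]
  la <- (r1 + r2) / sqrt(2); ld <- (r1 - r2) / sqrt(2)
  split2 <- function(a) {
    c1 <- a[, seq(1, ncol(a), 2), drop = FALSE]
    c2 <- a[, seq(2, ncol(a), 2), drop = FALSE]
    list((c1 + c2) / sqrt(2), (c1 - c2) / sqrt(2))
  }
  A <- split2(la); D <- split2(ld)
  list(LL = A[[1]], LH = A[[2]], HL = D[[1]], HH = D[[2]])
}

haarStepInv <- function(d) {
  merge2 <- function(a, b) {
    out <- matrix(0, nrow(a), 2 * ncol(a))
    out[, seq(1, ncol(out), 2)] <- (a + b) / sqrt(2)
    out[, seq(2, ncol(out), 2)] <- (a - b) / sqrt(2)
    out
  }
  la <- merge2(d$LL, d$LH); ld <- merge2(d$HL, d$HH)
  out <- matrix(0, 2 * nrow(la), ncol(la))
  out[seq(1, nrow(out), 2), ] <- (la + ld) / sqrt(2)
  out[seq(2, nrow(out), 2), ] <- (la - ld) / sqrt(2)
  out
}

# Multilevel 2-D Haar decomposition; levels reduced to fit the dimensions.
haarDecompose <- function(m, levels = 4) {
  maxLev <- 0L
  d <- dim(m)
  while (maxLev < levels && all(d %% 2 == 0) && all(d >= 2)) {
    maxLev <- maxLev + 1L
    d <- d / 2
  }
  details <- vector("list", maxLev)
  cur <- m
  for (l in seq_len(maxLev)) {
    s <- haarStep(cur)
    details[[l]] <- s[c("LH", "HL", "HH")]
    cur <- s$LL
  }
  list(approx = cur, details = details, levels = maxLev)
}

haarReconstruct <- function(dec) {
  cur <- dec$approx
  for (l in rev(seq_len(dec$levels)))
    cur <- haarStepInv(c(list(LL = cur), dec$details[[l]]))
  cur
}

#' Fuse face frames by wavelet decomposition
#'
#' Each grayscale image is decomposed by a multilevel 2-D orthonormal Haar
#' transform; fused detail coefficients take the per-position maximum
#' absolute value across images, the approximation takes the mean, and the
#' inverse transform yields the fused face representation. A single image
#' is returned unchanged (exact reconstruction); identical images fuse to
#' themselves.
#'
#' @param images list of numeric matrices of a common size.
#' @param levels decomposition depth (default 4, reduced to fit the size).
#' @return fused matrix.
#' @export
fuseFrames <- function(images, levels = 4) {
  if (length(images) < 1) stop("at least one image required")
  dims <- vapply(images, dim, numeric(2))
  if (any(apply(dims, 1, function(d) length(unique(d)) > 1)))
    stop("images must share dimensions")
  decs <- lapply(images, haarDecompose, levels = levels)
  fused <- decs[[1]]
  if (length(decs) > 1) {
    fused$approx <- Reduce(`+`, lapply(decs, `[[`, "approx")) / length(decs)
    for (l in seq_len(fused$levels)) {
      for (band in c("LH", "HL", "HH")) {
        stack <- vapply(decs, function(d) d$details[[l]][[band]],
                        fused$details[[l]][[band]])
        if (length(dim(stack)) == 2L) dim(stack) <- c(dim(stack), 1L)
        pick <- apply(abs(stack), c(1, 2), which.max)
        sel <- cbind(as.vector(row(pick)), as.vector(col(pick)),
                     as.vector(pick))
        fused$details[[l]][[band]] <- matrix(stack[sel], nrow(pick))
      }
    }
  }
  haarReconstruct(fused)
}

#' The canonical 30-feature table
#'
#' The repository's frozen definition of the 30 normalized facial-geometry
#' features: one row per feature with its name, kind (\code{h} = horizontal
#' distance / W, \code{v} = vertical distance / H, \code{area} = shoelace
#' polygon area / (W*H)) and the landmark indices entering the formula.
#' Distances are between single landmarks or means of landmark groups
#' (groups separated by \code{";"} in \code{points}). It includes every
#' feature the underlying analysis names: eye heights and widths,
#' eyebrow-to-eye and eyebrow-to-lip distances, lip width and height,
#' inner-mouth and nose areas, nose width and height.
#'
#' @return data.frame with columns \code{name}, \code{kind}, \code{points}.
#' @export
faceCueTable <- function() {
  data.frame(
    name = c("eye_height_left", "eye_height_right", "eye_width_left",
             "eye_width_right", "eye_area_left", "eye_area_right",
             "brow_eye_left", "brow_eye_right", "brow_lip_left",
             "brow_lip_right", "brow_width_left", "brow_width_right",
             "brow_arch_left", "brow_arch_right", "inner_brow_gap",
             "interocular", "lip_width", "lip_height", "inner_lip_width",
             "inner_lip_height", "mouth_area_inner", "mouth_area_outer",
             "nose_width", "nose_height", "nose_area", "nose_lip_gap",
             "eye_nose_left", "eye_nose_right", "mouth_eye_left",
             "mouth_eye_right"),
    kind = c("v", "v", "h", "h", "area", "area", "v", "v", "v", "v", "h",
             "h", "v", "v", "h", "h", "h", "v", "h", "v", "area", "area",
             "h", "v", "area", "v", "v", "v", "v", "v"),
    points = c("21,22;24,25", "27,28;30,31", "20;23", "26;29",
               "20,21,22,23,24,25", "26,27,28,29,30,31",
               "1,2,3,4,5;21,22", "6,7,8,9,10;27,28", "1,2,3,4,5;32",
               "6,7,8,9,10;38", "1;5", "6;10", "3;1,5", "8;6,10", "5;6",
               "20,21,22,23,24,25;26,27,28,29,30,31", "32;38", "35;41",
               "44;47", "45,46;48,49", "44,45,46,47,48,49",
               "32,33,34,35,36,37,38,39,40,41,42,43", "15;19", "11;17",
               "11,15,17,19", "17;35", "24,25;17", "30,31;17",
               "32;24,25", "38;30,31"),
    stringsAsFactors = FALSE)
}

parsePointGroups <- function(s)
  lapply(strsplit(s, ";", fixed = TRUE)[[1]],
         function(g) as.integer(strsplit(g, ",", fixed = TRUE)[[1]]))

#' Compute the 30 facial-geometry features
#'
#' Evaluates the canonical feature table (\code{\link{faceCueTable}}) on a
#' landmark set: horizontal distances are divided by the face-box width,
#' vertical distances by its height, and polygon areas (shoelace formula)
#' by width times height, making the features scale- and
#' translation-invariant.
#'
#' @param lm a \code{\link{LandmarkSet}}.
#' @return named numeric vector of length 30.
#' @export
computeFaceCues <- function(lm) {
  pts <- lm@points
  W <- lm@faceBox[3]; H <- lm@faceBox[4]
  if (W <= 0 || H <= 0) stop("degenerate face box")
  tab <- faceCueTable()
  out <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    groups <- parsePointGroups(tab$points[i])
    out[i] <- switch(tab$kind[i],
      h = {
        a <- mean(pts[groups[[1]], 1]); b <- mean(pts[groups[[2]], 1])
        abs(a - b) / W
      },
      v = {
        a <- mean(pts[groups[[1]], 2]); b <- mean(pts[groups[[2]], 2])
        abs(a - b) / H
      },
      area = polygonArea(pts[groups[[1]], , drop = FALSE]) / (W * H))
  }
  stats::setNames(out, tab$name)
}

#' Names of the 30 facial features (frozen order)
#' @return character vector of length 30.
#' @export
faceCueNames <- function() faceCueTable()$name

# Default detector: bounding box of pixels darker than the background.
defaultBoxDetector <- function(frame, darkThresh = 0.9) {
  sel <- which(frame < darkThresh, arr.ind = TRUE)
  if (nrow(sel) == 0) return(NULL)
  c(x = min(sel[, 2]), y = min(sel[, 1]),
    W = diff(range(sel[, 2])) + 1, H = diff(range(sel[, 1])) + 1)
}

#' Detect a face region
#'
#' Delegates to a pluggable detector returning a candidate box
#' \code{(x, y, W, H)}; candidates smaller than \code{minSize} pixels a
#' side or touching the configured image margin are rejected (the false-
#' positive filter). The synthetic landmark path bypasses detection.
#'
#' @param frame grayscale image matrix in [0, 1].
#' @param minSize minimum face side in pixels (default 50).
#' @param edgeExclude margin in pixels; boxes reaching into it are
#'   rejected (default 2).
#' @param detector function(frame) -> box or NULL.
#' @return named numeric box or NULL when no acceptable face is found.
#' @export
detectFace <- function(frame, minSize = 50, edgeExclude = 2,
                       detector = defaultBoxDetector) {
  box <- detector(frame)
  if (is.null(box)) return(NULL)
  if (box["W"] < minSize || box["H"] < minSize) return(NULL)
  if (box["x"] <= edgeExclude || box["y"] <= edgeExclude ||
      box["x"] + box["W"] - 1 > ncol(frame) - edgeExclude ||
      box["y"] + box["H"] - 1 > nrow(frame) - edgeExclude) return(NULL)
  box
}

#' Window-level facial cue extraction
#'
#' Computes the 30 features for a window of landmark frames. With
#' \code{method = "mean"} (the synthetic-path default) the per-frame
#' landmarks are averaged over the window before the features are
#' computed; with \code{method = "fused"} the features come from the
#' landmark set of the frame nearest (mean absolute difference) to the
#' wavelet-fused face image, the path used when real face video is
#' available.
#'
#' @param landmarks 49 x 2 x T array of per-frame landmarks.
#' @param faceBox numeric (x, y, W, H).
#' @param frameIdx indices of frames in the window (default all).
#' @param method "mean" or "fused".
#' @param images optional list of grayscale face images (required for
#'   \code{method = "fused"}).
#' @return named numeric vector of length 30.
#' @export
extractFaceCues <- function(landmarks, faceBox, frameIdx = NULL,
                            method = c("mean", "fused"), images = NULL) {
  method <- match.arg(method)
  if (is.null(frameIdx)) frameIdx <- seq_len(dim(landmarks)[3])
  if (method == "mean") {
    pts <- apply(landmarks[, , frameIdx, drop = FALSE], c(1, 2), mean)
  } else {
    if (is.null(images)) stop("images required for the fused path")
    fused <- fuseFrames(images[frameIdx])
    dists <- vapply(images[frameIdx], function(im) mean(abs(im - fused)),
                    numeric(1))
    pts <- landmarks[, , frameIdx[which.min(dists)]]
  }
  computeFaceCues(LandmarkSet(pts, faceBox))
}
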