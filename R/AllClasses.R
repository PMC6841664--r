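#' @import methods
#' @importFrom stats cor fft sd var median quantile rnorm runif t.test lm pt
#'   setNames aggregate mvfft
#' @importFrom utils head tail
NULL

#' Multi-channel EEG recording
#'
#' Container for one EEG recording or window: a channels x samples matrix in
#' microvolts, the sampling rate, channel names and 2-D scalp coordinates
#' (azimuthal projection, unit head disk, x = right, y = front).
#'
#' @slot data numeric matrix, channels x samples (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot channelNames character vector, one unique name per row of
#'   \code{data}.
#' @slot channelXY numeric matrix, channels x 2, scalp coordinates.
#' @export
setClass("EEGRecording",
  representation(data = "matrix", fs = "numeric",
                 channelNames = "character", channelXY = "matrix"))

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@channelNames) != nrow(object@data))
    msg <- c(msg, "one channel name per data row required")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channel names must be unique")
  if (nrow(object@channelXY) != nrow(object@data) ||
      ncol(object@channelXY) != 2L)
    msg <- c(msg, "channelXY must be channels x 2")
  if (any(!is.finite(object@channelXY)))
    msg <- c(msg, "channel coordinates must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate (Hz).
#' @param channelNames character vector of unique channel names; defaults to
#'   the standard 32-channel montage names when \code{nrow(data) == 32}.
#' @param channelXY channels x 2 matrix of 2-D scalp coordinates; defaults to
#'   the standard montage coordinates.
#' @return An \code{EEGRecording}.
#' @export
EEGRecording <- function(data, fs = 256,
                         channelNames = NULL, channelXY = NULL) {
  if (is.null(channelNames) || is.null(channelXY)) {
    mon <- standardMontage()
    if (nrow(data) != nrow(mon))
      stop("provide channelNames/channelXY for non-32-channel data")
    if (is.null(channelNames)) channelNames <- mon$name
    if (is.null(channelXY))
      channelXY <- as.matrix(mon[, c("x", "y")])
  }
  new("EEGRecording", data = data, fs = fs,
      channelNames = as.character(channelNames),
      channelXY = as.matrix(channelXY))
}

#' Ordered frame sequence
#'
#' RGB frames of a video window: a list of height x width x 3 arrays with
#' values in [0, 1], at a fixed frame rate.
#'
#' @slot frames list of numeric arrays, each height x width x 3 in [0, 1].
#' @slot fps frames per second.
#' @export
setClass("FrameSequence",
  representation(frames = "list", fps = "numeric"))

setValidity("FrameSequence", function(object) {
  msg <- character()
  if (length(object@frames) < 1L) msg <- c(msg, "at least one frame required")
  dims <- vapply(object@frames, function(f) dim(f)[1:2], numeric(2))
  if (length(object@frames) > 1L && any(apply(dims, 1, function(d) length(unique(d)) > 1)))
    msg <- c(msg, "frames must share dimensions")
  if (any(vapply(object@frames, function(f) length(dim(f)) != 3L || dim(f)[3] != 3L,
                 logical(1))))
    msg <- c(msg, "each frame must be height x width x 3")
  if (length(object@fps) != 1L || object@fps <= 0)
    msg <- c(msg, "fps must be positive")
  if (length(msg)) msg else TRUE
})

#' @param frames list of height x width x 3 arrays in [0, 1].
#' @param fps frames per second.
#' @rdname FrameSequence-class
#' @export
FrameSequence <- function(frames, fps) new("FrameSequence", frames = frames, fps = fps)

#' Mono audio clip
#'
#' @slot samples numeric vector of amplitudes (mono; stereo sources are
#'   downmixed by averaging before construction).
#' @slot fs sampling rate in Hz, at least 8000.
#' @export
setClass("AudioClip", representation(samples = "numeric", fs = "numeric"))

setValidity("AudioClip", function(object) {
  msg <- character()
  if (any(!is.finite(object@samples))) msg <- c(msg, "samples must be finite")
  if (length(object@fs) != 1L || object@fs < 8000)
    msg <- c(msg, "fs must be >= 8000 Hz")
  if (length(msg)) msg else TRUE
})

#' @param samples numeric amplitude vector.
#' @param fs sampling rate (Hz).
#' @rdname AudioClip-class
#' @export
AudioClip <- function(samples, fs = 8000) new("AudioClip", samples = samples, fs = fs)

#' Facial landmark set
#'
#' 49 (x, y) pixel coordinates in the canonical layout (eyebrows 2 x 5, nose
#' 9, eyes 2 x 6, outer lip 12, inner lip 6) together with the detected face
#' box. The 50 x 50 pixel minimum face size is enforced at detection time
#' (\code{\link{detectFace}}), not here, so that normalized unit-box fixtures
#' remain representable.
#'
#' @slot points 49 x 2 numeric matrix of (x, y) coordinates.
#' @slot faceBox numeric length-4 vector (x, y, W, H), W > 0, H > 0.
#' @export
setClass("LandmarkSet", representation(points = "matrix", faceBox = "numeric"))

setValidity("LandmarkSet", function(object) {
  msg <- character()
  if (nrow(object@points) != 49L || ncol(object@points) != 2L)
    msg <- c(msg, "exactly 49 (x, y) points required")
  if (any(!is.finite(object@points))) msg <- c(msg, "points must be finite")
  if (length(object@faceBox) != 4L || any(object@faceBox[3:4] <= 0))
    msg <- c(msg, "faceBox must be (x, y, W, H) with W, H > 0")
  if (length(msg)) msg else TRUE
})

#' @param points 49 x 2 matrix of (x, y) coordinates.
#' @param faceBox numeric (x, y, W, H).
#' @rdname LandmarkSet-class
#' @export
LandmarkSet <- function(points, faceBox) new("LandmarkSet", points = points, faceBox = faceBox)

#' One synthetic multimodal trial
#'
#' All modalities of one trial are generated from the same latent affect
#' vector and seed, so downstream stages have ground truth.
#'
#' @slot audio an \code{AudioClip}.
#' @slot frames a \code{FrameSequence}.
#' @slot eeg an \code{EEGRecording}.
#' @slot landmarks 49 x 2 x frames array of landmark trajectories.
#' @slot faceBox numeric (x, y, W, H) of the synthetic face.
#' @slot labels list with integer \code{valence}, \code{arousal} in 1..9 and
#'   an \code{emotion} tag from the 12-category vocabulary.
#' @slot latent named numeric: \code{z_valence}, \code{z_arousal}.
#' @slot subject,clip integer indices.
#' @slot seed integer seed the trial was generated from.
#' @export
setClass("SynthTrial",
  representation(audio = "AudioClip", frames = "FrameSequence",
                 eeg = "EEGRecording", landmarks = "array",
                 faceBox = "numeric", labels = "list", latent = "numeric",
                 subject = "integer", clip = "integer", seed = "integer"))

#' Canonical correlation analysis result
#'
#' @slot weightsX,weightsY feature x component weight matrices.
#' @slot cors canonical correlations, decreasing, in [0, 1].
#' @slot loadingsX,loadingsY structure correlations: correlation of each
#'   original feature with each canonical variate of its own side.
#' @slot xNames,yNames feature names (frozen column order).
#' @export
setClass("CCAResult",
  representation(weightsX = "matrix", weightsY = "matrix", cors = "numeric",
                 loadingsX = "matrix", loadingsY = "matrix",
                 xNames = "character", yNames = "character"))

setValidity("CCAResult", function(object) {
  msg <- character()
  if (any(object@cors < -1e-8 | object@cors > 1 + 1e-8))
    msg <- c(msg, "canonical correlations must lie in [0, 1]")
  if (is.unsorted(rev(object@cors), strictly = FALSE) && length(object@cors) > 1)
    msg <- c(msg, "components must be ordered by decreasing correlation")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@fs,
              ncol(object@data) / object@fs))
})

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames[[1]])
  cat(sprintf("FrameSequence: %d frames %dx%d @ %g fps\n",
              length(object@frames), d[1], d[2], object@fps))
})

setMethod("show", "AudioClip", function(object) {
  cat(sprintf("AudioClip: %.2f s @ %g Hz\n",
              length(object@samples) / object@fs, object@fs))
})

setMethod("show", "SynthTrial", function(object) {
  cat(sprintf(
    "SynthTrial subject %d clip %d: z_v=%.2f z_a=%.2f | V=%d A=%d %s\n",
    object@subject, object@clip, object@latent["z_valence"],
    object@latent["z_arousal"], object@labels$valence, object@labels$arousal,
    object@labels$emotion))
})

setMethod("show", "CCAResult", function(object) {
  cat(sprintf("CCAResult: %d components, correlations %s\n",
              length(object@cors),
              paste(sprintf("%.3f", object@cors), collapse = ", ")))
})

#' @describeIn EEGRecording-class channel x sample data matrix
#' @param object an object of the class.
#' @export
setGeneric("eegData", function(object) standardGeneric("eegData"))
setMethod("eegData", "EEGRecording", function(object) object@data)

#' @describeIn EEGRecording-class sampling rate (Hz)
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
setMethod("samplingRate", "EEGRecording", function(object) object@fs)
setMethod("samplingRate", "AudioClip", function(object) object@fs)

#' @describeIn EEGRecording-class channel names
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
setMethod("channelNames", "EEGRecording", function(object) object@channelNames)

#' @describeIn EEGRecording-class channels x 2 scalp coordinates
#' @export
setGeneric("channelCoords", function(object) standardGeneric("channelCoords"))
setMethod("channelCoords", "EEGRecording", function(object) object@channelXY)

#' @describeIn CCAResult-class canonical correlations
#' @export
setGeneric("canonicalCors", function(object) standardGeneric("canonicalCors"))
setMethod("canonicalCors", "CCAResult", function(object) object@cors)

#' @describeIn CCAResult-class structure correlations for one side
#' @param side "x" or "y".
#' @export
setGeneric("loadings2", function(object, side = c("x", "y")) standardGeneric("loadings2"))
setMethod("loadings2", "CCAResult", function(object, side = c("x", "y")) {
  side <- match.arg(side)
  if (side == "x") object@loadingsX else object@loadingsY
})

#' @describeIn CCAResult-class canonical weights for one side
#' @export
setGeneric("ccaWeights", function(object, side = c("x", "y")) standardGeneric("ccaWeights"))
setMethod("ccaWeights", "CCAResult", function(object, side = c("x", "y")) {
  side <- match.arg(side)
  if (side == "x") object@weightsX else object@weightsY
})
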