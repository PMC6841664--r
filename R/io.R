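# File adapters: WAV audio, PNG frame directories, landmark and EEG CSV
# tables with a JSON sidecar for recording metadata.

#' Read a WAV file as an AudioClip
#'
#' Supports PCM 8/16/24/32-bit and IEEE float WAV; multi-channel audio is
#' downmixed to mono by averaging.
#'
#' @param path WAV file path.
#' @return an \code{\link{AudioClip}}.
#' @export
readWAV <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audioFormat = readBin(con, "integer", 1, 2, endian = "little",
                              signed = FALSE),
        nChannels = readBin(con, "integer", 1, 2, endian = "little",
                            signed = FALSE),
        sampleRate = readBin(con, "integer", 1, 4, endian = "little"),
        byteRate = readBin(con, "integer", 1, 4, endian = "little"),
        blockAlign = readBin(con, "integer", 1, 2, endian = "little",
                             signed = FALSE),
        bits = readBin(con, "integer", 1, 2, endian = "little",
                       signed = FALSE))
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (id == "data") {
      data <- readBin(con, "raw", size)
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
  }
  if (is.null(fmt) || is.null(data)) stop("malformed WAV: ", path)
  bytes <- fmt$bits %/% 8
  n <- length(data) %/% bytes
  x <- if (fmt$audioFormat == 3) {
    readBin(data, "double", n, size = bytes, endian = "little")
  } else if (fmt$bits == 8) {
    (readBin(data, "integer", n, 1, signed = FALSE) - 128) / 128
  } else if (fmt$bits == 24) {
    m <- matrix(as.integer(data), nrow = 3)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    ifelse(v >= 2^23, v - 2^24, v) / 2^23
  } else {
    readBin(data, "integer", n, size = bytes, signed = TRUE,
            endian = "little") / 2^(fmt$bits - 1)
  }
  if (fmt$nChannels > 1) {
    nFrames <- length(x) %/% fmt$nChannels
    x <- colMeans(matrix(x[seq_len(nFrames * fmt$nChannels)],
                         nrow = fmt$nChannels))
  }
  AudioClip(x, fs = fmt$sampleRate)
}

#' Write an AudioClip as 16-bit PCM WAV
#'
#' @param clip an \code{\link{AudioClip}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeWAV <- function(clip, path) {
  x <- pmax(pmin(clip@samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  dataSize <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + dataSize), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(clip@fs), con, size = 4, endian = "little")
  writeBin(as.integer(clip@fs * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a PNG frame directory as a FrameSequence
#'
#' Frames are read in lexicographic file order (which is time order for
#' zero-padded frame names).
#'
#' @param dir directory containing PNG frames.
#' @param fps frame rate of the sequence.
#' @return a \code{\link{FrameSequence}}.
#' @export
readFrameDir <- function(dir, fps) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no PNG frames in ", dir)
  frames <- lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
    a[, , 1:3, drop = FALSE]
  })
  frames <- lapply(frames, function(a) array(a, dim = c(dim(a)[1:2], 3)))
  FrameSequence(frames, fps = fps)
}

#' Write a FrameSequence as a PNG frame directory
#'
#' @param frames a \code{\link{FrameSequence}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
writeFrameDir <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(frames@frames), function(i) {
    p <- file.path(dir, sprintf("frame_%05d.png", i))
    png::writePNG(frames@frames[[i]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Read per-frame landmarks from CSV
#'
#' Expected columns: \code{frame}, \code{point}, \code{x}, \code{y}, with
#' 49 points per frame.
#'
#' @param path CSV path.
#' @return 49 x 2 x frames array.
#' @export
readLandmarkCSV <- function(path) {
  if (!file.exists(path)) stop("landmark table not found: ", path)
  df <- utils::read.csv(path)
  frames <- sort(unique(df$frame))
  arr <- array(NA_real_, c(49, 2, length(frames)))
  for (k in seq_along(frames)) {
    sub <- df[df$frame == frames[k], ]
    sub <- sub[order(sub$point), ]
    if (nrow(sub) != 49) stop("frame ", frames[k], " has ", nrow(sub),
                              " points; expected 49")
    arr[, , k] <- as.matrix(sub[, c("x", "y")])
  }
  arr
}

#' Write per-frame landmarks to CSV
#'
#' @param landmarks 49 x 2 x frames array.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeLandmarkCSV <- function(landmarks, path) {
  nF <- dim(landmarks)[3]
  df <- do.call(rbind, lapply(seq_len(nF), function(k)
    data.frame(frame = k, point = 1:49,
               x = landmarks[, 1, k], y = landmarks[, 2, k])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an EEG recording from CSV plus JSON sidecar
#'
#' The CSV holds one row per channel (samples in columns, no header); the
#' sidecar (same path with extension \code{.json}) holds \code{fs},
#' \code{channel_names} and \code{channel_xy}.
#'
#' @param path CSV path.
#' @param sidecar optional explicit sidecar path.
#' @return an \code{\link{EEGRecording}}.
#' @export
readEEGCSV <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sub("\\.csv$", ".json", path)
  if (!file.exists(path)) stop("EEG table not found: ", path)
  if (!file.exists(sidecar)) stop("EEG sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  d <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(d) <- NULL
  new("EEGRecording", data = d, fs = as.numeric(meta$fs),
      channelNames = as.character(meta$channel_names),
      channelXY = matrix(as.numeric(unlist(meta$channel_xy)),
                         ncol = 2, byrow = FALSE))
}

#' Write an EEG recording to CSV plus JSON sidecar
#'
#' @param recording an \code{\link{EEGRecording}}.
#' @param path output CSV path; the sidecar goes next to it.
#' @return invisibly, the CSV path.
#' @export
writeEEGCSV <- function(recording, path) {
  utils::write.table(recording@data, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(
    list(fs = recording@fs, channel_names = recording@channelNames,
         channel_xy = recording@channelXY),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export one synthetic trial to files
#'
#' Writes the trial's audio (WAV), frames (PNG directory), EEG (CSV plus
#' JSON sidecar), landmarks (CSV), labels (CSV) and a JSON manifest with
#' the latent and seed, mirroring the on-disk layout a recorded study
#' would use.
#'
#' @param trial a \code{\link{SynthTrial}}.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
writeTrial <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeWAV(trial@audio, file.path(dir, "audio.wav"))
  writeFrameDir(trial@frames, file.path(dir, "frames"))
  writeEEGCSV(trial@eeg, file.path(dir, "eeg.csv"))
  writeLandmarkCSV(trial@landmarks, file.path(dir, "landmarks.csv"))
  utils::write.csv(data.frame(subject = trial@subject, clip = trial@clip,
                              valence = trial@labels$valence,
                              arousal = trial@labels$arousal,
                              emotion = trial@labels$emotion),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = trial@seed, fps = trial@frames@fps,
         latent = as.list(trial@latent)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
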