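# Orchestration: configuration, windowed cue-matrix extraction across
# modalities, per-pair CCA, behavior correlation and the optional
# representational-similarity stage.

#' Default pipeline configuration
#'
#' All analysis parameters with their defaults: 15 s windows advanced by
#' 1 s, theta/alpha/beta band edges, 8-level GLCM, 16-bin conditional
#' entropy, ridge 1e-3 CCA with 3 components fitted per subject, and the
#' synthetic-source geometry.
#'
#' @param seed master seed.
#' @param nSubjects,nClips,clipSeconds synthetic-dataset geometry.
#' @param linkage a \code{\link{linkageConfig}}.
#' @param winS,hopS windowing parameters (seconds).
#' @param entropy include the 496 conditional-entropy EEG features.
#' @param clean run the subspace cleaner on each recording.
#' @param grouping "subject" (fit CCA per subject, aggregate loadings by
#'   mean absolute value) or "pooled".
#' @param nComponents,ridge CCA parameters.
#' @param rsa logical; run the representational-similarity stage.
#' @param rsaInputsN inputs for the RSA stage.
#' @return named list of class \code{"affectlinkConfig"}.
#' @export
defaultConfig <- function(seed = 1, nSubjects = 3, nClips = 6,
                          clipSeconds = 35, linkage = linkageConfig(),
                          winS = 15, hopS = 1, entropy = TRUE,
                          clean = TRUE, grouping = c("subject", "pooled"),
                          nComponents = 3, ridge = 1e-3, rsa = FALSE,
                          rsaInputsN = 30) {
  grouping <- match.arg(grouping)
  structure(list(seed = seed, nSubjects = nSubjects, nClips = nClips,
                 clipSeconds = clipSeconds, linkage = linkage, winS = winS,
                 hopS = hopS, entropy = entropy, clean = clean,
                 grouping = grouping, nComponents = nComponents,
                 ridge = ridge, rsa = rsa, rsaInputsN = rsaInputsN),
            class = "affectlinkConfig")
}

configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

# One SummarizedExperiment per modality: assay "cues" is features x
# windows; colData carries subject, clip, window start and the labels.
cueExperiment <- function(featMat, meta) {
  SummarizedExperiment::SummarizedExperiment(
    assays = list(cues = featMat),
    colData = S4Vectors::DataFrame(meta))
}

#' Extract windowed cue matrices from synthetic trials
#'
#' For every trial, frame- and block-level features are computed once per
#' clip and aggregated per sliding window; EEG windows get band-PSD (and
#' optionally conditional-entropy) features. Rows are keyed by
#' (subject, clip, window_start_s) so the overlapping windows of the 1 s
#' hop are first-class.
#'
#' @param trials list of \code{\link{SynthTrial}} objects.
#' @param winS,hopS window and hop in seconds.
#' @param entropy include the 496-dim conditional-entropy block.
#' @param clean run \code{\link{cleanEEG}} before windowing.
#' @return list of SummarizedExperiments: \code{av} (30 features),
#'   \code{eeg} (96 or 592), \code{face} (30).
#' @export
extractCueMatrices <- function(trials, winS = 15, hopS = 1, entropy = TRUE,
                               clean = TRUE) {
  avList <- list(); eegList <- list(); faceList <- list(); metaList <- list()
  for (tr in trials) {
    fs <- tr@eeg@fs
    seconds <- ncol(tr@eeg@data) / fs
    nWin <- windowCount(seconds, winS, hopS)
    vf <- visualFrameFeatures(tr@frames)
    af <- audioFrameFeatures(tr@audio)
    rec <- if (clean) cleanEEG(tr@eeg) else tr@eeg
    segPSD <- segmentBandPSD(rec)
    wins <- if (entropy) windowEpochs(rec, winS, hopS) else NULL
    fps <- tr@frames@fps
    frameTimes <- (seq_len(length(tr@frames@frames)) - 1) / fps
    lmTimes <- (seq_len(dim(tr@landmarks)[3]) - 1) / fps
    for (w in seq_len(nWin)) {
      t0 <- (w - 1) * hopS; t1 <- t0 + winS
      fidx <- which(frameTimes >= t0 & frameTimes < t1)
      av <- c(aggregateVisualCues(vf, fidx), aggregateAudioCues(af, t0, t1))
      sidx <- segPSD$starts >= t0 - 1e-9 &
        segPSD$starts + segPSD$segS <= t1 + 1e-9
      psd <- colMeans(segPSD$values[sidx, , drop = FALSE])
      eegCues <- if (entropy)
        c(psd, conditionalEntropyMatrix(wins[[w]])) else psd
      lidx <- which(lmTimes >= t0 & lmTimes < t1)
      face <- extractFaceCues(tr@landmarks, tr@faceBox, frameIdx = lidx)
      avList[[length(avList) + 1L]] <- av
      eegList[[length(eegList) + 1L]] <- eegCues
      faceList[[length(faceList) + 1L]] <- face
      metaList[[length(metaList) + 1L]] <- data.frame(
        subject = tr@subject, clip = tr@clip, window_start_s = t0,
        valence = tr@labels$valence, arousal = tr@labels$arousal,
        emotion = tr@labels$emotion, stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, metaList)
  list(av = cueExperiment(t(do.call(rbind, avList)), meta),
       eeg = cueExperiment(t(do.call(rbind, eegList)), meta),
       face = cueExperiment(t(do.call(rbind, faceList)), meta))
}

# Standardize, fit CCA (per subject or pooled) and aggregate loadings by
# the mean absolute loading across fits.
fitModalityPair <- function(xSE, ySE, grouping = "subject",
                            nComponents = 3, ridge = 1e-3) {
  x <- asCueMatrix(xSE); y <- asCueMatrix(ySE)
  meta <- as.data.frame(SummarizedExperiment::colData(xSE))
  groups <- if (grouping == "subject") split(seq_len(nrow(x)), meta$subject)
    else list(all = seq_len(nrow(x)))
  fits <- lapply(groups, function(idx) {
    xs <- suppressWarnings(standardizeCues(x[idx, , drop = FALSE]))
    ys <- suppressWarnings(standardizeCues(y[idx, , drop = FALSE]))
    k <- min(nComponents, ncol(xs), ncol(ys))
    ccaFit(xs, ys, nComponents = k, ridge = ridge)
  })
  aggLoad <- function(side) {
    mats <- lapply(fits, function(f) abs(loadings2(f, side)[, 1]))
    nms <- Reduce(intersect, lapply(mats, names))
    rowMeans(vapply(mats, function(m) m[nms], numeric(length(nms))))
  }
  list(fits = fits,
       meanCor = mean(vapply(fits, function(f) canonicalCors(f)[1],
                             numeric(1))),
       loadingsX = aggLoad("x"), loadingsY = aggLoad("y"))
}

#' Run the full analysis pipeline
#'
#' Generates the synthetic dataset, extracts the windowed cue matrices for
#' the three modalities, fits CCA for each modality pair (AV-EEG, AV-Face,
#' EEG-Face), correlates first-component projections with the behavior
#' labels, optionally computes the layer-wise representational similarity
#' matrix, and returns everything with a manifest (seed, configuration
#' hash, package version). Deterministic: the same configuration yields an
#' identical bundle.
#'
#' @param config a \code{\link{defaultConfig}} list.
#' @return result bundle: \code{cues}, \code{cca} (per pair),
#'   \code{behavior} (per pair), \code{rsa} (or NULL), \code{manifest}.
#' @export
runAll <- function(config = defaultConfig()) {
  trials <- genDataset(config$nSubjects, config$nClips,
                       clipSeconds = config$clipSeconds,
                       linkage = config$linkage, seed = config$seed)
  cues <- extractCueMatrices(trials, winS = config$winS, hopS = config$hopS,
                             entropy = config$entropy, clean = config$clean)
  pairs <- list(`AV-EEG` = c("av", "eeg"), `AV-Face` = c("av", "face"),
                `EEG-Face` = c("eeg", "face"))
  cca <- lapply(pairs, function(p)
    fitModalityPair(cues[[p[1]]], cues[[p[2]]], grouping = config$grouping,
                    nComponents = config$nComponents, ridge = config$ridge))
  labels <- as.data.frame(SummarizedExperiment::colData(cues$av))
  behavior <- lapply(names(pairs), function(nm) {
    p <- pairs[[nm]]
    fit <- cca[[nm]]$fits[[1]]
    idx <- if (config$grouping == "subject")
      which(labels$subject == labels$subject[1]) else seq_len(nrow(labels))
    # project the same standardized matrices the fit was computed on
    x <- suppressWarnings(
      standardizeCues(asCueMatrix(cues[[p[1]]])[idx, , drop = FALSE]))
    y <- suppressWarnings(
      standardizeCues(asCueMatrix(cues[[p[2]]])[idx, , drop = FALSE]))
    projectAndCorrelate(fit, x[, fit@xNames, drop = FALSE],
                        y[, fit@yNames, drop = FALSE],
                        labels[idx, , drop = FALSE])
  })
  names(behavior) <- names(pairs)
  rsaRes <- NULL
  if (isTRUE(config$rsa)) {
    inp <- rsaInputs(config$rsaInputsN, seed = childSeed(config$seed, 99))
    netA <- buildNetwork(seed = childSeed(config$seed, 101))
    netB <- buildNetwork(seed = childSeed(config$seed, 102))
    rsaRes <- similarityMatrix(
      forwardActivations(netA, inp$eegImages),
      forwardActivations(netB, inp$faceImages))
  }
  list(cues = cues, cca = cca, behavior = behavior, rsa = rsaRes,
       manifest = list(seed = config$seed, configHash = configHash(config),
                       package = as.character(utils::packageVersion("affectlink")),
                       nTrials = length(trials),
                       nWindows = ncol(SummarizedExperiment::assay(cues$av))))
}

#' Planted-linkage recovery run
#'
#' The package's end-to-end benchmark: generate a synthetic dataset whose
#' arousal latent drives GLCM homogeneity and central-channel beta power
#' (texture <-> beta linkage), extract the audio-visual and EEG band-PSD
#' cue matrices over sliding windows, fit the AV-EEG canonical correlation
#' pooled across subjects, and check that the top absolute loading is
#' \code{glcm_homogeneity} on the AV side and a central-channel beta
#' feature on the EEG side. The default geometry (5 subjects x 15 clips x
#' 34 s, 15 s windows, 1 s hop) yields 1500 windows. The conditional-
#' entropy block and the artifact cleaner are off here: the planted signal
#' is spectral and no artifacts are injected (see the methods vignette).
#'
#' @param seed integer seed.
#' @param snr linkage signal-to-noise ratio (default 2).
#' @param nSubjects,nClips,clipSeconds dataset geometry.
#' @param ridge CCA regularization.
#' @return list: \code{detected}, \code{topAV}, \code{topEEG}, \code{rho},
#'   \code{nWindows}.
#' @export
plantedLinkageRun <- function(seed, snr = 2, nSubjects = 5, nClips = 15,
                              clipSeconds = 34, ridge = 1e-3) {
  trials <- genDataset(nSubjects, nClips, clipSeconds = clipSeconds,
                       linkage = linkageConfig(snr = snr), seed = seed)
  cues <- extractCueMatrices(trials, entropy = FALSE, clean = FALSE)
  fit <- fitModalityPair(cues$av, cues$eeg, grouping = "pooled",
                         nComponents = 3, ridge = ridge)
  topAV <- names(sort(fit$loadingsX, decreasing = TRUE))[1]
  topEEG <- names(sort(fit$loadingsY, decreasing = TRUE))[1]
  list(detected = topAV == "glcm_homogeneity" &&
         topEEG %in% paste0(centralChannels(), "_beta"),
       topAV = topAV, topEEG = topEEG, rho = fit$meanCor,
       nWindows = ncol(SummarizedExperiment::assay(cues$av)))
}

#' Write cue tables to CSV
#'
#' Writes one CSV per modality with the frozen column names, keyed by
#' (subject, clip, window_start_s).
#'
#' @param cues list from \code{\link{extractCueMatrices}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
writeCueTables <- function(cues, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(cues), function(nm) {
    se <- cues[[nm]]
    df <- cbind(as.data.frame(SummarizedExperiment::colData(se)),
                t(SummarizedExperiment::assay(se)))
    p <- file.path(dir, paste0(nm, "_cues.csv"))
    utils::write.csv(df, p, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Read a cue table written by \code{writeCueTables}
#'
#' @param path CSV path.
#' @return list with \code{cues} (trials x features matrix) and
#'   \code{meta} (the key and label columns).
#' @export
readCueTable <- function(path) {
  if (!file.exists(path)) stop("cue table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  metaCols <- c("subject", "clip", "window_start_s", "valence", "arousal",
                "emotion")
  keep <- setdiff(colnames(df), metaCols)
  list(cues = as.matrix(df[, keep, drop = FALSE]),
       meta = df[, intersect(metaCols, colnames(df)), drop = FALSE])
}
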