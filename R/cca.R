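# Regularized canonical correlation analysis with structure-correlation
# (loading) attribution, behavior-label correlation, emotion regression
# and paired band t-tests.

# Accept a trials x features matrix or a SummarizedExperiment whose assay
# is features x trials.
asCueMatrix <- function(x) {
  if (is(x, "SummarizedExperiment"))
    return(t(SummarizedExperiment::assay(x)))
  as.matrix(x)
}

#' Standardize a cue matrix
#'
#' Centers and scales every column to zero mean and unit variance; constant
#' columns cannot be scaled and are dropped with a warning naming them.
#' Idempotent.
#'
#' @param m trials x features matrix (>= 2 rows) with column names.
#' @return standardized matrix, possibly with fewer columns.
#' @export
standardizeCues <- function(m) {
  m <- asCueMatrix(m)
  if (nrow(m) < 2) stop("at least 2 rows required")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant columns: ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  scale(m)[, , drop = FALSE]
}

symInvSqrt <- function(S, ridge, what) {
  e <- eigen(S, symmetric = TRUE)
  tol <- max(e$values) * 1e-10
  if (any(e$values < tol)) {
    if (ridge <= 0)
      stop(what, " covariance is rank-deficient; refit with a positive ",
           "ridge (e.g. 1e-3)")
    e$values <- pmax(e$values, tol)
  }
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Fit a regularized canonical correlation analysis
#'
#' Solves the regularized canonical correlation eigenproblem
#' \code{(Cxx + ridge I)^-1 Cxy (Cyy + ridge I)^-1 Cyx} via its symmetric
#' form; returns paired weight matrices, canonical correlations in
#' decreasing order, and structure correlations (loadings) of every
#' original feature with the canonical variates of its own side. Weight
#' signs are fixed so the largest-magnitude x weight of each component is
#' positive (determinism).
#'
#' @param x,y trials x features matrices (or SummarizedExperiments with a
#'   features x trials assay) with equal row counts.
#' @param nComponents number of component pairs (default
#'   \code{min(ncol(x), ncol(y))}).
#' @param ridge non-negative regularization added to each within-set
#'   covariance diagonal; 0 requires full-rank covariances.
#' @return a \code{\link{CCAResult}}.
#' @export
ccaFit <- function(x, y, nComponents = NULL, ridge = 1e-3) {
  x <- asCueMatrix(x); y <- asCueMatrix(y)
  if (nrow(x) != nrow(y)) stop("x and y must have equal row counts")
  if (ridge < 0) stop("ridge must be >= 0")
  p <- ncol(x); q <- ncol(y)
  if (is.null(nComponents)) nComponents <- min(p, q)
  if (nComponents > min(p, q)) stop("nComponents exceeds min(p, q)")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  if (is.null(colnames(y))) colnames(y) <- paste0("y", seq_len(q))
  xc <- scale(x, scale = FALSE); yc <- scale(y, scale = FALSE)
  n <- nrow(xc)
  cxx <- crossprod(xc) / (n - 1) + diag(ridge, p)
  cyy <- crossprod(yc) / (n - 1) + diag(ridge, q)
  cxy <- crossprod(xc, yc) / (n - 1)
  rxi <- symInvSqrt(cxx, ridge, "x")
  ryInv <- tryCatch(solve(cyy), error = function(e)
    stop("y covariance is rank-deficient; refit with a positive ridge"))
  m <- rxi %*% cxy %*% ryInv %*% t(cxy) %*% rxi
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  k <- nComponents
  rho <- sqrt(pmin(pmax(e$values[seq_len(k)], 0), 1))
  wx <- rxi %*% e$vectors[, seq_len(k), drop = FALSE]
  wy <- ryInv %*% t(cxy) %*% wx
  # unit variance of y variates under the regularized metric
  wyn <- sqrt(colSums(wy * (cyy %*% wy)))
  wyn[wyn == 0] <- 1
  wy <- sweep(wy, 2, wyn, `/`)
  # deterministic sign: largest |wx| entry positive per component
  for (j in seq_len(k)) {
    s <- sign(wx[which.max(abs(wx[, j])), j])
    if (s < 0) { wx[, j] <- -wx[, j]; wy[, j] <- -wy[, j] }
  }
  sx <- xc %*% wx; sy <- yc %*% wy
  lx <- suppressWarnings(stats::cor(x, sx)); lx[is.na(lx)] <- 0
  ly <- suppressWarnings(stats::cor(y, sy)); ly[is.na(ly)] <- 0
  rownames(wx) <- colnames(x); rownames(wy) <- colnames(y)
  rownames(lx) <- colnames(x); rownames(ly) <- colnames(y)
  new("CCAResult", weightsX = wx, weightsY = wy, cors = rho,
      loadingsX = lx, loadingsY = ly,
      xNames = colnames(x), yNames = colnames(y))
}

#' Rank features by loading on the first canonical component
#'
#' Features of one side ranked by the absolute structure correlation
#' (loading) with the first canonical variate; ties are broken by the
#' frozen column order. Also reports the weight share of the top k:
#' the sum of their absolute loadings over the sum of all absolute
#' loadings.
#'
#' @param res a \code{\link{CCAResult}}.
#' @param side "x" or "y".
#' @param k number of features to return.
#' @param component component index (default 1).
#' @return list with \code{table} (data.frame: feature, loading, rank) and
#'   \code{weightShare} in [0, 1].
#' @export
topLoadings <- function(res, side = c("x", "y"), k = 5, component = 1) {
  side <- match.arg(side)
  l <- loadings2(res, side)[, component]
  if (k > length(l)) stop("k exceeds the feature count")
  ord <- order(-abs(l), seq_along(l))
  sel <- ord[seq_len(k)]
  list(table = data.frame(feature = names(l)[sel], loading = unname(l[sel]),
                          rank = seq_len(k), stringsAsFactors = FALSE),
       weightShare = sum(abs(l[sel])) / sum(abs(l)))
}

#' Correlate canonical projections with behavior labels
#'
#' The first canonical variate score of each side (rows times weights,
#' component 1) is correlated (Pearson) with the valence and arousal
#' labels; per side and label the single original cue with the largest
#' \code{|cor(cue, variate)| * |cor(variate, label)|} is reported as the
#' highest-correlating cue.
#'
#' @param res a \code{\link{CCAResult}}.
#' @param x,y the cue matrices the result was fitted on.
#' @param labels data.frame aligned to rows with columns \code{valence}
#'   and \code{arousal}.
#' @return data.frame with columns side, label, r, top_cue, top_cue_score.
#' @export
projectAndCorrelate <- function(res, x, y, labels) {
  x <- asCueMatrix(x); y <- asCueMatrix(y)
  if (nrow(x) != nrow(labels)) stop("labels must align to rows")
  out <- list()
  for (side in c("x", "y")) {
    m <- if (side == "x") x else y
    w <- ccaWeights(res, side)[, 1]
    v <- scale(m, scale = FALSE) %*% w
    if (stats::sd(v) == 0) stop("zero-variance canonical variate")
    cueCor <- abs(apply(m, 2, safeCor, b = as.vector(v)))
    for (lab in c("valence", "arousal")) {
      r <- safeCor(as.vector(v), labels[[lab]])
      score <- cueCor * abs(r)
      best <- order(-score, seq_along(score))[1]
      out[[length(out) + 1L]] <- data.frame(
        side = side, label = lab, r = r,
        top_cue = colnames(m)[best], top_cue_score = unname(score[best]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Regress a canonical variate on emotion categories
#'
#' Ordinary least squares of the variate on one-hot emotion indicators in
#' the grand-mean parameterization: the intercept is the overall mean and
#' each class coefficient is that class's mean deviation, so the
#' frequency-weighted coefficients sum to zero. Classes with fewer than 2
#' trials are excluded with a message. Returns the largest-magnitude class
#' coefficient.
#'
#' @param scores numeric variate per trial.
#' @param emotions character/factor of emotion tags (>= 2 classes present).
#' @return list with \code{coefficients} (named per class),
#'   \code{maxCoef}, \code{class}.
#' @export
regressEmotions <- function(scores, emotions) {
  emotions <- as.character(emotions)
  counts <- table(emotions)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    message("excluding classes with < 2 trials: ",
            paste(small, collapse = ", "))
    keep <- !(emotions %in% small)
    scores <- scores[keep]; emotions <- emotions[keep]
  }
  if (length(unique(emotions)) < 2) stop("at least 2 classes required")
  grand <- mean(scores)
  coefs <- tapply(scores, emotions, mean) - grand
  best <- which.max(abs(coefs))
  list(coefficients = coefs, maxCoef = unname(coefs[best]),
       class = names(coefs)[best])
}

#' Block-permutation p-value for a variate-label correlation
#'
#' The sliding windows of one clip overlap heavily, so nominal p-values on
#' window-level correlations overstate the evidence. This permutes labels
#' at the clip level (windows of a clip stay together), giving an honest
#' null for the absolute Pearson correlation between a canonical variate
#' and a label.
#'
#' @param variate numeric score per window.
#' @param label numeric label per window (constant within clip).
#' @param clip clip identifier per window.
#' @param nPerm number of permutations (default 199).
#' @param seed RNG seed.
#' @return list with \code{r}, \code{p} (permutation p-value including the
#'   observed statistic), \code{nPerm}.
#' @export
blockPermutePValue <- function(variate, label, clip, nPerm = 199, seed = 1) {
  r <- safeCor(variate, label)
  clips <- unique(clip)
  clipLabel <- vapply(clips, function(cl) label[match(cl, clip)], numeric(1))
  null <- withSeed(seed, function()
    replicate(nPerm, {
      perm <- sample(clipLabel)
      safeCor(variate, perm[match(clip, clips)])
    }))
  list(r = r, p = (1 + sum(abs(null) >= abs(r))) / (nPerm + 1),
       nPerm = nPerm)
}

#' Paired-sample t-test between two band coefficient columns
#'
#' Standard paired-sample t statistic with a two-sided p-value. A
#' zero-variance difference returns the documented sentinel: t = 0, p = 1
#' when the constant difference is zero, t = +/- Inf, p = 0 otherwise.
#'
#' @param coefs subjects x bands numeric matrix with band column names.
#' @param bandA,bandB column names or indices to compare.
#' @return list with \code{t}, \code{p}, \code{df}.
#' @export
pairedBandTTest <- function(coefs, bandA, bandB) {
  a <- coefs[, bandA]; b <- coefs[, bandB]
  if (length(a) < 3) stop("at least 3 paired subjects required")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, df = length(d) - 1))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = length(d) - 1))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}
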