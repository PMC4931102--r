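# Fit per-class joint densities for a given projection and score their
# separation on a fresh shared grid.
scoreProjection <- function(proj, Xpos, Xneg, resolution) {
  jp <- jointDensity(projectData(proj, Xpos))
  jn <- jointDensity(projectData(proj, Xneg))
  grid <- makeSharedGrid(jp, jn, resolution)
  list(
    pos = jp, neg = jn, grid = grid,
    dJ = jaccardDistance(jp, jn, grid)
  )
}

assembleBinaryModel <- function(proj, fit, stats, labels, nPos, nNeg, config) {
  new("BinaryRPModel",
    projection = proj, standardization = stats,
    posDensity = fit$pos, negDensity = fit$neg, grid = fit$grid,
    separation = min(1, max(0, fit$dJ)),
    labels = labels, trainCounts = c(nPos, nNeg), config = config
  )
}

#' Search for the best-separating random projection
#'
#' Repeatedly samples sparse random projections, projects both classes,
#' fits per-dimension kernel densities for each class and measures their
#' Jaccard distance on a shared grid; the projection with the largest
#' distance (smallest overlapping area) is kept. The search stops early
#' once the distance reaches `earlyStop`. Features are z-scored on the
#' pooled training data first and the statistics are frozen into the model.
#'
#' Per-trial seeds are drawn up front from `seed` with a prefix-stable
#' schedule, so increasing `trials` only appends candidates and can never
#' decrease the returned separation.
#'
#' @param xPos,xNeg numeric d x N matrices of the positive and negative
#'   training windows (N >= 2 each, equal d).
#' @param k projected dimension (default 2, matching the bivariate product
#'   density and 2-D overlap plots the method is built around).
#' @param trials maximum number of candidate projections (default 100).
#' @param earlyStop stop once separation reaches this value (default 0.99).
#' @param seed integer seed driving the whole search.
#' @param scale entry magnitude of candidate matrices.
#' @param resolution grid resolution per dimension for the overlap.
#' @param labels character 2-vector naming the (positive, negative) class.
#' @return a [BinaryRPModel-class]; `separationScore()` of the result is
#'   the maximum Jaccard distance over all tried projections.
#' @export
findBestProjection <- function(xPos, xNeg, k = 2L, trials = 100L,
                               earlyStop = 0.99, seed = 1L, scale = 1,
                               resolution = 256L,
                               labels = c("pos", "neg")) {
  xPos <- as.matrix(xPos); xNeg <- as.matrix(xNeg)
  if (nrow(xPos) != nrow(xNeg)) {
    stop(sprintf(
      "dimension mismatch: positive class has d = %d, negative d = %d",
      nrow(xPos), nrow(xNeg)
    ), call. = FALSE)
  }
  stopIfNot(ncol(xPos) >= 2L, "positive class needs >= 2 samples")
  stopIfNot(ncol(xNeg) >= 2L, "negative class needs >= 2 samples")
  trials <- as.integer(trials)
  stopIfNot(trials >= 1L, "'trials' must be >= 1")

  std <- standardizeFeatures(cbind(xPos, xNeg))
  nPos <- ncol(xPos)
  Zp <- std$X[, seq_len(nPos), drop = FALSE]
  Zn <- std$X[, -seq_len(nPos), drop = FALSE]

  trialSeeds <- deriveSeeds(seed, trials)
  best <- NULL; bestProj <- NULL; bestDJ <- -Inf
  for (t in seq_len(trials)) {
    proj <- sampleProjectionMatrix(k, nrow(xPos), trialSeeds[t], scale)
    fit <- scoreProjection(proj, Zp, Zn, resolution)
    if (fit$dJ > bestDJ) {
      bestDJ <- fit$dJ; best <- fit; bestProj <- proj
    }
    if (bestDJ >= earlyStop) break
  }
  assembleBinaryModel(
    bestProj, best, std$stats, labels,
    ncol(xPos), ncol(xNeg),
    list(
      k = k, trials = trials, earlyStop = earlyStop, seed = seed,
      scale = scale, resolution = resolution, bandwidth = "silverman",
      triedTrials = t
    )
  )
}

#' Two-feature selector baseline (no random projections)
#'
#' Same training pipeline as [findBestProjection()] but the projection is
#' the fixed 2 x d selector of two chosen features -- the classical
#' "top-ranked features only" baseline against which the projection search
#' is compared. No search is performed.
#'
#' @param X numeric d x N feature matrix or a [FeatureSet-class].
#' @param labels character vector of binary labels per column (ignored
#'   when `X` is a FeatureSet, whose activity labels are used).
#' @param featureIds exactly 2 distinct catalogue feature ids.
#' @param resolution grid resolution per dimension.
#' @return a [BinaryRPModel-class] with the selector projection; its
#'   separation is the Jaccard distance of the two class densities.
#' @export
trainBaselineTop2 <- function(X, labels = NULL, featureIds,
                              resolution = 256L) {
  if (is(X, "FeatureSet")) {
    labels <- activityLabels(X)
    X <- featureMatrix(X)
  }
  X <- as.matrix(X)
  featureIds <- as.integer(featureIds)
  stopIfNot(length(featureIds) == 2L, "exactly 2 feature ids required")
  if (featureIds[1] == featureIds[2]) {
    stop("duplicate feature ids", call. = FALSE)
  }
  lv <- sort(unique(labels))
  stopIfNot(length(lv) == 2L, "binary labels required")
  rows <- match(paste0("f", featureIds), rownames(X))
  if (anyNA(rows)) rows <- featureIds # bare row indices for unnamed input
  stopIfNot(all(rows >= 1 & rows <= nrow(X)), "feature ids out of range")

  xPos <- X[, labels == lv[1], drop = FALSE]
  xNeg <- X[, labels == lv[2], drop = FALSE]
  std <- standardizeFeatures(cbind(xPos, xNeg))
  nPos <- ncol(xPos)
  proj <- selectorProjection(rows, nrow(X))
  fit <- scoreProjection(
    proj, std$X[, seq_len(nPos), drop = FALSE],
    std$X[, -seq_len(nPos), drop = FALSE], resolution
  )
  assembleBinaryModel(
    proj, fit, std$stats, lv, ncol(xPos), ncol(xNeg),
    list(
      k = 2L, trials = 0L, featureIds = featureIds,
      resolution = resolution, bandwidth = "silverman"
    )
  )
}

#' Classify windows with a binary model
#'
#' Standardizes with the frozen training statistics, projects with the
#' stored matrix and evaluates both class densities; a window is assigned
#' the positive label when its positive density is at least its negative
#' density (ties go to the positive class).
#'
#' @param model a [BinaryRPModel-class].
#' @param x numeric feature vector of length d, or a d x N matrix / a
#'   [FeatureSet-class] to classify many windows at once.
#' @return data.frame with columns `label`, `scorePos`, `scoreNeg` (one row
#'   per window).
#' @export
classifyBinary <- function(model, x) {
  stopifnot(is(model, "BinaryRPModel"))
  if (is(x, "FeatureSet")) x <- featureMatrix(x)
  X <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
  d <- length(model@standardization@center)
  if (nrow(X) != d) {
    stop(sprintf(
      "feature mismatch: model expects %d features, got %d", d, nrow(X)
    ), call. = FALSE)
  }
  Z <- projectData(model@projection, standardizeFeatures(
    X, model@standardization
  )$X)
  sPos <- evalJoint(model@posDensity, Z)
  sNeg <- evalJoint(model@negDensity, Z)
  data.frame(
    label = ifelse(sPos >= sNeg, model@labels[1], model@labels[2]),
    scorePos = sPos, scoreNeg = sNeg
  )
}

#' Train a one-vs-rest multi-class model
#'
#' Fits one binary random-projection model per label, with that label's
#' windows as the positive class and all other windows pooled as the
#' negative class. Each per-label search gets its own derived seed, so the
#' whole model is reproducible from `seed`.
#'
#' @param X numeric d x N matrix or a [FeatureSet-class].
#' @param labels character labels per column (taken from the FeatureSet's
#'   activity labels when omitted).
#' @param outlierThreshold density threshold epsilon for the one-class
#'   outlier rule.
#' @param oneClass logical; enable the outlier rule at prediction time
#'   (off by default for closed-set activity classification).
#' @inheritParams findBestProjection
#' @return a [MultiClassRPModel-class].
#' @export
trainOneVsAll <- function(X, labels = NULL, k = 2L, trials = 100L,
                          earlyStop = 0.99, seed = 1L, scale = 1,
                          resolution = 256L, outlierThreshold = 1e-12,
                          oneClass = FALSE) {
  if (is(X, "FeatureSet")) {
    if (is.null(labels)) labels <- activityLabels(X)
    X <- featureMatrix(X)
  }
  X <- as.matrix(X)
  labels <- as.character(labels)
  stopIfNot(length(labels) == ncol(X), "one label per column required")
  lv <- sort(unique(labels))
  stopIfNot(length(lv) >= 2L, "need >= 2 distinct labels")
  counts <- table(labels)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    stop(
      "label(s) with < 2 windows: ", paste(small, collapse = ", "),
      call. = FALSE
    )
  }
  labelSeeds <- deriveSeeds(seed, length(lv))
  models <- lapply(seq_along(lv), function(i) {
    findBestProjection(
      X[, labels == lv[i], drop = FALSE],
      X[, labels != lv[i], drop = FALSE],
      k = k, trials = trials, earlyStop = earlyStop,
      seed = labelSeeds[i], scale = scale, resolution = resolution,
      labels = c(lv[i], "rest")
    )
  })
  names(models) <- lv
  new("MultiClassRPModel",
    models = models, outlierThreshold = outlierThreshold,
    oneClass = oneClass, labels = lv
  )
}

#' Predict labels with a one-vs-rest model
#'
#' For each label the per-model scores are combined into the normalized
#' ratio `sPos / (sPos + sNeg)` (comparable across models); the label with
#' the largest ratio wins, ties going to the lexicographically smallest
#' label. In one-class mode a window whose positive density is below the
#' model's epsilon under every label is returned as `"outlier"`.
#'
#' @param model a [MultiClassRPModel-class].
#' @param x feature vector, d x N matrix or [FeatureSet-class].
#' @return character vector of predicted labels.
#' @export
predictLabels <- function(model, x) {
  stopifnot(is(model, "MultiClassRPModel"))
  if (is(x, "FeatureSet")) x <- featureMatrix(x)
  X <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
  sPos <- sNeg <- matrix(0, length(model@labels), ncol(X))
  for (i in seq_along(model@labels)) {
    sc <- classifyBinary(model@models[[model@labels[i]]], X)
    sPos[i, ] <- sc$scorePos
    sNeg[i, ] <- sc$scoreNeg
  }
  tot <- sPos + sNeg
  ratio <- ifelse(tot > 0, sPos / tot, 0)
  out <- model@labels[apply(ratio, 2, which.max)] # first max = smallest label
  if (model@oneClass) {
    out[apply(sPos < model@outlierThreshold, 2, all)] <- "outlier"
  }
  out
}
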