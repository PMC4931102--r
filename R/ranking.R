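# Descending-score ordering with ties broken toward the smaller feature id.
orderIds <- function(scores) {
  ids <- as.integer(names(scores))
  ids[order(-scores, ids)]
}

featureIdsOf <- function(X) {
  ids <- suppressWarnings(as.integer(sub("^f", "", rownames(X))))
  if (is.null(rownames(X)) || anyNA(ids)) ids <- seq_len(nrow(X))
  ids
}

#' ReliefF feature weights
#'
#' Classical ReliefF relevance weighting: every instance contributes a
#' penalty for the distance to its nearest same-class neighbours (hits) and
#' a prior-weighted reward for the distance to the nearest neighbours of
#' every other class (misses). All instances are used (no subsampling), so
#' the result is deterministic; distances are Manhattan on min-max-scaled
#' features, and per-feature differences are likewise min-max-scaled so the
#' weights stay in [-1, 1].
#'
#' @param X numeric d x N matrix or a [FeatureSet-class].
#' @param labels class label per column (activity labels of the
#'   FeatureSet when omitted).
#' @param nNeighbors hits/misses per class (default 10); every class must
#'   have at least `nNeighbors + 1` windows.
#' @param seed accepted for interface symmetry; the estimator itself is
#'   deterministic.
#' @return a [FeatureRanking-class] with method tag `"relieff"`.
#' @export
relieffWeights <- function(X, labels = NULL, nNeighbors = 10L, seed = 1L) {
  if (is(X, "FeatureSet")) {
    if (is.null(labels)) labels <- activityLabels(X)
    X <- featureMatrix(X)
  }
  X <- as.matrix(X)
  labels <- as.character(labels)
  stopIfNot(length(labels) == ncol(X), "one label per column required")
  nNeighbors <- as.integer(nNeighbors)
  lv <- sort(unique(labels))
  stopIfNot(length(lv) >= 2L, "need >= 2 classes")
  counts <- table(labels)
  small <- names(counts)[counts < nNeighbors + 1L]
  if (length(small)) {
    stop(
      "class(es) too small for nNeighbors = ", nNeighbors, ": ",
      paste(small, collapse = ", "), call. = FALSE
    )
  }

  rng <- apply(X, 1, max) - apply(X, 1, min)
  rng[rng == 0] <- 1
  U <- (X - apply(X, 1, min)) / rng # rows in [0, 1]
  D <- as.matrix(stats::dist(t(U), method = "manhattan"))
  priors <- as.numeric(counts[lv]) / ncol(X)
  names(priors) <- lv

  n <- ncol(X)
  w <- numeric(nrow(X))
  for (i in seq_len(n)) {
    ci <- labels[i]
    for (cl in lv) {
      pool <- which(labels == cl)
      pool <- pool[pool != i]
      nn <- pool[order(D[i, pool])][seq_len(nNeighbors)]
      diffs <- rowMeans(abs(U[, nn, drop = FALSE] - U[, i]))
      if (cl == ci) {
        w <- w - diffs / n
      } else {
        w <- w + (priors[cl] / (1 - priors[ci])) * diffs / n
      }
    }
  }
  w <- clip01(w) # bounded by construction up to accumulated rounding
  scores <- stats::setNames(w, featureIdsOf(X))
  new("FeatureRanking",
    scores = scores, ordering = orderIds(scores), method = "relieff",
    params = list(nNeighbors = nNeighbors, seed = seed)
  )
}

#' Two-class Gaussian divergence feature ranking
#'
#' Scores each feature by the symmetric Kullback-Leibler divergence of the
#' two per-class Gaussian fits,
#' `0.5 * ((v1/v2 + v2/v1 - 2) + (m1 - m2)^2 * (1/v1 + 1/v2))`,
#' with a variance floor of 1e-12; larger scores mean better class
#' separability. This is the classical "entropy" separability criterion
#' for two-sample feature ranking.
#'
#' @param X numeric d x N matrix or a [FeatureSet-class].
#' @param labels binary class label per column.
#' @return a [FeatureRanking-class] with method tag `"entropy"`.
#' @export
entropyRank <- function(X, labels = NULL) {
  if (is(X, "FeatureSet")) {
    if (is.null(labels)) labels <- activityLabels(X)
    X <- featureMatrix(X)
  }
  X <- as.matrix(X)
  labels <- as.character(labels)
  stopIfNot(length(labels) == ncol(X), "one label per column required")
  lv <- sort(unique(labels))
  if (length(lv) != 2L) {
    stop("exactly 2 classes required, got ", length(lv), call. = FALSE)
  }
  stopIfNot(all(table(labels) >= 2L), "each class needs >= 2 windows")

  X1 <- X[, labels == lv[1], drop = FALSE]
  X2 <- X[, labels == lv[2], drop = FALSE]
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- pmax(apply(X1, 1, stats::var), 1e-12)
  v2 <- pmax(apply(X2, 1, stats::var), 1e-12)
  s <- 0.5 * ((v1 / v2 + v2 / v1 - 2) + (m1 - m2)^2 * (1 / v1 + 1 / v2))
  scores <- stats::setNames(s, featureIdsOf(X))
  new("FeatureRanking",
    scores = scores, ordering = orderIds(scores), method = "entropy",
    params = list(classes = lv)
  )
}

#' Top-k feature ids of a ranking
#'
#' @param ranking a [FeatureRanking-class].
#' @param k how many ids (1..number of ranked features); score ties are
#'   broken toward the smaller id.
#' @return integer vector of the first `k` feature ids.
#' @export
topFeatures <- function(ranking, k) {
  stopifnot(is(ranking, "FeatureRanking"))
  k <- as.integer(k)
  if (k < 1L || k > length(ranking@ordering)) {
    stop(sprintf(
      "k must lie in 1..%d, got %d", length(ranking@ordering), k
    ), call. = FALSE)
  }
  ranking@ordering[seq_len(k)]
}
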