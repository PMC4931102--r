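#' Feature ids of the catalogue
#'
#' The catalogue numbers its 99 time-domain and physical features 4 through
#' 102 (ids 1-3 are reserved and unused, so published cross-references by
#' feature number resolve unchanged).
#'
#' @return integer vector 4:102.
#' @export
featureIds <- function() 4:102

CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz")

#' Cut a recording into fixed-length sliding windows
#'
#' @param record a [SensorRecord-class].
#' @param windowLen window length in samples (default 100, i.e. 1 s at
#'   100 Hz -- the span over which the "moving" statistics of the feature
#'   catalogue are defined).
#' @param step hop between window starts in samples (default 50, 50%
#'   overlap).
#' @return list of numeric `windowLen` x 6 matrices with columns
#'   `ax, ay, az, gx, gy, gz`; each carries attributes `start` (1-based
#'   index of its first sample) and `windowLen`.
#' @examples
#' rec <- generateRecord(activityProfile("still"), subjectProfile(), 2, seed = 1)
#' length(slidingWindows(rec, 100, 50))
#' @export
slidingWindows <- function(record, windowLen = 100L, step = 50L) {
  stopifnot(is(record, "SensorRecord"))
  windowLen <- as.integer(windowLen)
  step <- as.integer(step)
  stopIfNot(windowLen >= 2L, "'windowLen' must be >= 2")
  stopIfNot(step >= 1L, "'step' must be >= 1")
  L <- nrow(record@samples)
  if (L < windowLen) {
    stop(sprintf(
      "record too short: %s/%s/%s has %d samples, need %d",
      record@subjectId, record@activity, record@trialId, L, windowLen
    ), call. = FALSE)
  }
  sig <- as.matrix(record@samples[, CHANNELS])
  starts <- seq.int(1L, L - windowLen + 1L, by = step)
  lapply(starts, function(s) {
    w <- sig[s:(s + windowLen - 1L), , drop = FALSE]
    attr(w, "start") <- s
    attr(w, "windowLen") <- windowLen
    w
  })
}

# Angle series arccos((u * v) / (|u| * |v|)) between two scalar axis series,
# with the argument clipped to [-1, 1] and a zero denominator mapped to 0.
angleSeries <- function(u, v) {
  den <- abs(u) * abs(v)
  phi <- numeric(length(u))
  ok <- den > 0
  phi[ok] <- acos(clip01(u[ok] * v[ok] / den[ok]))
  phi
}

# Largest eigenvalue of the 3 x 3 sample covariance of a 3-column matrix.
firstEigen <- function(m) {
  max(eigen(stats::cov(m), symmetric = TRUE, only.values = TRUE)$values)
}

# Pearson correlation with zero-variance operands mapped to 0.
safeCor <- function(u, v) {
  if (stats::sd(u) == 0 || stats::sd(v) == 0) return(0)
  stats::cor(u, v)
}

#' Compute the full 99-entry feature vector of one window
#'
#' Evaluates every catalogue feature on a single window. Per-sample
#' ("instantaneous") features -- the raw axis readings (ids 4-9), movement
#' intensities (16-18) and polar coordinates (22-30) -- are taken at the
#' window's last sample; all "moving" statistics are computed within the
#' window, and cumulative sums restart at the window start. Conventions for
#' degenerate inputs: correlations with a zero-variance operand are 0,
#' arccos arguments are clipped to [-1, 1], angle terms with a zero
#' denominator and projections onto a zero gyroscope vector are 0. Any
#' residual non-finite value is set to 0.
#'
#' @param window a `windowLen` x 6 numeric matrix as produced by
#'   [slidingWindows()] (columns `ax, ay, az, gx, gy, gz`), at least 2 rows.
#' @return named numeric vector of length 99 with names `f4` ... `f102`.
#' @export
extractFeatures <- function(window) {
  w <- as.matrix(window)
  stopIfNot(ncol(w) == 6L, "window must have 6 channels")
  n <- nrow(w)
  stopIfNot(n >= 2L, "window must have >= 2 samples")
  colnames(w) <- CHANNELS
  a <- w[, 1:3, drop = FALSE]
  g <- w[, 4:6, drop = FALSE]
  dag <- a - g
  out <- numeric(99)
  names(out) <- paste0("f", featureIds())
  put <- function(ids, vals) out[paste0("f", ids)] <<- vals

  last <- w[n, ]
  put(4:9, last)                                   # a_x..g_z at last sample
  put(10:15, apply(w, 2, var))                     # moving variances

  miA <- sqrt(rowSums(a^2))
  miG <- sqrt(rowSums(g^2))
  miGA <- sqrt(rowSums((g - a)^2))
  put(16:18, c(miA[n], miG[n], miGA[n]))           # movement intensities
  put(19:21, c(var(miA), var(miG), var(miGA)))

  put(22:24, c(atan2(last["ay"], last["ax"]),
               sqrt(last["ax"]^2 + last["ay"]^2), last["az"]))
  put(25:27, c(atan2(last["gy"], last["gx"]),
               sqrt(last["gx"]^2 + last["gy"]^2), last["gz"]))
  dl <- last[1:3] - last[4:6]
  put(28:30, c(atan2(dl[2], dl[1]), sqrt(dl[1]^2 + dl[2]^2), dl[3]))

  put(31, sum(abs(a)) / n)                         # signal magnitude areas
  put(32, sum(abs(g)) / n)
  put(33, sum(abs(dag)) / n)

  put(34:36, c(firstEigen(a), firstEigen(g), firstEigen(dag)))
  put(37:42, colMeans(w^2))                        # moving energies
  put(43:48, apply(w, 2, max) - apply(w, 2, min))  # moving ranges

  put(49, safeCor(a[, 1], a[, 2]))
  put(50, safeCor(a[, 1], a[, 3]))
  put(51, safeCor(a[, 2], a[, 3]))
  put(52, safeCor(g[, 1], g[, 2]))
  put(53, safeCor(g[, 1], g[, 3]))
  put(54, safeCor(g[, 2], g[, 3]))

  # componentwise projection of mean acceleration onto the mean gyroscope
  # direction, ((a.g)/|g|^2) g, from window-mean vectors
  ma <- colMeans(a); mg <- colMeans(g)
  g2 <- sum(mg^2)
  put(55:57, if (g2 == 0) c(0, 0, 0) else (sum(ma * mg) / g2) * mg)

  phiA <- angleSeries(a[, 1], a[, 2])
  put(58:60, c(mean(phiA), var(phiA), mean(phiA^2)))

  put(61:63, colMeans(dag^2))                      # per-axis a-g energies
  put(64, mean((a[, 1] - a[, 2])^2))
  put(65, mean((a[, 1] - a[, 3])^2))
  put(66, mean((a[, 2] - a[, 3])^2))

  phiD <- angleSeries(dag[, 1], dag[, 2])
  put(67:69, c(mean(phiD), var(phiD), mean(phiD^2)))
  phiG <- angleSeries(g[, 1], g[, 2])
  put(70:72, c(mean(phiG), var(phiG), mean(phiG^2)))
  phiAG <- phiA - phiG
  put(73:75, c(mean(phiAG), var(phiAG), mean(phiAG^2)))

  s1 <- apply(w, 2, cumsum)                        # first-order cumsum
  mcs <- colSums(s1)                               # double cumulative sums
  put(76:81, mcs)
  put(82, sum(abs(s1[, 1:3])) / n)                 # SMA of cumulative sums
  put(83, sum(abs(s1[, 4:6])) / n)
  put(84, sum(abs(s1[, 1:3] - s1[, 4:6])) / n)
  put(85:90, colSums(apply(s1, 2, cumsum)))        # second-order sums
  put(91:93, colSums(apply(s1[, 1:3] - s1[, 4:6], 2, cumsum)))

  put(94:96, c(atan2(mcs[2], mcs[1]), sqrt(mcs[1]^2 + mcs[2]^2), mcs[3]))
  put(97:99, c(atan2(mcs[5], mcs[4]), sqrt(mcs[4]^2 + mcs[5]^2), mcs[6]))
  dm <- mcs[1:3] - mcs[4:6]
  put(100:102, c(atan2(dm[2], dm[1]), sqrt(dm[1]^2 + dm[2]^2), dm[3]))

  out[!is.finite(out)] <- 0
  out
}

#' Compute a single catalogue feature
#'
#' @param featureId integer id in 4..102.
#' @param window window matrix as for [extractFeatures()].
#' @return the feature value (deterministic for a given window).
#' @export
computeFeature <- function(featureId, window) {
  featureId <- as.integer(featureId)
  if (length(featureId) != 1L || !(featureId %in% featureIds())) {
    stop(sprintf(
      "unknown feature id %s; valid ids are %d..%d",
      paste(featureId, collapse = ","), min(featureIds()), max(featureIds())
    ), call. = FALSE)
  }
  unname(extractFeatures(window)[paste0("f", featureId)])
}

#' Assemble the feature-by-window observation matrix
#'
#' Windows every record and evaluates the 99-feature catalogue on each
#' window. Columns are ordered by (record order, window start) and labelled
#' with the source record's activity and subject tokens.
#'
#' @param records list of [SensorRecord-class] objects; every record must
#'   be at least `windowLen` samples long.
#' @inheritParams slidingWindows
#' @return a [FeatureSet-class] (99 x N `SummarizedExperiment`).
#' @export
buildFeatureMatrix <- function(records, windowLen = 100L, step = 50L) {
  if (is(records, "SensorRecord")) records <- list(records)
  stopIfNot(length(records) >= 1L, "need at least one record")
  stopIfNot(
    all(vapply(records, is, logical(1), "SensorRecord")),
    "'records' must be SensorRecord objects"
  )
  cols <- list(); meta <- list()
  for (rec in records) {
    wins <- slidingWindows(rec, windowLen, step)
    feats <- vapply(wins, extractFeatures, numeric(99))
    cols[[length(cols) + 1L]] <- feats
    meta[[length(meta) + 1L]] <- data.frame(
      activity = rec@activity, subject = rec@subjectId,
      trial = rec@trialId,
      windowStart = vapply(wins, attr, integer(1), "start"),
      windowLen = as.integer(windowLen)
    )
  }
  X <- do.call(cbind, cols)
  cd <- do.call(rbind, meta)
  colnames(X) <- sprintf("w%04d", seq_len(ncol(X)))
  rownames(cd) <- colnames(X)
  new("FeatureSet", SummarizedExperiment::SummarizedExperiment(
    assays = list(features = X), colData = S4Vectors::DataFrame(cd)
  ))
}

# Internal: wrap a bare labelled matrix as a FeatureSet.
featureSetFromMatrix <- function(X, activity, subject = "sim") {
  if (is.null(rownames(X))) rownames(X) <- paste0("f", seq_len(nrow(X)) + 3L)
  colnames(X) <- sprintf("w%04d", seq_len(ncol(X)))
  subject <- rep_len(subject, ncol(X))
  cd <- S4Vectors::DataFrame(
    activity = as.character(activity), subject = as.character(subject),
    row.names = colnames(X)
  )
  new("FeatureSet", SummarizedExperiment::SummarizedExperiment(
    assays = list(features = X), colData = cd
  ))
}
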