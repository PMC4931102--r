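#' Draw a sparse Achlioptas random projection matrix
#'
#' Entries are independently +scale with probability 1/6, 0 with
#' probability 2/3 and -scale with probability 1/6, drawn row-major from a
#' single seeded stream so the same `(k, d, seed, scale)` always yields the
#' same matrix. The classifier is invariant to a global rescaling of the
#' matrix, so the default entry magnitude is 1; pass `scale = sqrt(3)` for
#' the variance-preserving normalization.
#'
#' @param k target dimension (rows), `1 <= k <= d`.
#' @param d source dimension (columns).
#' @param seed integer seed.
#' @param scale positive entry magnitude.
#' @return a [ProjectionMatrix-class].
#' @examples
#' R <- sampleProjectionMatrix(2, 99, seed = 7)
#' table(projectionMatrix(R)) / (2 * 99)
#' @export
sampleProjectionMatrix <- function(k, d, seed, scale = 1) {
  k <- as.integer(k); d <- as.integer(d)
  if (k < 1L || k > d) {
    stop(sprintf("need 1 <= k <= d, got k = %d, d = %d", k, d), call. = FALSE)
  }
  stopIfNot(scale > 0, "'scale' must be positive")
  entries <- withLocalSeed(seed, sample(
    c(-scale, 0, scale), k * d, replace = TRUE, prob = c(1 / 6, 2 / 3, 1 / 6)
  ))
  new("ProjectionMatrix",
    mat = matrix(entries, nrow = k, ncol = d, byrow = TRUE),
    scale = scale, seed = as.numeric(seed)
  )
}

# Internal: deterministic selector projection picking the given feature rows.
selectorProjection <- function(featureRows, d) {
  m <- matrix(0, nrow = length(featureRows), ncol = d)
  m[cbind(seq_along(featureRows), featureRows)] <- 1
  new("ProjectionMatrix", mat = m, scale = 1, seed = NA_real_)
}

#' Project observations to the low-dimensional space
#'
#' Exact matrix product `R %*% X`; linear in `X`.
#'
#' @param projection a [ProjectionMatrix-class].
#' @param X numeric d x N matrix (observations in columns).
#' @return numeric k x N matrix.
#' @export
projectData <- function(projection, X) {
  stopifnot(is(projection, "ProjectionMatrix"))
  X <- as.matrix(X)
  if (ncol(projection@mat) != nrow(X)) {
    stop(sprintf(
      "dimension mismatch: projection is %d x %d but X is %d x %d",
      nrow(projection@mat), ncol(projection@mat), nrow(X), ncol(X)
    ), call. = FALSE)
  }
  projection@mat %*% X
}

#' Z-score features by row
#'
#' Standardizes each feature row to mean 0 and unit (sample) standard
#' deviation. Raw catalogue features span several orders of magnitude, so
#' without this step a handful of large-scale features would dominate every
#' random projection. Zero-variance rows are flagged degenerate and divided
#' by 1 (so they map to all zeros). When `stats` is supplied, those frozen
#' training statistics are applied unchanged (test-time use).
#'
#' @param X numeric d x N matrix.
#' @param stats optional [StandardizationStats-class] from a previous call.
#' @return list with elements `X` (standardized matrix) and `stats`.
#' @export
standardizeFeatures <- function(X, stats = NULL) {
  X <- as.matrix(X)
  stopIfNot(ncol(X) >= 1L, "X must have at least one column")
  if (is.null(stats)) {
    ctr <- rowMeans(X)
    sc <- apply(X, 1, stats::sd)
    if (ncol(X) == 1L) sc[] <- 0
    degen <- !is.finite(sc) | sc == 0
    sc[degen] <- 1
    stats <- new("StandardizationStats",
      center = ctr, scale = sc, degenerate = degen
    )
  } else {
    stopifnot(is(stats, "StandardizationStats"))
    if (length(stats@center) != nrow(X)) {
      stop(sprintf(
        "stats cover %d features but X has %d rows",
        length(stats@center), nrow(X)
      ), call. = FALSE)
    }
  }
  list(X = (X - stats@center) / stats@scale, stats = stats)
}
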