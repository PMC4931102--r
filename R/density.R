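# Silverman's rule-of-thumb bandwidth; degenerate samples (zero spread)
# fall back to a small positive width so the density stays proper.
silvermanBandwidth <- function(x) {
  s <- if (length(x) > 1L) stats::sd(x) else 0
  if (!is.finite(s) || s == 0) return(max(1e-3, 1e-3 * abs(mean(x))))
  1.06 * s * length(x)^(-1 / 5)
}

#' Fit a one-dimensional Gaussian kernel density estimate
#'
#' Stores the sample points and the bandwidth; evaluation is the Parzen
#' sum `(1/(N h)) * sum_i K((x - x_i)/h)` with the standard Gaussian
#' kernel. The default bandwidth is Silverman's rule
#' `h = 1.06 * sd(x) * N^(-1/5)`, with a small positive fallback for
#' zero-spread samples.
#'
#' @param samples numeric vector, at least one point.
#' @param bandwidth optional positive bandwidth; default Silverman.
#' @return a [KernelDensity1D-class].
#' @examples
#' evalKde(fitKde(0, bandwidth = 1), 0) # 1/sqrt(2*pi)
#' @export
fitKde <- function(samples, bandwidth = NULL) {
  samples <- as.numeric(samples)
  stopIfNot(length(samples) >= 1L, "need at least one sample")
  if (is.null(bandwidth)) {
    bandwidth <- silvermanBandwidth(samples)
  } else {
    stopIfNot(
      is.numeric(bandwidth) && length(bandwidth) == 1L && bandwidth > 0,
      "'bandwidth' must be a single positive number"
    )
  }
  new("KernelDensity1D", samples = samples, bandwidth = bandwidth)
}

#' Evaluate a 1-D kernel density estimate
#'
#' @param model a [KernelDensity1D-class].
#' @param x numeric vector of evaluation points.
#' @return numeric vector of density values (>= 0).
#' @export
evalKde <- function(model, x) {
  stopifnot(is(model, "KernelDensity1D"))
  h <- model@bandwidth
  s <- model@samples
  # column = evaluation point
  u <- outer(s, as.numeric(x), function(si, xi) (xi - si) / h)
  colMeans(stats::dnorm(u)) / h
}

#' Build a product joint density from projected class samples
#'
#' Each row of `Z` (one projected dimension) gets its own 1-D KDE; the
#' joint density is their product -- no multivariate kernel is used.
#'
#' @param Z numeric k x N matrix of projected observations.
#' @param bandwidths optional numeric vector of per-dimension bandwidths.
#' @return a [JointDensity-class].
#' @export
jointDensity <- function(Z, bandwidths = NULL) {
  Z <- rbind(Z)
  dims <- lapply(seq_len(nrow(Z)), function(i) {
    fitKde(Z[i, ], if (is.null(bandwidths)) NULL else bandwidths[i])
  })
  new("JointDensity", dims = dims)
}

#' Evaluate a product joint density
#'
#' @param joint a [JointDensity-class] over k dimensions.
#' @param point numeric k-vector, or k x N matrix to evaluate N points.
#' @return nonnegative density value(s).
#' @export
evalJoint <- function(joint, point) {
  stopifnot(is(joint, "JointDensity"))
  k <- length(joint@dims)
  Z <- if (is.matrix(point)) point else matrix(point, ncol = 1L)
  if (nrow(Z) != k) {
    stop(sprintf(
      "dimension mismatch: joint density has k = %d but point has %d",
      k, nrow(Z)
    ), call. = FALSE)
  }
  out <- rep(1, ncol(Z))
  for (i in seq_len(k)) out <- out * evalKde(joint@dims[[i]], Z[i, ])
  if (!is.matrix(point)) out[[1L]] else out
}

#' Shared evaluation grid for two joint densities
#'
#' Per dimension the grid spans `[min(both samples) - 3 h_max,
#' max(both samples) + 3 h_max]`, where `h_max` is the larger of the two
#' class bandwidths, so both densities have decayed to a negligible level
#' at the boundary.
#'
#' @param jointA,jointB [JointDensity-class] objects of equal dimension.
#' @param resolution grid points per dimension (default 256).
#' @return an [EvaluationGrid-class].
#' @export
makeSharedGrid <- function(jointA, jointB, resolution = 256L) {
  stopifnot(is(jointA, "JointDensity"), is(jointB, "JointDensity"))
  k <- length(jointA@dims)
  stopIfNot(length(jointB@dims) == k, "densities must share dimension k")
  lo <- numeric(k); hi <- numeric(k)
  for (i in seq_len(k)) {
    da <- jointA@dims[[i]]; db <- jointB@dims[[i]]
    hmax <- max(da@bandwidth, db@bandwidth)
    lo[i] <- min(da@samples, db@samples) - 3 * hmax
    hi[i] <- max(da@samples, db@samples) + 3 * hmax
  }
  new("EvaluationGrid",
    lower = lo, upper = hi, resolution = as.integer(resolution)
  )
}

gridPoints <- function(grid, dim) {
  seq(grid@lower[dim], grid@upper[dim], length.out = grid@resolution)
}

#' Jaccard distance between two densities on a shared grid
#'
#' Discretizes both joint densities on the grid and returns
#' `1 - sum(min(fA, fB)) / sum(max(fA, fB))` over all cells (the cell
#' volume cancels). This is the overlap-over-union dissimilarity of the two
#' probability masses: 0 for identical densities, 1 for disjoint supports;
#' it is symmetric and a metric (the Marczewski-Steinhaus distance).
#'
#' @param jointA,jointB [JointDensity-class] objects.
#' @param grid an [EvaluationGrid-class] of the same dimension. Both
#'   product densities are evaluated exactly on its cells; dimensions above
#'   2 are supported but the cell count grows as `resolution^k`.
#' @return numeric distance in [0, 1].
#' @export
jaccardDistance <- function(jointA, jointB, grid) {
  stopifnot(is(grid, "EvaluationGrid"))
  k <- length(jointA@dims)
  stopIfNot(
    length(jointB@dims) == k && length(grid@lower) == k,
    "densities and grid must share dimension k"
  )
  fa <- vector("list", k); fb <- vector("list", k)
  for (i in seq_len(k)) {
    g <- gridPoints(grid, i)
    fa[[i]] <- evalKde(jointA@dims[[i]], g)
    fb[[i]] <- evalKde(jointB@dims[[i]], g)
  }
  A <- Reduce(outer, fa)
  B <- Reduce(outer, fb)
  denom <- sum(pmax(A, B))
  if (denom == 0) {
    message("jaccardDistance: both densities vanish on the grid; returning 1")
    return(1)
  }
  1 - sum(pmin(A, B)) / denom
}
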