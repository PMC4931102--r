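#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' One subject/activity/trial 6-axis inertial recording
#'
#' Holds a single trial of tri-axial accelerometer (in g) and gyroscope
#' (in deg/s) samples together with its metadata. Samples are stored as a
#' data frame with columns `t, ax, ay, az, gx, gy, gz` and must be strictly
#' time-ordered.
#'
#' @slot subjectId character scalar, subject token (e.g. `"S1"`).
#' @slot activity character scalar, activity token (e.g. `"WF"`).
#' @slot trialId character scalar, trial token.
#' @slot rateHz positive sampling rate in samples/second.
#' @slot samples data.frame of sensor samples.
#'
#' @seealso [sensorRecord()], [slidingWindows()]
#' @export
setClass("SensorRecord", representation(
  subjectId = "character",
  activity = "character",
  trialId = "character",
  rateHz = "numeric",
  samples = "data.frame"
))

setValidity("SensorRecord", function(object) {
  s <- object@samples
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(s))) {
    return(paste("samples must have columns", paste(need, collapse = ", ")))
  }
  if (length(object@rateHz) != 1L || object@rateHz <= 0) {
    return("rateHz must be a single positive number")
  }
  if (nrow(s) > 0) {
    if (!all(vapply(s[need], function(x) all(is.finite(x)), logical(1)))) {
      return("all sample values must be finite")
    }
    if (any(s$t < 0)) return("time must be nonnegative")
    if (nrow(s) > 1 && any(diff(s$t) <= 0)) {
      return("samples must be strictly time-ordered")
    }
  }
  TRUE
})

#' Construct a SensorRecord
#'
#' @param subjectId,activity,trialId metadata tokens.
#' @param samples data.frame with columns `t, ax, ay, az, gx, gy, gz`.
#' @param rateHz sampling rate in Hz.
#' @return A [SensorRecord-class] object.
#' @export
sensorRecord <- function(subjectId, activity, trialId, samples, rateHz = 100) {
  new("SensorRecord",
    subjectId = as.character(subjectId), activity = as.character(activity),
    trialId = as.character(trialId), rateHz = as.numeric(rateHz),
    samples = as.data.frame(samples)
  )
}

#' Windowed feature matrix with per-window labels
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay holds
#' the feature-by-window observation matrix X (features in rows, windows in
#' columns). `colData` carries the `activity` and `subject` token of each
#' window plus its start index and length in the source recording.
#'
#' @seealso [buildFeatureMatrix()], [featureMatrix()]
#' @export
setClass("FeatureSet", contains = "SummarizedExperiment")

setValidity("FeatureSet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("activity", "subject") %in% names(cd))) {
    return("colData must contain 'activity' and 'subject'")
  }
  if (is.null(rownames(object))) return("feature rows must be named")
  TRUE
})

#' Sparse random projection matrix
#'
#' A k x d matrix with entries in {-scale, 0, +scale}, drawn with
#' probabilities (1/6, 2/3, 1/6) in the sparse scheme of Achlioptas, or a
#' deterministic feature selector for baseline models.
#'
#' @slot mat numeric k x d matrix.
#' @slot scale positive entry magnitude.
#' @slot seed integer seed the matrix was drawn with (NA for selectors).
#' @export
setClass("ProjectionMatrix", representation(
  mat = "matrix", scale = "numeric", seed = "numeric"
))

setValidity("ProjectionMatrix", function(object) {
  k <- nrow(object@mat); d <- ncol(object@mat)
  if (k < 1L || d < k) return("need 1 <= k <= d")
  if (length(object@scale) != 1L || object@scale <= 0) {
    return("scale must be a single positive number")
  }
  vals <- unique(as.vector(object@mat))
  ok <- c(-object@scale, 0, object@scale)
  if (!all(vapply(vals, function(v) any(abs(v - ok) < 1e-12), logical(1)))) {
    return("entries must lie in {-scale, 0, +scale}")
  }
  TRUE
})

#' Per-feature standardization statistics
#'
#' Training-set means and standard deviations used to z-score features
#' before projection; frozen at training time and re-applied at prediction.
#' Zero-variance (degenerate) features are flagged and divided by 1.
#'
#' @slot center,scale numeric vectors of length d.
#' @slot degenerate logical vector flagging zero-variance features.
#' @export
setClass("StandardizationStats", representation(
  center = "numeric", scale = "numeric", degenerate = "logical"
))

setValidity("StandardizationStats", function(object) {
  if (length(object@center) != length(object@scale) ||
    length(object@center) != length(object@degenerate)) {
    return("center, scale and degenerate must have equal length")
  }
  if (any(object@scale < 0)) return("scale entries must be >= 0")
  TRUE
})

#' One-dimensional Gaussian kernel density model
#'
#' Parzen estimate f(x) = (1/(N h)) * sum_i K((x - x_i)/h) with standard
#' Gaussian kernel K; stores the sample points and the bandwidth.
#'
#' @slot samples numeric sample points (at least one).
#' @slot bandwidth positive smoothing bandwidth h.
#' @export
setClass("KernelDensity1D", representation(
  samples = "numeric", bandwidth = "numeric"
))

setValidity("KernelDensity1D", function(object) {
  if (length(object@samples) < 1L) return("need at least one sample point")
  if (!all(is.finite(object@samples))) return("samples must be finite")
  if (length(object@bandwidth) != 1L || !is.finite(object@bandwidth) ||
    object@bandwidth <= 0) {
    return("bandwidth must be a single positive number")
  }
  TRUE
})

#' Product joint density over k projected dimensions
#'
#' The joint density of a projected class is modelled as the product of
#' independent per-dimension kernel density estimates.
#'
#' @slot dims list of [KernelDensity1D-class], one per dimension.
#' @export
setClass("JointDensity", representation(dims = "list"))

setValidity("JointDensity", function(object) {
  if (length(object@dims) < 1L) return("need k >= 1 dimensions")
  if (!all(vapply(object@dims, is, logical(1), "KernelDensity1D"))) {
    return("every dimension must be a KernelDensity1D")
  }
  TRUE
})

#' Shared evaluation grid for comparing two densities
#'
#' Regular per-dimension grids covering both classes' samples padded by
#' three bandwidths, on which the Jaccard overlap of two joint densities is
#' discretized.
#'
#' @slot lower,upper numeric per-dimension bounds.
#' @slot resolution integer points per dimension (>= 16).
#' @export
setClass("EvaluationGrid", representation(
  lower = "numeric", upper = "numeric", resolution = "integer"
))

setValidity("EvaluationGrid", function(object) {
  if (length(object@lower) != length(object@upper)) {
    return("lower and upper must have equal length")
  }
  if (any(object@lower >= object@upper)) return("need lower < upper")
  if (length(object@resolution) != 1L || object@resolution < 16L) {
    return("resolution must be >= 16")
  }
  TRUE
})

#' Binary random-projection density classifier
#'
#' The trained binary model: the winning projection, the frozen
#' standardization statistics, one product-KDE per class, the shared grid
#' the classes were compared on, and the separation (Jaccard distance)
#' achieved by the kept projection.
#'
#' @slot projection [ProjectionMatrix-class].
#' @slot standardization [StandardizationStats-class].
#' @slot posDensity,negDensity [JointDensity-class] per class.
#' @slot grid [EvaluationGrid-class] shared by the two classes.
#' @slot separation best Jaccard distance found, in [0, 1].
#' @slot labels character 2-vector (positive, negative).
#' @slot trainCounts integer 2-vector (n positive, n negative windows).
#' @slot config list snapshot (k, trials, seed, bandwidth rule, ...).
#' @export
setClass("BinaryRPModel", representation(
  projection = "ProjectionMatrix",
  standardization = "StandardizationStats",
  posDensity = "JointDensity",
  negDensity = "JointDensity",
  grid = "EvaluationGrid",
  separation = "numeric",
  labels = "character",
  trainCounts = "integer",
  config = "list"
))

setValidity("BinaryRPModel", function(object) {
  if (length(object@separation) != 1L || object@separation < 0 ||
    object@separation > 1) {
    return("separation must lie in [0, 1]")
  }
  k <- nrow(object@projection@mat)
  if (length(object@posDensity@dims) != k ||
    length(object@negDensity@dims) != k) {
    return("densities must share the projection dimension k")
  }
  if (length(object@labels) != 2L) return("labels must be length 2")
  TRUE
})

#' One-vs-rest multi-class model with optional outlier rule
#'
#' One [BinaryRPModel-class] per label (that label against the pooled
#' rest). Prediction compares the normalized positive-density ratios across
#' the per-label models; in one-class mode a window whose positive density
#' falls below `outlierThreshold` under every model is declared an outlier.
#'
#' @slot models named list of [BinaryRPModel-class], one per label.
#' @slot outlierThreshold nonnegative density threshold epsilon.
#' @slot oneClass logical; apply the outlier rule when predicting?
#' @slot labels character vector of class labels (sorted).
#' @export
setClass("MultiClassRPModel", representation(
  models = "list", outlierThreshold = "numeric",
  oneClass = "logical", labels = "character"
))

setValidity("MultiClassRPModel", function(object) {
  if (length(object@labels) < 2L) return("need >= 2 labels")
  if (!identical(sort(object@labels), sort(names(object@models)))) {
    return("every label needs a model")
  }
  if (object@outlierThreshold < 0) return("outlierThreshold must be >= 0")
  TRUE
})

#' Feature ranking result
#'
#' Per-feature relevance scores and the induced ordering (descending score,
#' ties broken toward the smaller feature id).
#'
#' @slot scores named numeric vector (names are feature ids).
#' @slot ordering integer feature ids sorted by decreasing score.
#' @slot method character tag (`"relieff"` or `"entropy"`).
#' @slot params list parameter snapshot.
#' @export
setClass("FeatureRanking", representation(
  scores = "numeric", ordering = "integer",
  method = "character", params = "list"
))

setValidity("FeatureRanking", function(object) {
  ids <- as.integer(names(object@scores))
  if (anyNA(ids)) return("scores must be named by integer feature ids")
  if (!setequal(object@ordering, ids)) {
    return("ordering must be a permutation of the scored ids")
  }
  TRUE
})

#' Cross-validated evaluation report
#'
#' Confusion matrix plus per-class one-vs-rest metrics (accuracy,
#' precision, recall/sensitivity, specificity, F-score) and their
#' unweighted grand means.
#'
#' @slot confusion square count matrix, true labels in rows.
#' @slot perClass data.frame of per-class metrics.
#' @slot grandMeans named numeric grand means.
#' @slot folds integer per-window fold assignment (may be empty).
#' @slot seed numeric seed used (NA if not applicable).
#' @slot config list snapshot.
#' @export
setClass("EvaluationReport", representation(
  confusion = "matrix", perClass = "data.frame",
  grandMeans = "numeric", folds = "integer",
  seed = "numeric", config = "list"
))

#' Pairwise binary activity accuracy matrix
#'
#' Symmetric activity x activity table of cross-validated binary accuracies
#' with unit diagonal, the per-activity column means (computed over all
#' entries including the diagonal), and an optional baseline row from
#' two-feature selector models.
#'
#' @slot accuracy symmetric numeric matrix, diagonal 1.
#' @slot columnMeans named numeric column means.
#' @slot baseline named numeric baseline row (length 0 if not computed).
#' @slot config list snapshot.
#' @export
setClass("PairwiseMatrix", representation(
  accuracy = "matrix", columnMeans = "numeric",
  baseline = "numeric", config = "list"
))

setValidity("PairwiseMatrix", function(object) {
  a <- object@accuracy
  if (nrow(a) != ncol(a)) return("accuracy matrix must be square")
  # published tables are rounded to 3 decimals, so allow that much asymmetry
  if (max(abs(a - t(a))) > 1e-3 + 1e-9) {
    return("accuracy matrix must be symmetric")
  }
  if (any(abs(diag(a) - 1) > 1e-12)) return("diagonal must be 1")
  if (any(a < 0 | a > 1)) return("entries must lie in [0, 1]")
  TRUE
})
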