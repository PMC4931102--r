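#' Extract the feature-by-window matrix
#'
#' @param x a [FeatureSet-class].
#' @return numeric d x N matrix (features in rows).
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname featureMatrix
setMethod("featureMatrix", "FeatureSet", function(x) {
  SummarizedExperiment::assay(x, "features")
})

#' Per-window activity labels
#' @param x a [FeatureSet-class].
#' @return character vector, one token per window.
#' @export
setGeneric("activityLabels", function(x) standardGeneric("activityLabels"))

#' @rdname activityLabels
setMethod("activityLabels", "FeatureSet", function(x) {
  as.character(SummarizedExperiment::colData(x)$activity)
})

#' Per-window subject labels
#' @param x a [FeatureSet-class].
#' @return character vector, one token per window.
#' @export
setGeneric("subjectLabels", function(x) standardGeneric("subjectLabels"))

#' @rdname subjectLabels
setMethod("subjectLabels", "FeatureSet", function(x) {
  as.character(SummarizedExperiment::colData(x)$subject)
})

#' Separation (Jaccard distance) achieved by a trained model
#' @param x a [BinaryRPModel-class].
#' @return numeric in [0, 1].
#' @export
setGeneric("separationScore", function(x) standardGeneric("separationScore"))

#' @rdname separationScore
setMethod("separationScore", "BinaryRPModel", function(x) x@separation)

#' Projection matrix of a trained model
#' @param x a [BinaryRPModel-class] or [ProjectionMatrix-class].
#' @return numeric k x d matrix.
#' @export
setGeneric("projectionMatrix", function(x) standardGeneric("projectionMatrix"))

#' @rdname projectionMatrix
setMethod("projectionMatrix", "BinaryRPModel", function(x) x@projection@mat)

#' @rdname projectionMatrix
setMethod("projectionMatrix", "ProjectionMatrix", function(x) x@mat)

#' Class labels of a model
#' @param x a [BinaryRPModel-class] or [MultiClassRPModel-class].
#' @return character vector of labels.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname classLabels
setMethod("classLabels", "BinaryRPModel", function(x) x@labels)

#' @rdname classLabels
setMethod("classLabels", "MultiClassRPModel", function(x) x@labels)

setMethod("show", "SensorRecord", function(object) {
  cat(
    "SensorRecord", sprintf(
      "%s/%s/%s: %d samples @ %g Hz\n",
      object@subjectId, object@activity, object@trialId,
      nrow(object@samples), object@rateHz
    )
  )
})

setMethod("show", "ProjectionMatrix", function(object) {
  m <- object@mat
  cat(sprintf(
    "ProjectionMatrix %d x %d (scale %g, %.1f%% zero)\n",
    nrow(m), ncol(m), object@scale, 100 * mean(m == 0)
  ))
})

setMethod("show", "KernelDensity1D", function(object) {
  cat(sprintf(
    "KernelDensity1D: %d points, bandwidth %.4g\n",
    length(object@samples), object@bandwidth
  ))
})

setMethod("show", "BinaryRPModel", function(object) {
  cat(sprintf(
    "BinaryRPModel %s vs %s: k = %d, separation %.3f (n = %d/%d)\n",
    object@labels[1], object@labels[2], nrow(object@projection@mat),
    object@separation, object@trainCounts[1], object@trainCounts[2]
  ))
})

setMethod("show", "MultiClassRPModel", function(object) {
  cat(sprintf(
    "MultiClassRPModel: %d one-vs-rest models (%s)\n",
    length(object@models), paste(object@labels, collapse = ", ")
  ))
  sep <- vapply(object@models, slot, numeric(1), "separation")
  cat("  separations:", paste(sprintf("%.3f", sep), collapse = " "), "\n")
})

setMethod("show", "FeatureRanking", function(object) {
  cat(sprintf(
    "FeatureRanking (%s): top ids %s\n", object@method,
    paste(utils::head(object@ordering, 5), collapse = ", ")
  ))
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport:", sum(object@confusion), "test windows,",
    nrow(object@confusion), "classes\n")
  gm <- object@grandMeans
  cat("  grand means:", paste(
    sprintf("%s %.3f", names(gm), gm), collapse = ", "
  ), "\n")
})

setMethod("show", "PairwiseMatrix", function(object) {
  cat(sprintf(
    "PairwiseMatrix: %d activities, mean of column means %.3f\n",
    nrow(object@accuracy), mean(object@columnMeans)
  ))
})
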