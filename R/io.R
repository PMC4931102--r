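#' Read one trial CSV
#'
#' Trial files have a header `t,ax,ay,az,gx,gy,gz` and one row per sample;
#' metadata defaults to the `<subject>_<activity>_<trial>.csv` file-name
#' convention when not given explicitly.
#'
#' @param path CSV file path.
#' @param subjectId,activity,trialId optional metadata overrides.
#' @param rateHz sampling rate; inferred from the median time step when
#'   `NULL`.
#' @return a [SensorRecord-class].
#' @export
readTrialCsv <- function(path, subjectId = NULL, activity = NULL,
                         trialId = NULL, rateHz = NULL) {
  df <- utils::read.csv(path)
  parts <- strsplit(sub("\\.csv$", "", basename(path)), "_")[[1]]
  if (is.null(subjectId)) subjectId <- parts[1]
  if (is.null(activity)) activity <- if (length(parts) > 1) parts[2] else "NA"
  if (is.null(trialId)) trialId <- if (length(parts) > 2) parts[3] else "T1"
  if (is.null(rateHz)) {
    rateHz <- if (nrow(df) > 1) 1 / stats::median(diff(df$t)) else 100
  }
  sensorRecord(subjectId, activity, trialId, df, rateHz)
}

#' Write one trial CSV
#'
#' @param record a [SensorRecord-class].
#' @param dir output directory; the file is named
#'   `<subject>_<activity>_<trial>.csv`.
#' @return the written path, invisibly.
#' @export
writeTrialCsv <- function(record, dir = ".") {
  stopifnot(is(record, "SensorRecord"))
  path <- file.path(dir, sprintf(
    "%s_%s_%s.csv", record@subjectId, record@activity, record@trialId
  ))
  utils::write.csv(record@samples, path, row.names = FALSE)
  invisible(path)
}

#' Write a dataset of trials plus manifest
#'
#' @param records list of [SensorRecord-class] objects.
#' @param dir output directory (created if missing). A `manifest.csv`
#'   listing `file,subject,activity,trial` is written alongside the trials.
#' @return the manifest path, invisibly.
#' @export
writeDatasetCsv <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(records, function(r) {
    p <- writeTrialCsv(r, dir)
    data.frame(
      file = basename(p), subject = r@subjectId,
      activity = r@activity, trial = r@trialId
    )
  })
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), mp, row.names = FALSE)
  invisible(mp)
}

#' Read a directory of trial CSVs
#'
#' Reads every trial listed in `manifest.csv` when present, otherwise all
#' `*.csv` files named by the `<subject>_<activity>_<trial>.csv`
#' convention.
#'
#' @param dir directory path.
#' @return list of [SensorRecord-class] objects.
#' @export
readTrialDir <- function(dir) {
  mp <- file.path(dir, "manifest.csv")
  if (file.exists(mp)) {
    man <- utils::read.csv(mp)
    return(lapply(seq_len(nrow(man)), function(i) {
      readTrialCsv(
        file.path(dir, man$file[i]), man$subject[i], man$activity[i],
        man$trial[i]
      )
    }))
  }
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  stopIfNot(length(files) >= 1L, "no trial CSVs found")
  lapply(files, readTrialCsv)
}

#' Write a feature matrix CSV
#'
#' First column `window`, then the 99 feature columns `f4..f102`, then
#' `activity` and `subject`.
#'
#' @param data a [FeatureSet-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeFeatureCsv <- function(data, path) {
  stopifnot(is(data, "FeatureSet"))
  X <- featureMatrix(data)
  df <- data.frame(
    window = colnames(X), t(X),
    activity = activityLabels(data), subject = subjectLabels(data),
    check.names = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix CSV
#'
#' @param path CSV written by [writeFeatureCsv()].
#' @return a [FeatureSet-class].
#' @export
readFeatureCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  featCols <- grep("^f\\d+$", names(df), value = TRUE)
  X <- t(as.matrix(df[, featCols]))
  colnames(X) <- df$window
  featureSetFromMatrix(X, df$activity, df$subject)
}

#' Read a pairwise accuracy table CSV
#'
#' Reads a symmetric activity-by-activity accuracy table (first column =
#' activity names, remaining columns = one per activity) into a
#' [PairwiseMatrix-class], recomputing the per-activity column means over
#' all entries including the unit diagonal.
#'
#' @param path CSV path.
#' @return a [PairwiseMatrix-class].
#' @export
readPairwiseCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  new("PairwiseMatrix",
    accuracy = m, columnMeans = colMeans(m), baseline = numeric(0),
    config = list(source = basename(path))
  )
}

densityToList <- function(j) {
  lapply(j@dims, function(d) {
    list(samples = d@samples, bandwidth = d@bandwidth)
  })
}

densityFromList <- function(l) {
  new("JointDensity", dims = lapply(l, function(d) {
    new("KernelDensity1D",
      samples = as.numeric(d$samples), bandwidth = as.numeric(d$bandwidth)
    )
  }))
}

binaryToList <- function(m) {
  list(
    type = "binary",
    labels = m@labels,
    projection = list(
      mat = m@projection@mat, scale = m@projection@scale,
      seed = m@projection@seed
    ),
    standardization = list(
      center = m@standardization@center, scale = m@standardization@scale,
      degenerate = m@standardization@degenerate
    ),
    posDensity = densityToList(m@posDensity),
    negDensity = densityToList(m@negDensity),
    grid = list(
      lower = m@grid@lower, upper = m@grid@upper,
      resolution = m@grid@resolution
    ),
    separation = m@separation,
    trainCounts = m@trainCounts,
    config = m@config
  )
}

binaryFromList <- function(l) {
  new("BinaryRPModel",
    projection = new("ProjectionMatrix",
      mat = matrix(
        unlist(l$projection$mat),
        nrow = length(l$projection$mat), byrow = TRUE
      ),
      scale = as.numeric(l$projection$scale),
      seed = as.numeric(l$projection$seed)
    ),
    standardization = new("StandardizationStats",
      center = as.numeric(l$standardization$center),
      scale = as.numeric(l$standardization$scale),
      degenerate = as.logical(l$standardization$degenerate)
    ),
    posDensity = densityFromList(l$posDensity),
    negDensity = densityFromList(l$negDensity),
    grid = new("EvaluationGrid",
      lower = as.numeric(l$grid$lower), upper = as.numeric(l$grid$upper),
      resolution = as.integer(l$grid$resolution)
    ),
    separation = as.numeric(l$separation),
    labels = as.character(l$labels),
    trainCounts = as.integer(l$trainCounts),
    config = l$config
  )
}

#' Serialize a trained model to JSON
#'
#' Stores everything needed to reproduce predictions: the projection grid
#' and scale, frozen standardization statistics, per-class KDE samples and
#' bandwidths, the shared grid, separation, labels and the training
#' configuration (including seeds).
#'
#' @param model a [BinaryRPModel-class] or [MultiClassRPModel-class].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeModelJson <- function(model, path) {
  l <- if (is(model, "BinaryRPModel")) {
    binaryToList(model)
  } else if (is(model, "MultiClassRPModel")) {
    list(
      type = "multiclass",
      labels = model@labels,
      outlierThreshold = model@outlierThreshold,
      oneClass = model@oneClass,
      models = lapply(model@models, binaryToList)
    )
  } else {
    stop("unsupported model type", call. = FALSE)
  }
  jsonlite::write_json(l, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a model serialized by [writeModelJson()]
#'
#' @param path JSON path.
#' @return the deserialized model object.
#' @export
readModelJson <- function(path) {
  l <- jsonlite::read_json(path,
    simplifyVector = TRUE, simplifyDataFrame = FALSE, simplifyMatrix = FALSE
  )
  if (identical(l$type, "binary")) return(binaryFromList(l))
  stopIfNot(identical(l$type, "multiclass"), "unrecognized model file")
  models <- lapply(l$models, binaryFromList)
  new("MultiClassRPModel",
    models = models,
    outlierThreshold = as.numeric(l$outlierThreshold),
    oneClass = as.logical(l$oneClass),
    labels = as.character(l$labels)
  )
}
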