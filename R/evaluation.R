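#' Stratified k-fold assignment
#'
#' Assigns each window to exactly one test fold so that per-class counts
#' across folds differ by at most one. Standard 5-fold protocol: each fold
#' serves once as the 20% test split while the remaining 80% trains.
#'
#' @param labels class label per window.
#' @param k number of folds (default 5); every class needs >= k windows.
#' @param seed integer seed for the within-class shuffles.
#' @return integer vector of fold ids in 1..k, one per window.
#' @export
stratifiedKFold <- function(labels, k = 5L, seed = 1L) {
  labels <- as.character(labels)
  k <- as.integer(k)
  counts <- table(labels)
  small <- names(counts)[counts < k]
  if (length(small)) {
    stop(
      "class(es) smaller than k = ", k, ": ", paste(small, collapse = ", "),
      call. = FALSE
    )
  }
  folds <- integer(length(labels))
  withLocalSeed(seed, {
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      folds[idx[sample.int(length(idx))]] <-
        rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Per-class metrics from a confusion matrix
#'
#' Computes one-vs-rest accuracy, precision, recall (sensitivity),
#' specificity and F-score for every class, plus their unweighted grand
#' means. Metrics with a zero denominator are defined as 0.
#'
#' @param cm square nonnegative count matrix, true labels in rows,
#'   predicted in columns, with matching dimnames.
#' @param folds,seed,config optional bookkeeping stored in the report.
#' @return an [EvaluationReport-class].
#' @export
metricsFromConfusion <- function(cm, folds = integer(0), seed = NA_real_,
                                 config = list()) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) {
    stop("confusion matrix must be square", call. = FALSE)
  }
  stopIfNot(all(cm >= 0), "confusion counts must be nonnegative")
  classes <- rownames(cm)
  if (is.null(classes)) {
    classes <- paste0("C", seq_len(nrow(cm)))
    dimnames(cm) <- list(classes, classes)
  }
  total <- sum(cm)
  frac <- function(num, den) {
    den <- rep_len(den, length(num))
    ifelse(den > 0, num / den, 0)
  }
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  precision <- frac(tp, tp + fp)
  recall <- frac(tp, tp + fn)
  perClass <- data.frame(
    class = classes,
    accuracy = frac(tp + tn, total),
    precision = precision,
    recall = recall,
    specificity = frac(tn, tn + fp),
    fscore = fScore(precision, recall),
    row.names = NULL
  )
  gm <- colMeans(perClass[, -1])
  new("EvaluationReport",
    confusion = cm, perClass = perClass, grandMeans = gm,
    folds = as.integer(folds), seed = seed, config = config
  )
}

#' F-score from precision and recall
#'
#' Harmonic mean `2pr/(p + r)`, defined as 0 when `p + r = 0`. Vectorized.
#'
#' @param precision,recall values in [0, 1].
#' @return numeric F-score(s).
#' @export
fScore <- function(precision, recall) {
  stopIfNot(
    all(precision >= 0 & precision <= 1) && all(recall >= 0 & recall <= 1),
    "precision and recall must lie in [0, 1]"
  )
  ifelse(precision + recall > 0,
    2 * precision * recall / (precision + recall), 0
  )
}

#' Analytic random-classifier baseline row
#'
#' For one-vs-all identification among C classes the conventional random
#' baseline row is accuracy = precision = 1/C (the positive-class
#' prevalence) and recall = (C-1)/C, with the F-score of that
#' precision/recall pair; for C = 2 all entries reduce to 0.5. Values are
#' rounded to 3 decimals for display, matching the report tables. (The
#' accuracy and recall entries follow different random-classifier
#' conventions; the row is reported as conventionally printed.)
#'
#' @param nClasses number of classes C >= 2.
#' @return named numeric vector
#'   `(accuracy, precision, recall, fscore)`.
#' @examples
#' randomBaselines(14) # 0.071 0.071 0.929 0.133
#' randomBaselines(2) # all 0.5
#' @export
randomBaselines <- function(nClasses) {
  nClasses <- as.integer(nClasses)
  if (nClasses < 2L) stop("need nClasses >= 2", call. = FALSE)
  p <- 1 / nClasses
  r <- (nClasses - 1) / nClasses
  roundHalfUp(c(
    accuracy = p, precision = p, recall = r, fscore = fScore(p, r)
  ))
}

# Pooled k-fold CV accuracy (and mean F) of a binary trainer on two
# labelled column sets. `trainer(xPos, xNeg, seed)` -> BinaryRPModel.
binaryCv <- function(xPos, xNeg, folds = 5L, seed = 1L, trainer) {
  labels <- rep(c("pos", "neg"), c(ncol(xPos), ncol(xNeg)))
  X <- cbind(xPos, xNeg)
  fold <- stratifiedKFold(labels, folds, seed)
  foldSeeds <- deriveSeeds(seed + 1, folds)
  correct <- 0L
  tp <- fp <- fn <- 0L
  for (f in seq_len(folds)) {
    tr <- fold != f
    m <- trainer(
      X[, tr & labels == "pos", drop = FALSE],
      X[, tr & labels == "neg", drop = FALSE],
      foldSeeds[f]
    )
    pred <- classifyBinary(m, X[, !tr, drop = FALSE])$label
    truth <- ifelse(labels[!tr] == "pos", m@labels[1], m@labels[2])
    correct <- correct + sum(pred == truth)
    tp <- tp + sum(pred == m@labels[1] & truth == m@labels[1])
    fp <- fp + sum(pred == m@labels[1] & truth != m@labels[1])
    fn <- fn + sum(pred != m@labels[1] & truth == m@labels[1])
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  c(accuracy = correct / length(labels), fscore = fScore(prec, rec),
    precision = prec, recall = rec)
}

rpTrainer <- function(k, trials, earlyStop, resolution, labels) {
  function(xPos, xNeg, seed) {
    findBestProjection(
      xPos, xNeg, k = k, trials = trials, earlyStop = earlyStop,
      seed = seed, resolution = resolution, labels = labels
    )
  }
}

#' Pairwise binary activity accuracy matrix
#'
#' For every unordered pair of activities, trains the binary
#' random-projection classifier under stratified k-fold cross-validation
#' and records the pooled test accuracy. The diagonal is fixed at 1 and
#' the per-activity column mean is taken over all entries including the
#' diagonal. Optionally adds a baseline row: the same cross-validation
#' with the two-feature selector model on the divergence-ranked top 2
#' features of each training split.
#'
#' @param data a [FeatureSet-class]; activities are its activity labels.
#' @param k,trials,earlyStop,resolution passed to [findBestProjection()].
#' @param folds cross-validation folds (default 5); every activity needs
#'   at least `folds` windows.
#' @param seed master seed.
#' @param baseline logical; also compute the top-2-feature baseline row.
#' @param progress logical; print one line per finished pair.
#' @return a [PairwiseMatrix-class].
#' @export
pairwiseActivityMatrix <- function(data, k = 2L, trials = 100L,
                                   earlyStop = 0.99, resolution = 256L,
                                   folds = 5L, seed = 1L,
                                   baseline = FALSE, progress = FALSE) {
  stopifnot(is(data, "FeatureSet"))
  X <- featureMatrix(data)
  labels <- activityLabels(data)
  acts <- sort(unique(labels))
  stopIfNot(length(acts) >= 2L, "need >= 2 activities")
  counts <- table(labels)
  small <- names(counts)[counts < folds]
  if (length(small)) {
    stop(
      "activity with fewer windows than folds: ",
      paste(small, collapse = ", "), call. = FALSE
    )
  }
  nA <- length(acts)
  acc <- matrix(1, nA, nA, dimnames = list(acts, acts))
  base <- stats::setNames(numeric(nA), acts)
  nPairs <- nA * (nA - 1L) / 2L
  pairSeeds <- deriveSeeds(seed, nPairs)
  baseAcc <- matrix(
    NA_real_, nA, nA, dimnames = list(acts, acts)
  )
  pair <- 0L
  for (i in seq_len(nA - 1L)) {
    for (j in (i + 1L):nA) {
      pair <- pair + 1L
      xi <- X[, labels == acts[i], drop = FALSE]
      xj <- X[, labels == acts[j], drop = FALSE]
      cv <- binaryCv(
        xi, xj, folds, pairSeeds[pair],
        rpTrainer(k, trials, earlyStop, resolution, c(acts[i], acts[j]))
      )
      acc[i, j] <- acc[j, i] <- cv[["accuracy"]]
      if (baseline) {
        bl <- binaryCv(
          xi, xj, folds, pairSeeds[pair],
          function(xp, xn, s) {
            lab <- rep(c(acts[i], acts[j]), c(ncol(xp), ncol(xn)))
            ids <- topFeatures(entropyRank(cbind(xp, xn), lab), 2L)
            trainBaselineTop2(
              cbind(xp, xn), lab, ids, resolution = resolution
            )
          }
        )
        baseAcc[i, j] <- baseAcc[j, i] <- bl[["accuracy"]]
      }
      if (progress) {
        message(sprintf(
          "%s vs %s: accuracy %.3f", acts[i], acts[j], cv[["accuracy"]]
        ))
      }
    }
  }
  if (baseline) base[] <- rowMeans(baseAcc, na.rm = TRUE)
  new("PairwiseMatrix",
    accuracy = acc, columnMeans = colMeans(acc),
    baseline = if (baseline) base else numeric(0),
    config = list(
      k = k, trials = trials, earlyStop = earlyStop, folds = folds,
      seed = seed, resolution = resolution
    )
  )
}

#' Column means of a pairwise matrix
#'
#' @param x a [PairwiseMatrix-class].
#' @return named numeric vector of per-activity column means (including
#'   the unit diagonal entries).
#' @export
pairwiseMeans <- function(x) {
  stopifnot(is(x, "PairwiseMatrix"))
  x@columnMeans
}

#' Subject identification experiments
#'
#' Drives the three subject-identification designs over the binary
#' classifier with stratified k-fold cross-validation:
#' \describe{
#'   \item{`one_vs_all_pooled`}{all activities pooled; one binary model
#'     per subject (that subject vs everyone else), reported per subject
#'     with accuracy/precision/recall/F and their grand means.}
#'   \item{`one_vs_all_per_activity`}{the same one-vs-all design run
#'     separately within each activity; the per-activity row is the mean
#'     over subjects.}
#'   \item{`pairwise_binary`}{within each activity, a separate binary
#'     model per pair of subjects; the per-activity row is the mean over
#'     pairs. The matching analytic baseline is 0.5.}
#' }
#'
#' @param data a [FeatureSet-class] with subject and activity labels.
#' @param mode one of `"one_vs_all_pooled"`, `"one_vs_all_per_activity"`,
#'   `"pairwise_binary"`.
#' @param k,trials,earlyStop,resolution passed to [findBestProjection()].
#' @param folds cross-validation folds.
#' @param seed master seed.
#' @param activities optional subset of activities to evaluate (modes 2-3).
#' @return list with elements `mode`, `table` (per-subject or per-activity
#'   data.frame), `grandMean` (named numeric) and `baseline` (the analytic
#'   random row from [randomBaselines()]).
#' @export
subjectIdentificationEval <- function(data,
                                      mode = c(
                                        "one_vs_all_pooled",
                                        "one_vs_all_per_activity",
                                        "pairwise_binary"
                                      ),
                                      k = 2L, trials = 100L,
                                      earlyStop = 0.99, resolution = 256L,
                                      folds = 5L, seed = 1L,
                                      activities = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(data, "FeatureSet"))
  X <- featureMatrix(data)
  subj <- subjectLabels(data)
  act <- activityLabels(data)
  subjects <- sort(unique(subj))
  stopIfNot(length(subjects) >= 2L, "need >= 2 subjects")
  trainer <- function(lab) {
    rpTrainer(k, trials, earlyStop, resolution, lab)
  }

  oneVsAll <- function(cols, tag) {
    seeds <- deriveSeeds(seed + match(tag, c("pooled", activities,
      sort(unique(act)))), length(subjects))
    rows <- lapply(seq_along(subjects), function(i) {
      s <- subjects[i]
      pos <- cols & subj == s
      neg <- cols & subj != s
      if (sum(pos) < folds || sum(neg) < folds) {
        stop(sprintf(
          "insufficient windows for subject %s (%s)", s, tag
        ), call. = FALSE)
      }
      cv <- binaryCv(
        X[, pos, drop = FALSE], X[, neg, drop = FALSE], folds, seeds[i],
        trainer(c(s, "rest"))
      )
      data.frame(
        subject = s, accuracy = cv[["accuracy"]],
        precision = cv[["precision"]], recall = cv[["recall"]],
        fscore = cv[["fscore"]]
      )
    })
    do.call(rbind, rows)
  }

  if (mode == "one_vs_all_pooled") {
    tab <- oneVsAll(rep(TRUE, ncol(X)), "pooled")
    gm <- colMeans(tab[, -1])
    return(list(
      mode = mode, table = tab, grandMean = gm,
      baseline = randomBaselines(length(subjects))
    ))
  }

  if (is.null(activities)) activities <- sort(unique(act))
  if (mode == "one_vs_all_per_activity") {
    rows <- lapply(activities, function(a) {
      tab <- oneVsAll(act == a, a)
      data.frame(
        activity = a, accuracy = mean(tab$accuracy),
        fscore = mean(tab$fscore)
      )
    })
    tab <- do.call(rbind, rows)
    return(list(
      mode = mode, table = tab,
      grandMean = colMeans(tab[, -1]),
      baseline = randomBaselines(length(subjects))
    ))
  }

  # pairwise_binary
  pairs <- utils::combn(subjects, 2L)
  rows <- lapply(seq_along(activities), function(ai) {
    a <- activities[ai]
    seeds <- deriveSeeds(seed + 7L * ai, ncol(pairs))
    accs <- fs <- numeric(ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
      s1 <- pairs[1, p]; s2 <- pairs[2, p]
      c1 <- act == a & subj == s1
      c2 <- act == a & subj == s2
      if (sum(c1) < folds || sum(c2) < folds) {
        stop(sprintf(
          "insufficient windows for pair %s/%s in %s", s1, s2, a
        ), call. = FALSE)
      }
      cv <- binaryCv(
        X[, c1, drop = FALSE], X[, c2, drop = FALSE], folds, seeds[p],
        trainer(c(s1, s2))
      )
      accs[p] <- cv[["accuracy"]]; fs[p] <- cv[["fscore"]]
    }
    data.frame(activity = a, accuracy = mean(accs), fscore = mean(fs))
  })
  tab <- do.call(rbind, rows)
  list(
    mode = mode, table = tab, grandMean = colMeans(tab[, -1]),
    baseline = randomBaselines(2L)
  )
}
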