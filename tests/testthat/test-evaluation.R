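test_that("stratified folds balance classes and partition the data", {
  lab <- rep(c("A", "B"), each = 50)
  f <- stratifiedKFold(lab, 5, seed = 1)
  expect_equal(as.vector(table(f)), rep(20L, 5))
  for (k in 1:5) {
    expect_equal(sum(lab[f == k] == "A"), 10L)
    expect_equal(sum(lab[f == k] == "B"), 10L)
  }
  expect_true(all(f %in% 1:5))
  expect_identical(stratifiedKFold(lab, 5, seed = 1), f)
  expect_false(identical(stratifiedKFold(lab, 5, seed = 2), f))
  expect_error(stratifiedKFold(c("A", "A", "B"), 2), "smaller than k")
  # uneven classes differ by at most one across folds
  lab2 <- rep(c("A", "B"), c(23, 31))
  f2 <- stratifiedKFold(lab2, 5, seed = 3)
  for (cl in c("A", "B")) {
    cnt <- table(f2[lab2 == cl])
    expect_lte(max(cnt) - min(cnt), 1)
  }
})

test_that("confusion-matrix metrics match hand-computed formulas", {
  perfect <- diag(c(5, 7, 9))
  dimnames(perfect) <- list(LETTERS[1:3], LETTERS[1:3])
  r <- metricsFromConfusion(perfect)
  expect_true(all(as.matrix(r@perClass[, -1]) == 1))
  expect_true(all(r@grandMeans == 1))

  wrong <- matrix(c(0, 10, 10, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  rw <- metricsFromConfusion(wrong)
  expect_true(all(rw@perClass$accuracy == 0))
  expect_true(all(rw@perClass$fscore == 0))

  set.seed(4)
  cm <- matrix(sample(0:20, 9), 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  r3 <- metricsFromConfusion(cm)
  tot <- sum(cm)
  for (i in 1:3) {
    tp <- cm[i, i]; fn <- sum(cm[i, ]) - tp; fp <- sum(cm[, i]) - tp
    tn <- tot - tp - fn - fp
    expect_equal(r3@perClass$accuracy[i], (tp + tn) / tot)
    expect_equal(r3@perClass$precision[i], tp / (tp + fp))
    expect_equal(r3@perClass$recall[i], tp / (tp + fn))
    expect_equal(r3@perClass$specificity[i], tn / (tn + fp))
  }
  expect_equal(sum(r3@confusion), tot)
  expect_error(metricsFromConfusion(matrix(1, 2, 3)), "square")
})

test_that("f-score is the harmonic mean with a zero-denominator rule", {
  expect_equal(fScore(0.8, 0.8), 0.8)
  expect_equal(fScore(0, 0.9), 0)
  expect_equal(fScore(0, 0), 0)
  expect_equal(round(fScore(1 / 14, 13 / 14), 3), 0.133)
})

test_that("analytic random baselines match the printed conventions", {
  expect_equal(
    randomBaselines(14),
    c(accuracy = 0.071, precision = 0.071, recall = 0.929, fscore = 0.133)
  )
  expect_equal(unname(randomBaselines(2)), rep(0.5, 4))
  b4 <- randomBaselines(4)
  expect_equal(b4[["accuracy"]], 0.25)
  expect_equal(b4[["recall"]], 0.75)
  expect_error(randomBaselines(1), "nClasses >= 2")
})

test_that("published pairwise tables reproduce their printed column means", {
  pm <- readPairwiseCsv(
    system.file("extdata", "uschad_pairwise_published.csv", package = "rpHAR")
  )
  means <- pairwiseMeans(pm)
  expect_equal(round(means[["WF"]], 3), 0.965)
  expect_equal(round(means[["WU"]], 3), 0.937)
})

test_that("pairwise activity matrices are symmetric with unit diagonal", {
  fs <- generateFeatureClusters(3, nPerClass = 30, separation = 8, seed = 31)
  pm <- pairwiseActivityMatrix(fs, trials = 25, folds = 5, seed = 5)
  a <- pm@accuracy
  expect_identical(a, t(a))
  expect_equal(unname(diag(a)), rep(1, 3))
  expect_true(all(a[upper.tri(a)] >= 0.95))
  expect_equal(pairwiseMeans(pm), colMeans(a))
  expect_error(
    pairwiseActivityMatrix(
      generateFeatureClusters(2, nPerClass = 4, separation = 1, seed = 1)
    ),
    "fewer windows than folds"
  )
})

test_that("subject identification drivers cover all designs", {
  # feature clusters standing in for per-subject walking windows
  fs <- generateFeatureClusters(3, nPerClass = 40, separation = 7, seed = 41)
  fs2 <- rpHAR:::featureSetFromMatrix(
    featureMatrix(fs), rep("WF", ncol(fs)), activityLabels(fs)
  )
  pw <- subjectIdentificationEval(
    fs2, "pairwise_binary", trials = 25, seed = 6
  )
  expect_identical(pw$table$activity, "WF")
  expect_gte(pw$grandMean[["accuracy"]], 0.9)
  expect_equal(unname(pw$baseline), rep(0.5, 4))

  ova <- subjectIdentificationEval(
    fs2, "one_vs_all_pooled", trials = 25, seed = 7
  )
  expect_setequal(ova$table$subject, c("C01", "C02", "C03"))
  expect_true(all(c("accuracy", "precision", "recall", "fscore")
  %in% names(ova$table)))
  expect_gte(ova$grandMean[["accuracy"]], 0.9)

  pa <- subjectIdentificationEval(
    fs2, "one_vs_all_per_activity", trials = 25, seed = 8
  )
  expect_identical(pa$table$activity, "WF")
  expect_gte(pa$grandMean[["accuracy"]], 0.9)
})
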