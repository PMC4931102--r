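test_that("identical training samples give zero separation", {
  set.seed(1)
  X <- matrix(rnorm(99 * 30), 99, 30)
  m <- findBestProjection(X, X, trials = 5, seed = 3)
  expect_lt(separationScore(m), 1e-9)
})

test_that("the search separates clusters informative on many features", {
  cl <- twoClusters(60, separation = 6, seed = 2)
  m <- findBestProjection(
    cl$X[, cl$labels == "C01"], cl$X[, cl$labels == "C02"],
    trials = 100, seed = 7
  )
  expect_gte(separationScore(m), 0.9)
})

test_that("sparse informative signal is drowned by standardized noise dims", {
  # with only 2 of 99 dims informative the projected noise dominates;
  # simulation-derived behaviour: separation well below the
  # informative-rich case but clearly above the identical-sample case
  cl <- twoClusters(60, separation = 10, informativeDims = 1:2, seed = 3)
  m <- findBestProjection(
    cl$X[, cl$labels == "C01"], cl$X[, cl$labels == "C02"],
    trials = 100, seed = 7
  )
  expect_lt(separationScore(m), 0.85)
  expect_gt(separationScore(m), 0.2)
})

test_that("a single-trial search equals its direct recomputation", {
  cl <- twoClusters(30, separation = 3, seed = 4)
  xp <- cl$X[, cl$labels == "C01"]
  xn <- cl$X[, cl$labels == "C02"]
  m <- findBestProjection(xp, xn, trials = 1, seed = 11)
  std <- standardizeFeatures(cbind(xp, xn))
  zp <- projectData(m@projection, std$X[, seq_len(ncol(xp))])
  zn <- projectData(m@projection, std$X[, -seq_len(ncol(xp))])
  jp <- jointDensity(zp); jn <- jointDensity(zn)
  dj <- jaccardDistance(jp, jn, makeSharedGrid(jp, jn))
  expect_equal(separationScore(m), dj)
})

test_that("separation never decreases with more trials (nested seeds)", {
  cl <- twoClusters(25, separation = 2, seed = 5)
  xp <- cl$X[, cl$labels == "C01"]
  xn <- cl$X[, cl$labels == "C02"]
  seps <- vapply(c(3, 10, 25), function(tr) {
    separationScore(
      findBestProjection(xp, xn, trials = tr, seed = 13, earlyStop = 1)
    )
  }, numeric(1))
  expect_true(all(diff(seps) >= 0))
})

test_that("binary classification follows the density-ratio rule", {
  cl <- twoClusters(80, separation = 6, seed = 6)
  xp <- cl$X[, cl$labels == "C01"]
  xn <- cl$X[, cl$labels == "C02"]
  m <- findBestProjection(xp, xn, seed = 17, labels = c("A", "B"))
  # the positive training mean is classified positive
  expect_equal(classifyBinary(m, rowMeans(xp))$label, "A")
  # swapping class roles flips every positive/negative role assignment
  mr <- findBestProjection(xp, xn, seed = 17)
  mr2 <- findBestProjection(xn, xp, seed = 17)
  te <- twoClusters(20, separation = 6, seed = 60)$X
  p1 <- classifyBinary(mr, te)$label # "pos"/"neg" role labels
  p2 <- classifyBinary(mr2, te)$label
  expect_true(all(p1 != p2))
  # ties go to the positive label: identical class densities tie everywhere
  set.seed(7)
  same <- matrix(rnorm(99 * 20), 99, 20)
  mt <- findBestProjection(same, same, trials = 2, seed = 19,
    labels = c("pos", "neg"))
  expect_true(all(classifyBinary(mt, same[, 1:5])$label == "pos"))
  expect_error(classifyBinary(m, rnorm(98)), "feature mismatch")
})

test_that("scores are invariant to per-feature affine rescaling", {
  cl <- twoClusters(40, separation = 4, seed = 8)
  xp <- cl$X[, cl$labels == "C01"]
  xn <- cl$X[, cl$labels == "C02"]
  set.seed(9)
  a <- runif(99, 0.2, 30); b <- rnorm(99, 0, 10)
  m1 <- findBestProjection(xp, xn, trials = 10, seed = 23)
  m2 <- findBestProjection(xp * a + b, xn * a + b, trials = 10, seed = 23)
  te <- twoClusters(10, separation = 4, seed = 80)$X
  s1 <- classifyBinary(m1, te)
  s2 <- classifyBinary(m2, te * a + b)
  expect_equal(s1$scorePos, s2$scorePos, tolerance = 1e-9)
  expect_equal(s1$scoreNeg, s2$scoreNeg, tolerance = 1e-9)
  expect_identical(s1$label, s2$label)
})

test_that("one-vs-rest training yields a reproducible per-class ensemble", {
  fs <- generateFeatureClusters(3, nPerClass = 40, separation = 8, seed = 10)
  mc <- trainOneVsAll(fs, trials = 30, seed = 29)
  expect_identical(classLabels(mc), c("C01", "C02", "C03"))
  for (m in mc@models) expect_gte(separationScore(m), 0.9)
  mc2 <- trainOneVsAll(fs, trials = 30, seed = 29)
  expect_equal(
    lapply(mc@models, projectionMatrix),
    lapply(mc2@models, projectionMatrix)
  )
  expect_equal(
    vapply(mc@models, separationScore, numeric(1)),
    vapply(mc2@models, separationScore, numeric(1))
  )
  expect_error(
    trainOneVsAll(featureMatrix(fs)[, 1:41], c(rep("A", 40), "B")),
    "< 2 windows"
  )
})

test_that("multi-class prediction recovers held-out cluster labels", {
  tr <- generateFeatureClusters(3, nPerClass = 60, separation = 8, seed = 11)
  te <- generateFeatureClusters(3, nPerClass = 30, separation = 8, seed = 12)
  mc <- trainOneVsAll(tr, trials = 40, seed = 31)
  pred <- predictLabels(mc, te)
  expect_gte(mean(pred == activityLabels(te)), 0.95)
})

test_that("the one-class rule flags far-away windows as outliers", {
  tr <- generateFeatureClusters(3, nPerClass = 30, separation = 6, seed = 13)
  mc <- trainOneVsAll(tr, trials = 10, seed = 37, oneClass = TRUE)
  far <- matrix(1e4, 99, 1) # >> 20 pooled SDs from everything
  expect_identical(predictLabels(mc, far), "outlier")
  # exactly tied ratios resolve to the lexicographically smallest label
  set.seed(14)
  same <- matrix(rnorm(99 * 30), 99, 30)
  tie <- trainOneVsAll(
    cbind(same, same), rep(c("b", "a"), each = 30),
    trials = 2, seed = 41
  )
  expect_identical(predictLabels(tie, same[, 1]), "a")
})

test_that("the two-feature baseline is a fixed selector pipeline", {
  cl <- twoClusters(60, separation = 8, informativeDims = 1:2, seed = 15)
  bl <- trainBaselineTop2(cl$X, cl$labels, c(4, 5))
  R <- projectionMatrix(bl)
  expect_equal(rowSums(R == 1), c(1, 1), ignore_attr = TRUE)
  expect_equal(rowSums(R != 0), c(1, 1), ignore_attr = TRUE)
  expect_error(trainBaselineTop2(cl$X, cl$labels, c(4, 4)), "duplicate")

  # with only the selected features informative, the direct selector beats
  # (or matches) the noise-drowned random-projection search
  blCv <- rpHAR:::binaryCv(
    cl$X[, cl$labels == "C01"], cl$X[, cl$labels == "C02"],
    folds = 5, seed = 1,
    trainer = function(xp, xn, s) {
      trainBaselineTop2(
        cbind(xp, xn),
        rep(c("C01", "C02"), c(ncol(xp), ncol(xn))), c(4, 5)
      )
    }
  )
  rpCv <- rpHAR:::binaryCv(
    cl$X[, cl$labels == "C01"], cl$X[, cl$labels == "C02"],
    folds = 5, seed = 1,
    trainer = function(xp, xn, s) {
      findBestProjection(xp, xn, trials = 25, seed = s)
    }
  )
  expect_gte(blCv[["accuracy"]], rpCv[["accuracy"]] - 0.05)
  expect_gte(blCv[["accuracy"]], 0.95)

  # two pure-noise features classify at chance
  noise <- twoClusters(100, separation = 8, informativeDims = 1:2, seed = 16)
  nCv <- rpHAR:::binaryCv(
    noise$X[, noise$labels == "C01"], noise$X[, noise$labels == "C02"],
    folds = 5, seed = 2,
    trainer = function(xp, xn, s) {
      trainBaselineTop2(
        cbind(xp, xn),
        rep(c("C01", "C02"), c(ncol(xp), ncol(xn))), c(50, 51)
      )
    }
  )
  expect_gt(nCv[["accuracy"]], 0.35)
  expect_lt(nCv[["accuracy"]], 0.65)
})
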