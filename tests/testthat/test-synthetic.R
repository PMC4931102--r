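test_that("noise-free records are exact sinusoid sums", {
  prof <- activityProfile("gait",
    freqHz = 2, amp = matrix(c(0.5, 0.3, 0.2, 10, 20, 30), 6),
    phase = matrix(seq(0, 2.5, by = 0.5), 6), gravity = c(0, 0, 1),
    noiseSd = 0
  )
  subj <- subjectProfile(cadence = 1.1, ampScale = 0.8)
  rec <- generateRecord(prof, subj, 2, rateHz = 100, seed = 5)
  t <- rec@samples$t
  for (ch in seq_along(c("ax", "ay", "az", "gx", "gy", "gz"))) {
    want <- 0.8 * prof$amp[ch, 1] *
      sin(2 * pi * 2 * 1.1 * t + prof$phase[ch, 1]) +
      if (ch <= 3) prof$gravity[ch] else 0
    expect_equal(rec@samples[[ch + 1]], want, tolerance = 1e-9)
  }
})

test_that("a static gravity-only profile has unit movement intensity", {
  prof <- activityProfile("still", gravity = c(0, 0, 1), noiseSd = 0)
  rec <- generateRecord(prof, subjectProfile(), 3, seed = 1)
  for (w in slidingWindows(rec, 100, 50)) {
    expect_equal(computeFeature(16, w), 1)
  }
})

test_that("record generation is bit-reproducible", {
  prof <- defaultActivityProfiles()$WF
  r1 <- generateRecord(prof, subjectProfile(1.05, 1.1, 3L), 2, seed = 42)
  r2 <- generateRecord(prof, subjectProfile(1.05, 1.1, 3L), 2, seed = 42)
  expect_identical(r1@samples, r2@samples)
  r3 <- generateRecord(prof, subjectProfile(1.05, 1.1, 3L), 2, seed = 43)
  expect_false(identical(r1@samples, r3@samples))
})

test_that("dataset generation produces the full subject/activity/trial grid", {
  acts <- defaultActivityProfiles()[c("WF", "RF", "Si", "St")]
  ds <- generateDataset(3, acts, nTrials = 2, durationS = 2, seed = 9)
  expect_length(ds, 3 * 4 * 2)
  meta <- data.frame(
    subject = vapply(ds, function(r) r@subjectId, character(1)),
    activity = vapply(ds, function(r) r@activity, character(1)),
    trial = vapply(ds, function(r) r@trialId, character(1))
  )
  expect_equal(nrow(unique(meta)), 24L)
  expect_setequal(unique(meta$subject), c("S1", "S2", "S3"))
  expect_setequal(unique(meta$activity), c("WF", "RF", "Si", "St"))
  ds2 <- generateDataset(3, acts, nTrials = 2, durationS = 2, seed = 9)
  expect_identical(
    lapply(ds, function(r) r@samples), lapply(ds2, function(r) r@samples)
  )
  expect_error(generateDataset(2, list(), 1, 2), "at least one activity")
})

test_that("feature clusters honour the requested per-dimension separation", {
  fs <- generateFeatureClusters(
    2, nPerClass = 200, informativeDims = c(5, 17), separation = 4,
    seed = 21
  )
  X <- featureMatrix(fs)
  lab <- activityLabels(fs)
  gap <- rowMeans(X[, lab == "C01"]) - rowMeans(X[, lab == "C02"])
  se <- sqrt(1 / 200 + 1 / 200)
  expect_true(all(abs(abs(gap[c(5, 17)]) - 4) < 3 * se))
  expect_true(all(abs(gap[-c(5, 17)]) < 4 * se))
  # class labels and determinism
  expect_setequal(unique(lab), c("C01", "C02"))
  fs2 <- generateFeatureClusters(
    2, nPerClass = 200, informativeDims = c(5, 17), separation = 4,
    seed = 21
  )
  expect_equal(featureMatrix(fs2), X)
  expect_error(
    generateFeatureClusters(2, nPerClass = 10, separation = -1),
    "must be >= 0"
  )
})

test_that("holdout accuracy trends upward with cluster separation", {
  levels <- c(0, 1.5, 3, 6)
  acc <- sapply(1:4, function(s) {
    vapply(levels, function(sep) {
      tr <- generateFeatureClusters(2,
        nPerClass = 40, separation = sep,
        seed = 100 * s
      )
      te <- generateFeatureClusters(2,
        nPerClass = 25, separation = sep,
        seed = 100 * s + 1
      )
      X <- featureMatrix(tr); lab <- activityLabels(tr)
      m <- findBestProjection(
        X[, lab == "C01"], X[, lab == "C02"],
        trials = 15, seed = s, labels = c("C01", "C02")
      )
      mean(classifyBinary(m, te)$label == activityLabels(te))
    }, numeric(1))
  })
  m <- rowMeans(acc)
  expect_true(all(diff(m) > -0.05)) # monotone trend up to seed noise
  expect_gt(m[4], m[1] + 0.2)
})
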