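# Shared fixture builders (all generated in code, seeded).

randomWindow <- function(n = 50, seed = 1) {
  set.seed(seed)
  w <- matrix(rnorm(n * 6, sd = rep(c(0.5, 30), each = n * 3)), n, 6)
  colnames(w) <- c("ax", "ay", "az", "gx", "gy", "gz")
  w
}

constantWindow <- function(vals, n = 10) {
  w <- matrix(rep(vals, each = n), n, 6)
  colnames(w) <- c("ax", "ay", "az", "gx", "gy", "gz")
  w
}

# A two-class feature set with per-dimension gap `separation` on the given
# informative dims; returns list(X, labels).
twoClusters <- function(nPerClass, separation, informativeDims = 1:99,
                        seed = 1) {
  fs <- generateFeatureClusters(
    2, nPerClass = nPerClass, separation = separation,
    informativeDims = informativeDims, seed = seed
  )
  list(X = featureMatrix(fs), labels = activityLabels(fs))
}

walkingSubjects <- function(cadences, amps = rep(1, length(cadences)),
                            nTrials = 2, durationS = 30, seed = 1) {
  profs <- lapply(seq_along(cadences), function(i) {
    subjectProfile(cadences[i], ampScale = amps[i], seedOffset = i)
  })
  generateDataset(
    length(cadences), defaultActivityProfiles()["WF"],
    nTrials = nTrials, durationS = durationS, seed = seed,
    subjects = profs
  )
}
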