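#' Synthetic activity signal profile
#'
#' Describes one activity as a sum of per-channel sinusoids plus a gravity
#' offset on the accelerometer axes and white Gaussian sensor noise. Phases
#' are part of the profile (not random), so two recordings of the same
#' profile differ only by noise.
#'
#' @param name activity token.
#' @param freqHz numeric vector of component frequencies (Hz); may be
#'   empty for static activities.
#' @param amp 6 x F matrix of amplitudes (rows `ax..gz`, one column per
#'   frequency component; acceleration in g, angular rate in deg/s).
#' @param phase 6 x F matrix of phase offsets (radians).
#' @param gravity length-3 gravity offset added to `ax, ay, az` (g).
#' @param noiseSd length-6 (or scalar) white-noise SD per channel.
#' @return an object of class `ActivityProfile`.
#' @export
activityProfile <- function(name, freqHz = numeric(0), amp = NULL,
                            phase = NULL, gravity = c(0, 0, 1),
                            noiseSd = 0.05) {
  nf <- length(freqHz)
  if (is.null(amp)) amp <- matrix(0, 6, nf)
  if (is.null(phase)) phase <- matrix(0, 6, nf)
  amp <- matrix(amp, nrow = 6)
  phase <- matrix(phase, nrow = 6)
  stopIfNot(ncol(amp) == nf && ncol(phase) == nf,
    "amp and phase need one column per frequency")
  stopIfNot(all(freqHz >= 0), "frequencies must be >= 0")
  noiseSd <- rep_len(noiseSd, 6)
  stopIfNot(all(noiseSd >= 0), "noise SD must be >= 0")
  structure(
    list(
      name = as.character(name), freqHz = freqHz, amp = amp,
      phase = phase, gravity = rep_len(gravity, 3), noiseSd = noiseSd
    ),
    class = "ActivityProfile"
  )
}

#' Synthetic subject gait profile
#'
#' A subject is characterized by a cadence multiplier (scales every
#' component frequency), an amplitude multiplier (scales the dynamic
#' components, not gravity) and a seed offset folded into record seeds.
#'
#' @param cadence positive frequency multiplier (1 = nominal).
#' @param ampScale positive amplitude multiplier.
#' @param seedOffset integer folded into per-record seeds.
#' @return an object of class `SubjectProfile`.
#' @export
subjectProfile <- function(cadence = 1, ampScale = 1, seedOffset = 0L) {
  stopIfNot(cadence > 0 && ampScale > 0, "multipliers must be > 0")
  structure(
    list(
      cadence = cadence, ampScale = ampScale,
      seedOffset = as.integer(seedOffset)
    ),
    class = "SubjectProfile"
  )
}

# Helper used by defaultActivityProfiles(): fundamental + one harmonic at
# 40% amplitude, with fixed per-axis phase offsets.
gaitProfile <- function(name, f0, accAmp, gyrAmp, phaseShift = 0,
                        gravity = c(0, 0, 1), noiseSd = c(
                          rep(0.05, 3), rep(2, 3)
                        )) {
  amp <- cbind(c(accAmp, gyrAmp), 0.4 * c(accAmp, gyrAmp))
  phase <- cbind(
    (0:5) * pi / 3 + phaseShift,
    (0:5) * pi / 4 + phaseShift + pi / 7
  )
  activityProfile(name, c(f0, 2 * f0), amp, phase, gravity, noiseSd)
}

#' The twelve default activity profiles
#'
#' Qualitative emulations of the canonical hip-worn IMU activity set:
#' five gait variants (forward/left/right/upstairs/downstairs walking),
#' running, jumping, three static postures (sitting, standing, sleeping)
#' and two elevator rides expressed as a slow vertical transient. Gait
#' activities share a 1.4-1.9 Hz fundamental with axis-specific amplitude
#' mixes; running and jumping are faster and larger; static postures are
#' gravity plus low noise. The set reproduces the qualitative separability
#' structure of real data (gait most subject-discriminative, static and
#' elevator activities hardest to tell apart) without claiming
#' biomechanical realism.
#'
#' @return named list of 12 `ActivityProfile` objects
#'   (WF, WL, WR, WU, WD, RF, JU, Si, St, Sl, EU, ED).
#' @export
defaultActivityProfiles <- function() {
  quiet <- c(rep(0.01, 3), rep(0.5, 3))
  list(
    WF = gaitProfile("WF", 1.8, c(0.35, 0.25, 0.50), c(30, 25, 18)),
    WL = gaitProfile("WL", 1.8, c(0.28, 0.38, 0.48), c(22, 34, 20),
      phaseShift = pi / 5),
    WR = gaitProfile("WR", 1.8, c(0.40, 0.18, 0.46), c(36, 18, 24),
      phaseShift = -pi / 5),
    WU = gaitProfile("WU", 1.4, c(0.30, 0.22, 0.62), c(26, 22, 30)),
    WD = gaitProfile("WD", 1.55, c(0.33, 0.20, 0.58), c(28, 20, 34),
      phaseShift = pi / 9),
    RF = gaitProfile("RF", 2.8, c(1.10, 0.80, 1.60), c(80, 60, 55),
      noiseSd = c(rep(0.10, 3), rep(4, 3))),
    JU = gaitProfile("JU", 2.2, c(0.70, 0.50, 1.90), c(40, 35, 70),
      noiseSd = c(rep(0.08, 3), rep(3, 3))),
    Si = activityProfile("Si", gravity = c(0.45, 0, 0.89),
      noiseSd = c(rep(0.012, 3), rep(0.6, 3))),
    St = activityProfile("St", gravity = c(0, 0, 1),
      noiseSd = c(rep(0.010, 3), rep(0.5, 3))),
    Sl = activityProfile("Sl", gravity = c(0, 0.97, -0.24),
      noiseSd = c(rep(0.006, 3), rep(0.3, 3))),
    EU = activityProfile("EU", freqHz = 0.08,
      amp = c(0, 0, 0.06, 0.5, 0.5, 0.8), phase = rep(0, 6),
      gravity = c(0, 0, 1), noiseSd = quiet),
    ED = activityProfile("ED", freqHz = 0.08,
      amp = c(0, 0, 0.06, 0.5, 0.5, 0.8), phase = rep(pi, 6),
      gravity = c(0, 0, 1), noiseSd = quiet)
  )
}

#' Generate one synthetic 6-axis recording
#'
#' Each channel is the profile's sinusoid sum -- frequencies scaled by the
#' subject's cadence multiplier and amplitudes by its amplitude multiplier
#' -- plus the gravity offset (accelerometer axes only) and white Gaussian
#' noise. Bit-reproducible for a given (profiles, seed).
#'
#' @param activity an `ActivityProfile`.
#' @param subject a `SubjectProfile`.
#' @param durationS duration in seconds (`durationS * rateHz >= 2`).
#' @param rateHz sampling rate (default 100).
#' @param seed integer seed for the noise.
#' @param subjectId,trialId metadata tokens for the resulting record.
#' @return a [SensorRecord-class].
#' @export
generateRecord <- function(activity, subject, durationS, rateHz = 100,
                           seed = 1L, subjectId = "S1", trialId = "T1") {
  stopifnot(inherits(activity, "ActivityProfile"),
    inherits(subject, "SubjectProfile"))
  stopIfNot(durationS > 0 && rateHz > 0, "duration and rate must be > 0")
  n <- round(durationS * rateHz)
  stopIfNot(n >= 2, "need at least 2 samples (durationS * rateHz >= 2)")
  t <- (seq_len(n) - 1) / rateHz
  sig <- matrix(0, n, 6, dimnames = list(NULL, CHANNELS))
  for (f in seq_along(activity$freqHz)) {
    w <- 2 * pi * activity$freqHz[f] * subject$cadence
    for (ch in 1:6) {
      sig[, ch] <- sig[, ch] + subject$ampScale * activity$amp[ch, f] *
        sin(w * t + activity$phase[ch, f])
    }
  }
  sig[, 1:3] <- sig[, 1:3] + rep(activity$gravity, each = n)
  noise <- withLocalSeed(seed + subject$seedOffset, {
    matrix(stats::rnorm(n * 6), n, 6) %*% diag(activity$noiseSd)
  })
  sensorRecord(
    subjectId, activity$name, trialId,
    data.frame(t = t, sig + noise), rateHz
  )
}

#' Generate a full synthetic multi-subject dataset
#'
#' Emulates the shape of a multi-subject activity corpus: every subject
#' performs every activity for `nTrials` trials. Subject profiles are drawn
#' with seeded jitter -- cadence multipliers uniform on [0.9, 1.1] (so
#' subject identification is hard but solvable) and amplitude multipliers
#' uniform on [0.9, 1.1].
#'
#' @param nSubjects number of subjects (ids `S1`, `S2`, ...).
#' @param activities list of `ActivityProfile`s
#'   (default [defaultActivityProfiles()]).
#' @param nTrials trials per subject/activity pair.
#' @param durationS trial duration in seconds.
#' @param rateHz sampling rate.
#' @param seed master seed; everything derives from it.
#' @param subjects optional list of `SubjectProfile`s to use instead of
#'   drawing them (length `nSubjects`).
#' @return list of `nSubjects * length(activities) * nTrials`
#'   [SensorRecord-class] objects.
#' @export
generateDataset <- function(nSubjects, activities = defaultActivityProfiles(),
                            nTrials = 1L, durationS = 30, rateHz = 100,
                            seed = 1L, subjects = NULL) {
  stopIfNot(length(activities) >= 1L, "need at least one activity profile")
  stopIfNot(nSubjects >= 1L && nTrials >= 1L, "counts must be >= 1")
  if (is.null(subjects)) {
    subjects <- withLocalSeed(seed, {
      cad <- stats::runif(nSubjects, 0.9, 1.1)
      amp <- stats::runif(nSubjects, 0.9, 1.1)
      lapply(seq_len(nSubjects), function(i) {
        subjectProfile(cad[i], amp[i], seedOffset = i)
      })
    })
  }
  stopIfNot(length(subjects) == nSubjects, "need one profile per subject")
  recSeeds <- deriveSeeds(
    seed, nSubjects * length(activities) * nTrials
  )
  records <- list(); idx <- 0L
  for (s in seq_len(nSubjects)) {
    for (act in activities) {
      for (tr in seq_len(nTrials)) {
        idx <- idx + 1L
        records[[idx]] <- generateRecord(
          act, subjects[[s]], durationS, rateHz, recSeeds[idx],
          subjectId = paste0("S", s), trialId = paste0("T", tr)
        )
      }
    }
  }
  records
}

#' Generate labelled Gaussian feature clusters
#'
#' Direct test bed for the classifier: classes are unit-within-SD Gaussian
#' clusters in d dimensions whose means differ only on the informative
#' dimensions. Each class carries a distinct sign code over the informative
#' dimensions and its mean is `+/- separation/2` per coded dimension, so
#' any two classes differ by `separation` (in pooled within-class SD
#' units) on every dimension where their codes disagree -- two classes get
#' opposite codes and therefore differ by `separation` on every informative
#' dimension. This mirrors windowed activity features, where most catalogue
#' features shift by some multiple of their within-class spread and
#' different class pairs are separated by different feature subsets.
#'
#' @param nClasses number of classes (labels `C01`, `C02`, ...).
#' @param d feature dimension (default 99, the catalogue size).
#' @param nPerClass windows per class (>= 4).
#' @param informativeDims indices (1..d) of the informative dimensions.
#' @param separation per-dimension class-mean gap in within-class SD units
#'   (>= 0).
#' @param seed integer seed for the Gaussian noise.
#' @param codeSeed integer seed for the class sign codes, separate from
#'   `seed` so that training and held-out sets drawn with different noise
#'   seeds share the same class geometry.
#' @return a [FeatureSet-class] with the class label in its activity
#'   column; rows are named `f4..f102` when `d = 99` so the matrix is
#'   interchangeable with extracted features.
#' @export
generateFeatureClusters <- function(nClasses, d = 99L, nPerClass,
                                    informativeDims = seq_len(d),
                                    separation, seed = 1L,
                                    codeSeed = 1L) {
  stopIfNot(separation >= 0, "'separation' must be >= 0")
  stopIfNot(nPerClass >= 4L, "'nPerClass' must be >= 4")
  stopIfNot(nClasses >= 1L, "'nClasses' must be >= 1")
  informativeDims <- as.integer(informativeDims)
  stopIfNot(
    all(informativeDims >= 1L & informativeDims <= d),
    "informative dims must lie in 1..d"
  )
  m <- length(informativeDims)
  codes <- withLocalSeed(codeSeed, {
    cd <- matrix(1, nClasses, max(m, 1L))
    if (nClasses >= 2L) cd[2L, ] <- -1
    if (nClasses > 2L && m > 0L) {
      for (c in 3:nClasses) {
        repeat {
          cand <- sample(c(-1, 1), m, replace = TRUE)
          dup <- any(apply(
            cd[seq_len(c - 1L), , drop = FALSE], 1,
            function(r) all(r == cand)
          ))
          if (!dup) break
        }
        cd[c, ] <- cand
      }
    }
    cd
  })
  withLocalSeed(seed, {
    means <- matrix(0, d, nClasses)
    if (m > 0L) {
      means[informativeDims, ] <- t(codes[, seq_len(m), drop = FALSE]) *
        (separation / 2)
    }
    labels <- rep(sprintf("C%02d", seq_len(nClasses)), each = nPerClass)
    X <- matrix(stats::rnorm(d * nClasses * nPerClass), nrow = d) +
      means[, rep(seq_len(nClasses), each = nPerClass)]
    rownames(X) <- if (d == 99L) paste0("f", featureIds()) else
      paste0("f", seq_len(d) + 3L)
    featureSetFromMatrix(X, labels)
  })
}
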