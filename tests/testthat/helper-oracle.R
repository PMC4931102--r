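# Independent straight-from-formula implementation of the 99-feature
# catalogue, written with explicit loops/sums and kept deliberately separate
# from the package's vectorized registry. Used to cross-check every feature.

oracleVar <- function(x) {
  n <- length(x)
  (1 / (n * (n - 1))) * (n * sum(x^2) - sum(x)^2)
}

oracleAngle <- function(u, v) {
  phi <- numeric(length(u))
  for (i in seq_along(u)) {
    den <- abs(u[i]) * abs(v[i])
    phi[i] <- if (den == 0) 0 else acos(min(1, max(-1, u[i] * v[i] / den)))
  }
  phi
}

oracleFeature <- function(id, w) {
  n <- nrow(w)
  ax <- w[, 1]; ay <- w[, 2]; az <- w[, 3]
  gx <- w[, 4]; gy <- w[, 5]; gz <- w[, 6]
  chan <- list(ax, ay, az, gx, gy, gz)
  corr0 <- function(u, v) {
    if (oracleVar(u) == 0 || oracleVar(v) == 0) 0 else cor(u, v)
  }
  dsum <- function(x) { # double cumulative sum
    s <- 0
    for (j in seq_len(n)) s <- s + sum(x[1:j])
    s
  }
  miA <- sqrt(ax^2 + ay^2 + az^2)
  miG <- sqrt(gx^2 + gy^2 + gz^2)
  miGA <- sqrt((gx - ax)^2 + (gy - ay)^2 + (gz - az)^2)

  if (id %in% 4:9) return(chan[[id - 3]][n])
  if (id %in% 10:15) return(oracleVar(chan[[id - 9]]))
  if (id == 16) return(miA[n])
  if (id == 17) return(miG[n])
  if (id == 18) return(miGA[n])
  if (id == 19) return(oracleVar(miA))
  if (id == 20) return(oracleVar(miG))
  if (id == 21) return(oracleVar(miGA))
  if (id == 22) return(atan2(ay[n], ax[n]))
  if (id == 23) return(sqrt(ax[n]^2 + ay[n]^2))
  if (id == 24) return(az[n])
  if (id == 25) return(atan2(gy[n], gx[n]))
  if (id == 26) return(sqrt(gx[n]^2 + gy[n]^2))
  if (id == 27) return(gz[n])
  if (id == 28) return(atan2(ay[n] - gy[n], ax[n] - gx[n]))
  if (id == 29) return(sqrt((ay[n] - gy[n])^2 + (ax[n] - gx[n])^2))
  if (id == 30) return(az[n] - gz[n])
  if (id == 31) return((sum(abs(ax)) + sum(abs(ay)) + sum(abs(az))) / n)
  if (id == 32) return((sum(abs(gx)) + sum(abs(gy)) + sum(abs(gz))) / n)
  if (id == 33) {
    return((sum(abs(ax - gx)) + sum(abs(ay - gy)) + sum(abs(az - gz))) / n)
  }
  if (id %in% 34:36) {
    m <- switch(id - 33,
      cbind(ax, ay, az), cbind(gx, gy, gz),
      cbind(ax - gx, ay - gy, az - gz)
    )
    return(max(eigen(cov(m))$values))
  }
  if (id %in% 37:42) return(sum(chan[[id - 36]]^2) / n)
  if (id %in% 43:48) {
    x <- chan[[id - 42]]
    return(max(x) - min(x))
  }
  if (id == 49) return(corr0(ax, ay))
  if (id == 50) return(corr0(ax, az))
  if (id == 51) return(corr0(ay, az))
  if (id == 52) return(corr0(gx, gy))
  if (id == 53) return(corr0(gx, gz))
  if (id == 54) return(corr0(gy, gz))
  if (id %in% 55:57) {
    ma <- c(mean(ax), mean(ay), mean(az))
    mg <- c(mean(gx), mean(gy), mean(gz))
    p <- if (sum(mg^2) == 0) c(0, 0, 0) else sum(ma * mg) / sum(mg^2) * mg
    return(p[id - 54])
  }
  if (id %in% 58:60) {
    phi <- oracleAngle(ax, ay)
    return(switch(id - 57, mean(phi), oracleVar(phi), sum(phi^2) / n))
  }
  if (id %in% 61:63) {
    i <- id - 60
    return(sum((chan[[i]] - chan[[i + 3]])^2) / n)
  }
  if (id == 64) return(sum((ax - ay)^2) / n)
  if (id == 65) return(sum((ax - az)^2) / n)
  if (id == 66) return(sum((ay - az)^2) / n)
  if (id %in% 67:69) {
    phi <- oracleAngle(ax - gx, ay - gy)
    return(switch(id - 66, mean(phi), oracleVar(phi), sum(phi^2) / n))
  }
  if (id %in% 70:72) {
    phi <- oracleAngle(gx, gy)
    return(switch(id - 69, mean(phi), oracleVar(phi), sum(phi^2) / n))
  }
  if (id %in% 73:75) {
    phi <- oracleAngle(ax, ay) - oracleAngle(gx, gy)
    return(switch(id - 72, mean(phi), oracleVar(phi), sum(phi^2) / n))
  }
  if (id %in% 76:81) return(dsum(chan[[id - 75]]))
  if (id == 82) {
    s <- 0
    for (i in seq_len(n)) {
      s <- s + abs(sum(ax[1:i])) + abs(sum(ay[1:i])) + abs(sum(az[1:i]))
    }
    return(s / n)
  }
  if (id == 83) {
    s <- 0
    for (i in seq_len(n)) {
      s <- s + abs(sum(gx[1:i])) + abs(sum(gy[1:i])) + abs(sum(gz[1:i]))
    }
    return(s / n)
  }
  if (id == 84) {
    s <- 0
    for (i in seq_len(n)) {
      s <- s + abs(sum(ax[1:i]) - sum(gx[1:i])) +
        abs(sum(ay[1:i]) - sum(gy[1:i])) +
        abs(sum(az[1:i]) - sum(gz[1:i]))
    }
    return(s / n)
  }
  if (id %in% 85:90) {
    x <- chan[[id - 84]]
    s1 <- vapply(seq_len(n), function(i) sum(x[1:i]), numeric(1))
    return(dsum(s1))
  }
  if (id %in% 91:93) {
    i <- id - 90
    d <- vapply(seq_len(n), function(j) {
      sum(chan[[i]][1:j]) - sum(chan[[i + 3]][1:j])
    }, numeric(1))
    return(dsum(d))
  }
  if (id %in% 94:102) {
    mcs <- vapply(chan, dsum, numeric(1))
    if (id == 94) return(atan2(mcs[2], mcs[1]))
    if (id == 95) return(sqrt(mcs[1]^2 + mcs[2]^2))
    if (id == 96) return(mcs[3])
    if (id == 97) return(atan2(mcs[5], mcs[4]))
    if (id == 98) return(sqrt(mcs[4]^2 + mcs[5]^2))
    if (id == 99) return(mcs[6])
    if (id == 100) return(atan2(mcs[2] - mcs[5], mcs[1] - mcs[4]))
    if (id == 101) return(sqrt((mcs[1] - mcs[4])^2 + (mcs[2] - mcs[5])^2))
    if (id == 102) return(mcs[3] - mcs[6])
  }
  stop("oracle: unknown id ", id)
}

oracleFeatureVector <- function(w) {
  vapply(4:102, oracleFeature, numeric(1), w = w)
}
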