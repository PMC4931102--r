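trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

test_that("kernel density evaluation follows the Parzen sum", {
  m <- fitKde(0, bandwidth = 1)
  expect_equal(evalKde(m, 0), 1 / sqrt(2 * pi))
  sym <- fitKde(c(-1, 1), bandwidth = 0.5)
  xs <- seq(0.1, 4, by = 0.3)
  expect_equal(evalKde(sym, xs), evalKde(sym, -xs))
  expect_true(all(evalKde(sym, seq(-10, 10, length.out = 101)) >= 0))
  expect_error(fitKde(numeric(0)), "at least one sample")
  expect_error(fitKde(1:3, bandwidth = 0), "positive")
})

test_that("densities integrate to one on a wide grid", {
  set.seed(1)
  m <- fitKde(rnorm(500))
  x <- seq(-8, 8, length.out = 2048)
  expect_equal(trapezoid(x, evalKde(m, x)), 1, tolerance = 1e-3)
})

test_that("joint densities are per-dimension products", {
  set.seed(2)
  Z <- matrix(rnorm(3 * 40), 3, 40)
  j <- jointDensity(Z)
  p <- c(0.3, -1, 0.7)
  expect_equal(
    evalJoint(j, p),
    prod(vapply(1:3, function(i) evalKde(j@dims[[i]], p[i]), numeric(1)))
  )
  j1 <- jointDensity(Z[1, , drop = FALSE])
  expect_equal(evalJoint(j1, 0.4), evalKde(j1@dims[[1]], 0.4))
  expect_true(all(evalJoint(j, matrix(rnorm(30), 3)) >= 0))
  expect_error(evalJoint(j, c(1, 2)), "dimension mismatch")
})

test_that("shared grids cover both samples padded by three bandwidths", {
  set.seed(3)
  a <- jointDensity(matrix(runif(50), 1), bandwidths = 0.1)
  b <- jointDensity(matrix(runif(50), 1), bandwidths = 0.08)
  g <- makeSharedGrid(a, b, 256L)
  expect_identical(g@resolution, 256L)
  hmax <- max(a@dims[[1]]@bandwidth, b@dims[[1]]@bandwidth)
  expect_equal(g@lower, min(a@dims[[1]]@samples, b@dims[[1]]@samples) - 3 * hmax)
  expect_equal(g@upper, max(a@dims[[1]]@samples, b@dims[[1]]@samples) + 3 * hmax)
  # samples span (0, 1) and h_max = 0.1, so bounds stay within the 3h pad
  expect_true(g@lower > -0.3 - 1e-9 && g@upper < 1.3 + 1e-9)
  g2 <- makeSharedGrid(a, b, 256L)
  expect_identical(g, g2)
})

test_that("jaccard distance is a bounded symmetric dissimilarity", {
  set.seed(4)
  s <- rnorm(60)
  a <- jointDensity(matrix(s, 1))
  b <- jointDensity(matrix(s, 1))
  g <- makeSharedGrid(a, b)
  expect_equal(jaccardDistance(a, b, g), 0, tolerance = 1e-12)

  far <- jointDensity(matrix(rnorm(30, 100, 0.1), 1))
  near <- jointDensity(matrix(rnorm(30, 0, 0.1), 1))
  gf <- makeSharedGrid(near, far)
  expect_gte(jaccardDistance(near, far, gf), 0.999)
  expect_equal(
    jaccardDistance(near, far, gf), jaccardDistance(far, near, gf)
  )

  for (i in 1:20) {
    x <- jointDensity(matrix(rnorm(40, runif(1, -2, 2)), 1))
    y <- jointDensity(matrix(rnorm(40, runif(1, -2, 2)), 1))
    gg <- makeSharedGrid(x, y)
    dj <- jaccardDistance(x, y, gg)
    expect_true(dj >= 0 && dj <= 1)
  }
})

test_that("jaccard distance is invariant under a common affine rescaling", {
  set.seed(5)
  sa <- rnorm(80); sb <- rnorm(80, 1.5)
  mk <- function(x, h) {
    new("JointDensity", dims = list(fitKde(x, h)))
  }
  ha <- 0.3; hb <- 0.4
  a <- mk(sa, ha); b <- mk(sb, hb)
  d1 <- jaccardDistance(a, b, makeSharedGrid(a, b))
  sc <- 3.7; off <- -2
  a2 <- mk(sa * sc + off, ha * sc); b2 <- mk(sb * sc + off, hb * sc)
  d2 <- jaccardDistance(a2, b2, makeSharedGrid(a2, b2))
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("discretized jaccard matches a fine-quadrature oracle", {
  # two gaussian densities N(0,1) vs N(1,1): oracle integrates the true
  # densities; the estimate uses KDEs of large samples on the shared grid
  set.seed(6)
  xa <- rnorm(4000); xb <- rnorm(4000, 1)
  a <- jointDensity(matrix(xa, 1)); b <- jointDensity(matrix(xb, 1))
  dj <- jaccardDistance(a, b, makeSharedGrid(a, b))
  x <- seq(-9, 10, length.out = 20001)
  fa <- dnorm(x); fb <- dnorm(x, 1)
  oracle <- 1 - trapezoid(x, pmin(fa, fb)) / trapezoid(x, pmax(fa, fb))
  expect_lt(abs(dj - oracle), 0.02)
})
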