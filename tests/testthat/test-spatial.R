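test_that("manhattan distance is the coordinate-wise L1 metric", {
  expect_equal(manhattanDistance(c(0, 0), c(3, 4)), 7)
  expect_equal(manhattanDistance(c(2, -1), c(2, -1)), 0)
  set.seed(1)
  for (k in 1:10) {
    a <- runif(2, -5, 5); b <- runif(2, -5, 5)
    expect_equal(manhattanDistance(a, b), manhattanDistance(b, a))
  }
  expect_error(manhattanDistance(c(Inf, 0), c(0, 0)), "finite")
})

test_that("auto threshold is the largest nearest-neighbor distance", {
  line <- data.frame(id = 1:3, x = c(0, 1, 6), y = 0)
  expect_equal(minNeighborThreshold(line), 5)
  expect_equal(minNeighborThreshold(data.frame(x = c(0, 3), y = c(0, 4))), 7)
  expect_equal(minNeighborThreshold(gridPoints(3, 3)), 1)
  expect_error(minNeighborThreshold(gridPoints(1, 1)), "at least 2")
})

test_that("fixed-distance weights are inclusive, binary, row-standardized", {
  two <- data.frame(id = 1:2, x = c(0, 3), y = 0)
  W <- buildWeights(two, threshold = 3)
  expect_equal(as.matrix(W@W), matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)
  expect_equal(W@S0, 2)
  line <- data.frame(id = 1:3, x = c(0, 1, 6), y = 0)
  Wl <- buildWeights(line, threshold = "auto")
  expect_equal(Wl@threshold, 5)
  # neighbor relation: 0-1 (d=1), 1-6 (d=5, inclusive); 0-6 (d=6) out
  expect_equal(Wl@nbCounts, c(1L, 2L, 1L))
  expect_equal(neighborCountHistogram(Wl), c("1" = 2L, "2" = 1L))
  expect_equal(unname(Matrix::rowSums(Wl@W)), rep(1, 3))
  expect_equal(Wl@S0, 3)
  expect_error(buildWeights(line, threshold = 0.5), "isolated")
  expect_warning(buildWeights(rbind(line, data.frame(id = 4, x = 100,
                                                     y = 0)),
                              threshold = 5), "isolated")
  # histogram partitions the point set
  Wg <- randomWeights(30, seed = 4)
  expect_equal(sum(neighborCountHistogram(Wg)), 30)
})

test_that("checkerboard dispersion gives I and every local I of -1", {
  cb <- checkerboard()
  m <- globalMoransI(cb$values, cb$W)
  expect_equal(m$I, -1)
  sc <- moranScatter(cb$values, cb$W)
  slope <- coef(lm(lag ~ z, data = sc))[["z"]]
  expect_equal(slope, -1)
  li <- localMoransI(cb$values, cb$W, nPerm = 99, seed = 1)
  expect_equal(li$Ii, rep(-1, 4))
  expect_equal(sum(li$Ii), cb$W@S0 * m$I)
})

test_that("global I matches the naive double-sum oracle to 1e-12", {
  for (s in 1:5) {
    W <- randomWeights(5 + 9 * s, seed = s)
    set.seed(100 + s)
    v <- runif(nrow(W@W), 0, 100)
    expect_equal(globalMoransI(v, W)$I, naiveMoran(v, as.matrix(W@W)),
                 tolerance = 1e-12)
  }
  cb <- checkerboard()
  expect_error(globalMoransI(rep(5, 4), cb$W), "constant")
})

test_that("independent Moran implementation agrees on observed I", {
  skip_if_not_installed("ape")
  W <- randomWeights(40, seed = 9)
  set.seed(2); v <- rnorm(40, 50, 10)
  ours <- globalMoransI(v, W)
  # ape row-normalizes internally; feed the binary relation
  Wb <- as.matrix(W@W) > 0
  theirs <- ape::Moran.I(v, Wb * 1, scaled = FALSE)
  # ape row-normalizes the weights too, so observed I must agree
  expect_equal(ours$I, theirs$observed, tolerance = 1e-9)
})

test_that("variance modes give consistent significance calls", {
  pts <- gridPoints(10, 10)
  W <- buildWeights(pts, threshold = 1)
  set.seed(42)
  sss <- generateSceneCompositions(pts, defaultArchetypes()["arterial"],
                                   seed = 6)
  v <- generateLatentStress(sss, W, spatialRho = 0.7, noiseSd = 6, seed = 8)
  mr <- globalMoransI(v, W, "randomization")
  mn <- globalMoransI(v, W, "normality")
  mp <- globalMoransI(v, W, "permutation", nPerm = 499, seed = 2)
  expect_equal(mr$I, mn$I)
  expect_equal(mr$I, mp$I)
  expect_equal(mr$E_I, -1 / 99)
  expect_true(mr$p < 0.05 && mn$p < 0.05 && mp$p < 0.05)
  expect_gt(mr$Z, 1.96)
  # the closed-form variances agree with the permutation spread broadly
  expect_equal(mr$VAR_I, mp$VAR_I, tolerance = 0.5)
})

test_that("Moran scatter slope equals I on random fixtures", {
  for (s in 1:4) {
    W <- randomWeights(25, seed = 20 + s)
    set.seed(s); v <- rnorm(25, 40, 15)
    sc <- moranScatter(v, W)
    slope <- coef(lm(lag ~ z, data = sc))[["z"]]
    expect_equal(slope, globalMoransI(v, W)$I, tolerance = 1e-9)
  }
})

test_that("local I decomposes the global statistic and labels quadrants", {
  for (s in 1:4) {
    W <- randomWeights(30, seed = 30 + s)
    set.seed(s); v <- runif(30, 0, 100)
    li <- localMoransI(v, W, nPerm = 99, seed = s)
    expect_equal(li$Ii, naiveLocalMoran(v, as.matrix(W@W)),
                 tolerance = 1e-10)
    expect_equal(sum(li$Ii), W@S0 * globalMoransI(v, W)$I,
                 tolerance = 1e-9)
    # quadrants agree with the scatter signs wherever significant
    sc <- moranScatter(v, W)
    sig <- li$quadrant != "ns"
    expect_true(all((li$quadrant[sig] %in% c("HH", "HL")) ==
                      (sc$z[sig] >= 0)))
    expect_true(all((li$quadrant[sig] %in% c("HH", "LH")) ==
                      (sc$lag[sig] >= 0)))
  }
})

test_that("conditional permutation p matches the exhaustive law at n = 6", {
  pts <- data.frame(id = 1:6, x = c(0, 1, 2, 0, 1, 2), y = rep(c(0, 1), 3))
  W <- buildWeights(pts, threshold = 1)
  set.seed(7); v <- c(90, 85, 20, 88, 15, 25)
  li <- localMoransI(v, W, nPerm = 999, seed = 3)
  d <- v - mean(v)
  S2 <- sum(d^2) / 6
  i <- 1L
  wrow <- as.numeric(W@W[i, ])
  nbr <- which(wrow != 0)
  others <- d[-i]
  # exhaustive: all ordered arrangements of the 5 other values over the
  # neighbor slots
  perms <- permsAll(5)
  Istar <- apply(perms, 1, function(pp)
    d[i] / S2 * sum(wrow[nbr] * others[pp][seq_along(nbr)]))
  exhaustive <- mean(abs(Istar) >= abs(li$Ii[i]))
  expect_lt(abs(li$p[i] - exhaustive), 3 * sqrt(0.25 / 999) + 2 / 999)
})
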