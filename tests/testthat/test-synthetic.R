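test_that("road networks are seed-deterministic and stay inside the extent", {
  ext <- c(0, 0, 1000, 1000)
  n1 <- generateRoadNetwork(50, ext, seed = 1)
  n2 <- generateRoadNetwork(50, ext, seed = 1)
  expect_identical(n1@segments, n2@segments)
  for (s in n1@segments) {
    expect_true(all(s[, 1] >= 0 & s[, 1] <= 1000))
    expect_true(all(s[, 2] >= 0 & s[, 2] <= 1000))
  }
  # total length recomputed by coordinate arithmetic
  len <- sum(vapply(n1@segments,
                    function(s) sum(sqrt(rowSums(diff(s)^2))), numeric(1)))
  expect_gt(len, 0)
  one <- generateRoadNetwork(1, c(0, 0, 1, 1), seed = 7)
  expect_length(one@segments, 1)
  expect_error(generateRoadNetwork(0, ext), "nSegments")
})

test_that("scene compositions live on the extended simplex", {
  pts <- gridPoints(10, 10)
  sss <- generateSceneCompositions(pts, defaultArchetypes(), seed = 3)
  fr <- stressFractions(sss)
  expect_true(all(fr >= 0))
  expect_true(all(rowSums(fr) <= 1 + 1e-9))
  expect_equal(unname(rowSums(fr) + voidFraction(sss)), rep(1, 100))
  # reproducibility
  sss2 <- generateSceneCompositions(pts, defaultArchetypes(), seed = 3)
  expect_identical(stressFractions(sss), stressFractions(sss2))
  expect_error(
    generateSceneCompositions(pts, defaultArchetypes(),
                              assignment = rep("nope", 100)),
    "unassigned|unknown")
})

test_that("near-degenerate sky archetype concentrates mass on sky", {
  skyArk <- list(sky = sceneArchetype("sky", c(sky = 0.999, void = 0.001),
                                      precision = 1e5))
  sss <- generateSceneCompositions(gridPoints(5, 2), skyArk, seed = 1)
  expect_true(all(stressFractions(sss)[, "sky"] > 0.98))
})

test_that("park archetype draws more vegetation than commercial", {
  arks <- defaultArchetypes()
  pts <- gridPoints(25, 20)  # 500 draws
  park <- generateSceneCompositions(pts, arks["park"], seed = 11)
  comm <- generateSceneCompositions(pts, arks["commercial"], seed = 11)
  expect_gt(mean(stressFractions(park)[, "vegetation"]),
            mean(stressFractions(comm)[, "vegetation"]))
})

test_that("latent stress is exactly linear in the noiseless limit", {
  pts <- gridPoints(5, 5)
  sss <- generateSceneCompositions(pts, defaultArchetypes(), seed = 2)
  W <- buildWeights(pts, threshold = 1)
  co <- defaultStressCoefficients()
  sc <- generateLatentStress(sss, W, coefficients = co, intercept = 55,
                             spatialRho = 0, noiseSd = 0)
  expect_equal(sc, pmin(pmax(55 + drop(stressFractions(sss) %*% co), 0),
                        100))
  expect_error(generateLatentStress(sss, W, spatialRho = 1), "spatialRho")
  big <- generateLatentStress(sss, W, intercept = 300, noiseSd = 20,
                              spatialRho = 0.5, seed = 4)
  expect_true(all(big >= 0 & big <= 100))
  expect_true(any(big == 100))  # clipping engaged
})

test_that("SAR fields with rho = 0.7 carry more spatial signal than rho = 0", {
  pts <- gridPoints(12, 12)
  W <- buildWeights(pts, threshold = 1)
  sss <- generateSceneCompositions(pts, defaultArchetypes()["arterial"],
                                   seed = 5)
  i07 <- i00 <- numeric(20)
  for (r in 1:20) {
    s7 <- generateLatentStress(sss, W, spatialRho = 0.7, noiseSd = 8,
                               seed = 100 + r)
    s0 <- generateLatentStress(sss, W, spatialRho = 0, noiseSd = 8,
                               seed = 100 + r)
    i07[r] <- globalMoransI(s7, W)$I
    i00[r] <- globalMoransI(s0, W)$I
  }
  expect_gt(mean(i07), mean(i00))
  # rho = 0 fields center near E(I) = -1/(n-1)
  expect_lt(abs(mean(i00) - (-1 / 143)), 0.05)
})

test_that("raters score linearly, clip, and replay their noise stream", {
  zero <- setNames(rep(0, 19), cityscapesClasses())
  const <- raterProfile(zero, intercept = 42, noiseSd = 0)
  expect_equal(rateScore(const, zero), 42)
  high <- raterProfile(zero, intercept = 120, noiseSd = 0)
  expect_equal(rateScore(high, zero), 100)
  # monotone in building when its coefficient is positive
  co <- zero; co["building"] <- 50
  r <- raterProfile(co, intercept = 20, noiseSd = 0)
  scores <- vapply(seq(0, 0.9, by = 0.1),
                   function(b) rateScore(r, buildingComposition(b, 0)),
                   numeric(1))
  expect_true(all(diff(scores) > 0))
  # stream reproducibility: same draws after reset, different along stream
  noisy <- raterProfile(zero, intercept = 50, noiseSd = 5, seed = 9)
  a <- rateScore(noisy, zero); b <- rateScore(noisy, zero)
  expect_false(a == b)
  resetRater(noisy)
  expect_equal(rateScore(noisy, zero), a)
  expect_equal(rateScore(noisy, zero), b)
  expect_error(rateScore(noisy, zero - 1), "invalid composition")
})

test_that("label-raster rendering apportions pixels within one per class", {
  skyOnly <- setNames(c(rep(0, 10), 1, rep(0, 8)), cityscapesClasses())
  r <- renderLabelRaster(skyOnly, 4, 4)
  expect_true(all(r@labels == 10L))  # sky id
  mix <- setNames(rep(0, 19), cityscapesClasses())
  mix[c("sky", "road", "building")] <- c(0.5, 0.25, 0.25)
  r2 <- renderLabelRaster(mix, 2, 2)
  expect_equal(sort(tabulate(r2@labels + 1L, 19)[c(11, 1, 3)],
                    decreasing = TRUE), c(2, 1, 1))
  expect_error(renderLabelRaster(mix, 0, 0), "at least one pixel")
  # deterministic for a fixed seed
  expect_identical(renderLabelRaster(mix, 8, 8, seed = 3)@labels,
                   renderLabelRaster(mix, 8, 8, seed = 3)@labels)
})

test_that("render/extract round trip is identity within quantization", {
  fr <- randomFractions(5, seed = 21)
  for (i in 1:5) {
    r <- renderLabelRaster(fr[i, ], 416, 416, seed = i)
    back <- fractionsFromLabelRaster(r)
    expect_true(all(abs(back - fr[i, ]) <= 1 / 173056 + 1e-12))
  }
})
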