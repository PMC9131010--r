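test_that("forest fits are seed-deterministic and handle degenerate targets", {
  fr <- randomFractions(60, seed = 1)
  yConst <- rep(55, 60)
  m <- fitForest(fr, yConst, nTrees = 25, seed = 3)
  expect_equal(predictScores(m, fr), rep(55, 60))
  oe <- oobError(m, fr, yConst)
  expect_equal(oe$oob_error_pct, 0)
  expect_equal(oe$oob_rmse, 0)
  m2 <- fitForest(fr, yConst, nTrees = 25, seed = 3)
  expect_identical(m@fit$inbag, m2@fit$inbag)
  m3 <- fitForest(fr, yConst, nTrees = 25, seed = 4)
  expect_false(identical(m@fit$inbag, m3@fit$inbag))
  expect_error(fitForest(fr[1, , drop = FALSE], 50), "at least 2")
  expect_error(fitForest(fr, rep(150, 60)), "\\[0, 100\\]")
})

test_that("the forest beats the mean predictor on a linear signal", {
  fr <- randomFractions(500, seed = 2)
  y <- pmin(pmax(20 + 150 * fr[, "building"], 0), 100)
  m <- fitForest(fr, y, nTrees = 100, seed = 5)
  oe <- oobError(m, fr, y)
  expect_lt(oe$oob_rmse, sd(y))
  expect_gte(oe$oob_rmse, oe$oob_error_pct)  # RMSE >= MAE
})

test_that("exact two-thirds subsampling leaves one third out of bag", {
  fr <- randomFractions(90, seed = 3)
  y <- 50 + 30 * fr[, "sky"]
  m <- fitForest(fr, pmin(y, 100), nTrees = 20, seed = 1,
                 sampleFrac = 2 / 3)
  expect_true(all(colSums(m@fit$inbag > 0) == 60))
  expect_true(all(colSums(m@fit$inbag == 0) == 30))
})

test_that("OOB aggregation matches a hand-built single-tree fixture", {
  # one tree, 4 samples; samples 3 and 4 in bag, 1 and 2 out of bag
  y <- c(10, 20, 30, 40)
  treePreds <- matrix(c(12, 26, 31, 39), 4, 1)
  inbag <- matrix(c(0L, 0L, 2L, 2L), 4, 1)
  st <- urbanstress:::oobStats(y, treePreds, inbag)
  expect_equal(st$oob_pred[1:2], c(12, 26))
  expect_true(all(is.na(st$oob_pred[3:4])))
  expect_equal(st$n_excluded, 2)
  expect_equal(st$oob_error_pct, mean(c(2, 6)))
  expect_equal(st$oob_rmse, sqrt(mean(c(4, 36))))
  # two trees: sample 2 OOB in both -> average of the two tree predictions
  tp2 <- cbind(treePreds, c(18, 22, 29, 41))
  ib2 <- cbind(inbag, c(1L, 0L, 1L, 0L))
  st2 <- urbanstress:::oobStats(y, tp2, ib2)
  expect_equal(st2$oob_pred[2], mean(c(26, 22)))
  expect_equal(st2$oob_pred[4], 41)
  expect_equal(st2$n_excluded, 1)
})

test_that("indicator importance arithmetic follows the OOB formula", {
  # 3 OOB samples; predictions agree 3 times before permutation and once
  # after -> VI = (3 - 1) / 3
  y <- c(50, 60, 70)
  pred <- c(52, 58, 71)
  predPerm <- c(44, 61, 80)
  expect_equal(urbanstress:::viFromPredictions(y, pred, predPerm, tol = 5),
               (3 - 1) / 3)
  expect_equal(urbanstress:::viFromPredictions(y, pred, predPerm,
                                               tol = Inf), 0)
  expect_equal(urbanstress:::viFromPredictions(y, pred, predPerm, tol = 0),
               0)
  expect_error(urbanstress:::viFromPredictions(numeric(), numeric(),
                                               numeric(), 5), "empty OOB")
})

test_that("permutation importance flags the active feature, not idle ones", {
  fr <- randomFractions(150, seed = 6)
  y <- pmin(pmax(25 + 120 * fr[, "building"], 0), 100)
  m <- fitForest(fr, y, nTrees = 40, seed = 2)
  vi <- variableImportance(m, fr, y, agreementTol = 5, seed = 1)
  expect_s3_class(vi, "importanceResult")
  expect_equal(vi$feature[which.max(vi$vi)], "building")
  # infinite tolerance collapses every importance to zero
  vi0 <- variableImportance(m, fr, y, agreementTol = Inf, seed = 1)
  expect_equal(vi0$vi, rep(0, 19))
  # MSE-increase cross-check ranks the same feature first
  mi <- mseImportance(m, fr, y, seed = 1)
  expect_equal(names(which.max(mi)), "building")
})

test_that("a feature the target never uses has importance near zero", {
  # independent (non-compositional) features so the idle column carries no
  # indirect signal
  set.seed(77)
  X <- matrix(runif(150 * 6, 0, 0.5), 150, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  y <- pmin(pmax(20 + 140 * X[, "f1"], 0), 100)
  viIdle <- numeric(20)
  for (r in 1:20) {
    m <- fitForest(X, y, nTrees = 25, mtry = 2, seed = 300 + r)
    vi <- variableImportance(m, X, y, agreementTol = 5, seed = r)
    viIdle[r] <- vi$vi[vi$feature == "f6"]
  }
  expect_lt(abs(mean(viIdle)), 0.05)
})

test_that("single-feature importance dominates across seeded replicates", {
  wins <- 0L
  for (r in 1:20) {
    fr <- randomFractions(100, seed = 200 + r)
    y <- pmin(pmax(30 + 100 * fr[, "sky"], 0), 100)
    m <- fitForest(fr, y, nTrees = 25, seed = r)
    vi <- variableImportance(m, fr, y, seed = r)
    if (vi$feature[which.max(vi$vi)] == "sky") wins <- wins + 1L
  }
  expect_gte(wins, 18)
})

test_that("a scripted rater triggers exactly one intervention at streak 6", {
  fr <- randomFractions(70, seed = 7)
  # during warm-up score by a fixed rule; afterwards force errors of 12 for
  # the first six predictions, then errors of 3
  count <- new.env(); count$k <- 0L
  scripted <- function(i, comp, pred) {
    if (is.na(pred)) return(50 + 20 * comp["building"])
    count$k <- count$k + 1L
    if (count$k <= 6L) min(pred + 12, 100) else min(pred + 3, 100)
  }
  s <- runScoringSession(scripted, fr, nInit = 50, errThresh = 10,
                         streak = 6, forestParams = list(nTrees = 25),
                         seed = 11)
  expect_equal(s@interventions, 1L)
  ph <- s@records$phase
  expect_equal(ph[1:50], rep("warmup", 50))
  expect_equal(ph[51:57], c(rep("predict", 5), "intervene", "intervene"))
  expect_equal(ph[58:70], rep("predict", 13))
  expect_length(s@finalScores, 70)
})

test_that("an unreachable threshold never triggers interventions", {
  fr <- randomFractions(70, seed = 8)
  rater <- raterProfile(defaultStressCoefficients(), noiseSd = 8, seed = 3)
  s <- runScoringSession(rater, fr, nInit = 50, errThresh = 101,
                         forestParams = list(nTrees = 25), seed = 1)
  expect_equal(s@interventions, 0L)
  expect_true(all(s@records$phase[51:70] == "predict"))
  expect_error(runScoringSession(rater, fr, nInit = 70), "more images")
})

test_that("sessions replay byte-for-byte and interventions fall as the
          threshold rises", {
  fr <- randomFractions(120, seed = 9)
  run1 <- runScoringSession(raterProfile(noiseSd = 6, seed = 5), fr,
                            errThresh = 8,
                            forestParams = list(nTrees = 25), seed = 2)
  run2 <- runScoringSession(raterProfile(noiseSd = 6, seed = 5), fr,
                            errThresh = 8,
                            forestParams = list(nTrees = 25), seed = 2)
  expect_identical(run1@records, run2@records)
  expect_identical(run1@finalScores, run2@finalScores)
  iv <- vapply(c(5, 12, 101), function(th)
    runScoringSession(raterProfile(noiseSd = 6, seed = 5), fr,
                      errThresh = th,
                      forestParams = list(nTrees = 25),
                      seed = 2)@interventions, integer(1))
  expect_true(all(diff(iv) <= 0))
  expect_equal(iv[3], 0L)
})

test_that("the model's error shrinks as the session accumulates scores", {
  fr <- randomFractions(300, seed = 10)
  rater <- raterProfile(defaultStressCoefficients(), noiseSd = 0, seed = 1)
  s <- runScoringSession(rater, fr, nInit = 50, errThresh = 10,
                         forestParams = list(nTrees = 50), seed = 3)
  err <- abs(s@records$predicted - s@records$subjective)
  expect_lt(mean(err[251:300]), mean(err[51:100]))
})

test_that("consensus is the normalized weighted mean across raters", {
  mkSession <- function(scores) new("ScoringSession", raterId = "r",
                                    records = data.frame(),
                                    interventions = 0L,
                                    finalScores = scores, model = NULL)
  a <- mkSession(c(40, 80)); b <- mkSession(c(60, 80))
  expect_equal(consensusScores(list(a, b)), c(50, 80))
  expect_equal(consensusScores(list(a, b), weights = c(1, 0)), c(40, 80))
  c3 <- mkSession(c(30, 0)); d3 <- mkSession(c(50, 0)); e3 <- mkSession(c(70, 0))
  expect_equal(consensusScores(list(c3, d3, e3), weights = c(1, 2, 1))[1],
               50)
  expect_equal(consensusScores(list(a, a, a)), a@finalScores)
  expect_error(consensusScores(list(a, mkSession(1:3))), "same image set")
  expect_error(consensusScores(list(a, b), weights = c(0, 0)), "sum > 0")
})

test_that("holdout evaluation splits by rounding and nails easy targets", {
  fr <- randomFractions(999, seed = 11)
  y <- rep(50, 999)
  hv <- evaluateHoldout(fr, y, forestParams = list(nTrees = 20), seed = 1)
  expect_equal(hv$n_train, 666)
  expect_equal(hv$n_test, 333)
  expect_equal(hv$mean_abs_error, 0)
  expect_equal(hv$rmse, 0)
  expect_equal(hv$oob_error_pct, 0)
  expect_equal(hv$oob_rmse, 0)
  expect_error(evaluateHoldout(fr[1:2, ], y[1:2]), "at least 3|degenerate")
})
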