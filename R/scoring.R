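#' Fit a seeded random-forest score model
#'
#' Regression forest over the 19-element coverage fractions, fitted through
#' the \pkg{randomForest} package with bootstrap bookkeeping retained
#' (`keep.inbag`), so per-tree out-of-bag sets are recoverable exactly.
#' Each tree's bootstrap draws n samples with replacement, leaving about a
#' third of the data out of bag; `sampleFrac` switches to exact
#' without-replacement subsampling (e.g. `2/3`) instead.
#'
#' @param X numeric matrix of coverage fractions (points x features).
#' @param y numeric stress scores in `[0, 100]`.
#' @param nTrees trees (default 500).
#' @param mtry features tried per split (default 6, about a third of 19).
#' @param seed integer RNG seed; identical seed reproduces identical
#'   per-tree in-bag multisets.
#' @param nodesize minimum terminal-node size (default 2).
#' @param sampleFrac optional fraction for exact subsampling without
#'   replacement instead of the bootstrap.
#' @return a [ForestModel-class].
#' @export
fitForest <- function(X, y, nTrees = 500L, mtry = 6L, seed = 1L,
                      nodesize = 2L, sampleFrac = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  if (nrow(X) < 2L) stop("need at least 2 samples")
  if (any(y < 0 | y > 100)) stop("scores must lie in [0, 100]")
  mtry <- min(mtry, ncol(X))
  fit <- withSeed(seed, {
    if (is.null(sampleFrac))
      randomForest::randomForest(X, y, ntree = nTrees, mtry = mtry,
                                 nodesize = nodesize, keep.inbag = TRUE)
    else
      randomForest::randomForest(X, y, ntree = nTrees, mtry = mtry,
                                 nodesize = nodesize, keep.inbag = TRUE,
                                 replace = FALSE,
                                 sampsize = max(1L, round(sampleFrac *
                                                            nrow(X))))
  })
  new("ForestModel", fit = fit, seed = as.integer(seed),
      nTrees = as.integer(nTrees), mtry = as.integer(mtry),
      featureNames = if (is.null(colnames(X))) character(0) else
        colnames(X))
}

#' @rdname fitForest
#' @param model a [ForestModel-class].
#' @param newX matrix of compositions to score.
#' @return `predictScores()`: numeric predictions (mean over trees).
#' @export
predictScores <- function(model, newX) {
  newX <- as.matrix(newX)
  if (length(model@featureNames) && !is.null(colnames(newX)))
    newX <- newX[, model@featureNames, drop = FALSE]
  unname(predict(model@fit, newX))
}

# per-tree predictions (rows = samples, cols = trees)
treePredictions <- function(model, X) {
  X <- as.matrix(X)
  if (length(model@featureNames) && !is.null(colnames(X)))
    X <- X[, model@featureNames, drop = FALSE]
  predict(model@fit, X, predict.all = TRUE)$individual
}

# OOB aggregation from per-tree predictions and in-bag counts; pure so it
# can be verified against hand-built fixtures
oobStats <- function(y, treePreds, inbag) {
  oobMask <- inbag == 0L
  nOobTrees <- rowSums(oobMask)
  covered <- nOobTrees > 0L
  pred <- rep(NA_real_, length(y))
  pred[covered] <- rowSums(treePreds * oobMask)[covered] /
    nOobTrees[covered]
  err <- pred[covered] - y[covered]
  list(oob_error_pct = mean(abs(err)),  # scale is 0-100, so units = %
       oob_rmse = sqrt(mean(err^2)),
       oob_pred = pred, n_excluded = sum(!covered))
}

#' Out-of-bag error of a fitted forest
#'
#' For each training sample, the OOB prediction averages only the trees
#' whose bootstrap excluded it; reported as mean absolute error (in score
#' units, equal to percent of the 0--100 scale) and RMSE. Samples never out
#' of bag are excluded with a warning.
#'
#' @param model a [ForestModel-class] fitted on `(X, y)`.
#' @param X,y the training data.
#' @return list `oob_error_pct`, `oob_rmse`, `oob_pred`, `n_excluded`.
#' @export
oobError <- function(model, X, y) {
  if (nrow(as.matrix(X)) != length(y) ||
      length(y) != nrow(model@fit$inbag))
    stop("model and data sizes do not match")
  st <- oobStats(y, treePredictions(model, X), model@fit$inbag)
  if (st$n_excluded > 0L)
    warning(st$n_excluded, " sample(s) never out of bag; excluded")
  st
}

# Indicator-based per-tree importance arithmetic: (agreements on intact
# OOB data minus agreements after permuting one feature) / N_OOB.
viFromPredictions <- function(y, pred, predPerm, tol) {
  nOob <- length(y)
  if (nOob == 0L) stop("empty OOB set")
  (sum(abs(y - pred) <= tol) - sum(abs(y - predPerm) <= tol)) / nOob
}

#' Permutation variable importance (indicator form)
#'
#' For tree n and feature j: the number of OOB samples the tree scores
#' "correctly" (within `agreementTol` of the observed score -- the
#' regression adaptation of an exact-equality indicator) minus the number
#' scored correctly after permuting feature j within the tree's OOB set,
#' divided by the OOB count; averaged over trees. Irrelevant features get
#' importance near zero; `agreementTol = Inf` gives exactly zero for every
#' feature.
#'
#' @param model a [ForestModel-class].
#' @param X,y the training data.
#' @param agreementTol agreement tolerance in score units (default 5).
#' @param seed seed for the within-OOB permutations.
#' @return object of class `"importanceResult"`: data.frame `feature`,
#'   `vi`, with attribute `n_oob` (mean OOB size) and `trees_used`.
#' @export
variableImportance <- function(model, X, y, agreementTol = 5, seed = 1L) {
  if (agreementTol < 0) stop("agreementTol must be >= 0")
  X <- as.matrix(X)
  inbag <- model@fit$inbag
  allPreds <- treePredictions(model, X)
  p <- ncol(X)
  nt <- ncol(inbag)
  vi <- matrix(NA_real_, nt, p)
  nOobs <- integer(nt)
  skipped <- 0L
  withSeed(seed, {
    for (tr in seq_len(nt)) {
      oobIdx <- which(inbag[, tr] == 0L)
      nOobs[tr] <- length(oobIdx)
      if (length(oobIdx) == 0L) { skipped <- skipped + 1L; next }
      predB <- allPreds[oobIdx, tr]
      agreeB <- sum(abs(y[oobIdx] - predB) <= agreementTol)
      for (j in seq_len(p)) {
        Xp <- X[oobIdx, , drop = FALSE]
        Xp[, j] <- Xp[sample.int(length(oobIdx)), j]
        predA <- treePredictions(model, Xp)[, tr]
        vi[tr, j] <- (agreeB - sum(abs(y[oobIdx] - predA) <=
                                     agreementTol)) / length(oobIdx)
      }
    }
  })
  if (skipped > 0L)
    warning(skipped, " tree(s) had an empty OOB set and were skipped")
  feat <- if (is.null(colnames(X))) paste0("x", seq_len(p)) else colnames(X)
  out <- data.frame(feature = feat,
                    vi = colMeans(vi, na.rm = TRUE), row.names = NULL)
  attr(out, "n_oob") <- mean(nOobs[nOobs > 0L])
  attr(out, "trees_used") <- nt - skipped
  class(out) <- c("importanceResult", "data.frame")
  out
}

#' @rdname variableImportance
#' @return `mseImportance()`: the standard mean-decrease-in-MSE permutation
#'   importance of the underlying forest, as an independent cross-check of
#'   the indicator form (requires refitting; computed directly here from
#'   OOB predictions).
#' @export
mseImportance <- function(model, X, y, seed = 1L) {
  X <- as.matrix(X)
  inbag <- model@fit$inbag
  allPreds <- treePredictions(model, X)
  p <- ncol(X); nt <- ncol(inbag)
  inc <- matrix(NA_real_, nt, p)
  withSeed(seed, for (tr in seq_len(nt)) {
    oobIdx <- which(inbag[, tr] == 0L)
    if (length(oobIdx) == 0L) next
    mseB <- mean((y[oobIdx] - allPreds[oobIdx, tr])^2)
    for (j in seq_len(p)) {
      Xp <- X[oobIdx, , drop = FALSE]
      Xp[, j] <- Xp[sample.int(length(oobIdx)), j]
      predA <- treePredictions(model, Xp)[, tr]
      inc[tr, j] <- mean((y[oobIdx] - predA)^2) - mseB
    }
  })
  setNames(colMeans(inc, na.rm = TRUE), colnames(X))
}

subjectiveScore <- function(rater, i, comp, prediction) {
  if (is(rater, "RaterProfile")) rateScore(rater, comp)
  else if (is.function(rater)) rater(i, comp, prediction)
  else stop("rater must be a RaterProfile or a function(i, comp, pred)")
}

#' Run one human--machine adversarial scoring session
#'
#' Implements the iterative scoring protocol: the rater subjectively scores
#' the first `nInit` images (presented in a seeded non-complete random
#' order); a random forest is trained on them; from the next image onward
#' the model predicts each image's score while the rater keeps scoring
#' subjectively. When the absolute prediction error exceeds `errThresh`
#' for `streak` images in a row (the counter resets on any smaller error),
#' an intervention occurs: the model is refit on all subjective scores
#' accumulated so far, and refitting continues image by image until an
#' error below `errThresh` is observed. Final scores for every image come
#' from the last fitted model.
#'
#' @param rater a [RaterProfile-class], or a function
#'   `(i, composition, prediction)` returning a subjective score
#'   (`prediction` is `NA` during warm-up) -- useful for scripted fixtures.
#' @param images a [StreetSceneSet-class] or points x 19 fraction matrix.
#' @param nInit warm-up size (default 50).
#' @param errThresh intervention error threshold in score units
#'   (default 10).
#' @param streak consecutive exceedances that trigger an intervention
#'   (default 6).
#' @param forestParams list of [fitForest()] arguments (e.g. `nTrees`,
#'   `mtry`).
#' @param seed integer session seed (presentation order and forest fits).
#' @param raterId label stored in the session.
#' @return a [ScoringSession-class].
#' @export
runScoringSession <- function(rater, images, nInit = 50L, errThresh = 10,
                              streak = 6L, forestParams = list(),
                              seed = 1L, raterId = "rater") {
  fr <- if (is(images, "StreetSceneSet")) stressFractions(images) else
    as.matrix(images)
  n <- nrow(fr)
  if (nInit >= n) stop("need more images than the warm-up size")
  ord <- withSeed(stageSeed(seed, "presentation"), sample.int(n))
  fitNum <- 0L
  refit <- function(idx, subj) {
    fitNum <<- fitNum + 1L
    do.call(fitForest, c(list(X = fr[idx, , drop = FALSE], y = subj,
                              seed = stageSeed(seed, paste0("fit", fitNum))),
                         forestParams))
  }
  subj <- rep(NA_real_, n)   # indexed by presentation position
  pred <- rep(NA_real_, n)
  phase <- rep(NA_character_, n)
  for (k in seq_len(nInit)) {
    subj[k] <- subjectiveScore(rater, ord[k], fr[ord[k], ], NA_real_)
    phase[k] <- "warmup"
  }
  model <- refit(ord[seq_len(nInit)], subj[seq_len(nInit)])
  interventions <- 0L
  run <- 0L
  intervening <- FALSE
  for (k in seq(nInit + 1L, n)) {
    i <- ord[k]
    pred[k] <- predictScores(model, fr[i, , drop = FALSE])
    subj[k] <- subjectiveScore(rater, i, fr[i, ], pred[k])
    err <- abs(pred[k] - subj[k])
    if (intervening) {
      phase[k] <- "intervene"
      if (err < errThresh) { intervening <- FALSE; run <- 0L }
      else model <- refit(ord[seq_len(k)], subj[seq_len(k)])
    } else {
      phase[k] <- "predict"
      if (err > errThresh) {
        run <- run + 1L
        if (run >= streak) {
          interventions <- interventions + 1L
          phase[k] <- "intervene"
          intervening <- TRUE
          model <- refit(ord[seq_len(k)], subj[seq_len(k)])
        }
      } else run <- 0L
    }
  }
  final <- predictScores(model, fr)
  new("ScoringSession", raterId = raterId,
      records = data.frame(position = seq_len(n), image_id = ord,
                           subjective = subj, predicted = pred,
                           phase = phase),
      interventions = interventions, finalScores = final, model = model)
}

#' Consensus score across raters
#'
#' Weighted mean of the per-rater final model scores, weights normalized
#' to sum one (default uniform).
#'
#' @param sessions list of [ScoringSession-class] covering the same images.
#' @param weights optional non-negative per-rater weights.
#' @return numeric consensus score per image.
#' @export
consensusScores <- function(sessions, weights = NULL) {
  ns <- vapply(sessions, function(s) length(s@finalScores), integer(1))
  if (length(unique(ns)) != 1L)
    stop("sessions do not cover the same image set")
  if (is.null(weights)) weights <- rep(1, length(sessions))
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative and sum > 0")
  w <- weights / sum(weights)
  mat <- do.call(rbind, lapply(sessions, slot, "finalScores"))
  drop(w %*% mat)
}

#' Hold-out accuracy of the forest score model
#'
#' Seeded random split into `round(trainFrac * n)` training and the rest
#' test; a forest is fit on the training side and evaluated on the held-out
#' side (mean absolute error in score units = percent of the 0--100 scale,
#' and RMSE), with the training fit's OOB error attached.
#'
#' @param X points x features fraction matrix.
#' @param y consensus scores.
#' @param trainFrac training fraction (default 0.667).
#' @param forestParams list of [fitForest()] arguments.
#' @param seed integer seed.
#' @return list `mean_abs_error`, `mean_abs_error_pct`, `rmse`,
#'   `oob_error_pct`, `oob_rmse`, `n_train`, `n_test`.
#' @export
evaluateHoldout <- function(X, y, trainFrac = 0.667, forestParams = list(),
                            seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 samples")
  nTrain <- round(trainFrac * n)
  if (nTrain < 2L || nTrain >= n) stop("degenerate train/test split")
  idx <- withSeed(stageSeed(seed, "holdout"), sample.int(n, nTrain))
  model <- do.call(fitForest, c(list(X = X[idx, , drop = FALSE], y = y[idx],
                                     seed = stageSeed(seed, "holdoutfit")),
                                forestParams))
  predTest <- predictScores(model, X[-idx, , drop = FALSE])
  errs <- predTest - y[-idx]
  oob <- oobError(model, X[idx, , drop = FALSE], y[idx])
  list(mean_abs_error = mean(abs(errs)), mean_abs_error_pct = mean(abs(errs)),
       rmse = sqrt(mean(errs^2)), oob_error_pct = oob$oob_error_pct,
       oob_rmse = oob$oob_rmse, n_train = nTrain, n_test = n - nTrain)
}
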