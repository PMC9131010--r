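#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom Matrix Matrix
#' @importFrom stats rnorm runif sd var aggregate dist lm
#'   pnorm predict rgamma setNames format.pval residuals
#' @importFrom utils head
NULL

#' RoadNetwork: planar polyline road network
#'
#' Holds road segments as planar polylines (projected coordinates in meters)
#' plus the bounding extent. Stands in for an OpenStreetMap street network
#' export.
#'
#' @slot segments list of numeric matrices, one per segment, each with
#'   columns `x`, `y` and at least two vertices.
#' @slot extent numeric length-4 vector `(xmin, ymin, xmax, ymax)`.
#' @export
setClass("RoadNetwork",
  representation(segments = "list", extent = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@extent) != 4L || anyNA(object@extent))
      msg <- c(msg, "extent must be (xmin, ymin, xmax, ymax)")
    for (s in object@segments) {
      if (!is.matrix(s) || ncol(s) != 2L || nrow(s) < 2L)
        msg <- c(msg, "every segment needs >= 2 two-column vertices")
      else if (!all(is.finite(s)))
        msg <- c(msg, "segment coordinates must be finite")
    }
    if (length(msg)) msg else TRUE
  })

#' LabelRaster: integer semantic-segmentation raster
#'
#' A pixel grid of visual-element class ids (0..18 in Cityscapes id order)
#' with a designated void id for unlabeled pixels.
#'
#' @slot labels integer matrix (rows = pixel rows).
#' @slot voidId integer scalar marking void pixels.
#' @export
setClass("LabelRaster",
  representation(labels = "matrix", voidId = "integer"),
  validity = function(object) {
    lab <- object@labels
    if (length(lab) < 1L) return("raster must contain at least one pixel")
    ok <- (lab >= 0L & lab <= 18L) | lab == object@voidId
    if (!all(ok)) return("labels must be class ids 0..18 or the void id")
    TRUE
  })

#' RaterProfile: a simulated volunteer rater
#'
#' Scores a scene as a noisy linear function of its 19 element coverages on
#' the 0--100 stress scale; successive calls consume the rater's private
#' seeded noise stream, so a session is reproducible end to end.
#'
#' @slot coefficients named numeric length-19 (score units per unit
#'   coverage fraction).
#' @slot intercept numeric scalar (score units).
#' @slot noiseSd numeric scalar >= 0 (score units).
#' @slot seed integer seed of the private noise stream.
#' @slot state environment holding the stream cursor.
#' @export
setClass("RaterProfile",
  representation(coefficients = "numeric", intercept = "numeric",
                 noiseSd = "numeric", seed = "integer",
                 state = "environment"),
  validity = function(object) {
    if (length(object@coefficients) != 19L)
      return("coefficients must have length 19")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    TRUE
  })

#' SpatialWeights: fixed-distance-band spatial weights
#'
#' Sparse spatial weight matrix over sample points: weight 1 for pairs
#' within the distance threshold (inclusive) under the chosen metric, 0
#' beyond it, optionally row-standardized. `S0` is the sum of all weights
#' after standardization; `nbCounts` records the pre-standardization
#' neighbor relation.
#'
#' @slot W a `dgCMatrix` of weights (n x n, zero diagonal).
#' @slot threshold numeric band radius in meters.
#' @slot metric `"manhattan"` or `"euclidean"`.
#' @slot standardization `"row"` or `"none"`.
#' @slot S0 numeric sum of weights.
#' @slot nbCounts integer per-point neighbor counts.
#' @slot isolates integer indices of points with no neighbor.
#' @export
setClass("SpatialWeights",
  representation(W = "Matrix", threshold = "numeric", metric = "character",
                 standardization = "character", S0 = "numeric",
                 nbCounts = "integer", isolates = "integer"),
  validity = function(object) {
    if (nrow(object@W) != ncol(object@W)) return("W must be square")
    if (any(object@W@x < 0)) return("weights must be non-negative")
    TRUE
  })

#' ForestModel: seeded random-forest regressor
#'
#' Wraps a fitted `randomForest` regression with its bootstrap bookkeeping
#' (per-tree in-bag count matrix) so that out-of-bag aggregation and the
#' indicator-based permutation importance can be computed exactly.
#'
#' @slot fit the underlying `randomForest` object (fitted with
#'   `keep.inbag = TRUE`).
#' @slot seed integer RNG seed used for the fit.
#' @slot nTrees,mtry forest size and features tried per split.
#' @slot featureNames character column names of the training matrix.
#' @export
setClass("ForestModel",
  representation(fit = "ANY", seed = "integer", nTrees = "integer",
                 mtry = "integer", featureNames = "character"))

#' ScoringSession: one rater's adversarial scoring history
#'
#' Ordered record of a human--machine adversarial scoring run: warm-up
#' subjective scores, model predictions, intervention log, and the final
#' model scores for every image.
#'
#' @slot raterId character label.
#' @slot records data.frame with columns `position`, `image_id`,
#'   `subjective`, `predicted`, `phase` (`warmup`/`predict`/`intervene`).
#' @slot interventions integer number of retraining triggers.
#' @slot finalScores numeric final model score per image (original order).
#' @slot model the last fitted [ForestModel-class].
#' @export
setClass("ScoringSession",
  representation(raterId = "character", records = "data.frame",
                 interventions = "integer", finalScores = "numeric",
                 model = "ANY"))

#' StreetSceneSet: the central container
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay
#' `"fractions"` stores the 19-element coverage-fraction matrix (elements x
#' points) and whose `colData` carries the per-point metadata: planar
#' coordinates `x`, `y` (meters), `void_fraction`, optional `district`, and
#' once scored the consensus `score` on the 0--100 scale.
#'
#' @export
setClass("StreetSceneSet", contains = "SummarizedExperiment",
  validity = function(object) {
    if (!"fractions" %in% SummarizedExperiment::assayNames(object))
      return("assay 'fractions' is required")
    fr <- SummarizedExperiment::assay(object, "fractions")
    if (nrow(fr) != 19L) return("fractions assay must have 19 element rows")
    if (!identical(rownames(fr), cityscapesClasses()))
      return("fraction rows must be the 19 Cityscapes classes in order")
    cd <- SummarizedExperiment::colData(object)
    need <- c("x", "y", "void_fraction")
    if (!all(need %in% colnames(cd)))
      return("colData needs columns x, y, void_fraction")
    if (any(fr < -1e-12)) return("fractions must be >= 0")
    tot <- colSums(fr) + cd$void_fraction
    if (any(abs(tot - 1) > 1e-9))
      return("fractions + void_fraction must sum to 1 per point")
    TRUE
  })
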