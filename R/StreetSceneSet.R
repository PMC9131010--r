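#' Construct a StreetSceneSet
#'
#' @param fractions numeric matrix of coverage fractions, either
#'   points x 19 (rows = points, columns named by element) or 19 x points.
#' @param points data.frame with columns `id`, `x`, `y` and optionally
#'   `district` (see [pointsAlongNetwork()]).
#' @param scores optional numeric vector of 0--100 stress scores per point.
#' @return a [StreetSceneSet-class].
#' @examples
#' pts <- data.frame(id = 1:3, x = c(0, 50, 100), y = 0)
#' fr <- matrix(1 / 19, 3, 19, dimnames = list(NULL, cityscapesClasses()))
#' sss <- StreetSceneSet(fr, pts)
#' stressFractions(sss)[1:3, ]
#' @export
StreetSceneSet <- function(fractions, points, scores = NULL) {
  cls <- cityscapesClasses()
  if (!is.matrix(fractions)) fractions <- as.matrix(fractions)
  if (ncol(fractions) == 19L && !is.null(colnames(fractions)) &&
      all(colnames(fractions) %in% c(cls, "grass", "auto"))) {
    colnames(fractions) <- elementAlias(colnames(fractions))
    fractions <- t(fractions[, cls, drop = FALSE])
  } else if (nrow(fractions) != 19L) {
    stop("fractions must be points x 19 (named columns) or 19 x points")
  }
  rownames(fractions) <- cls
  n <- ncol(fractions)
  stopifnot(nrow(points) == n)
  void <- pmax(0, 1 - colSums(fractions))
  cd <- S4Vectors::DataFrame(
    point_id = points$id, x = points$x, y = points$y,
    void_fraction = void,
    district = if ("district" %in% names(points)) points$district
               else rep(NA_character_, n))
  if (!is.null(scores)) cd$score <- scores
  colnames(fractions) <- as.character(points$id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fractions = fractions), colData = cd)
  new("StreetSceneSet", se)
}

#' Accessors for StreetSceneSet
#'
#' `stressFractions()` returns the points x 19 coverage-fraction matrix,
#' `voidFraction()` the per-point void fraction, `stressScores()` the 0--100
#' consensus scores (NULL until assigned), `pointCoords()` the planar
#' coordinate matrix, and `districts()` the district labels.
#'
#' @param x a [StreetSceneSet-class].
#' @param value replacement value.
#' @return see individual descriptions.
#' @name StreetSceneSet-accessors
NULL

#' @rdname StreetSceneSet-accessors
#' @export
setGeneric("stressFractions", function(x) standardGeneric("stressFractions"))
#' @rdname StreetSceneSet-accessors
#' @export
setMethod("stressFractions", "StreetSceneSet", function(x)
  t(SummarizedExperiment::assay(x, "fractions")))

#' @rdname StreetSceneSet-accessors
#' @export
setGeneric("voidFraction", function(x) standardGeneric("voidFraction"))
#' @rdname StreetSceneSet-accessors
#' @export
setMethod("voidFraction", "StreetSceneSet", function(x)
  SummarizedExperiment::colData(x)$void_fraction)

#' @rdname StreetSceneSet-accessors
#' @export
setGeneric("stressScores", function(x) standardGeneric("stressScores"))
#' @rdname StreetSceneSet-accessors
#' @export
setMethod("stressScores", "StreetSceneSet", function(x)
  SummarizedExperiment::colData(x)$score)

#' @rdname StreetSceneSet-accessors
#' @export
setGeneric("stressScores<-", function(x, value)
  standardGeneric("stressScores<-"))
#' @rdname StreetSceneSet-accessors
#' @export
setReplaceMethod("stressScores", "StreetSceneSet", function(x, value) {
  stopifnot(length(value) == ncol(x), all(value >= 0 & value <= 100))
  SummarizedExperiment::colData(x)$score <- value
  x
})

#' @rdname StreetSceneSet-accessors
#' @export
setGeneric("pointCoords", function(x) standardGeneric("pointCoords"))
#' @rdname StreetSceneSet-accessors
#' @export
setMethod("pointCoords", "StreetSceneSet", function(x) {
  cd <- SummarizedExperiment::colData(x)
  cbind(x = cd$x, y = cd$y)
})

#' @rdname StreetSceneSet-accessors
#' @export
setGeneric("districts", function(x) standardGeneric("districts"))
#' @rdname StreetSceneSet-accessors
#' @export
setMethod("districts", "StreetSceneSet", function(x)
  SummarizedExperiment::colData(x)$district)

#' @rdname StreetSceneSet-accessors
#' @export
setGeneric("samplePoints", function(x) standardGeneric("samplePoints"))
#' @rdname StreetSceneSet-accessors
#' @export
setMethod("samplePoints", "StreetSceneSet", function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(id = cd$point_id, x = cd$x, y = cd$y,
             district = cd$district)
})

setMethod("show", "StreetSceneSet", function(object) {
  cat("StreetSceneSet with", ncol(object), "sample points\n")
  cat("  19-element coverage fractions; mean void:",
      signif(mean(voidFraction(object)), 3), "\n")
  sc <- stressScores(object)
  if (!is.null(sc))
    cat("  stress scores: mean", signif(mean(sc), 4),
        " range [", signif(min(sc), 4), ",", signif(max(sc), 4), "]\n")
  dis <- districts(object)
  if (!all(is.na(dis)))
    cat("  districts:", length(unique(dis[!is.na(dis)])), "labels\n")
})

setMethod("show", "RoadNetwork", function(object) {
  len <- sum(vapply(object@segments, function(s)
    sum(sqrt(rowSums(diff(s)^2))), numeric(1)))
  cat("RoadNetwork:", length(object@segments), "segments, total length",
      round(len, 1), "m\n")
})

setMethod("show", "SpatialWeights", function(object) {
  cat("SpatialWeights: n =", nrow(object@W),
      "| metric", object@metric, "| threshold", signif(object@threshold, 6),
      "m |", object@standardization, "standardized | S0 =",
      signif(object@S0, 6), "\n")
  if (length(object@isolates))
    cat("  isolates:", length(object@isolates), "\n")
})

setMethod("show", "ScoringSession", function(object) {
  cat("ScoringSession", object@raterId, "-", nrow(object@records),
      "images,", object@interventions, "intervention(s)\n")
})

setMethod("show", "ForestModel", function(object) {
  cat("ForestModel:", object@nTrees, "trees, mtry", object@mtry,
      ", seed", object@seed, "\n")
})
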