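#' Coverage fractions from a label raster
#'
#' Exact integer pixel counting: the fraction of class k is (pixels labeled
#' k) / (width * height); void pixels go to the void fraction. The 19
#' fractions plus void always partition the pixel set.
#'
#' @param raster a [LabelRaster-class].
#' @return named numeric vector of the 19 class fractions, with the void
#'   fraction attached as attribute `"void"`.
#' @examples
#' r <- new("LabelRaster", labels = matrix(10L, 4, 4), voidId = 255L)
#' fractionsFromLabelRaster(r)["sky"]   # 1
#' @export
fractionsFromLabelRaster <- function(raster) {
  lab <- raster@labels
  npix <- length(lab)
  if (npix == 0L) stop("raster is empty")
  bad <- !((lab >= 0L & lab <= 18L) | lab == raster@voidId)
  if (any(bad)) stop("label id outside 0..18 and not void")
  counts <- tabulate(lab + 1L, nbins = 19L)
  f <- setNames(counts / npix, cityscapesClasses())
  attr(f, "void") <- sum(lab == raster@voidId) / npix
  f
}

#' Aggregate per-view compositions into one per-point composition
#'
#' The four-heading views of one point are combined by the unweighted mean
#' of their per-class fractions -- identical to computing fractions on the
#' stitched panorama when each view contributes the same pixel count (as
#' equal-size square views do).
#'
#' @param viewCompositions list of 1--4 named length-19 fraction vectors
#'   (as from [fractionsFromLabelRaster()]), all for the same point. If the
#'   vectors carry a `point_id` attribute, ids must agree.
#' @return one named length-19 fraction vector, void attached as in
#'   [fractionsFromLabelRaster()].
#' @export
aggregateViews <- function(viewCompositions) {
  k <- length(viewCompositions)
  if (k < 1L || k > 4L) stop("expected 1 to 4 view compositions")
  ids <- unlist(lapply(viewCompositions, attr, "point_id"))
  if (length(unique(ids)) > 1L) stop("mixed point_ids in one aggregation")
  m <- do.call(rbind, lapply(viewCompositions, function(v)
    v[cityscapesClasses()]))
  f <- colMeans(m)
  voids <- vapply(viewCompositions, function(v) {
    vd <- attr(v, "void")
    if (is.null(vd)) 1 - sum(v[cityscapesClasses()]) else vd
  }, numeric(1))
  attr(f, "void") <- mean(voids)
  if (length(ids)) attr(f, "point_id") <- ids[1]
  f
}

#' Per-element summary statistics
#'
#' Mean, max, min and population SD of each element's coverage fraction
#' across a set of scenes, ranked by descending mean (ties broken by class
#' id) with the top `topK` elements retained -- the element table usually
#' reported for segmented street imagery.
#'
#' @param compositions a [StreetSceneSet-class] or points x 19 fraction
#'   matrix.
#' @param topK how many elements to keep (default 8).
#' @return data.frame `element`, `mean`, `max`, `min`, `sd` in rank order.
#' @export
elementSummary <- function(compositions, topK = 8L) {
  fr <- if (is(compositions, "StreetSceneSet"))
    stressFractions(compositions) else as.matrix(compositions)
  if (nrow(fr) == 0L) stop("no compositions supplied")
  mu <- colMeans(fr)
  popSd <- sqrt(colMeans(sweep(fr, 2L, mu)^2))
  out <- data.frame(element = colnames(fr), mean = mu,
                    max = apply(fr, 2L, max), min = apply(fr, 2L, min),
                    sd = popSd, row.names = NULL)
  ord <- order(-out$mean, seq_len(nrow(out)))
  head(out[ord, ], topK)
}
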