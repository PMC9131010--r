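#' Generate a synthetic road network
#'
#' Draws `nSegments` random polyline street segments inside `extent` by a
#' seeded random walk (3--6 vertices each, coordinates clamped to the
#' extent). Stands in for an OpenStreetMap street-network export so the
#' sampling stage can be exercised without any download.
#'
#' @param nSegments number of segments (>= 1).
#' @param extent numeric `(xmin, ymin, xmax, ymax)` in meters.
#' @param seed integer seed; identical arguments and seed reproduce the
#'   identical network.
#' @return a [RoadNetwork-class].
#' @examples
#' net <- generateRoadNetwork(5, c(0, 0, 1000, 1000), seed = 1)
#' net
#' @export
generateRoadNetwork <- function(nSegments, extent, seed = 1L) {
  if (nSegments < 1L) stop("nSegments must be >= 1")
  if (length(extent) != 4L || extent[3] <= extent[1] || extent[4] <= extent[2])
    stop("extent must be a non-degenerate (xmin, ymin, xmax, ymax)")
  segs <- withSeed(seed, {
    w <- extent[3] - extent[1]; h <- extent[4] - extent[2]
    step <- 0.15 * min(w, h)
    lapply(seq_len(nSegments), function(i) {
      nv <- sample(3:6, 1L)
      ang <- runif(1, 0, 2 * pi)
      pts <- matrix(0, nv, 2)
      pts[1, ] <- c(runif(1, extent[1], extent[3]),
                    runif(1, extent[2], extent[4]))
      for (k in 2:nv) {
        ang <- ang + rnorm(1, 0, 0.4)
        pts[k, ] <- pts[k - 1, ] + step * runif(1, 0.5, 1) *
          c(cos(ang), sin(ang))
      }
      pts[, 1] <- pmin(pmax(pts[, 1], extent[1]), extent[3])
      pts[, 2] <- pmin(pmax(pts[, 2], extent[2]), extent[4])
      colnames(pts) <- c("x", "y")
      pts
    })
  })
  new("RoadNetwork", segments = segs, extent = as.numeric(extent))
}

#' Scene archetypes for compositional simulation
#'
#' An archetype is a Dirichlet concentration vector over the 19 visual
#' elements plus a void pseudo-class; scenes of that archetype are drawn
#' from the corresponding Dirichlet so that fractions are non-negative and
#' sum (with void) to one. `defaultArchetypes()` provides four urban scene
#' types -- residential, commercial, park, arterial -- whose mean coverages
#' echo the magnitudes typical of segmented street imagery (road and sky
#' dominant, building next, vegetation moderate, the rest small).
#'
#' @param name archetype label.
#' @param means named mean coverage fractions (subset of elements plus
#'   optionally `void`); remaining mass is spread thinly over unnamed
#'   classes and void.
#' @param precision Dirichlet concentration total; larger = less
#'   scene-to-scene variation.
#' @return `sceneArchetype()`: a list with `name` and a length-20
#'   concentration vector (19 elements + void). `defaultArchetypes()`: a
#'   named list of four archetypes.
#' @examples
#' arks <- defaultArchetypes()
#' names(arks)
#' @export
sceneArchetype <- function(name, means, precision = 80) {
  cls <- c(cityscapesClasses(), "void")
  m <- setNames(rep(0, 20L), cls)
  nm <- names(means)
  nm[nm != "void"] <- elementAlias(nm[nm != "void"])
  names(means) <- nm
  m[names(means)] <- means
  left <- 1 - sum(m)
  if (left < -1e-9) stop("archetype means exceed 1")
  zero <- m == 0
  m[zero] <- max(left, 0) / sum(zero)
  conc <- m * precision
  conc[conc <= 0] <- 1e-3
  list(name = name, concentration = conc)
}

#' @rdname sceneArchetype
#' @export
defaultArchetypes <- function() {
  list(
    residential = sceneArchetype("residential",
      c(road = 0.24, sky = 0.22, building = 0.27, vegetation = 0.08,
        sidewalk = 0.06, wall = 0.025, car = 0.03, terrain = 0.01,
        void = 0.03)),
    commercial = sceneArchetype("commercial",
      c(road = 0.27, sky = 0.16, building = 0.37, vegetation = 0.03,
        sidewalk = 0.08, wall = 0.01, car = 0.045, terrain = 0.003,
        void = 0.02)),
    park = sceneArchetype("park",
      c(road = 0.16, sky = 0.30, building = 0.05, vegetation = 0.29,
        sidewalk = 0.05, wall = 0.003, car = 0.01, terrain = 0.09,
        void = 0.02)),
    arterial = sceneArchetype("arterial",
      c(road = 0.40, sky = 0.30, building = 0.10, vegetation = 0.05,
        sidewalk = 0.035, wall = 0.004, car = 0.06, terrain = 0.005,
        void = 0.02)))
}

#' Draw scene compositions for sample points
#'
#' For each sample point, draws a 19-element coverage-fraction vector from
#' the Dirichlet distribution of its assigned archetype (the 20th Dirichlet
#' component becomes the void fraction, so fractions sum to <= 1).
#'
#' @param points data.frame of sample points (`id`, `x`, `y`, optional
#'   `district`).
#' @param archetypes named list of [sceneArchetype()] objects.
#' @param assignment character/integer vector (one entry per point) naming
#'   the archetype of each point.
#' @param seed integer seed.
#' @return a [StreetSceneSet-class] carrying the drawn fractions.
#' @export
generateSceneCompositions <- function(points, archetypes,
                                      assignment = NULL, seed = 1L) {
  n <- nrow(points)
  if (is.null(assignment))
    assignment <- rep_len(names(archetypes), n)
  if (length(assignment) != n)
    stop("every point needs an archetype assignment")
  if (is.numeric(assignment)) assignment <- names(archetypes)[assignment]
  if (anyNA(assignment) || !all(assignment %in% names(archetypes)))
    stop("unassigned point or unknown archetype")
  fr <- withSeed(seed, {
    out <- matrix(0, n, 19L, dimnames = list(NULL, cityscapesClasses()))
    for (a in unique(assignment)) {
      idx <- which(assignment == a)
      conc <- archetypes[[a]]$concentration
      g <- matrix(rgamma(length(idx) * 20L, shape = rep(conc, each =
        length(idx))), nrow = length(idx))
      g <- g / rowSums(g)
      out[idx, ] <- g[, 1:19, drop = FALSE]
    }
    out
  })
  StreetSceneSet(fr, points)
}

#' Ground-truth element effects on perceived stress
#'
#' Default signed coefficients (score units per unit coverage fraction) of
#' the latent stress field: walls and buildings raise stress; sky,
#' vegetation, road, grass (terrain), sidewalk and auto (car) lower it;
#' the remaining eleven elements are neutral. Sign pattern matches the
#' direction of effects reported for segmented street imagery; magnitudes
#' are chosen so that typical scenes land mid-scale on 0--100.
#'
#' @return named numeric vector of length 19.
#' @export
defaultStressCoefficients <- function() {
  co <- setNames(rep(0, 19L), cityscapesClasses())
  co[c("wall", "building")] <- c(80, 60)
  co[c("sky", "vegetation", "road", "terrain", "sidewalk", "car")] <-
    c(-40, -35, -25, -30, -15, -10)
  co
}

#' Generate a spatially autocorrelated latent stress field
#'
#' Builds per-point stress scores that are linear in element coverages with
#' a spatially autocorrelated residual:
#' `score_i = clip(intercept + coefficients . fractions_i + u_i, 0, 100)`,
#' where `u = (I - rho W)^{-1} eps`, `eps ~ N(0, noiseSd)` -- the standard
#' simultaneous-autoregressive (SAR) construction on the row-standardized
#' weights, giving tunable positive spatial autocorrelation. Clipping to
#' the bounded scoring instrument is applied last.
#'
#' @param compositions a [StreetSceneSet-class] or points x 19 fraction
#'   matrix.
#' @param W a row-standardized [SpatialWeights-class] on the same points.
#' @param coefficients named length-19 vector; default
#'   [defaultStressCoefficients()].
#' @param intercept baseline score (default 55).
#' @param spatialRho SAR parameter in `[0, 1)` (default 0.7).
#' @param noiseSd innovation SD in score units (default 5).
#' @param seed integer seed.
#' @return numeric vector of scores in `[0, 100]`.
#' @export
generateLatentStress <- function(compositions, W,
                                 coefficients = defaultStressCoefficients(),
                                 intercept = 55, spatialRho = 0.7,
                                 noiseSd = 5, seed = 1L) {
  fr <- if (is(compositions, "StreetSceneSet"))
    stressFractions(compositions) else as.matrix(compositions)
  if (spatialRho < 0 || spatialRho >= 1)
    stop("spatialRho must lie in [0, 1)")
  n <- nrow(fr)
  if (nrow(W@W) != n) stop("W dimension does not match compositions")
  base <- intercept + drop(fr[, names(coefficients), drop = FALSE] %*%
                             coefficients)
  u <- rep(0, n)
  if (noiseSd > 0) {
    eps <- withSeed(seed, rnorm(n, 0, noiseSd))
    u <- if (spatialRho == 0) eps else
      as.numeric(Matrix::solve(Matrix::Diagonal(n) - spatialRho * W@W, eps))
  }
  pmin(pmax(base + u, 0), 100)
}

#' Simulated raters
#'
#' `raterProfile()` creates a volunteer stand-in whose subjective score for
#' a scene is `clip(intercept + coefficients . fractions + N(0, noiseSd),
#' 0, 100)`. `rateScore()` scores one or many compositions, consuming the
#' rater's private seeded noise stream sequentially (so replaying the same
#' scenes in the same order reproduces the same scores);
#' `resetRater()` rewinds the stream.
#'
#' @param coefficients named length-19 element weights.
#' @param intercept baseline score.
#' @param noiseSd subjective noise SD (score units, >= 0).
#' @param seed integer stream seed.
#' @return `raterProfile()`: a [RaterProfile-class]; `rateScore()`: numeric
#'   scores in `[0, 100]`.
#' @examples
#' r <- raterProfile(defaultStressCoefficients(), noiseSd = 0, seed = 1)
#' comp <- setNames(rep(0, 19), cityscapesClasses())
#' rateScore(r, comp)   # the intercept
#' @export
raterProfile <- function(coefficients = defaultStressCoefficients(),
                         intercept = 55, noiseSd = 5, seed = 1L) {
  st <- new.env(parent = emptyenv())
  st$rng <- NULL
  new("RaterProfile", coefficients = coefficients, intercept = intercept,
      noiseSd = noiseSd, seed = as.integer(seed), state = st)
}

#' @rdname raterProfile
#' @param rater a [RaterProfile-class].
#' @param composition one named length-19 fraction vector, or a points x 19
#'   matrix (scored in row order).
#' @export
rateScore <- function(rater, composition) {
  fr <- if (is.matrix(composition)) composition else
    matrix(composition, 1L, dimnames = list(NULL, names(composition)))
  if (ncol(fr) != 19L) stop("composition must have 19 element fractions")
  if (any(fr < 0) || any(rowSums(fr) > 1 + 1e-9))
    stop("invalid composition: fractions must be >= 0 and sum <= 1")
  fr <- fr[, names(rater@coefficients), drop = FALSE]
  mu <- rater@intercept + drop(fr %*% rater@coefficients)
  noise <- if (rater@noiseSd > 0) raterNoise(rater, nrow(fr)) else 0
  pmin(pmax(mu + noise, 0), 100)
}

#' @rdname raterProfile
#' @export
resetRater <- function(rater) {
  rater@state$rng <- NULL
  invisible(rater)
}

# draw n values from the rater's private stream without touching the
# caller's RNG state
raterNoise <- function(rater, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
    globalenv()) else NULL
  on.exit(restoreSeed(old), add = TRUE)
  if (is.null(rater@state$rng)) set.seed(rater@seed) else
    assign(".Random.seed", rater@state$rng, envir = globalenv())
  x <- rnorm(n, 0, rater@noiseSd)
  rater@state$rng <- get(".Random.seed", globalenv())
  x
}

#' Render a composition to a label raster
#'
#' Inverse of [fractionsFromLabelRaster()]: apportions `width * height`
#' pixels to the 19 classes by largest-remainder rounding (ties broken by
#' class id), leaves the residual as void, and scatters the pixels in a
#' seeded random arrangement. Per-class counts match the composition within
#' one pixel.
#'
#' @param composition named length-19 fraction vector with sum <= 1.
#' @param width,height raster size in pixels.
#' @param seed integer seed for the pixel arrangement.
#' @return a [LabelRaster-class].
#' @export
renderLabelRaster <- function(composition, width, height, seed = 1L) {
  if (width * height < 1L) stop("raster must have at least one pixel")
  f <- composition[cityscapesClasses()]
  if (anyNA(f)) stop("composition must name all 19 classes")
  npix <- as.integer(width * height)
  quota <- f * npix
  base <- floor(quota)
  extra <- round(sum(quota)) - sum(base)
  counts <- base
  if (extra > 0) {
    rem <- quota - base
    ord <- order(-rem, seq_along(rem))  # ties -> lower class id first
    counts[ord[seq_len(extra)]] <- counts[ord[seq_len(extra)]] + 1
  }
  ids <- rep(c(0:18, VOID_ID), c(counts, npix - sum(counts)))
  pos <- withSeed(seed, sample.int(npix))
  lab <- matrix(0L, height, width)
  lab[pos] <- as.integer(ids)
  new("LabelRaster", labels = lab, voidId = VOID_ID)
}
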