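#' Manhattan distance
#'
#' City-block distance `|x_a - x_b| + |y_a - y_b|` between planar points
#' (meters). This is the metric used to define the fixed-distance
#' neighborhood band of the stress field's spatial weights.
#'
#' @param a,b numeric length-2 coordinate vectors.
#' @return distance in meters.
#' @examples manhattanDistance(c(0, 0), c(3, 4))  # 7
#' @export
manhattanDistance <- function(a, b) {
  if (!all(is.finite(c(a, b)))) stop("coordinates must be finite")
  abs(a[1] - b[1]) + abs(a[2] - b[2])
}

coordsOf <- function(points) {
  if (is(points, "StreetSceneSet")) return(pointCoords(points))
  if (is.data.frame(points)) return(cbind(points$x, points$y))
  as.matrix(points)
}

#' Smallest band radius giving every point a neighbor
#'
#' The maximum over points of the distance to their nearest other point:
#' with a fixed-distance band at (or above) this threshold, every point has
#' at least one neighbor. Duplicate coordinates contribute distance 0.
#'
#' @param points data.frame/matrix of coordinates or a
#'   [StreetSceneSet-class].
#' @param metric `"manhattan"` (default) or `"euclidean"`.
#' @return threshold in meters.
#' @export
minNeighborThreshold <- function(points, metric = "manhattan") {
  xy <- coordsOf(points)
  if (nrow(xy) < 2L) stop("need at least 2 points")
  D <- as.matrix(dist(xy, method = metric))
  diag(D) <- Inf
  max(apply(D, 1L, min))
}

#' Build fixed-distance-band spatial weights
#'
#' Binary weight 1 for pairs within `threshold` (inclusive -- a pair at
#' exactly the threshold distance are neighbors, which makes the automatic
#' threshold guarantee at least one neighbor exactly), 0 beyond. Row
#' standardization divides each row by its sum, after which `S0` is
#' recorded (equal to `n` when no point is isolated). Row standardization
#' makes the weights asymmetric; all downstream statistics use the
#' standardized weights as-is.
#'
#' @param points coordinates as in [minNeighborThreshold()].
#' @param threshold band radius in meters, or `"auto"` for
#'   [minNeighborThreshold()].
#' @param metric `"manhattan"` (default) or `"euclidean"`.
#' @param standardization `"row"` (default) or `"none"`.
#' @return a [SpatialWeights-class].
#' @examples
#' pts <- data.frame(x = c(0, 1, 6), y = 0)
#' W <- buildWeights(pts, threshold = "auto")
#' neighborCountHistogram(W)
#' @export
buildWeights <- function(points, threshold = "auto", metric = "manhattan",
                         standardization = c("row", "none")) {
  standardization <- match.arg(standardization)
  xy <- coordsOf(points)
  n <- nrow(xy)
  if (n < 2L) stop("need at least 2 points")
  if (identical(threshold, "auto"))
    threshold <- minNeighborThreshold(xy, metric)
  D <- as.matrix(dist(xy, method = metric))
  A <- (D <= threshold + 1e-9)
  diag(A) <- FALSE
  nb <- as.integer(rowSums(A))
  iso <- which(nb == 0L)
  if (length(iso) == n) stop("all points isolated at this threshold")
  if (length(iso) > 0L)
    warning(length(iso), " isolated point(s) at threshold ", threshold)
  Wm <- Matrix::Matrix(A * 1, sparse = TRUE)
  if (standardization == "row") {
    rs <- Matrix::rowSums(Wm)
    rs[rs == 0] <- 1
    Wm <- Wm / rs
  }
  new("SpatialWeights", W = methods::as(Wm, "generalMatrix"),
      threshold = threshold, metric = metric,
      standardization = standardization, S0 = sum(Wm),
      nbCounts = nb, isolates = as.integer(iso))
}

#' Histogram of neighbor counts
#'
#' Counts of points by number of neighbors under the pre-standardization
#' neighbor relation (the bar-chart companion of the Moran scatter plot).
#'
#' @param W a [SpatialWeights-class].
#' @return named integer vector: names are neighbor counts, values are
#'   numbers of points.
#' @export
neighborCountHistogram <- function(W) {
  tab <- table(W@nbCounts)
  setNames(as.integer(tab), names(tab))
}

moranCrossProducts <- function(values, W) {
  n <- length(values)
  if (nrow(W@W) != n) stop("length(values) must equal the weights dimension")
  d <- values - mean(values)
  if (sum(d^2) == 0) stop("values are constant: Moran's I is undefined")
  list(d = d, m2sum = sum(d^2),
       num = as.numeric(Matrix::crossprod(d, W@W %*% d)))
}

#' Global Moran's I with significance test
#'
#' Computes `I = n * sum_ij w_ij d_i d_j / (S0 * sum_i d_i^2)` with
#' `d_i = x_i - xbar` (with row-standardized weights `S0 = n` and the
#' expression collapses to the familiar weighted cross-product form),
#' `E(I) = -1/(n-1)`, a variance under the randomization (default) or
#' normality assumption or by value permutation, the standardized
#' `Z = (I - E(I)) / sqrt(VAR(I))` and a two-sided p-value. `|Z| > 1.96`
#' corresponds to significance at the 95% level.
#'
#' @param values numeric stress scores (non-constant).
#' @param W a [SpatialWeights-class] on the same points.
#' @param varianceMode `"randomization"` (default), `"normality"` or
#'   `"permutation"`.
#' @param nPerm permutations when `varianceMode = "permutation"`.
#' @param seed seed for the permutation mode.
#' @return object of class `"moranResult"`: list with `I`, `E_I`, `VAR_I`,
#'   `Z`, `p`, `n`, `mode`.
#' @export
globalMoransI <- function(values, W,
                          varianceMode = c("randomization", "normality",
                                           "permutation"),
                          nPerm = 999L, seed = 1L) {
  varianceMode <- match.arg(varianceMode)
  n <- length(values)
  cp <- moranCrossProducts(values, W)
  I <- n / W@S0 * cp$num / cp$m2sum
  E <- -1 / (n - 1)
  if (varianceMode == "permutation") {
    Istar <- withSeed(seed, vapply(seq_len(nPerm), function(k) {
      v <- values[sample.int(n)]
      cpk <- moranCrossProducts(v, W)
      n / W@S0 * cpk$num / cpk$m2sum
    }, numeric(1)))
    V <- var(Istar)
    p <- (sum(abs(Istar - E) >= abs(I - E)) + 1) / (nPerm + 1)
    Z <- (I - E) / sqrt(V)
  } else {
    Wd <- as.matrix(W@W)
    S0 <- W@S0
    S1 <- 0.5 * sum((Wd + t(Wd))^2)
    rsum <- rowSums(Wd); csum <- colSums(Wd)
    S2 <- sum((rsum + csum)^2)
    if (varianceMode == "normality") {
      V <- (n^2 * S1 - n * S2 + 3 * S0^2) / ((n^2 - 1) * S0^2) - E^2
    } else {
      b2 <- n * sum(cp$d^4) / cp$m2sum^2
      V <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
              b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
        ((n - 1) * (n - 2) * (n - 3) * S0^2) - E^2
    }
    Z <- (I - E) / sqrt(V)
    p <- zToP(Z)
  }
  structure(list(I = I, E_I = E, VAR_I = V, Z = Z, p = p, n = n,
                 mode = varianceMode), class = "moranResult")
}

#' @export
print.moranResult <- function(x, ...) {
  cat("Global Moran's I (", x$mode, " variance)\n", sep = "")
  cat("  I =", signif(x$I, 6), " E(I) =", signif(x$E_I, 6),
      " VAR(I) =", signif(x$VAR_I, 6), "\n")
  cat("  Z =", signif(x$Z, 6), " p =", format.pval(x$p), " n =", x$n, "\n")
  invisible(x)
}

#' Moran scatter data
#'
#' Standardized values `z_i` against their spatial lag
#' `lag_i = sum_j w_ij z_j`. With row-standardized weights and no isolates
#' the OLS slope of lag on z equals global Moran's I.
#'
#' @inheritParams globalMoransI
#' @return data.frame with columns `z` and `lag`.
#' @export
moranScatter <- function(values, W) {
  if (W@standardization != "row")
    stop("moranScatter expects row-standardized weights")
  if (sd(values) == 0) stop("values are constant")
  z <- (values - mean(values)) / sd(values)
  data.frame(z = z, lag = as.numeric(W@W %*% z))
}

#' Local Moran's I (LISA) with conditional permutation
#'
#' Per-point local statistic `I_i = (d_i / S2) * sum_j w_ij d_j` with
#' `S2 = sum_i d_i^2 / n`, so that `sum_i I_i = S0 * I` exactly.
#' Significance by conditional permutation: the value at point i is held
#' fixed while the neighbor slots are filled by values sampled without
#' replacement from the remaining n-1 points; the two-sided pseudo p is
#' `(count(|I_i*| >= |I_i|) + 1) / (nPerm + 1)`. Points significant at
#' `alpha` are labeled by quadrant -- HH (high surrounded by high), LL, HL,
#' LH from the signs of `d_i` and the lag -- and `"ns"` otherwise.
#'
#' @inheritParams globalMoransI
#' @param nPerm conditional permutations per point (default 999).
#' @param alpha significance level for quadrant labeling (default 0.05).
#' @return data.frame with columns `Ii`, `z_value`, `p`, `lag`, `quadrant`;
#'   attributes `S0` and `I` (the global statistic implied by the sum).
#' @export
localMoransI <- function(values, W, nPerm = 999L, alpha = 0.05, seed = 1L) {
  n <- length(values)
  cp <- moranCrossProducts(values, W)
  d <- cp$d
  S2 <- cp$m2sum / n
  lag <- as.numeric(W@W %*% d)
  Ii <- d / S2 * lag
  Wm <- W@W
  res <- withSeed(seed, {
    p <- numeric(n); zv <- numeric(n)
    for (i in seq_len(n)) {
      wrow <- Wm[i, ]
      nbr <- which(wrow != 0)
      if (length(nbr) == 0L) { p[i] <- NA_real_; zv[i] <- NA_real_; next }
      wts <- as.numeric(wrow[nbr])
      k <- length(nbr)
      others <- d[-i]
      lagStar <- vapply(seq_len(nPerm), function(q)
        sum(wts * others[sample.int(n - 1L, k)]), numeric(1))
      Istar <- d[i] / S2 * lagStar
      p[i] <- (sum(abs(Istar) >= abs(Ii[i])) + 1) / (nPerm + 1)
      s <- sd(Istar)
      zv[i] <- if (s > 0) (Ii[i] - mean(Istar)) / s else NA_real_
    }
    list(p = p, zv = zv)
  })
  quad <- ifelse(d >= 0,
                 ifelse(lag >= 0, "HH", "HL"),
                 ifelse(lag >= 0, "LH", "LL"))
  quad[is.na(res$p) | res$p >= alpha] <- "ns"
  out <- data.frame(Ii = Ii, z_value = res$zv, p = res$p, lag = lag,
                    quadrant = quad)
  attr(out, "S0") <- W@S0
  attr(out, "I") <- sum(Ii) / W@S0
  out
}
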