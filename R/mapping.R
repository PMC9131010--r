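#' Jenks natural-breaks classification
#'
#' Exact Fisher--Jenks dynamic programming (on distinct values with
#' multiplicities, `O(k n^2)`): partitions the scores into `k` contiguous
#' classes minimizing the total within-class sum of squared deviations.
#' Boundaries are reported as the maximum of each class but the last.
#'
#' @param values numeric scores.
#' @param k number of classes (>= 1, at most the number of distinct
#'   values).
#' @return object of class `"breaksClassification"`: list with `k`,
#'   `boundaries` (k-1 ascending upper bounds), `min`, `max`, `wss` (the
#'   optimal within-class sum of squares).
#' @examples
#' jenksBreaks(c(1, 2, 3, 10, 11, 12), 2)$boundaries   # 3
#' @export
jenksBreaks <- function(values, k) {
  v <- sort(unique(values))
  m <- length(v)
  if (k < 1L) stop("k must be >= 1")
  if (k > m) stop("k exceeds the number of distinct values")
  cnt <- as.numeric(table(factor(values, levels = v)))
  cs <- cumsum(cnt); csv <- cumsum(cnt * v); csv2 <- cumsum(cnt * v^2)
  wss <- function(i, j) { # within-class SS over distinct values i..j
    n <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s <- csv[j] - if (i > 1L) csv[i - 1L] else 0
    s2 <- csv2[j] - if (i > 1L) csv2[i - 1L] else 0
    s2 - s^2 / n
  }
  D <- matrix(Inf, k, m)
  B <- matrix(1L, k, m)
  for (j in 1:m) D[1, j] <- wss(1L, j)
  if (k > 1L) for (cl in 2:k) for (j in cl:m) {
    for (i in cl:j) {
      cand <- D[cl - 1L, i - 1L] + wss(i, j)
      if (cand < D[cl, j]) { D[cl, j] <- cand; B[cl, j] <- i }
    }
  }
  # backtrack class start indices
  starts <- integer(k)
  j <- m
  for (cl in k:1) { starts[cl] <- B[cl, j]; j <- starts[cl] - 1L }
  bounds <- if (k > 1L) v[starts[-1L] - 1L] else numeric(0)
  breaksClassification(bounds, range = range(values), wss = D[k, m])
}

#' @rdname jenksBreaks
#' @param boundaries ascending upper bounds of classes 1..k-1 (the class
#'   maxima but the last), e.g. printed score-range cut points.
#' @param range numeric `(min, max)` envelope of the classified scores.
#' @param wss optional within-class sum of squares.
#' @export
breaksClassification <- function(boundaries, range, wss = NA_real_) {
  if (is.unsorted(boundaries, strictly = TRUE))
    stop("boundaries must be strictly ascending")
  structure(list(k = length(boundaries) + 1L,
                 boundaries = as.numeric(boundaries),
                 min = range[1], max = range[2], wss = wss),
            class = "breaksClassification")
}

#' @export
print.breaksClassification <- function(x, ...) {
  cat("Natural-breaks classification: k =", x$k, "\n")
  cat("  boundaries:", paste(signif(x$boundaries, 6), collapse = ", "),
      "\n  envelope: [", x$min, ",", x$max, "]\n")
  invisible(x)
}

#' Classify scores into levels and stress tiers
#'
#' Level = index of the first class whose upper bound is >= the value.
#' Scores outside the classification envelope are clamped to the end
#' classes with a warning. For a six-level classification the fixed tier
#' grouping is levels 1--2 = Low, 3--4 = Medium, 5--6 = High.
#'
#' @param values numeric scores.
#' @param breaks a `"breaksClassification"`.
#' @return integer levels in `1..k`.
#' @export
classifyScores <- function(values, breaks) {
  outside <- values < breaks$min - 1e-9 | values > breaks$max + 1e-9
  if (any(outside))
    warning(sum(outside), " value(s) outside the classification envelope; ",
            "clamped to end classes")
  lev <- 1L + vapply(values, function(v) sum(v > breaks$boundaries),
                     integer(1))
  pmin(pmax(lev, 1L), breaks$k)
}

#' @rdname classifyScores
#' @param levels integer levels from a six-class classification.
#' @return `levelToTier()`: factor with levels Low, Medium, High.
#' @export
levelToTier <- function(levels) {
  if (any(levels < 1L | levels > 6L))
    stop("tier mapping is defined for six-level classifications")
  factor(c("Low", "Low", "Medium", "Medium", "High", "High")[levels],
         levels = c("Low", "Medium", "High"))
}

#' Level summary table
#'
#' Six-interval statistical summary of classified scores: per level the
#' score range, point count and dataset percentage, plus the percentage of
#' each Low/Medium/High tier.
#'
#' @param values numeric scores.
#' @param breaks a six-class `"breaksClassification"`.
#' @return data.frame `level`, `tier`, `from`, `to`, `count`, `percent`,
#'   `tier_percent` (tier percentage repeated on the tier's first row, NA
#'   elsewhere, mirroring the usual presentation).
#' @export
levelTable <- function(values, breaks) {
  if (breaks$k != 6L) stop("levelTable expects a six-class classification")
  lev <- classifyScores(values, breaks)
  tier <- levelToTier(lev)
  ub <- c(breaks$boundaries, breaks$max)
  lb <- c(breaks$min, breaks$boundaries)
  cnt <- tabulate(lev, nbins = breaks$k)
  pct <- 100 * cnt / length(values)
  tierOf <- levelToTier(1:6)
  tp <- vapply(levels(tierOf), function(tt)
    sum(pct[tierOf == tt]), numeric(1))
  data.frame(level = 1:6, tier = as.character(tierOf), from = lb, to = ub,
             count = cnt, percent = pct,
             tier_percent = ifelse(1:6 %in% c(1L, 3L, 5L),
                                   tp[as.character(tierOf)], NA_real_))
}

# axial center of a pointy-top hexagon
hexCenter <- function(q, r, radius, origin) {
  cbind(origin[1] + sqrt(3) * radius * (q + r / 2),
        origin[2] + 1.5 * radius * r)
}

#' Aggregate scores to a hexagonal grid
#'
#' Pointy-top hexagonal tessellation (axial coordinates) anchored at the
#' minimum corner of the data bounding box; each point joins the cell with
#' the nearest center (boundary ties to the lexicographically smaller
#' `(q, r)`), cells average their member scores, and empty cells are
#' omitted.
#'
#' @param points coordinates as in [buildWeights()].
#' @param scores numeric score per point.
#' @param radius hexagon circumradius in meters (> 0).
#' @return list with `cells` (data.frame `q`, `r`, `cx`, `cy`, `count`,
#'   `mean_score`) and `assignment` (cell row index per point).
#' @export
hexBin <- function(points, scores, radius) {
  if (radius <= 0) stop("radius must be positive")
  xy <- coordsOf(points)
  stopifnot(nrow(xy) == length(scores))
  origin <- c(min(xy[, 1]), min(xy[, 2]))
  px <- xy[, 1] - origin[1]; py <- xy[, 2] - origin[2]
  rf <- py / (1.5 * radius)
  qf <- px / (sqrt(3) * radius) - rf / 2
  # cube rounding gives the containing hexagon; scan its neighborhood and
  # keep the nearest center with a deterministic tie-break
  xf <- qf; zf <- rf; yf <- -xf - zf
  rx <- round(xf); ry <- round(yf); rz <- round(zf)
  dx <- abs(rx - xf); dy <- abs(ry - yf); dz <- abs(rz - zf)
  fix <- dx > dy & dx > dz
  rx[fix] <- -ry[fix] - rz[fix]
  fix2 <- !fix & dy > dz
  rz[!fix & !fix2] <- -rx[!fix & !fix2] - ry[!fix & !fix2]
  q0 <- rx; r0 <- rz
  nOff <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                c(1, -1), c(-1, 1))
  n <- nrow(xy)
  bq <- q0; br <- r0; bd <- rep(Inf, n)
  for (k in seq_len(nrow(nOff))) {
    qq <- q0 + nOff[k, 1]; rr <- r0 + nOff[k, 2]
    ctr <- hexCenter(qq, rr, radius, c(0, 0))
    dd <- (ctr[, 1] - px)^2 + (ctr[, 2] - py)^2
    better <- dd < bd - 1e-9 |
      (abs(dd - bd) <= 1e-9 & (qq < bq | (qq == bq & rr < br)))
    bq[better] <- qq[better]; br[better] <- rr[better]; bd[better] <-
      dd[better]
  }
  key <- paste(bq, br)
  cells <- unique(data.frame(q = bq, r = br, key = key,
                             stringsAsFactors = FALSE))
  cells <- cells[order(cells$q, cells$r), ]
  idx <- match(key, cells$key)
  agg <- vapply(seq_len(nrow(cells)), function(i)
    c(sum(idx == i), mean(scores[idx == i])), numeric(2))
  ctr <- hexCenter(cells$q, cells$r, radius, origin)
  list(cells = data.frame(q = cells$q, r = cells$r,
                          cx = ctr[, 1], cy = ctr[, 2],
                          count = as.integer(agg[1, ]),
                          mean_score = agg[2, ], row.names = NULL),
       assignment = idx)
}

#' Mean stress by district
#'
#' Unweighted per-district mean scores ranked in descending order;
#' `"unassigned"` points (outside every district polygon) are reported
#' separately, never ranked.
#'
#' @param points data.frame with a `district` column (see
#'   [assignDistricts()]).
#' @param scores numeric score per point.
#' @return list with `districts` (data.frame `district`, `mean_score`,
#'   `count`, `rank`) and `unassigned` (list `mean_score`, `count`).
#' @export
districtMeans <- function(points, scores) {
  stopifnot(nrow(points) == length(scores))
  lab <- points$district
  keep <- !is.na(lab) & lab != "unassigned"
  if (!any(keep)) stop("no points carry a district label")
  ag <- aggregate(scores[keep], list(district = lab[keep]),
                  function(v) c(mean(v), length(v)))
  df <- data.frame(district = ag$district, mean_score = ag$x[, 1],
                   count = as.integer(ag$x[, 2]))
  df <- df[order(-df$mean_score), ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  un <- !keep
  list(districts = df,
       unassigned = list(mean_score = if (any(un)) mean(scores[un])
                         else NA_real_, count = sum(un)))
}

#' Element-composition profiles by stress tier
#'
#' Mean coverage fraction of every element within each Low/Medium/High
#' tier, plus per-image radar rows over the eight most influential
#' elements (wall, building, sky, vegetation, road, grass, sidewalk, auto).
#'
#' @param compositions a [StreetSceneSet-class] or points x 19 fraction
#'   matrix.
#' @param tiers factor/character tier per point (Low/Medium/High).
#' @return list with `profiles` (tier x 19 mean-fraction matrix; a tier
#'   with no members has NA means), `counts` (images per tier), and
#'   `radar` (data.frame: tier + the eight study-vocabulary elements per
#'   image).
#' @export
tierProfiles <- function(compositions, tiers) {
  fr <- if (is(compositions, "StreetSceneSet"))
    stressFractions(compositions) else as.matrix(compositions)
  tiers <- factor(tiers, levels = c("Low", "Medium", "High"))
  if (nrow(fr) != length(tiers))
    stop("compositions and tiers are not aligned")
  prof <- t(vapply(levels(tiers), function(tt) {
    if (!any(tiers == tt, na.rm = TRUE)) rep(NA_real_, ncol(fr))
    else colMeans(fr[which(tiers == tt), , drop = FALSE])
  }, numeric(ncol(fr))))
  colnames(prof) <- colnames(fr)
  radar <- as.data.frame(fr[, topElements(), drop = FALSE])
  colnames(radar) <- topElements(alias = FALSE)
  radar <- cbind(tier = tiers, radar)
  list(profiles = prof,
       counts = setNames(as.integer(table(tiers)), levels(tiers)),
       radar = radar)
}
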