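#' Place sample points along a road network
#'
#' Walks every segment and emits a point at arc length 0, `interval`,
#' `2 * interval`, ... strictly below the segment length (half-open
#' `[0, L)` spacing, so a shared junction endpoint is never emitted twice).
#' Ids are assigned in traversal order. Duplicate coordinates across
#' segments are retained unless `dedupe = TRUE`.
#'
#' @param network a [RoadNetwork-class].
#' @param interval spacing in meters (> 0); street-imagery collection
#'   protocols typically use 50 m.
#' @param dedupe drop later points that duplicate an earlier coordinate
#'   pair exactly (default `FALSE`).
#' @return data.frame with columns `id`, `x`, `y`, `district` (NA).
#' @examples
#' seg <- matrix(c(0, 0, 120, 0), 2, 2, byrow = TRUE,
#'               dimnames = list(NULL, c("x", "y")))
#' net <- new("RoadNetwork", segments = list(seg),
#'            extent = c(0, 0, 120, 1))
#' pointsAlongNetwork(net, 50)   # arc lengths 0, 50, 100
#' @export
pointsAlongNetwork <- function(network, interval, dedupe = FALSE) {
  if (!is(network, "RoadNetwork"))
    stop("network must be a RoadNetwork (a point table is not a network)")
  if (interval <= 0) stop("interval must be positive")
  if (length(network@segments) == 0L) stop("network is empty")
  out <- lapply(network@segments, function(seg) {
    dxy <- diff(seg)
    len <- sqrt(rowSums(dxy^2))
    cum <- c(0, cumsum(len))
    total <- cum[length(cum)]
    s <- seq(0, total, by = interval)
    s <- s[s < total | total == 0]
    if (total == 0) s <- 0
    idx <- findInterval(s, cum, rightmost.closed = FALSE)
    idx <- pmin(idx, nrow(seg) - 1L)
    frac <- ifelse(len[idx] > 0, (s - cum[idx]) / len[idx], 0)
    cbind(seg[idx, 1] + frac * dxy[idx, 1],
          seg[idx, 2] + frac * dxy[idx, 2])
  })
  xy <- do.call(rbind, out)
  pts <- data.frame(id = seq_len(nrow(xy)), x = xy[, 1], y = xy[, 2],
                    district = NA_character_)
  if (dedupe) {
    keep <- !duplicated(paste(pts$x, pts$y))
    pts <- pts[keep, ]
    pts$id <- seq_len(nrow(pts))
  }
  pts
}

#' Enumerate street-view requests for sample points
#'
#' One request per point and heading; defaults follow the standard
#' collection protocol for human-perspective street imagery: four headings
#' at 90 degrees apart, a 90-degree field of view, 6-degree pitch, and
#' 640 px square images. No network call is made -- this enumerates the
#' request table only.
#'
#' @param points data.frame with an `id` column.
#' @param headings numeric degrees in `[0, 360)`.
#' @param fov,pitch,size request parameters.
#' @return data.frame `point_id`, `heading`, `fov`, `pitch`, `size` with
#'   `nrow(points) * length(headings)` rows.
#' @export
enumerateViewRequests <- function(points, headings = c(0, 90, 180, 270),
                                  fov = 90, pitch = 6, size = 640) {
  if (length(headings) == 0L) stop("headings must be non-empty")
  if (any(headings < 0 | headings >= 360)) stop("headings must be in [0, 360)")
  if (fov <= 0 || size <= 0) stop("fov and size must be positive")
  if (nrow(points) == 0L)
    return(data.frame(point_id = integer(), heading = numeric(),
                      fov = numeric(), pitch = numeric(), size = numeric()))
  data.frame(point_id = rep(points$id, each = length(headings)),
             heading = rep(headings, times = nrow(points)),
             fov = fov, pitch = pitch, size = size)
}

# Even-odd ray-casting containment with on-edge points counted inside.
pointInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-edge check
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    if (abs(cross) < 1e-12 &&
        px >= min(xi, xj) - 1e-12 && px <= max(xi, xj) + 1e-12 &&
        py >= min(yi, yj) - 1e-12 && py <= max(yi, yj) + 1e-12)
      return(TRUE)
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Label sample points with districts
#'
#' Assigns each point the name of the first polygon containing it under the
#' even-odd ray-casting rule; points exactly on an edge count as inside the
#' first polygon tested (polygon order as given), and points in no polygon
#' are labeled `"unassigned"`.
#'
#' @param points data.frame with `x`, `y` columns.
#' @param polygons named list of polygons, each a two-column coordinate
#'   matrix (closed or open ring; consecutive duplicate vertices are
#'   collapsed; fewer than 3 distinct vertices is an error).
#' @return `points` with the `district` column filled.
#' @export
assignDistricts <- function(points, polygons) {
  if (is.null(names(polygons)) || any(names(polygons) == ""))
    stop("polygons must be a named list")
  polys <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (nrow(p) > 1L) {
      dup <- c(FALSE, rowSums(abs(diff(p))) == 0)
      p <- p[!dup, , drop = FALSE]
    }
    # drop closing vertex if the ring is explicitly closed
    if (nrow(p) > 1L && all(p[1, ] == p[nrow(p), ]))
      p <- p[-nrow(p), , drop = FALSE]
    if (nrow(p) < 3L) stop("polygon has fewer than 3 distinct vertices")
    p
  })
  lab <- vapply(seq_len(nrow(points)), function(i) {
    for (k in seq_along(polys))
      if (pointInPolygon(points$x[i], points$y[i], polys[[k]]))
        return(names(polys)[k])
    "unassigned"
  }, character(1))
  points$district <- lab
  points
}
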