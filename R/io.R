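#' Read a validated CSV table
#'
#' CSV dialect: UTF-8, comma separator, header row, '.' decimal. Missing
#' required columns raise an error naming them; columns required to be
#' numeric raise an error with the offending row number; unknown extra
#' columns are preserved.
#'
#' @param path file path.
#' @param required character vector of required column names.
#' @param numericCols columns that must parse as numbers.
#' @return data.frame.
#' @export
loadTable <- function(path, required = character(),
                      numericCols = character()) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  for (cc in intersect(numericCols, names(df))) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      suppress <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(suppress) & !is.na(v) & v != "")
      if (length(bad))
        stop("unparseable value in column '", cc, "' at row ", bad[1])
      df[[cc]] <- suppress
    }
  }
  df
}

#' Tabular writers and readers for pipeline artifacts
#'
#' Points (`id,x,y,district`), compositions (`id`, 19 element columns,
#' `void`), and scores (`id,score`) round-trip through plain CSV.
#'
#' @param points,sss,scores,path arguments as named.
#' @return readers return data.frames ([readCompositionsCSV()] returns a
#'   [StreetSceneSet-class]).
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @export
writePointsCSV <- function(points, path)
  utils::write.csv(points, path, row.names = FALSE)

#' @rdname pipeline-io
#' @export
readPointsCSV <- function(path)
  loadTable(path, required = c("id", "x", "y"),
            numericCols = c("id", "x", "y"))

#' @rdname pipeline-io
#' @export
writeCompositionsCSV <- function(sss, path) {
  df <- data.frame(id = samplePoints(sss)$id, stressFractions(sss),
                   void = voidFraction(sss), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}

#' @rdname pipeline-io
#' @export
readCompositionsCSV <- function(path) {
  df <- loadTable(path, required = c("id", cityscapesClasses()),
                  numericCols = c("id", cityscapesClasses(), "void"))
  pts <- data.frame(id = df$id,
                    x = if ("x" %in% names(df)) df$x else seq_len(nrow(df)),
                    y = if ("y" %in% names(df)) df$y else 0)
  StreetSceneSet(as.matrix(df[, cityscapesClasses()]), pts)
}

#' @rdname pipeline-io
#' @export
writeScoresCSV <- function(scores, path, ids = seq_along(scores))
  utils::write.csv(data.frame(id = ids, score = scores), path,
                   row.names = FALSE)

#' @rdname pipeline-io
#' @param ids point ids for [writeScoresCSV()].
#' @export
readScoresCSV <- function(path)
  loadTable(path, required = c("id", "score"),
            numericCols = c("id", "score"))

#' GeoJSON readers and writers
#'
#' Minimal RFC 7946 interchange for the pipeline's geometries, with planar
#' coordinates (meters) declared in a `crs_note` property. Networks are
#' FeatureCollections of LineString/MultiLineString; districts of
#' Polygon/MultiPolygon (named by a `name` property; only outer rings are
#' used); hexagonal cells are written as Polygon features carrying their
#' mean score.
#'
#' @param network,polygons,hex,path arguments as named.
#' @return `readNetworkGeoJSON()` a [RoadNetwork-class];
#'   `readDistrictsGeoJSON()` a named list of coordinate matrices.
#' @name geojson-io
NULL

geoFeature <- function(geomType, coords, props = list())
  list(type = "Feature", properties = props,
       geometry = list(type = geomType, coordinates = coords))

writeGeoJSON <- function(features, path) {
  fc <- list(type = "FeatureCollection",
             crs_note = "planar coordinates in meters (projected)",
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
}

#' @rdname geojson-io
#' @export
writeNetworkGeoJSON <- function(network, path) {
  feats <- lapply(network@segments, function(s)
    geoFeature("LineString", lapply(seq_len(nrow(s)), function(i)
      c(s[i, 1], s[i, 2]))))
  writeGeoJSON(feats, path)
}

#' @rdname geojson-io
#' @export
readNetworkGeoJSON <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  segs <- list()
  for (f in gj$features) {
    g <- f$geometry
    lines <- switch(g$type,
      LineString = list(g$coordinates),
      MultiLineString = g$coordinates,
      stop("unsupported geometry for a network: ", g$type))
    for (ln in lines)
      segs[[length(segs) + 1L]] <- do.call(rbind, lapply(ln, function(c2)
        c(x = c2[[1]], y = c2[[2]])))
  }
  xy <- do.call(rbind, segs)
  new("RoadNetwork", segments = segs,
      extent = c(min(xy[, 1]), min(xy[, 2]), max(xy[, 1]), max(xy[, 2])))
}

#' @rdname geojson-io
#' @export
writeDistrictsGeoJSON <- function(polygons, path) {
  feats <- lapply(names(polygons), function(nm) {
    p <- as.matrix(polygons[[nm]])
    if (!all(p[1, ] == p[nrow(p), ])) p <- rbind(p, p[1, ])  # close ring
    geoFeature("Polygon",
               list(lapply(seq_len(nrow(p)), function(i) c(p[i, 1], p[i, 2]))),
               props = list(name = nm))
  })
  writeGeoJSON(feats, path)
}

#' @rdname geojson-io
#' @export
readDistrictsGeoJSON <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- list()
  for (f in gj$features) {
    g <- f$geometry
    nm <- f$properties$name
    if (is.null(nm)) nm <- paste0("district_", length(out) + 1L)
    rings <- switch(g$type,
      Polygon = list(g$coordinates[[1]]),
      MultiPolygon = lapply(g$coordinates, `[[`, 1L),
      stop("unsupported geometry for a district: ", g$type))
    for (r in rings) {
      m <- do.call(rbind, lapply(r, function(c2) c(x = c2[[1]], y = c2[[2]])))
      out[[nm]] <- m
      if (length(rings) > 1L) nm <- paste0(nm, "+")
    }
  }
  out
}

#' @rdname geojson-io
#' @param radius hexagon circumradius used to draw cell outlines.
#' @export
writeHexGeoJSON <- function(hex, radius, path) {
  ang <- pi / 180 * (60 * 0:5 + 30)  # pointy-top vertex angles
  feats <- lapply(seq_len(nrow(hex$cells)), function(i) {
    cc <- hex$cells[i, ]
    vx <- cc$cx + radius * cos(ang); vy <- cc$cy + radius * sin(ang)
    ring <- lapply(c(1:6, 1L), function(k) c(vx[k], vy[k]))
    geoFeature("Polygon", list(ring),
               props = list(q = cc$q, r = cc$r, count = cc$count,
                            mean_score = cc$mean_score))
  })
  writeGeoJSON(feats, path)
}

#' @rdname geojson-io
#' @param hex result of [hexBin()].
#' @param W a [SpatialWeights-class] for [writeWeightsCSV()].
#' @export
writeWeightsCSV <- function(W, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# threshold=%.10g metric=%s standardization=%s",
                     W@threshold, W@metric, W@standardization), con)
  tr <- Matrix::summary(W@W)
  utils::write.csv(data.frame(i = tr$i, j = tr$j, w = tr$x),
                   con, row.names = FALSE)
}

#' @rdname geojson-io
#' @export
readWeightsCSV <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- regmatches(hdr, gregexpr("[a-z]+=[^ ]+", hdr))[[1]]
  meta <- setNames(sub(".*=", "", kv), sub("=.*", "", kv))
  df <- utils::read.csv(path, comment.char = "#")
  n <- max(df$i, df$j)
  Wm <- Matrix::sparseMatrix(i = df$i, j = df$j, x = df$w, dims = c(n, n))
  nb <- as.integer(Matrix::rowSums(Wm != 0))
  new("SpatialWeights", W = methods::as(Wm, "generalMatrix"),
      threshold = as.numeric(meta[["threshold"]]),
      metric = meta[["metric"]], standardization = meta[["standardization"]],
      S0 = sum(Wm), nbCounts = nb,
      isolates = as.integer(which(nb == 0L)))
}
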