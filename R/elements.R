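#' Visual-element vocabulary
#'
#' The 19 Cityscapes training classes used as the visual-element feature
#' space of a street scene, in canonical id order (0-based ids follow this
#' ordering). Street-perception studies describe two of these under different
#' names: "grass" is the Cityscapes "terrain" class and "auto" is "car";
#' [elementAlias()] reconciles the two vocabularies.
#'
#' @return `cityscapesClasses()` returns a character vector of length 19.
#' @examples
#' cityscapesClasses()
#' elementAlias(c("grass", "auto", "sky"))
#' @export
cityscapesClasses <- function() {
  c("road", "sidewalk", "building", "wall", "fence", "pole",
    "traffic_light", "traffic_sign", "vegetation", "terrain", "sky",
    "person", "rider", "car", "truck", "bus", "train", "motorcycle",
    "bicycle")
}

#' @rdname cityscapesClasses
#' @param x character vector of element names, possibly in the
#'   perception-study vocabulary ("grass", "auto").
#' @return `elementAlias()` returns `x` with "grass" mapped to "terrain" and
#'   "auto" mapped to "car".
#' @export
elementAlias <- function(x) {
  x[x == "grass"] <- "terrain"
  x[x == "auto"] <- "car"
  bad <- setdiff(x, cityscapesClasses())
  if (length(bad) > 0L)
    stop("unknown visual element(s): ", paste(bad, collapse = ", "))
  x
}

#' The eight most influential visual elements
#'
#' Element set used for stress-tier radar profiles and as the default
#' predictor set of the stress regression: wall, building, sky, vegetation,
#' road, grass (terrain), sidewalk, auto (car).
#'
#' @param alias if `TRUE` (default) return the Cityscapes class names;
#'   otherwise the perception-study names.
#' @return character vector of length 8.
#' @export
topElements <- function(alias = TRUE) {
  study <- c("wall", "building", "sky", "vegetation", "road", "grass",
             "sidewalk", "auto")
  if (alias) elementAlias(study) else study
}

# default void label id in integer label rasters (classes use 0..18)
VOID_ID <- 255L
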