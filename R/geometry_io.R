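## GeoJSON input/output for the geofence primitives: a FeatureCollection
## whose Polygon features become entry polygons and whose LineString
## features (2 points) become finish lines. Feature properties may carry a
## "role" (e.g. "entry", "finish") used as the element name.

#' Read geofence geometry from GeoJSON
#'
#' @param path Path to a GeoJSON FeatureCollection with Polygon and/or
#'   LineString features. A feature property `role` names the element;
#'   otherwise features are named `polygon_1`, `line_1`, ...
#' @return A named list of [geo_polygon()] and [cross_line()] objects.
#' @export
read_geometry <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  out <- list()
  np <- 0; nl <- 0
  for (feat in gj$features) {
    geom <- feat$geometry
    role <- feat$properties$role
    if (geom$type == "Polygon") {
      ring <- geom$coordinates[[1]]
      lon <- vapply(ring, function(c) c[[1]], numeric(1))
      lat <- vapply(ring, function(c) c[[2]], numeric(1))
      ## GeoJSON rings repeat the first vertex; ours close implicitly
      if (lon[1] == lon[length(lon)] && lat[1] == lat[length(lat)]) {
        lon <- lon[-length(lon)]
        lat <- lat[-length(lat)]
      }
      np <- np + 1
      nm <- if (!is.null(role)) role else paste0("polygon_", np)
      out[[nm]] <- geo_polygon(lat = lat, lon = lon)
    } else if (geom$type == "LineString") {
      lon <- vapply(geom$coordinates, function(c) c[[1]], numeric(1))
      lat <- vapply(geom$coordinates, function(c) c[[2]], numeric(1))
      if (length(lon) != 2) {
        stop("finish lines must be 2-point LineStrings", call. = FALSE)
      }
      nl <- nl + 1
      nm <- if (!is.null(role)) role else paste0("line_", nl)
      out[[nm]] <- cross_line(lat = lat, lon = lon)
    } else {
      stop("unsupported geometry type: ", geom$type, call. = FALSE)
    }
  }
  out
}

#' Write geofence geometry to GeoJSON
#'
#' @param geometry Named list of [geo_polygon()] / [cross_line()] objects
#'   (names become the `role` property).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geometry, path) {
  feats <- purrr::imap(geometry, function(g, nm) {
    if (inherits(g, "geo_polygon")) {
      ring <- rbind(as.matrix(g$vertices[c("lon", "lat")]),
                    as.matrix(g$vertices[1, c("lon", "lat")]))
      list(
        type = "Feature",
        properties = list(role = nm),
        geometry = list(type = "Polygon",
                        coordinates = list(lapply(seq_len(nrow(ring)),
                                                  function(i) as.numeric(ring[i, ]))))
      )
    } else if (inherits(g, "cross_line")) {
      list(
        type = "Feature",
        properties = list(role = nm),
        geometry = list(type = "LineString",
                        coordinates = list(c(g$lon[1], g$lat[1]),
                                           c(g$lon[2], g$lat[2])))
      )
    } else {
      stop("geometry elements must be geo_polygon or cross_line", call. = FALSE)
    }
  })
  gj <- list(type = "FeatureCollection", features = unname(feats))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
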