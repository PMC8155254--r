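## Spherical-geometry kernel. All distances use the mean Earth radius;
## ellipsoidal precision is irrelevant at the ~150 m scale of field courses.

#' Mean Earth radius in metres
#'
#' Sphere radius used by every distance in the package (6,371,000 m).
#' @export
EARTH_RADIUS_M <- 6371000

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

check_coords <- function(lat, lon, what = "coordinate") {
  if (!is.numeric(lat) || !is.numeric(lon)) {
    stop(what, "s must be numeric", call. = FALSE)
  }
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    stop("non-finite ", what, "s", call. = FALSE)
  }
  if (any(lat < -90 | lat > 90)) {
    stop("latitude outside [-90, 90]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Great-circle (haversine) distance
#'
#' Distance in metres between points on a sphere of radius
#' [EARTH_RADIUS_M], by the haversine formula. Vectorised; arguments are
#' recycled by the usual rules.
#'
#' @param lat1,lon1 First point(s), WGS84 decimal degrees.
#' @param lat2,lon2 Second point(s), WGS84 decimal degrees.
#' @return Numeric vector of distances in metres.
#' @examples
#' gc_distance(0, 0, 0, 1) # one degree of longitude at the equator
#' @export
gc_distance <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  phi1 <- deg2rad(lat1)
  phi2 <- deg2rad(lat2)
  dphi <- deg2rad(lat2 - lat1)
  dlam <- deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_M * asin(sqrt(a))
}

#' Initial bearing (forward azimuth)
#'
#' Forward azimuth of the great circle from the first point to the second,
#' in degrees clockwise from north, in `[0, 360)`.
#'
#' @inheritParams gc_distance
#' @return Numeric vector of bearings in degrees.
#' @export
gc_bearing <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  if (any(lat1 == lat2 & lon1 == lon2)) {
    stop("bearing undefined for coincident points", call. = FALSE)
  }
  phi1 <- deg2rad(lat1)
  phi2 <- deg2rad(lat2)
  dlam <- deg2rad(lon2 - lon1)
  y <- sin(dlam) * cos(phi2)
  x <- cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dlam)
  (rad2deg(atan2(y, x)) + 360) %% 360
}

#' Cross-track distance to a great-circle path
#'
#' Unsigned perpendicular distance in metres from a point to the great
#' circle through the path `a -> b`. This is the per-fix quantity behind
#' route deviation: how far a fix lies from the shortest route between a
#' participant's start and finish points.
#'
#' @param lat,lon Point(s) to measure, decimal degrees.
#' @param lat1,lon1 Path start.
#' @param lat2,lon2 Path end (must differ from the start).
#' @return Numeric vector of unsigned distances in metres.
#' @export
gc_cross_track <- function(lat, lon, lat1, lon1, lat2, lon2) {
  check_coords(lat, lon)
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  if (any(lat1 == lat2 & lon1 == lon2)) {
    stop("degenerate path: start and end coincide", call. = FALSE)
  }
  n <- max(length(lat), length(lon), length(lat1), length(lon1),
           length(lat2), length(lon2))
  lat <- rep_len(lat, n);   lon <- rep_len(lon, n)
  lat1 <- rep_len(lat1, n); lon1 <- rep_len(lon1, n)
  lat2 <- rep_len(lat2, n); lon2 <- rep_len(lon2, n)
  d13 <- gc_distance(lat1, lon1, lat, lon) / EARTH_RADIUS_M
  out <- numeric(n)
  nz <- d13 > 0 # a point at the path start is on the path
  if (any(nz)) {
    b13 <- deg2rad(gc_bearing(lat1[nz], lon1[nz], lat[nz], lon[nz]))
    b12 <- deg2rad(gc_bearing(lat1[nz], lon1[nz], lat2[nz], lon2[nz]))
    out[nz] <- abs(asin(sin(d13[nz]) * sin(b13 - b12))) * EARTH_RADIUS_M
  }
  out
}

## Local equirectangular projection centred at (lat0, lon0): x east, y
## north, both in metres. Accurate to well under 0.1% for extents < 1 km,
## the scale of the field sites this package targets.
local_xy <- function(lat, lon, lat0, lon0) {
  k <- pi / 180 * EARTH_RADIUS_M
  list(
    x = (lon - lon0) * k * cos(deg2rad(lat0)),
    y = (lat - lat0) * k
  )
}

#' Geofence polygon
#'
#' Builds a validated geofence polygon from an ordered ring of vertices
#' (first vertex not repeated; closure is implicit). Used to mark areas of
#' interest such as a start or visibility area.
#'
#' @param lat,lon Numeric vectors (length >= 3) of vertex coordinates in
#'   decimal degrees, in ring order.
#' @return An object of class `geo_polygon`.
#' @examples
#' sq <- geo_polygon(lat = c(0, 0, 0.001, 0.001), lon = c(0, 0.001, 0.001, 0))
#' point_in_polygon(0.0005, 0.0005, sq)
#' @export
geo_polygon <- function(lat, lon) {
  check_coords(lat, lon, "vertex coordinate")
  if (length(lat) != length(lon)) stop("lat and lon lengths differ", call. = FALSE)
  v <- tibble::tibble(lat = as.numeric(lat), lon = as.numeric(lon))
  if (nrow(dplyr::distinct(v)) < 3) {
    stop("polygon needs at least 3 distinct vertices", call. = FALSE)
  }
  if (diff(range(v$lon)) > 180) {
    stop("polygon spanning the antimeridian is unsupported", call. = FALSE)
  }
  if (diff(range(v$lat)) >= 1 || diff(range(v$lon)) >= 1) {
    stop("polygon extent must be below 1 degree per axis (field-site scale)",
         call. = FALSE)
  }
  lat0 <- mean(v$lat)
  lon0 <- mean(v$lon)
  xy <- local_xy(v$lat, v$lon, lat0, lon0)
  if (ring_self_intersects(xy$x, xy$y)) {
    stop("polygon ring is self-intersecting", call. = FALSE)
  }
  structure(
    list(vertices = v, lat0 = lat0, lon0 = lon0),
    class = "geo_polygon"
  )
}

#' @export
print.geo_polygon <- function(x, ...) {
  cat("<geo_polygon> ", nrow(x$vertices), " vertices, centred at (",
      signif(x$lat0, 7), ", ", signif(x$lon0, 7), ")\n", sep = "")
  invisible(x)
}

## Non-adjacent edge pairs must not intersect.
ring_self_intersects <- function(x, y) {
  n <- length(x)
  xs <- c(x, x[1])
  ys <- c(y, y[1])
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next # adjacent edges share a vertex
      hit <- seg_seg_intersect(xs[i], ys[i], xs[i + 1], ys[i + 1],
                               xs[j], ys[j], xs[j + 1], ys[j + 1])
      if (hit$crossed) return(TRUE)
    }
  }
  FALSE
}

## Planar segment-segment intersection p0->p1 vs a->b; scalar inputs.
seg_seg_intersect <- function(p0x, p0y, p1x, p1y, ax, ay, bx, by) {
  s1x <- p1x - p0x; s1y <- p1y - p0y
  s2x <- bx - ax;   s2y <- by - ay
  den <- s1x * s2y - s1y * s2x
  if (abs(den) < .Machine$double.eps * 10) {
    return(list(crossed = FALSE, fraction = NA_real_))
  }
  t <- ((ax - p0x) * s2y - (ay - p0y) * s2x) / den
  u <- ((ax - p0x) * s1y - (ay - p0y) * s1x) / den
  if (t >= 0 && t <= 1 && u >= 0 && u <= 1) {
    list(crossed = TRUE, fraction = t)
  } else {
    list(crossed = FALSE, fraction = NA_real_)
  }
}

#' Point-in-polygon test
#'
#' Even-odd (ray-casting) containment test in a local equirectangular
#' projection centred on the polygon. Points on the boundary count as
#' inside, so segmentation is deterministic at polygon edges.
#'
#' @param lat,lon Point coordinate vectors in decimal degrees.
#' @param polygon A [geo_polygon()].
#' @return Logical vector.
#' @export
point_in_polygon <- function(lat, lon, polygon) {
  stopifnot(inherits(polygon, "geo_polygon"))
  check_coords(lat, lon)
  p <- local_xy(lat, lon, polygon$lat0, polygon$lon0)
  v <- local_xy(polygon$vertices$lat, polygon$vertices$lon,
                polygon$lat0, polygon$lon0)
  n <- length(p$x)
  m <- length(v$x)
  inside <- rep(FALSE, n)
  on_edge <- rep(FALSE, n)
  eps <- 1e-9 # metres; boundary tolerance
  j <- m
  for (i in seq_len(m)) {
    xi <- v$x[i]; yi <- v$y[i]
    xj <- v$x[j]; yj <- v$y[j]
    ## boundary: distance from point to edge i-j
    ex <- xj - xi; ey <- yj - yi
    len2 <- ex^2 + ey^2
    t <- if (len2 > 0) pmin(pmax(((p$x - xi) * ex + (p$y - yi) * ey) / len2, 0), 1) else 0
    dx <- p$x - (xi + t * ex)
    dy <- p$y - (yi + t * ey)
    on_edge <- on_edge | (dx^2 + dy^2 <= eps^2)
    ## even-odd crossing of a horizontal ray
    crosses <- ((yi > p$y) != (yj > p$y)) &
      (p$x < (xj - xi) * (p$y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside | on_edge
}

#' Finish line
#'
#' A two-point line segment whose crossing by a movement step terminates an
#' analysis window.
#'
#' @param lat,lon Length-2 numeric vectors: the two endpoints in decimal
#'   degrees.
#' @return An object of class `cross_line`.
#' @export
cross_line <- function(lat, lon) {
  check_coords(lat, lon, "endpoint coordinate")
  if (length(lat) != 2 || length(lon) != 2) {
    stop("a cross line has exactly two endpoints", call. = FALSE)
  }
  if (lat[1] == lat[2] && lon[1] == lon[2]) {
    stop("cross-line endpoints coincide", call. = FALSE)
  }
  structure(
    list(lat = as.numeric(lat), lon = as.numeric(lon),
         lat0 = mean(lat), lon0 = mean(lon)),
    class = "cross_line"
  )
}

#' @export
print.cross_line <- function(x, ...) {
  cat("<cross_line> (", x$lat[1], ",", x$lon[1], ") -- (",
      x$lat[2], ",", x$lon[2], ")\n")
  invisible(x)
}

#' Does a movement step cross a finish line?
#'
#' Tests each consecutive-fix segment `p0 -> p1` against the line in a local
#' equirectangular projection centred on the line, and reports the fraction
#' along the step at which the crossing occurs (enabling interpolation of
#' the crossing time and point). Zero-length steps never cross.
#'
#' @param lat0,lon0 Step start point(s), decimal degrees.
#' @param lat1,lon1 Step end point(s), decimal degrees.
#' @param line A [cross_line()].
#' @return A tibble with columns `crossed` (logical) and `fraction`
#'   (numeric in `[0, 1]`, `NA` when not crossed).
#' @export
segment_crosses <- function(lat0, lon0, lat1, lon1, line) {
  stopifnot(inherits(line, "cross_line"))
  check_coords(lat0, lon0)
  check_coords(lat1, lon1)
  n <- max(length(lat0), length(lon0), length(lat1), length(lon1))
  lat0 <- rep_len(lat0, n); lon0 <- rep_len(lon0, n)
  lat1 <- rep_len(lat1, n); lon1 <- rep_len(lon1, n)
  p0 <- local_xy(lat0, lon0, line$lat0, line$lon0)
  p1 <- local_xy(lat1, lon1, line$lat0, line$lon0)
  l <- local_xy(line$lat, line$lon, line$lat0, line$lon0)
  crossed <- logical(n)
  fraction <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (p0$x[i] == p1$x[i] && p0$y[i] == p1$y[i]) next
    hit <- seg_seg_intersect(p0$x[i], p0$y[i], p1$x[i], p1$y[i],
                             l$x[1], l$y[1], l$x[2], l$y[2])
    crossed[i] <- hit$crossed
    fraction[i] <- hit$fraction
  }
  tibble::tibble(crossed = crossed, fraction = fraction)
}
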