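## Independent oracles, deliberately implemented on different formulas
## than the package kernel.

R_EARTH <- 6371000
d2r <- function(x) x * pi / 180

## spherical law of cosines (vs the package's haversine)
slc_distance <- function(lat1, lon1, lat2, lon2) {
  p1 <- d2r(lat1); p2 <- d2r(lat2); dl <- d2r(lon2 - lon1)
  cosang <- sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl)
  R_EARTH * acos(pmin(pmax(cosang, -1), 1))
}

## atan2 form of the spherical distance: unlike the law of cosines it is
## well conditioned at metre separations (used for small-scale oracles)
atan2_distance <- function(lat1, lon1, lat2, lon2) {
  p1 <- d2r(lat1); p2 <- d2r(lat2); dl <- d2r(lon2 - lon1)
  a <- sqrt((cos(p2) * sin(dl))^2 +
              (cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl))^2)
  b <- sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl)
  R_EARTH * atan2(a, b)
}

## forward azimuth via 3-D cross products (vs the package's direct atan2)
vec_bearing <- function(lat1, lon1, lat2, lon2) {
  to_xyz <- function(lat, lon) {
    c(cos(d2r(lat)) * cos(d2r(lon)), cos(d2r(lat)) * sin(d2r(lon)), sin(d2r(lat)))
  }
  cross <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  }
  p1 <- to_xyz(lat1, lon1); p2 <- to_xyz(lat2, lon2)
  n <- c(0, 0, 1)
  c1 <- cross(p1, p2)  # normal of the great circle p1->p2
  c2 <- cross(p1, n)   # normal of the meridian through p1
  ang <- atan2(sum(cross(c1, c2) * p1), sum(c1 * c2))
  (ang * 180 / pi + 360) %% 360
}

## planar perpendicular distance to the infinite line a->b in a local
## equirectangular frame centred at a
planar_cross_track <- function(lat, lon, lat1, lon1, lat2, lon2) {
  k <- pi / 180 * R_EARTH
  x <- (lon - lon1) * k * cos(d2r(lat1)); y <- (lat - lat1) * k
  bx <- (lon2 - lon1) * k * cos(d2r(lat1)); by <- (lat2 - lat1) * k
  abs(bx * y - by * x) / sqrt(bx^2 + by^2)
}

## winding-number containment test in the same local frame the package
## uses (so only the counting rule differs)
winding_inside <- function(px, py, vx, vy) {
  n <- length(vx)
  wn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    if (vy[i] <= py) {
      if (vy[j] > py &&
          (vx[j] - vx[i]) * (py - vy[i]) - (px - vx[i]) * (vy[j] - vy[i]) > 0) {
        wn <- wn + 1
      }
    } else {
      if (vy[j] <= py &&
          (vx[j] - vx[i]) * (py - vy[i]) - (px - vx[i]) * (vy[j] - vy[i]) < 0) {
        wn <- wn - 1
      }
    }
  }
  wn != 0
}

## segment-segment intersection by solving the 2x2 linear system
solve_intersection <- function(p0, p1, a, b) {
  A <- cbind(p1 - p0, -(b - a))
  if (abs(det(A)) < 1e-14) return(list(crossed = FALSE, fraction = NA_real_))
  tu <- solve(A, a - p0)
  crossed <- all(tu >= 0) && all(tu <= 1)
  list(crossed = crossed, fraction = if (crossed) tu[1] else NA_real_)
}
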