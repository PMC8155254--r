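test_that("great-circle distance matches closed forms", {
  expect_identical(gc_distance(0, 0, 0, 0), 0)
  one_deg <- EARTH_RADIUS_M * pi / 180
  expect_equal(gc_distance(0, 0, 0, 1), one_deg, tolerance = 1e-12)
  expect_equal(gc_distance(0, 0, 1, 0), one_deg, tolerance = 1e-12)
  ## antipodal bound, attained for (0,0) vs (0,180)
  expect_equal(gc_distance(0, 0, 0, 180), pi * EARTH_RADIUS_M,
               tolerance = 1e-6)
})

test_that("haversine agrees with independent oracles on random pairs", {
  set.seed(41)
  n <- 1000
  lat1 <- runif(n, -80, 80); lon1 <- runif(n, -180, 180)
  lat2 <- runif(n, -80, 80); lon2 <- runif(n, -180, 180)
  d <- gc_distance(lat1, lon1, lat2, lon2)
  d_slc <- slc_distance(lat1, lon1, lat2, lon2)
  keep <- d > 1
  expect_gt(sum(keep), 990)
  expect_lt(max(abs(d[keep] - d_slc[keep]) / d[keep]), 1e-6)
  ## extra cross-check against an established geodesy library
  skip_if_not_installed("geosphere")
  d_geo <- geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                    r = EARTH_RADIUS_M)
  expect_equal(d, d_geo, tolerance = 1e-9)
})

test_that("distance satisfies metric axioms on random triples", {
  set.seed(42)
  for (i in 1:50) {
    p <- runif(6, -60, 60)
    d_pq <- gc_distance(p[1], p[2], p[3], p[4])
    d_qp <- gc_distance(p[3], p[4], p[1], p[2])
    d_pr <- gc_distance(p[1], p[2], p[5], p[6])
    d_rq <- gc_distance(p[5], p[6], p[3], p[4])
    expect_equal(d_pq, d_qp, tolerance = 1e-12)
    expect_lte(d_pq, (d_pr + d_rq) * (1 + 1e-9))
    expect_lte(d_pq, pi * EARTH_RADIUS_M)
  }
})

test_that("initial bearing matches cardinal directions and the vector oracle", {
  expect_equal(gc_bearing(0, 0, 1, 0), 0)
  expect_equal(gc_bearing(0, 0, 0, 1), 90)
  expect_equal(gc_bearing(0, 0, -1, 0), 180)
  expect_equal(gc_bearing(0, 0, 0, -1), 270)
  set.seed(43)
  for (i in 1:100) {
    p <- runif(4, -80, 80)
    if (p[1] == p[3] && p[2] == p[4]) next
    b <- gc_bearing(p[1], p[2], p[3], p[4])
    b_o <- vec_bearing(p[1], p[2], p[3], p[4])
    dd <- abs(b - b_o) %% 360
    expect_lt(min(dd, 360 - dd), 1e-9)
  }
  expect_error(gc_bearing(1, 2, 1, 2), "coincident")
})

test_that("cross-track distance: on-path zero, planar oracle, symmetry", {
  ## midpoint of an equatorial path lies on it
  expect_equal(gc_cross_track(0, 0.5, 0, 0, 0, 1), 0, tolerance = 1e-6)
  ## ~111 m offset example
  xt <- gc_cross_track(0.001, 0.5, 0, 0, 0, 1)
  expect_equal(xt, 0.001 * pi / 180 * EARTH_RADIUS_M, tolerance = 1e-3)
  ## mirror symmetry across the path
  expect_equal(gc_cross_track(0.002, 0.3, 0, 0, 0, 1),
               gc_cross_track(-0.002, 0.3, 0, 0, 0, 1), tolerance = 1e-9)
  expect_error(gc_cross_track(0, 0, 1, 1, 1, 1), "degenerate")
  ## never exceeds the distance to the path start
  set.seed(44)
  for (i in 1:100) {
    p <- runif(6, -60, 60)
    if (p[3] == p[5] && p[4] == p[6]) next
    xt <- gc_cross_track(p[1], p[2], p[3], p[4], p[5], p[6])
    expect_lte(xt, gc_distance(p[1], p[2], p[3], p[4]) * (1 + 1e-12))
  }
})

test_that("cross-track matches the planar oracle at field scale", {
  ## ~1 km paths at habitable latitudes, offsets 50-500 m: the local
  ## equirectangular planar model agrees within 0.1%
  set.seed(45)
  mx <- 0
  for (i in 1:200) {
    lat0 <- runif(1, -55, 55); lon0 <- runif(1, -170, 170)
    brg <- runif(1, 0, 2 * pi)
    len <- runif(1, 800, 1200)
    k <- pi / 180 * EARTH_RADIUS_M
    lat1 <- lat0 + len * cos(brg) / k
    lon1 <- lon0 + len * sin(brg) / (k * cos(d2r(lat0)))
    along <- runif(1, 0.1, 0.9)
    off <- sample(c(-1, 1), 1) * runif(1, 50, 500)
    px <- along * len * sin(brg) - off * cos(brg)
    py <- along * len * cos(brg) + off * sin(brg)
    plat <- lat0 + py / k
    plon <- lon0 + px / (k * cos(d2r(lat0)))
    xt <- gc_cross_track(plat, plon, lat0, lon0, lat1, lon1)
    oracle <- planar_cross_track(plat, plon, lat0, lon0, lat1, lon1)
    mx <- max(mx, abs(xt - oracle) / oracle)
  }
  expect_lt(mx, 1e-3)
})

test_that("polygon construction validates its ring", {
  expect_error(geo_polygon(c(0, 0), c(0, 1)), "3 distinct")
  expect_error(geo_polygon(c(0, 0, 0), c(0, 0, 0)), "3 distinct")
  ## bow-tie ring self-intersects
  expect_error(geo_polygon(c(0, 0.001, 0, 0.001), c(0, 0.001, 0.001, 0)),
               "self-intersect")
  expect_error(geo_polygon(c(0, 0, 2, 2), c(0, 2, 2, 0)), "extent")
  expect_error(geo_polygon(c(0, 0, 0.1), c(-179, 179, 0)), "antimeridian")
})

test_that("point-in-polygon: unit square, boundary-inside, winding oracle", {
  sq <- geo_polygon(lat = c(0, 0, 0.001, 0.001), lon = c(0, 0.001, 0.001, 0))
  expect_true(point_in_polygon(0.0005, 0.0005, sq))
  expect_false(point_in_polygon(0.002, 0.002, sq))
  ## boundary and vertex count as inside
  expect_true(point_in_polygon(0, 0.0005, sq))
  expect_true(point_in_polygon(0.001, 0.001, sq))

  set.seed(46)
  for (rep in 1:5) {
    ## random convex polygon from sorted angles
    ang <- sort(runif(8, 0, 2 * pi))
    r <- 0.002
    poly <- geo_polygon(lat = 0.005 + r * sin(ang), lon = 0.005 + r * cos(ang))
    v <- trackmetrics:::local_xy(poly$vertices$lat, poly$vertices$lon,
                                 poly$lat0, poly$lon0)
    plat <- runif(100, 0.001, 0.009); plon <- runif(100, 0.001, 0.009)
    got <- point_in_polygon(plat, plon, poly)
    p <- trackmetrics:::local_xy(plat, plon, poly$lat0, poly$lon0)
    want <- vapply(seq_along(plat), function(i) {
      winding_inside(p$x[i], p$y[i], v$x, v$y)
    }, logical(1))
    ## verdicts agree away from the boundary (boundary ties follow the
    ## declared boundary-inside rule)
    edge_dist <- vapply(seq_along(plat), function(i) {
      min(vapply(seq_along(v$x), function(j) {
        jj <- if (j == length(v$x)) 1 else j + 1
        ex <- v$x[jj] - v$x[j]; ey <- v$y[jj] - v$y[j]
        t <- max(0, min(1, ((p$x[i] - v$x[j]) * ex + (p$y[i] - v$y[j]) * ey) /
                          (ex^2 + ey^2)))
        sqrt((p$x[i] - v$x[j] - t * ex)^2 + (p$y[i] - v$y[j] - t * ey)^2)
      }, numeric(1)))
    }, numeric(1))
    off_boundary <- edge_dist > 1e-6
    expect_identical(got[off_boundary], want[off_boundary])
  }
})

test_that("segment-line crossing matches the parametric-solve oracle", {
  ln <- cross_line(lat = c(0, 0.001), lon = c(0.0005, 0.0005))
  ## symmetric straddle crosses at fraction 0.5
  hit <- segment_crosses(0.0005, 0, 0.0005, 0.001, ln)
  expect_true(hit$crossed)
  expect_equal(hit$fraction, 0.5, tolerance = 1e-12)
  ## fully one side: no crossing; zero-length: no crossing
  expect_false(segment_crosses(0.0005, 0, 0.0005, 0.0004, ln)$crossed)
  expect_false(segment_crosses(0.0005, 0, 0.0005, 0, ln)$crossed)

  set.seed(47)
  k <- pi / 180 * EARTH_RADIUS_M
  for (i in 1:250) {
    pts <- runif(8, 0, 0.004)
    ln_i <- cross_line(lat = pts[1:2], lon = pts[3:4])
    got <- segment_crosses(pts[5], pts[7], pts[6], pts[8], ln_i)
    ## oracle in the same frame: scale lon by cos(lat0) about line centre
    sc <- function(lat, lon) {
      c((lon - ln_i$lon0) * k * cos(d2r(ln_i$lat0)), (lat - ln_i$lat0) * k)
    }
    want <- solve_intersection(sc(pts[5], pts[7]), sc(pts[6], pts[8]),
                               sc(pts[1], pts[3]), sc(pts[2], pts[4]))
    expect_identical(got$crossed, want$crossed)
    if (got$crossed) expect_equal(got$fraction, want$fraction, tolerance = 1e-9)
  }
})

test_that("coordinate validation rejects bad input", {
  expect_error(gc_distance(NA_real_, 0, 0, 0), "non-finite")
  expect_error(gc_distance(Inf, 0, 0, 0), "non-finite")
  expect_error(gc_distance(91, 0, 0, 0), "latitude")
  expect_error(cross_line(c(1, 1), c(2, 2)), "coincide")
})
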