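## Programmatic fixtures: tracks built from local metre coordinates.

M_PER_DEG <- pi / 180 * 6371000
T0 <- as.POSIXct("2015-05-15 10:00:00", tz = "UTC")

## xy metres (x east, y north) around an anchor -> tracks tibble at 1 Hz
xy_track <- function(x, y, id = "p1", anchor_lat = 0, anchor_lon = 0,
                     t0 = T0, dt = 1) {
  tibble::tibble(
    participant_id = id,
    time = t0 + seq_along(x) * dt - dt,
    lat = anchor_lat + y / M_PER_DEG,
    lon = anchor_lon + x / (M_PER_DEG * cos(anchor_lat * pi / 180)),
    ele = NA_real_
  )
}

## constant-speed walk due east along the equator (exact haversine steps)
equator_walk <- function(n, speed_ms = 1.2, id = "p1") {
  xy_track(x = (seq_len(n) - 1) * speed_ms, y = rep(0, n), id = id)
}

## a small square entry polygon and a finish line in the same local frame
local_geometry <- function(entry_x = c(-20, 20), entry_y = c(60, 90),
                           finish_y = 150, finish_x = c(-20, 20),
                           anchor_lat = 0, anchor_lon = 0) {
  to_lat <- function(y) anchor_lat + y / M_PER_DEG
  to_lon <- function(x) anchor_lon + x / (M_PER_DEG * cos(anchor_lat * pi / 180))
  list(
    entry = geo_polygon(
      lat = to_lat(c(entry_y[1], entry_y[1], entry_y[2], entry_y[2])),
      lon = to_lon(c(entry_x[1], entry_x[2], entry_x[2], entry_x[1]))
    ),
    finish = cross_line(lat = rep(to_lat(finish_y), 2), lon = to_lon(finish_x))
  )
}

## straight 1 Hz march up the y axis: enters the polygon, crosses the line
straight_march <- function(id = "p1", from_y = 0, to_y = 170, step = 2,
                           x = 0) {
  y <- seq(from_y, to_y, by = step)
  xy_track(x = rep(x, length(y)), y = y, id = id)
}

expect_no_mask <- function(tracks) {
  expect_true(all(tracks$mask_reason %in% c("none", "first_point")))
}
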