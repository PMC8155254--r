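## Manual windows spanning a whole single-participant track.
whole_window <- function(tr, round = 1L) {
  tibble::tibble(
    participant_id = unique(tr$participant_id), round = round,
    start_index = 1L, end_index = nrow(tr),
    start_time = tr$time[1], end_time = tr$time[nrow(tr)],
    crossing_fraction = NA_real_, closed = FALSE
  )
}

test_that("constant 1.2 m/s equatorial walk: speed 4.32 km/h, SDs 0", {
  tr <- apply_qc(equator_walk(101, speed_ms = 1.2))
  w <- whole_window(tr)
  m <- suppressWarnings(track_metrics(tr, w))
  expect_equal(m$speed_mean_kmh, 4.32, tolerance = 1e-9)
  expect_equal(m$speed_sd_kmh, 0, tolerance = 1e-9)
  expect_equal(m$route_deviation_mean_m, 0, tolerance = 1e-9)
  expect_equal(m$route_deviation_sd_m, 0, tolerance = 1e-9)
  expect_identical(m$n_points, 101L)
  expect_identical(m$n_masked, 0L)
})

test_that("speed statistics: closed form and brute-force oracle", {
  ## steps at 3 and 5 km/h -> mean 4, SD sqrt(2)
  x <- c(0, 3 / 3.6, 8 / 3.6)
  tr <- apply_qc(xy_track(x = x, y = rep(0, 3)))
  s <- speed_stats(tr, whole_window(tr))
  expect_equal(s$speed_mean_kmh, 4, tolerance = 1e-9)
  expect_equal(s$speed_sd_kmh, sqrt(2), tolerance = 1e-9)
  ## random window equals the oracle mean/SD of pointwise speeds
  set.seed(31)
  n <- 80
  tr2 <- apply_qc(xy_track(x = cumsum(runif(n, 0.5, 2)),
                           y = cumsum(runif(n, -1, 1)), anchor_lat = 48))
  s2 <- speed_stats(tr2, whole_window(tr2))
  or <- 3.6 * atan2_distance(tr2$lat[-n], tr2$lon[-n], tr2$lat[-1], tr2$lon[-1])
  expect_equal(s2$speed_mean_kmh, mean(or), tolerance = 1e-6)
  expect_equal(s2$speed_sd_kmh, sd(or), tolerance = 1e-6)
})

test_that("route deviation: straight walk zero, offset fix, reversal", {
  tr <- apply_qc(equator_walk(51))
  w <- window_endpoints(whole_window(tr), tr)
  rd <- route_deviation(tr, w)
  expect_equal(max(rd$deviation_m), 0, tolerance = 1e-9)
  ## single offset fix matches the planar oracle
  x <- seq(0, 100, by = 2)
  y <- rep(0, length(x)); y[26] <- 7
  tr2 <- apply_qc(xy_track(x = x, y = y))
  w2 <- window_endpoints(whole_window(tr2), tr2)
  rd2 <- route_deviation(tr2, w2)
  oracle <- planar_cross_track(tr2$lat[26], tr2$lon[26],
                               tr2$lat[1], tr2$lon[1],
                               tr2$lat[51], tr2$lon[51])
  expect_equal(rd2$deviation_m[26], oracle, tolerance = 1e-3)
  expect_equal(oracle, 7, tolerance = 1e-3)
  ## unsigned distance is invariant under path reversal
  w2r <- w2
  w2r[c("start_lat", "start_lon", "finish_lat", "finish_lon")] <-
    w2[c("finish_lat", "finish_lon", "start_lat", "start_lon")]
  rd2r <- route_deviation(tr2, w2r)
  expect_equal(rd2$deviation_m, rd2r$deviation_m, tolerance = 1e-9)
  ## [0, 2, 4] summary closed form
  expect_equal(mean(c(0, 2, 4)), 2)
  stats <- rd2 |>
    dplyr::summarise(m = mean(deviation_m), s = sd(deviation_m))
  expect_equal(stats$m, mean(c(rep(0, 50), oracle)), tolerance = 1e-6)
  ## degenerate endpoints error
  wbad <- w2
  wbad$finish_lat <- wbad$start_lat
  wbad$finish_lon <- wbad$start_lon
  expect_error(route_deviation(tr2, wbad), "degenerate")
})

test_that("intra-team distance: parallel tracks, collinear trio, oracle", {
  ## two parallel equatorial walks 100 m apart -> 100 m each
  a <- equator_walk(61, id = "a")
  b <- equator_walk(61, id = "b")
  b$lat <- b$lat + 100 / M_PER_DEG
  tr <- apply_qc(dplyr::bind_rows(a, b))
  tr$team_id <- "T1"
  w <- dplyr::bind_rows(whole_window(a), whole_window(b))
  suppressWarnings(itd <- intra_team_distance(tr, w))
  expect_equal(itd$intra_team_distance_m, c(100, 100), tolerance = 0.1)

  ## three collinear members spaced 100 m -> {150, 100, 150}
  c3 <- equator_walk(61, id = "c")
  c3$lat <- c3$lat + 200 / M_PER_DEG
  tr3 <- apply_qc(dplyr::bind_rows(a, b, c3))
  tr3$team_id <- "T1"
  w3 <- dplyr::bind_rows(whole_window(a), whole_window(b), whole_window(c3))
  itd3 <- intra_team_distance(tr3, w3)
  itd3 <- itd3[order(itd3$participant_id), ]
  expect_equal(itd3$intra_team_distance_m, c(150, 100, 150), tolerance = 0.1)

  ## random team against a brute-force all-pairs oracle
  set.seed(32)
  make_m <- function(id) {
    t <- xy_track(x = cumsum(runif(40, 0.5, 2)) + runif(1, 0, 20),
                  y = cumsum(runif(40, -1, 1)) + runif(1, 0, 20), id = id,
                  anchor_lat = 52)
    t
  }
  team <- apply_qc(dplyr::bind_rows(make_m("m1"), make_m("m2"), make_m("m3")))
  team$team_id <- "T9"
  wt <- dplyr::bind_rows(lapply(c("m1", "m2", "m3"), function(id) {
    whole_window(team[team$participant_id == id, ])
  }))
  got <- intra_team_distance(team, wt)
  for (id in c("m1", "m2", "m3")) {
    others <- setdiff(c("m1", "m2", "m3"), id)
    per_t <- sapply(seq_len(40), function(i) {
      me <- team[team$participant_id == id, ][i, ]
      mean(sapply(others, function(o) {
        ot <- team[team$participant_id == o, ][i, ]
        atan2_distance(me$lat, me$lon, ot$lat, ot$lon)
      }))
    })
    expect_equal(got$intra_team_distance_m[got$participant_id == id],
                 mean(per_t), tolerance = 1e-6)
  }

  ## a single-member team yields NA with a warning
  solo <- apply_qc(equator_walk(10, id = "solo"))
  solo$team_id <- "T2"
  expect_warning(itd1 <- intra_team_distance(solo, whole_window(solo)),
                 "co-present")
  expect_true(is.na(itd1$intra_team_distance_m))
})

test_that("metric table composes per-operation results deterministically", {
  sim <- simulate_tracks(sim_config(n_teams = 2, members_per_team = 2,
                                    n_rounds = 2, seed = 33))
  qc <- apply_qc(sim$tracks)
  geom <- course_geometry(sim$truth$config)
  w <- segment_rounds(qc, geom$entry, geom$finish)
  m <- track_metrics(qc, w)
  expect_identical(nrow(m), 8L) # 2 teams x 2 members x 2 rounds
  expect_identical(
    m[c("team_id", "participant_id", "round")],
    dplyr::arrange(m[c("team_id", "participant_id", "round")],
                   team_id, participant_id, round)
  )
  ## column-wise equality with the per-operation functions
  we <- window_endpoints(w, qc)
  s <- speed_stats(qc, we)
  joined <- dplyr::left_join(m, s, by = c("participant_id", "round"))
  expect_equal(joined$speed_mean_kmh.x, joined$speed_mean_kmh.y)
  itd <- intra_team_distance(qc, we)
  joined2 <- dplyr::left_join(m, itd, by = c("team_id", "participant_id", "round"))
  expect_equal(joined2$intra_team_distance_m.x, joined2$intra_team_distance_m.y)
})

test_that("metrics are invariant under longitude translation", {
  sim <- simulate_tracks(sim_config(n_teams = 1, members_per_team = 2,
                                    n_rounds = 1, seed = 34))
  qc <- apply_qc(sim$tracks)
  geom <- course_geometry(sim$truth$config)
  w <- segment_rounds(qc, geom$entry, geom$finish)
  m1 <- track_metrics(qc, w)

  cfg2 <- sim_config(n_teams = 1, members_per_team = 2, n_rounds = 1,
                     seed = 34, anchor_lon = 6.85 + 40)
  sim2 <- simulate_tracks(cfg2)
  qc2 <- apply_qc(sim2$tracks)
  geom2 <- course_geometry(cfg2)
  w2 <- segment_rounds(qc2, geom2$entry, geom2$finish)
  m2 <- track_metrics(qc2, w2)
  num <- c("speed_mean_kmh", "speed_sd_kmh", "intra_team_distance_m",
           "route_deviation_mean_m", "route_deviation_sd_m")
  for (col in num) {
    expect_equal(m1[[col]], m2[[col]], tolerance = 1e-6)
  }
})

test_that("simulated speed is recovered within sampling error", {
  cfg <- sim_config(n_teams = 1, members_per_team = 3, n_rounds = 1,
                    speed_mean_ms = 1.4, speed_sd_ms = 0.25, cohesion = 0,
                    seed = 35)
  sim <- simulate_tracks(cfg)
  qc <- apply_qc(sim$tracks)
  geom <- course_geometry(cfg)
  w <- segment_rounds(qc, geom$entry, geom$finish)
  m <- track_metrics(qc, w)
  ## windowed mean speed close to the realized outbound speed, and the
  ## realized speed close to the configured 5.04 km/h
  j <- dplyr::left_join(m, sim$truth$rounds,
                        by = c("team_id", "participant_id", "round"))
  expect_true(all(abs(j$speed_mean_kmh - j$realized_speed_kmh) < 0.5))
  expect_true(all(abs(j$realized_speed_kmh - 1.4 * 3.6) < 0.3))
})
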