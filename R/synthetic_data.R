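## Seeded generator of team GPS tracks and coupled state scores with known
## ground truth. Members walk a correlated random walk from a start area,
## through a mid-course entry (visibility) polygon, across a finish line
## ~150 m away, and loop back outside the course for the next round; the
## whole journey is emitted as a continuous 1 Hz log per participant, so
## QC, segmentation, metrics and model recovery are all exercised
## end-to-end without any real data.

## Evaluate code under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Parameters of the synthetic team-walk generator. Defaults emulate the
#' field setting the package targets: 1 Hz logging, a 150 m start-to-finish
#' course, teams of four walking at ~1.4 m/s (typical adult walking
#' speed), moderate heading persistence and mild team cohesion.
#'
#' @param n_teams Number of teams.
#' @param members_per_team Members per team.
#' @param n_rounds Rounds (start -> finish passes) per participant.
#' @param sample_hz Logging rate in fixes per second (default 1).
#' @param speed_mean_ms,speed_sd_ms Walking-speed distribution in m/s;
#'   step lengths are truncated at zero.
#' @param heading_persistence Correlated-random-walk persistence in
#'   `[0, 1]`: each second the heading blends this weight of the previous
#'   heading with the bearing to the current waypoint.
#' @param heading_noise_deg SD of the wrapped-Gaussian heading noise,
#'   degrees per step.
#' @param cohesion Pull toward the team centroid in `[0, 1]` (fraction of
#'   5%% of the centroid offset added to each step).
#' @param course_length_m Start-to-finish distance in metres.
#' @param course_width_m Width of the entry polygon and finish line.
#' @param anchor_lat,anchor_lon WGS84 anchor of the course start
#'   (campus-scale default 52.24 N, 6.85 E; arbitrary).
#' @param spike_rate,gap_rate Per-fix rates of injected position spikes
#'   and recording gaps (applied by [inject_anomalies()]).
#' @param seed Integer seed fixing all randomness.
#' @return A `sim_config` object (list).
#' @export
sim_config <- function(n_teams = 4, members_per_team = 4, n_rounds = 3,
                       sample_hz = 1, speed_mean_ms = 1.4,
                       speed_sd_ms = 0.25, heading_persistence = 0.7,
                       heading_noise_deg = 12, cohesion = 0.3,
                       course_length_m = 150, course_width_m = 40,
                       anchor_lat = 52.24, anchor_lon = 6.85,
                       spike_rate = 0, gap_rate = 0, seed = 1) {
  stopifnot(
    n_teams >= 1, members_per_team >= 1, n_rounds >= 1, sample_hz > 0,
    speed_mean_ms > 0, speed_sd_ms >= 0,
    heading_persistence >= 0, heading_persistence <= 1,
    cohesion >= 0, cohesion <= 1,
    spike_rate >= 0, spike_rate <= 1, gap_rate >= 0, gap_rate <= 1,
    course_length_m > 0, course_width_m > 0
  )
  structure(
    list(
      n_teams = n_teams, members_per_team = members_per_team,
      n_rounds = n_rounds, sample_hz = sample_hz,
      speed_mean_ms = speed_mean_ms, speed_sd_ms = speed_sd_ms,
      heading_persistence = heading_persistence,
      heading_noise_deg = heading_noise_deg, cohesion = cohesion,
      course_length_m = course_length_m, course_width_m = course_width_m,
      anchor_lat = anchor_lat, anchor_lon = anchor_lon,
      spike_rate = spike_rate, gap_rate = gap_rate, seed = seed
    ),
    class = "sim_config"
  )
}

## metres in the course frame (x east, y north of the anchor) -> WGS84
xy_to_latlon <- function(x, y, cfg) {
  k <- pi / 180 * EARTH_RADIUS_M
  list(
    lat = cfg$anchor_lat + y / k,
    lon = cfg$anchor_lon + x / (k * cos(deg2rad(cfg$anchor_lat)))
  )
}

#' Course geometry for a simulation
#'
#' Entry (visibility) polygon spanning the course width at mid-course, and
#' the finish line across the course at `course_length_m`.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `entry` ([geo_polygon()]) and `finish`
#'   ([cross_line()]).
#' @export
course_geometry <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  w <- cfg$course_width_m / 2
  L <- cfg$course_length_m
  ep <- xy_to_latlon(c(-w, w, w, -w), c(0.4 * L, 0.4 * L, 0.6 * L, 0.6 * L), cfg)
  fl <- xy_to_latlon(c(-w, w), c(L, L), cfg)
  list(
    entry = geo_polygon(lat = ep$lat, lon = ep$lon),
    finish = cross_line(lat = fl$lat, lon = fl$lon)
  )
}

## circular blend of two headings (radians) with weight w on the first
blend_heading <- function(h, target, w) {
  atan2(w * sin(h) + (1 - w) * sin(target),
        w * cos(h) + (1 - w) * cos(target))
}

#' Simulate team GPS tracks
#'
#' Correlated random walk per member: each second the heading blends the
#' previous heading (weight `heading_persistence`) with the bearing to the
#' current waypoint, plus wrapped-Gaussian noise; the step length is drawn
#' from a zero-truncated normal; a cohesion term pulls each member toward
#' the team centroid. Rounds alternate an outbound pass (start -> finish
#' line) with a recorded return loop outside the course. The same seed
#' yields identical output.
#'
#' @param cfg A [sim_config()].
#' @return A list: `tracks` (tracks tibble with `team_id` attached),
#'   `meta` (participant table), `truth` (per participant x round realized
#'   outbound speed, in km/h, plus the config).
#' @export
simulate_tracks <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  L <- cfg$course_length_m
  w <- cfg$course_width_m / 2
  dt <- 1 / cfg$sample_hz
  noise_sd <- deg2rad(cfg$heading_noise_deg)
  kappa <- cfg$heading_persistence
  ret_x <- w + 25 # return-loop lane, clear of polygon and finish line
  base_time <- as.POSIXct("2015-05-15 10:00:00", tz = "UTC")
  max_steps <- ceiling(cfg$n_rounds * (2.5 * L + 200) / cfg$speed_mean_ms *
                         cfg$sample_hz) + 200 * cfg$n_rounds

  with_seed(cfg$seed, {
    all_tracks <- list()
    truth_rows <- list()
    for (tm in seq_len(cfg$n_teams)) {
      team_id <- sprintf("T%02d", tm)
      M <- cfg$members_per_team
      x0 <- (seq_len(M) - (M + 1) / 2) * 3 + stats::rnorm(M, 0, 1)
      y0 <- stats::rnorm(M, -8, 1.5)
      ## per-member journey waypoints: outbound, then (if more rounds) a
      ## return loop outside the course
      journeys <- lapply(seq_len(M), function(m) {
        wps <- list()
        for (r in seq_len(cfg$n_rounds)) {
          wps <- c(wps, list(c(x0[m] * 0.3, 0.5 * L), c(0, L + 8)))
          if (r < cfg$n_rounds) {
            wps <- c(wps, list(c(ret_x, L + 5), c(ret_x, -8), c(x0[m], -5)))
          }
        }
        wps
      })
      ## outbound waypoint pairs delimit rounds: indices 1,2 then +5 each
      round_of_wp <- lapply(seq_len(M), function(m) {
        idx <- integer(length(journeys[[m]]))
        r <- 1
        for (i in seq_along(idx)) {
          idx[i] <- r
          if (i %% 5 == 2) r <- r + 1 # after the 2nd wp of each block of 5
        }
        idx
      })
      pos_x <- x0; pos_y <- y0
      wp_i <- rep(1L, M)
      heading <- vapply(seq_len(M), function(m) {
        wp <- journeys[[m]][[1]]
        atan2(wp[1] - pos_x[m], wp[2] - pos_y[m])
      }, numeric(1))
      done <- rep(FALSE, M)
      fixes <- vector("list", M)
      speeds <- lapply(seq_len(M), function(m) vector("list", cfg$n_rounds))
      step_no <- 0L
      while (!all(done) && step_no < max_steps) {
        step_no <- step_no + 1L
        cx <- mean(pos_x[!done]); cy <- mean(pos_y[!done])
        for (m in seq_len(M)) {
          if (done[m]) next
          wps <- journeys[[m]]
          wp <- wps[[wp_i[m]]]
          target <- atan2(wp[1] - pos_x[m], wp[2] - pos_y[m])
          h <- blend_heading(heading[m], target, kappa)
          if (noise_sd > 0) h <- h + stats::rnorm(1, 0, noise_sd)
          heading[m] <- h
          step <- max(0, stats::rnorm(1, cfg$speed_mean_ms, cfg$speed_sd_ms)) * dt
          dx <- step * sin(h) + cfg$cohesion * 0.05 * (cx - pos_x[m]) * dt
          dy <- step * cos(h) + cfg$cohesion * 0.05 * (cy - pos_y[m]) * dt
          pos_x[m] <- pos_x[m] + dx
          pos_y[m] <- pos_y[m] + dy
          fixes[[m]] <- c(fixes[[m]], list(c(step_no, pos_x[m], pos_y[m])))
          r <- round_of_wp[[m]][wp_i[m]]
          ## realized speed during the outbound pass of round r
          if (wp_i[m] %% 5 %in% c(1, 2)) {
            speeds[[m]][[r]] <- c(speeds[[m]][[r]], sqrt(dx^2 + dy^2) / dt)
          }
          ## waypoint advance / completion
          d_wp <- sqrt((wp[1] - pos_x[m])^2 + (wp[2] - pos_y[m])^2)
          final_outbound <- wp_i[m] == length(wps)
          if (final_outbound && pos_y[m] > L + 5) {
            done[m] <- TRUE
          } else if (!final_outbound && d_wp < 6) {
            wp_i[m] <- wp_i[m] + 1L
          } else if (!final_outbound && wp_i[m] %% 5 == 2 && pos_y[m] > L + 5) {
            wp_i[m] <- wp_i[m] + 1L # crossed the line before closing on wp
          }
        }
      }
      for (m in seq_len(M)) {
        f <- do.call(rbind, fixes[[m]])
        ll <- xy_to_latlon(f[, 2], f[, 3], cfg)
        pid <- sprintf("%sP%d", team_id, m)
        all_tracks[[pid]] <- tibble::tibble(
          participant_id = pid,
          time = base_time + f[, 1] * dt,
          lat = ll$lat, lon = ll$lon, ele = NA_real_,
          team_id = team_id
        )
        for (r in seq_len(cfg$n_rounds)) {
          sp <- unlist(speeds[[m]][[r]])
          truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
            participant_id = pid, team_id = team_id, round = r,
            realized_speed_kmh = if (length(sp)) mean(sp) * 3.6 else NA_real_
          )
        }
      }
    }
    tracks <- dplyr::bind_rows(all_tracks)
    meta <- tracks |>
      dplyr::distinct(.data$participant_id, .data$team_id) |>
      dplyr::mutate(card_type = dplyr::if_else(
        stats::runif(dplyr::n()) < 0.5, "illegal", "legal"
      ))
    list(
      tracks = tracks,
      meta = meta,
      truth = list(config = cfg,
                   rounds = dplyr::bind_rows(truth_rows))
    )
  })
}

#' Inject position spikes and recording gaps
#'
#' Degrades a clean 1 Hz trackset with the two fault types the cleaning
#' rules target: `spikes` displace a fix ~30 m sideways so both adjacent
#' steps imply speeds far above 40 km/h, and `gaps` delete a run of two
#' consecutive fixes so the surviving step spans 3 s. Injection sites are
#' kept apart so faults never interact, and every affected step is
#' recorded in the returned truth table (a displaced fix corrupts two
#' steps, both recorded).
#'
#' @param tracks A clean tracks tibble.
#' @param spike_rate,gap_rate Per-fix injection rates in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list: `tracks` (degraded tibble) and `truth` (tibble of
#'   `participant_id`, `time` of each affected step's end fix, and `type`
#'   `"speed"` or `"gap"`).
#' @export
inject_anomalies <- function(tracks, spike_rate = 0.01, gap_rate = 0.005,
                             seed = 1) {
  validate_tracks(tracks)
  stopifnot(spike_rate >= 0, spike_rate <= 1, gap_rate >= 0, gap_rate <= 1)
  if (spike_rate == 0 && gap_rate == 0) {
    return(list(tracks = tracks, truth = tibble::tibble(
      participant_id = character(), time = as.POSIXct(character(), tz = "UTC"),
      type = character()
    )))
  }
  with_seed(seed, {
    out <- list()
    truth <- list()
    for (pid in unique(tracks$participant_id)) {
      tr <- tracks[tracks$participant_id == pid, ]
      n <- nrow(tr)
      n_spike <- round(spike_rate * n)
      n_gap <- round(gap_rate * n)
      if ((n_spike + n_gap) > 0 && n < 20) {
        stop("track too short for requested injection rates", call. = FALSE)
      }
      if ((n_spike + n_gap) == 0) {
        out[[pid]] <- tr
        next
      }
      ## candidate interior fixes, chosen greedily with >= 4 fixes between
      ## any two sites so injections never interact
      cand <- sample(5:(n - 5))
      sites <- integer(0)
      for (i in cand) {
        if (length(sites) == n_spike + n_gap) break
        if (all(abs(i - sites) > 4)) sites <- c(sites, i)
      }
      if (length(sites) < n_spike + n_gap) {
        stop("could not place all injections for ", pid, call. = FALSE)
      }
      spike_at <- sites[seq_len(n_spike)]
      gap_at <- sites[n_spike + seq_len(n_gap)]
      ## spikes: displace the fix ~30 m at a random bearing; both the
      ## incoming and outgoing step speeds then exceed any walking speed
      for (i in spike_at) {
        ang <- stats::runif(1, 0, 2 * pi)
        ll <- xy_to_latlon(30 * sin(ang), 30 * cos(ang),
                           list(anchor_lat = tr$lat[i], anchor_lon = tr$lon[i]))
        tr$lat[i] <- ll$lat
        tr$lon[i] <- ll$lon
        truth[[length(truth) + 1]] <- tibble::tibble(
          participant_id = pid, time = tr$time[c(i, i + 1)], type = "speed"
        )
      }
      ## gaps: delete fixes i and i+1; the survivor step ends at i+2
      drop <- integer(0)
      for (i in gap_at) {
        drop <- c(drop, i, i + 1L)
        truth[[length(truth) + 1]] <- tibble::tibble(
          participant_id = pid, time = tr$time[i + 2], type = "gap"
        )
      }
      if (length(drop)) tr <- tr[-drop, ]
      out[[pid]] <- tr
    }
    list(tracks = dplyr::bind_rows(out), truth = dplyr::bind_rows(truth))
  })
}

#' Simulate state scores with a planted linear effect
#'
#' Generates the questionnaire-style state table and a synthetic outcome
#' obeying the model the fitting stage assumes, with known ground truth:
#' states are drawn first (1-7 scale, clipped), then
#' `outcome = sum(beta * state) + team effect + participant effect +
#' residual`. With `beta = 0` the outcome is independent of every state.
#'
#' @param keys Data frame with `participant_id`, `team_id`, `round` (one
#'   row per participant x round), e.g. from [track_metrics()] or
#'   [sim_keys()].
#' @param beta Named numeric vector of planted coefficients over `round`
#'   and the [STATE_PREDICTORS]; missing names default to 0.
#' @param re_sd Named numeric: SDs of the team and participant random
#'   intercepts, e.g. `c(team = 0.5, participant = 0.5)`.
#' @param resid_sd Residual SD.
#' @param seed Integer seed.
#' @return A tibble with the key columns, the state predictors and an
#'   `outcome` column; planted parameters in attribute `"truth"`.
#' @export
simulate_state_scores <- function(keys, beta = NULL,
                                  re_sd = c(team = 0.5, participant = 0.5),
                                  resid_sd = 1, seed = 1) {
  need <- c("participant_id", "team_id", "round")
  miss <- setdiff(need, names(keys))
  if (length(miss)) {
    stop("keys lack column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  terms <- c("round", STATE_PREDICTORS)
  b <- stats::setNames(numeric(length(terms)), terms)
  if (!is.null(beta)) {
    unknown <- setdiff(names(beta), terms)
    if (length(unknown)) {
      stop("unknown beta name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    b[names(beta)] <- beta
  }
  with_seed(seed, {
    n <- nrow(keys)
    tab <- tibble::as_tibble(keys[need])
    tab$illegal_card <- stats::rbinom(n, 1, 0.5)
    for (p in setdiff(STATE_PREDICTORS, "illegal_card")) {
      tab[[p]] <- pmin(pmax(stats::rnorm(n, 4, 1.2), 1), 7)
    }
    teams <- unique(tab$team_id)
    parts <- unique(paste(tab$team_id, tab$participant_id))
    b_team <- stats::setNames(stats::rnorm(length(teams), 0, re_sd[["team"]]),
                              teams)
    b_part <- stats::setNames(
      stats::rnorm(length(parts), 0, re_sd[["participant"]]), parts
    )
    lin <- as.matrix(tab[terms]) %*% b
    tab$outcome <- as.numeric(lin) +
      b_team[tab$team_id] +
      b_part[paste(tab$team_id, tab$participant_id)] +
      stats::rnorm(n, 0, resid_sd)
    attr(tab, "truth") <- list(beta = b, re_sd = re_sd, resid_sd = resid_sd)
    tab
  })
}

#' Participant x round key grid
#'
#' Convenience builder of the `(participant_id, team_id, round)` grid for
#' [simulate_state_scores()] without simulating tracks.
#'
#' @param n_teams,members_per_team,n_rounds Design sizes.
#' @return A tibble with one row per participant and round.
#' @export
sim_keys <- function(n_teams, members_per_team, n_rounds) {
  tidyr::expand_grid(
    team = seq_len(n_teams),
    member = seq_len(members_per_team),
    round = seq_len(n_rounds)
  ) |>
    dplyr::transmute(
      participant_id = sprintf("T%02dP%d", .data$team, .data$member),
      team_id = sprintf("T%02d", .data$team),
      round = .data$round
    )
}

#' Simulate a full study
#'
#' [simulate_tracks()] plus [inject_anomalies()] (at the configured rates)
#' and the course geometry, bundled for the pipeline and the command-line
#' interface.
#'
#' @param cfg A [sim_config()].
#' @return A list: `tracks`, `meta`, `geometry`, `truth` (with element
#'   `anomalies`).
#' @export
simulate_study <- function(cfg) {
  sim <- simulate_tracks(cfg)
  geom <- course_geometry(cfg)
  anom <- inject_anomalies(sim$tracks, spike_rate = cfg$spike_rate,
                           gap_rate = cfg$gap_rate, seed = cfg$seed + 1)
  truth <- sim$truth
  truth$anomalies <- anom$truth
  list(tracks = anom$tracks, meta = sim$meta, geometry = geom, truth = truth)
}
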