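## The five behavioural movement variables, per participant x round window:
## speed (mean km/h over clean steps), speed variability (sample SD of
## those step speeds), intra-team distance (time-averaged mean distance to
## co-present team members), route deviation (mean cross-track distance to
## the start->finish great circle) and route-deviation variability (sample
## SD of that series).
##
## Masking conventions: speed-masked steps contribute neither speeds nor
## positions (the fix itself is suspect); gap-masked steps contribute no
## speeds but their fixes keep anchoring route deviation and intra-team
## distance.

## Steps attributable to a window are rows start_index+1 .. end_index
## (each row's step columns describe the step arriving at that row).
window_step_speeds <- function(tr, start_index, end_index) {
  if (end_index <= start_index) return(numeric(0))
  rows <- (start_index + 1L):end_index
  sp <- tr$speed_kmh[rows][tr$mask_reason[rows] == "none"]
  sp[is.finite(sp)]
}

## Fixes whose position is trustworthy: everything except speed-masked.
window_position_rows <- function(tr, start_index, end_index) {
  rows <- start_index:end_index
  rows[tr$mask_reason[rows] != "speed_exceeds_max"]
}

#' Per-window speed statistics
#'
#' Mean and sample standard deviation (n - 1 denominator) of the clean
#' step speeds inside each window, in km/h.
#'
#' @param tracks A QC-processed tracks tibble (see [apply_qc()]).
#' @param windows A windows tibble.
#' @return A tibble: `participant_id`, `round`, `speed_mean_kmh`,
#'   `speed_sd_kmh`, `n_steps`.
#' @export
speed_stats <- function(tracks, windows) {
  check_kinematics(tracks)
  split_tracks <- split(tracks, tracks$participant_id)
  purrr::pmap_dfr(windows, function(participant_id, round, start_index,
                                    end_index, ...) {
    sp <- window_step_speeds(split_tracks[[participant_id]],
                             start_index, end_index)
    tibble::tibble(
      participant_id = participant_id, round = round,
      speed_mean_kmh = if (length(sp) >= 1) mean(sp) else NA_real_,
      speed_sd_kmh = if (length(sp) >= 2) stats::sd(sp) else NA_real_,
      n_steps = length(sp)
    )
  })
}

#' Route-deviation series
#'
#' For each window, the unsigned cross-track distance (metres) of every
#' trustworthy fix to the great-circle path from the participant's start
#' point to their (interpolated) finish point. Degenerate windows whose
#' start and finish coincide raise an error.
#'
#' @inheritParams speed_stats
#' @return A tibble: `participant_id`, `round`, `time`, `deviation_m`.
#' @export
route_deviation <- function(tracks, windows) {
  validate_tracks(tracks)
  if (!"start_lat" %in% names(windows)) {
    windows <- window_endpoints(windows, tracks)
  }
  split_tracks <- split(tracks, tracks$participant_id)
  purrr::pmap_dfr(windows, function(participant_id, round, start_index,
                                    end_index, start_lat, start_lon,
                                    finish_lat, finish_lon, ...) {
    tr <- split_tracks[[participant_id]]
    if (start_lat == finish_lat && start_lon == finish_lon) {
      stop("degenerate window for participant ", participant_id, " round ",
           round, ": start and finish coincide", call. = FALSE)
    }
    rows <- if ("mask_reason" %in% names(tr)) {
      window_position_rows(tr, start_index, end_index)
    } else {
      start_index:end_index
    }
    tibble::tibble(
      participant_id = participant_id, round = round,
      time = tr$time[rows],
      deviation_m = gc_cross_track(tr$lat[rows], tr$lon[rows],
                                   start_lat, start_lon,
                                   finish_lat, finish_lon)
    )
  })
}

#' Per-member intra-team distance
#'
#' At every shared 1 Hz timestamp within a team and round, each member's
#' mean great-circle distance to all co-present members; the per-member
#' value is the time average of those means. Members co-present with a
#' teammate at fewer than 2 timestamps get `NA`. Alignment is by exact
#' timestamp; recording gaps simply drop that timestamp for that member.
#'
#' @param tracks A QC-processed tracks tibble carrying `team_id` (see
#'   [attach_metadata()]).
#' @param windows A windows tibble.
#' @return A tibble: `team_id`, `participant_id`, `round`,
#'   `intra_team_distance_m`, `n_shared`.
#' @export
intra_team_distance <- function(tracks, windows) {
  validate_tracks(tracks)
  if (!"team_id" %in% names(tracks)) {
    stop("tracks lack team_id; attach_metadata() first", call. = FALSE)
  }
  fixes <- window_fixes(windows, tracks)
  if ("mask_reason" %in% names(fixes)) {
    fixes <- fixes[fixes$mask_reason != "speed_exceeds_max", ]
  }
  fixes$t <- as.numeric(fixes$time)
  pairs <- dplyr::inner_join(
    dplyr::select(fixes, "team_id", "round", "t", "participant_id", "lat", "lon"),
    dplyr::select(fixes, "team_id", "round", "t", "participant_id", "lat", "lon"),
    by = c("team_id", "round", "t"), suffix = c("", "_other"),
    relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$participant_id != .data$participant_id_other)
  singles <- setdiff(
    unique(paste(fixes$team_id, fixes$participant_id, fixes$round)),
    unique(paste(pairs$team_id, pairs$participant_id, pairs$round))
  )
  if (length(singles)) {
    warning("no co-present teammates for ", length(singles),
            " participant-round(s); intra-team distance is NA", call. = FALSE)
  }
  per_t <- pairs |>
    dplyr::mutate(d = gc_distance(.data$lat, .data$lon,
                                  .data$lat_other, .data$lon_other)) |>
    dplyr::group_by(.data$team_id, .data$participant_id, .data$round, .data$t) |>
    dplyr::summarise(mean_d = mean(.data$d), .groups = "drop")
  res <- per_t |>
    dplyr::group_by(.data$team_id, .data$participant_id, .data$round) |>
    dplyr::summarise(
      intra_team_distance_m = mean(.data$mean_d),
      n_shared = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(intra_team_distance_m = dplyr::if_else(
      .data$n_shared < 2, NA_real_, .data$intra_team_distance_m
    ))
  all_keys <- dplyr::distinct(fixes, .data$team_id, .data$participant_id,
                              .data$round)
  dplyr::left_join(all_keys, res,
                   by = c("team_id", "participant_id", "round")) |>
    dplyr::mutate(n_shared = dplyr::coalesce(.data$n_shared, 0L))
}

#' Behavioural metric table
#'
#' One row per participant and round with the five movement variables plus
#' QC counts, ordered by team, participant, round. Degenerate windows
#' (coincident endpoints, too few clean steps) yield `NA` fields and a
#' `flag` note instead of errors.
#'
#' @param tracks A QC-processed tracks tibble; `team_id` is required for
#'   intra-team distance (attach it with [attach_metadata()]).
#' @param windows A windows tibble from [segment_rounds()].
#' @return A tibble with columns `team_id`, `participant_id`, `round`,
#'   `speed_mean_kmh`, `speed_sd_kmh`, `intra_team_distance_m`,
#'   `route_deviation_mean_m`, `route_deviation_sd_m`, `n_points`,
#'   `n_masked`, `flag`.
#' @export
track_metrics <- function(tracks, windows) {
  check_kinematics(tracks)
  windows <- window_endpoints(windows, tracks)
  sp <- speed_stats(tracks, windows)
  have_team <- "team_id" %in% names(tracks)
  split_tracks <- split(tracks, tracks$participant_id)
  rd <- purrr::pmap_dfr(windows, function(participant_id, round, start_index,
                                          end_index, start_lat, start_lon,
                                          finish_lat, finish_lon, ...) {
    tr <- split_tracks[[participant_id]]
    rows <- start_index:end_index
    base <- tibble::tibble(
      participant_id = participant_id, round = round,
      n_points = length(rows),
      n_masked = sum(tr$mask_reason[rows] %in% c("speed_exceeds_max", "time_gap"))
    )
    if (start_lat == finish_lat && start_lon == finish_lon) {
      return(dplyr::mutate(base, route_deviation_mean_m = NA_real_,
                           route_deviation_sd_m = NA_real_,
                           flag = "degenerate_endpoints"))
    }
    prows <- window_position_rows(tr, start_index, end_index)
    dev <- gc_cross_track(tr$lat[prows], tr$lon[prows],
                          start_lat, start_lon, finish_lat, finish_lon)
    dplyr::mutate(
      base,
      route_deviation_mean_m = if (length(dev) >= 1) mean(dev) else NA_real_,
      route_deviation_sd_m = if (length(dev) >= 2) stats::sd(dev) else NA_real_,
      flag = NA_character_
    )
  })
  out <- dplyr::left_join(sp, rd, by = c("participant_id", "round"))
  if (have_team) {
    itd <- intra_team_distance(tracks, windows)
    out <- out |>
      dplyr::left_join(dplyr::select(itd, -"n_shared"),
                       by = c("participant_id", "round"))
  } else {
    warning("no team_id on tracks; intra_team_distance_m is NA", call. = FALSE)
    out <- dplyr::mutate(out, team_id = NA_character_,
                         intra_team_distance_m = NA_real_)
  }
  out |>
    dplyr::select("team_id", "participant_id", "round",
                  "speed_mean_kmh", "speed_sd_kmh", "intra_team_distance_m",
                  "route_deviation_mean_m", "route_deviation_sd_m",
                  "n_points", "n_masked", "flag") |>
    dplyr::arrange(.data$team_id, .data$participant_id, .data$round)
}
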