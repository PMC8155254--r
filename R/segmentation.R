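## Cutting continuous per-participant logs into analysis windows.
##
## A window opens at the first fix inside the entry polygon (boundary
## counts as inside) and closes at the first fix after the step that
## crosses the finish line. Fixes between a crossing and the next entry
## are ignored; repeated entry/crossing alternation yields consecutively
## numbered rounds.

## Core scanner for one participant's ordered fixes. Returns a tibble of
## windows (possibly zero rows).
scan_windows <- function(tr, entry, finish, first_only = FALSE) {
  n <- nrow(tr)
  inside <- point_in_polygon(tr$lat, tr$lon, entry)
  cross <- if (n >= 2) {
    segment_crosses(tr$lat[-n], tr$lon[-n], tr$lat[-1], tr$lon[-1], finish)
  } else {
    tibble::tibble(crossed = logical(0), fraction = numeric(0))
  }
  out <- list()
  cursor <- 1L
  round <- 0L
  while (cursor <= n) {
    starts <- which(inside[cursor:n])
    if (length(starts) == 0) break
    start <- cursor + starts[1] - 1L
    round <- round + 1L
    ## first crossing step at or after the start fix
    cand <- which(cross$crossed & seq_len(n - 1) >= start)
    if (length(cand)) {
      end <- cand[1] + 1L # first fix beyond the crossing
      frac <- cross$fraction[cand[1]]
      closed <- TRUE
    } else {
      warning("participant '", tr$participant_id[1], "': entry at index ",
              start, " never followed by a finish-line crossing; ",
              "window left open to track end", call. = FALSE)
      end <- n
      frac <- NA_real_
      closed <- FALSE
    }
    out[[round]] <- tibble::tibble(
      participant_id = tr$participant_id[1],
      round = round,
      start_index = start, end_index = end,
      start_time = tr$time[start], end_time = tr$time[end],
      crossing_fraction = frac, closed = closed
    )
    if (!closed) break
    cursor <- end + 1L
    if (first_only) break
  }
  dplyr::bind_rows(out)
}

#' Split each participant's log into rounds
#'
#' Scans each participant's fixes for repeated entry-polygon /
#' finish-line alternation and returns one window per pass, numbered
#' `round = 1, 2, ...` in temporal order. Indices are row positions within
#' the participant's time-ordered fixes. A participant who never enters
#' the polygon contributes zero windows, with a warning.
#'
#' @param tracks A tracks tibble (QC-processed; positions of masked steps
#'   are still used, since masking hides step quantities, not fixes).
#' @param entry Entry region, a [geo_polygon()] (in the field study this is
#'   the visibility area from which teams and guards could see each other).
#' @param finish A [cross_line()].
#' @return A windows tibble: `participant_id`, `round`, `start_index`,
#'   `end_index`, `start_time`, `end_time`, `crossing_fraction`, `closed`.
#' @export
segment_rounds <- function(tracks, entry, finish) {
  validate_tracks(tracks)
  stopifnot(inherits(entry, "geo_polygon"), inherits(finish, "cross_line"))
  out <- tracks |>
    dplyr::group_split(.data$participant_id, .keep = TRUE) |>
    purrr::map_dfr(scan_windows, entry = entry, finish = finish)
  none <- setdiff(unique(tracks$participant_id), out[["participant_id"]])
  if (length(none)) {
    warning("no entry into the polygon for participant(s): ",
            paste(none, collapse = ", "), call. = FALSE)
  }
  out
}

#' Select a single analysis window per participant
#'
#' Like [segment_rounds()] but returns only the first window per
#' participant and treats a participant who never enters the entry region
#' as an error.
#'
#' @inheritParams segment_rounds
#' @return A windows tibble with one row per participant.
#' @export
select_span <- function(tracks, entry, finish) {
  validate_tracks(tracks)
  stopifnot(inherits(entry, "geo_polygon"), inherits(finish, "cross_line"))
  out <- tracks |>
    dplyr::group_split(.data$participant_id, .keep = TRUE) |>
    purrr::map_dfr(scan_windows, entry = entry, finish = finish,
                   first_only = TRUE)
  none <- setdiff(unique(tracks$participant_id), out[["participant_id"]])
  if (length(none)) {
    stop("no entry into the polygon for participant(s): ",
         paste(none, collapse = ", "), call. = FALSE)
  }
  out
}

#' Per-participant start and finish points
#'
#' The start point is the window's first fix (the first fix inside the
#' entry region); the finish point is interpolated along the crossing step
#' at the recorded crossing fraction, so it lies on the finish line rather
#' than at the up-to-1-s-late first fix beyond it. Open windows use the
#' last fix and are flagged (`finish_interpolated = FALSE`).
#'
#' @param windows A windows tibble from [segment_rounds()]/[select_span()].
#' @param tracks The tracks tibble the windows were derived from.
#' @return The windows tibble with `start_lat`, `start_lon`, `finish_lat`,
#'   `finish_lon`, `finish_interpolated` added.
#' @export
window_endpoints <- function(windows, tracks) {
  validate_tracks(tracks)
  split_tracks <- split(tracks, tracks$participant_id)
  res <- purrr::pmap_dfr(windows, function(participant_id, round, start_index,
                                           end_index, crossing_fraction,
                                           closed, ...) {
    tr <- split_tracks[[participant_id]]
    if (is.null(tr) || end_index > nrow(tr)) {
      stop("window indices out of bounds for participant ", participant_id,
           call. = FALSE)
    }
    s <- list(lat = tr$lat[start_index], lon = tr$lon[start_index])
    if (closed && !is.na(crossing_fraction)) {
      i <- end_index - 1L
      f <- crossing_fraction
      fin <- list(
        lat = tr$lat[i] + f * (tr$lat[end_index] - tr$lat[i]),
        lon = tr$lon[i] + f * (tr$lon[end_index] - tr$lon[i])
      )
      interp <- TRUE
    } else {
      fin <- list(lat = tr$lat[end_index], lon = tr$lon[end_index])
      interp <- FALSE
    }
    tibble::tibble(
      participant_id = participant_id, round = round,
      start_lat = s$lat, start_lon = s$lon,
      finish_lat = fin$lat, finish_lon = fin$lon,
      finish_interpolated = interp
    )
  })
  dplyr::left_join(windows, res, by = c("participant_id", "round"))
}

#' Label fixes with their analysis window
#'
#' Convenience join: returns the window rows of the tracks tibble with a
#' `round` column attached (fixes outside any window are dropped).
#'
#' @inheritParams window_endpoints
#' @return A tracks tibble restricted to windowed fixes, with `round`.
#' @export
window_fixes <- function(windows, tracks) {
  validate_tracks(tracks)
  split_tracks <- split(tracks, tracks$participant_id)
  purrr::pmap_dfr(windows, function(participant_id, round, start_index,
                                    end_index, ...) {
    tr <- split_tracks[[participant_id]]
    dplyr::mutate(tr[start_index:end_index, ], round = round,
                  .window_pos = dplyr::row_number())
  })
}
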