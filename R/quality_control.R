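## Movement quality control.
##
## A step is the interval between consecutive fixes of one participant.
## Cleaning marks a step's derived quantities (distance, dt, speed) as
## unusable while the fix itself is retained, so segmentation and
## intra-team alignment keep positional continuity. mask_reason values:
##   "first_point"        first fix of a participant (no incoming step)
##   "speed_exceeds_max"  implied speed above the threshold (signal jump)
##   "time_gap"           time difference above the threshold (logger gap)
##   "none"               clean step

MASK_LEVELS <- c("none", "first_point", "speed_exceeds_max", "time_gap")

## haversine that propagates NA instead of erroring (lagged first rows)
gc_distance_na <- function(lat1, lon1, lat2, lon2) {
  ok <- !(is.na(lat1) | is.na(lon1) | is.na(lat2) | is.na(lon2))
  out <- rep(NA_real_, length(lat2))
  if (any(ok)) {
    out[ok] <- gc_distance(lat1[ok], lon1[ok], lat2[ok], lon2[ok])
  }
  out
}

#' Derive per-step kinematics
#'
#' Adds `step_dt_s`, `step_distance_m` (great-circle) and `speed_kmh`
#' between consecutive fixes of each participant, and initialises
#' `mask_reason` ("first_point" for each participant's first fix, "none"
#' otherwise). Speed is `3.6 * distance / dt`, the mean km/h over the step.
#'
#' @param tracks A tracks tibble.
#' @return The tracks tibble with kinematic columns added.
#' @export
derive_kinematics <- function(tracks) {
  validate_tracks(tracks)
  tracks |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(
      step_dt_s = as.numeric(.data$time) - dplyr::lag(as.numeric(.data$time)),
      step_distance_m = gc_distance_na(dplyr::lag(.data$lat),
                                       dplyr::lag(.data$lon),
                                       .data$lat, .data$lon),
      speed_kmh = 3.6 * .data$step_distance_m / .data$step_dt_s,
      mask_reason = dplyr::if_else(dplyr::row_number() == 1L,
                                   "first_point", "none")
    ) |>
    dplyr::ungroup()
}

check_kinematics <- function(tracks) {
  need <- c("step_dt_s", "step_distance_m", "speed_kmh", "mask_reason")
  if (!all(need %in% names(tracks))) {
    stop("kinematic columns missing; run derive_kinematics() first",
         call. = FALSE)
  }
  invisible(tracks)
}

#' Mask steps with unrealistic speed
#'
#' Steps whose implied speed strictly exceeds `max_kmh` (default 40 km/h,
#' the conventional bound for pedestrian GPS: faster steps indicate signal
#' loss or multipath jumps) are masked with reason `"speed_exceeds_max"`
#' and excluded from all downstream metric aggregation. Exactly-threshold
#' speeds are kept. Idempotent; only `"none"` steps can acquire the mask,
#' so speed masking takes priority over later gap masking.
#'
#' @param tracks A tracks tibble with kinematics.
#' @param max_kmh Positive speed threshold in km/h.
#' @return The tracks tibble with updated `mask_reason`.
#' @export
mask_unrealistic_speed <- function(tracks, max_kmh = 40) {
  check_kinematics(tracks)
  if (!is.numeric(max_kmh) || length(max_kmh) != 1 || max_kmh <= 0) {
    stop("max_kmh must be a positive number", call. = FALSE)
  }
  dplyr::mutate(tracks, mask_reason = dplyr::if_else(
    .data$mask_reason == "none" & is.finite(.data$speed_kmh) &
      .data$speed_kmh > max_kmh,
    "speed_exceeds_max", .data$mask_reason
  ))
}

#' Mask steps across recording gaps
#'
#' Steps whose time difference strictly exceeds `max_gap_s` (default 1 s,
#' i.e., any break in the 1 Hz cadence) are masked with reason
#' `"time_gap"`: the step's speed and distance become missing while the
#' positions on both sides are retained. Non-positive time differences
#' (duplicate or reversed logger timestamps) are masked too, with a
#' warning.
#'
#' @param tracks A tracks tibble with kinematics.
#' @param max_gap_s Positive gap threshold in seconds.
#' @return The tracks tibble with updated `mask_reason`.
#' @export
mask_time_gaps <- function(tracks, max_gap_s = 1) {
  check_kinematics(tracks)
  if (!is.numeric(max_gap_s) || length(max_gap_s) != 1 || max_gap_s <= 0) {
    stop("max_gap_s must be a positive number", call. = FALSE)
  }
  nonpos <- tracks$mask_reason == "none" & !is.na(tracks$step_dt_s) &
    tracks$step_dt_s <= 0
  if (any(nonpos)) {
    warning(sum(nonpos), " step(s) with non-positive time difference masked",
            call. = FALSE)
  }
  dplyr::mutate(tracks, mask_reason = dplyr::if_else(
    .data$mask_reason == "none" & !is.na(.data$step_dt_s) &
      (.data$step_dt_s > max_gap_s | .data$step_dt_s <= 0),
    "time_gap", .data$mask_reason
  ))
}

#' Apply the standard cleaning pipeline
#'
#' [derive_kinematics()], then [mask_unrealistic_speed()], then
#' [mask_time_gaps()] — speed masking first, so a step can carry only its
#' first triggered reason with speed taking priority.
#'
#' @param tracks A tracks tibble.
#' @param max_kmh,max_gap_s Thresholds passed through.
#' @return The cleaned tracks tibble.
#' @export
apply_qc <- function(tracks, max_kmh = 40, max_gap_s = 1) {
  tracks |>
    derive_kinematics() |>
    mask_unrealistic_speed(max_kmh = max_kmh) |>
    mask_time_gaps(max_gap_s = max_gap_s)
}

#' Drop participants whose sensor went dead
#'
#' Removes participants with fewer than `min_valid_points` clean
#' (unmasked) steps — the signature of a logger that stopped recording.
#' Dropped participants are reported and listed in attribute
#' `"dropped"`.
#'
#' @param tracks A tracks tibble with QC masks applied.
#' @param min_valid_points Minimum number of clean steps to keep a
#'   participant. Default 60 (one minute of clean 1 Hz walking).
#' @return The filtered tracks tibble with attribute `dropped` (tibble of
#'   participant_id and clean-step counts).
#' @export
drop_dead_sensors <- function(tracks, min_valid_points = 60) {
  check_kinematics(tracks)
  counts <- tracks |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_valid = sum(.data$mask_reason == "none")) |>
    dplyr::ungroup()
  dead <- dplyr::filter(counts, .data$n_valid < min_valid_points)
  if (nrow(dead)) {
    message("dropping ", nrow(dead), " dead sensor(s): ",
            paste(dead$participant_id, collapse = ", "))
  }
  out <- dplyr::filter(tracks, !.data$participant_id %in% dead$participant_id)
  attr(out, "dropped") <- dead
  out
}

#' Quality-control report
#'
#' Per-rule masked step counts and percentages of all fixes, in the shape
#' of a cleaning summary (how many fixes were excluded and why).
#'
#' @param tracks A tracks tibble with QC masks applied.
#' @return A tibble with columns `rule`, `n`, `pct`.
#' @export
qc_report <- function(tracks) {
  check_kinematics(tracks)
  total <- nrow(tracks)
  counts <- table(factor(tracks$mask_reason, levels = MASK_LEVELS))
  rep <- tibble::tibble(
    rule = MASK_LEVELS,
    n = as.integer(counts[MASK_LEVELS]),
    pct = round(100 * as.integer(counts[MASK_LEVELS]) / total, 2)
  )
  dropped <- attr(tracks, "dropped")
  if (!is.null(dropped)) {
    rep <- dplyr::bind_rows(rep, tibble::tibble(
      rule = "dead_sensor_tracks", n = nrow(dropped),
      pct = NA_real_
    ))
  }
  rep
}
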