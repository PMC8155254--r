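## Track data model + GPX / logger-CSV readers and writers.
##
## A track table ("tracks tibble") has one row per GPS fix:
##   participant_id (chr), time (POSIXct, UTC), lat, lon (dbl, decimal
##   degrees), ele (dbl metres, NA allowed), plus any metadata or derived
##   columns added downstream. Rows are sorted by participant then time,
## with strictly increasing timestamps within a participant.

GPX_NS <- "http://www.topografix.com/GPX/1/1"
GPX_TIME_FMT <- "%Y-%m-%dT%H:%M:%SZ"

#' Validate a tracks tibble
#'
#' Checks the track-table contract: required columns, finite coordinates,
#' and strictly increasing timestamps within each participant.
#'
#' @param tracks A tracks tibble.
#' @return The input, invisibly, or an error.
#' @export
validate_tracks <- function(tracks) {
  need <- c("participant_id", "time", "lat", "lon")
  miss <- setdiff(need, names(tracks))
  if (length(miss)) {
    stop("tracks table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tracks) == 0) stop("tracks table is empty", call. = FALSE)
  if (!inherits(tracks$time, "POSIXct")) {
    stop("time column must be POSIXct", call. = FALSE)
  }
  check_coords(tracks$lat, tracks$lon)
  bad <- tracks |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$time, strictly = TRUE)) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad)) {
    stop("timestamps not strictly increasing for: ",
         paste(bad$participant_id, collapse = ", "), call. = FALSE)
  }
  invisible(tracks)
}

## Sort, then collapse duplicate timestamps (keep first) with a warning.
normalise_tracks <- function(tracks, source = "input") {
  tracks <- dplyr::arrange(tracks, .data$participant_id, .data$time)
  dup <- tracks |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(.dup = duplicated(.data$time)) |>
    dplyr::ungroup()
  n_dup <- sum(dup$.dup)
  if (n_dup > 0) {
    warning(n_dup, " duplicate timestamp(s) in ", source,
            "; keeping first occurrence", call. = FALSE)
    tracks <- dup |> dplyr::filter(!.data$.dup) |> dplyr::select(-".dup")
  }
  tracks
}

#' Read tracks from a GPX 1.1 file
#'
#' One track per `<trk>` element (named by `<name>`, else by file basename
#' with an index). Points are sorted into time order; duplicate timestamps
#' are collapsed to the first occurrence with a warning. Timestamps are
#' interpreted as UTC.
#'
#' @param path Path to a GPX file.
#' @return A tracks tibble.
#' @export
read_gpx <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  trks <- xml2::xml_find_all(doc, ".//trk")
  if (length(trks) == 0) stop("no <trk> elements in ", path, call. = FALSE)
  base <- tools::file_path_sans_ext(basename(path))
  out <- purrr::map2_dfr(trks, seq_along(trks), function(trk, i) {
    nm <- xml2::xml_text(xml2::xml_find_first(trk, "./name"))
    if (is.na(nm) || nm == "") {
      nm <- if (length(trks) == 1) base else paste0(base, "_", i)
    }
    pts <- xml2::xml_find_all(trk, ".//trkpt")
    if (length(pts) == 0) {
      stop("track '", nm, "' has no points", call. = FALSE)
    }
    times <- xml2::xml_text(xml2::xml_find_first(pts, "./time"))
    if (any(is.na(times))) {
      stop("track '", nm, "' has points without timestamps", call. = FALSE)
    }
    ele <- xml2::xml_text(xml2::xml_find_first(pts, "./ele"))
    tibble::tibble(
      participant_id = nm,
      time = as.POSIXct(times, format = GPX_TIME_FMT, tz = "UTC"),
      lat = as.numeric(xml2::xml_attr(pts, "lat")),
      lon = as.numeric(xml2::xml_attr(pts, "lon")),
      ele = suppressWarnings(as.numeric(ele))
    )
  })
  if (any(is.na(out$time))) {
    stop("unparseable timestamp(s) in ", path, call. = FALSE)
  }
  out <- normalise_tracks(out, source = path)
  validate_tracks(out)
  out
}

#' Write tracks to a GPX 1.1 file
#'
#' One `<trk>` per participant; coordinates at 1e-7 degree precision,
#' timestamps in UTC.
#'
#' @param tracks A tracks tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gpx <- function(tracks, path) {
  validate_tracks(tracks)
  fmt_num <- function(x) formatC(x, format = "f", digits = 7)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<gpx version=\"1.1\" creator=\"trackmetrics\" xmlns=\"%s\">", GPX_NS)
  )
  for (pid in unique(tracks$participant_id)) {
    tr <- tracks[tracks$participant_id == pid, ]
    lines <- c(lines, "  <trk>", sprintf("    <name>%s</name>", pid), "    <trkseg>")
    has_ele <- "ele" %in% names(tr) && any(!is.na(tr$ele))
    for (i in seq_len(nrow(tr))) {
      pt <- sprintf("      <trkpt lat=\"%s\" lon=\"%s\">",
                    fmt_num(tr$lat[i]), fmt_num(tr$lon[i]))
      if (has_ele && !is.na(tr$ele[i])) {
        pt <- c(pt, sprintf("        <ele>%s</ele>", formatC(tr$ele[i], format = "f", digits = 2)))
      }
      pt <- c(pt,
              sprintf("        <time>%s</time>", format(tr$time[i], GPX_TIME_FMT, tz = "UTC")),
              "      </trkpt>")
      lines <- c(lines, pt)
    }
    lines <- c(lines, "    </trkseg>", "  </trk>")
  }
  lines <- c(lines, "</gpx>")
  writeLines(lines, path)
  invisible(path)
}

#' Describe a logger CSV dialect
#'
#' Column mapping and parsing rules for a GPS-logger CSV export (the kind
#' of per-second id/time/lat/lon/elevation table a consumer logger writes).
#'
#' @param id,time,lat,lon,elevation Column names in the file; `elevation`
#'   may be `NULL` when absent.
#' @param time_format `strptime` format for the timestamp column.
#' @param delim Field delimiter.
#' @param decimal_mark Decimal separator.
#' @param tz Timezone the timestamps are recorded in (normalised to UTC on
#'   read); naive loggers are assumed UTC.
#' @return A `csv_dialect` object.
#' @export
csv_dialect <- function(id = "id", time = "time", lat = "lat", lon = "lon",
                        elevation = "ele", time_format = "%Y-%m-%d %H:%M:%S",
                        delim = ",", decimal_mark = ".", tz = "UTC") {
  structure(
    list(id = id, time = time, lat = lat, lon = lon, elevation = elevation,
         time_format = time_format, delim = delim,
         decimal_mark = decimal_mark, tz = tz),
    class = "csv_dialect"
  )
}

#' Read tracks from a logger CSV file
#'
#' Rows with unparseable coordinates or timestamps are skipped and counted;
#' the skip count is attached as attribute `"skipped"` and reported.
#'
#' @param path Path to the CSV file.
#' @param dialect A [csv_dialect()].
#' @return A tracks tibble with attribute `skipped` (integer).
#' @export
read_track_csv <- function(path, dialect = csv_dialect()) {
  stopifnot(inherits(dialect, "csv_dialect"))
  raw <- readr::read_delim(
    path, delim = dialect$delim, col_types = readr::cols(.default = "c"),
    locale = readr::locale(decimal_mark = dialect$decimal_mark),
    progress = FALSE, show_col_types = FALSE
  )
  need <- c(dialect$id, dialect$time, dialect$lat, dialect$lon)
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("CSV lacks mapped column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  parse_num <- function(x) {
    if (dialect$decimal_mark != ".") x <- gsub(dialect$decimal_mark, ".", x, fixed = TRUE)
    suppressWarnings(as.numeric(x))
  }
  out <- tibble::tibble(
    participant_id = as.character(raw[[dialect$id]]),
    time = as.POSIXct(raw[[dialect$time]], format = dialect$time_format,
                      tz = dialect$tz),
    lat = parse_num(raw[[dialect$lat]]),
    lon = parse_num(raw[[dialect$lon]]),
    ele = if (!is.null(dialect$elevation) && dialect$elevation %in% names(raw)) {
      parse_num(raw[[dialect$elevation]])
    } else NA_real_
  )
  bad <- is.na(out$time) | is.na(out$lat) | is.na(out$lon) |
    out$lat < -90 | out$lat > 90
  n_skip <- sum(bad)
  out <- out[!bad, ]
  if (nrow(out) == 0) stop("no parseable rows in ", path, call. = FALSE)
  if (n_skip > 0) {
    message(n_skip, " unparseable row(s) skipped in ", path)
  }
  if (dialect$tz != "UTC") attr(out$time, "tzone") <- "UTC"
  out <- normalise_tracks(out, source = path)
  validate_tracks(out)
  attr(out, "skipped") <- as.integer(n_skip)
  out
}

#' Write tracks to a logger CSV file
#'
#' RFC 4180-compliant CSV with columns `id, time, lat, lon, ele`.
#'
#' @param tracks A tracks tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(tracks, path) {
  validate_tracks(tracks)
  ele <- if ("ele" %in% names(tracks)) tracks$ele else rep(NA_real_, nrow(tracks))
  out <- tibble::tibble(
    id = tracks$participant_id,
    time = format(tracks$time, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    lat = sprintf("%.7f", tracks$lat),
    lon = sprintf("%.7f", tracks$lon),
    ele = ifelse(is.na(ele), "", sprintf("%.2f", ele))
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Attach participant metadata to tracks
#'
#' Left-joins participant-level columns (e.g., `team_id`, `card_type`) from
#' a metadata table onto the tracks tibble by `participant_id`. Round-level
#' columns (state scores) stay in the metadata table and are joined later
#' by [build_model_table()]. Tracks without a metadata match are reported
#' via a warning and listed in attribute `"unmatched"`. The join is
#' idempotent: already-attached columns are replaced, not duplicated.
#'
#' @param tracks A tracks tibble.
#' @param meta Metadata table with `participant_id` and participant-level
#'   columns; if it carries a `round` column, `(participant_id, round)`
#'   must be unique.
#' @return The tracks tibble with metadata columns attached.
#' @export
attach_metadata <- function(tracks, meta) {
  validate_tracks(tracks)
  if (!"participant_id" %in% names(meta)) {
    stop("metadata lacks participant_id", call. = FALSE)
  }
  if ("round" %in% names(meta)) {
    if (anyDuplicated(meta[c("participant_id", "round")])) {
      stop("duplicate (participant_id, round) rows in metadata", call. = FALSE)
    }
  }
  keep <- intersect(c("participant_id", "team_id", "card_type"), names(meta))
  pmeta <- dplyr::distinct(meta[keep])
  if (anyDuplicated(pmeta$participant_id)) {
    stop("inconsistent participant-level metadata (conflicting team/card rows)",
         call. = FALSE)
  }
  tracks <- dplyr::select(tracks, -dplyr::any_of(setdiff(keep, "participant_id")))
  out <- dplyr::left_join(tracks, pmeta, by = "participant_id")
  unmatched <- setdiff(unique(tracks$participant_id), pmeta$participant_id)
  if (length(unmatched)) {
    warning("no metadata for participant(s): ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  }
  attr(out, "unmatched") <- unmatched
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
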