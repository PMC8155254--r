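## Offline track visualisation: plain lon/lat axes with a map-true aspect
## ratio, polygons and finish lines overlaid, tracks coloured by a
## grouping variable. No tile services, no network.

#' Plot tracks with geofences
#'
#' Draws each participant's path on lon/lat axes (aspect corrected by
#' `cos(latitude)` so distances look right), overlays geofence polygons
#' and finish lines, and colours tracks by a grouping column.
#'
#' @param tracks A tracks tibble.
#' @param polygons A [geo_polygon()] or list of them (optional).
#' @param lines A [cross_line()] or list of them (optional).
#' @param color_by Grouping column: `"participant_id"`, `"team_id"` or
#'   `"card_type"` (the latter two require [attach_metadata()]).
#' @return A ggplot object.
#' @export
plot_tracks <- function(tracks, polygons = NULL, lines = NULL,
                        color_by = c("participant_id", "team_id", "card_type")) {
  validate_tracks(tracks)
  color_by <- match.arg(color_by)
  if (!color_by %in% names(tracks)) {
    stop("color_by column '", color_by, "' not on tracks; valid keys: ",
         paste(intersect(c("participant_id", "team_id", "card_type"),
                         names(tracks)), collapse = ", "), call. = FALSE)
  }
  if (inherits(polygons, "geo_polygon")) polygons <- list(polygons)
  if (inherits(lines, "cross_line")) lines <- list(lines)
  p <- ggplot2::ggplot(tracks, ggplot2::aes(
    x = .data$lon, y = .data$lat,
    group = .data$participant_id, colour = .data[[color_by]]
  )) +
    ggplot2::geom_path(linewidth = 0.4)
  for (poly in polygons) {
    ring <- dplyr::bind_rows(poly$vertices, poly$vertices[1, ])
    p <- p + ggplot2::geom_path(
      data = ring, ggplot2::aes(x = .data$lon, y = .data$lat),
      inherit.aes = FALSE, colour = "grey30", linetype = "dashed"
    )
  }
  for (ln in lines) {
    p <- p + ggplot2::geom_path(
      data = tibble::tibble(lon = ln$lon, lat = ln$lat),
      ggplot2::aes(x = .data$lon, y = .data$lat),
      inherit.aes = FALSE, colour = "red", linewidth = 0.8
    )
  }
  p +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude", y = "Latitude", colour = color_by) +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a state-movement model
#'
#' Point estimates with approximate 95% intervals (+- 1.96 SE) per fixed
#' term.
#'
#' @param object A `state_model` from [fit_state_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.state_model <- function(object, ...) {
  tab <- object$coefficients
  tab <- tab[tab$term != "(Intercept)", ]
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error
    ), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Estimate (95% interval)", y = NULL,
      title = paste("Outcome:", object$outcome)
    ) +
    ggplot2::theme_minimal()
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot
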