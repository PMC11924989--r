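#' Default stimulus geometry
#'
#' Screen layout of the two fixation points and the eight possible stimulus
#' locations, in degrees of visual angle (dva) with the screen centre at the
#' origin. The fixation points sit 20.08 dva apart on the horizontal meridian;
#' each is flanked by four stimulus centres 5.05 dva away (above, below,
#' outward and inward along the meridian). Locations 1-4 belong to the left
#' fixation point, 5-8 to the right, with location k and k + 4 occupying the
#' same screen offset relative to their respective fixation points, so that a
#' 20.08 dva horizontal saccade maps each parafoveal location onto its
#' congruent peripheral partner (pairs 1-5, 2-6, 3-7, 4-8).
#'
#' @param fixation_sep Horizontal separation of the fixation points in dva.
#' @param offset Distance of each stimulus centre from its fixation point, dva.
#'
#' @return A list with elements `fixation_points` (tibble: side, x, y),
#'   `locations` (tibble: location_id, side, x, y) and `eccentricity_breaks`
#'   (cut-points, in dva, separating the near / mid / far test-location groups).
#' @export
#' @examples
#' default_geometry()$locations
default_geometry <- function(fixation_sep = 20.08, offset = 5.05) {
  fx <- tibble::tibble(
    side = c("left", "right"),
    x = c(-fixation_sep / 2, fixation_sep / 2),
    y = 0
  )
  # per-fixation offsets: up, down, outward, inward (inward = toward centre)
  off <- function(sgn) {
    tibble::tibble(
      dx = c(0, 0, -sgn * offset, sgn * offset),
      dy = c(offset, -offset, 0, 0)
    )
  }
  left <- off(1); right <- off(1)
  locs <- tibble::tibble(
    location_id = 1:8,
    side = rep(c("left", "right"), each = 4),
    x = c(fx$x[1] + left$dx, fx$x[2] + right$dx),
    y = c(fx$y[1] + left$dy, fx$y[2] + right$dy)
  )
  list(
    fixation_points = fx,
    locations = locs,
    eccentricity_breaks = c(7.5, 17.5)
  )
}

#' Distance of a stimulus location from a fixation point
#' @noRd
location_distance <- function(geometry, location_id, side) {
  loc <- geometry$locations[match(location_id, geometry$locations$location_id), ]
  fx <- geometry$fixation_points[match(side, geometry$fixation_points$side), ]
  sqrt((loc$x - fx$x)^2 + (loc$y - fx$y)^2)
}

#' Eccentricity group of a test location relative to current fixation
#'
#' Bins a stimulus location by its distance from the currently fixated point:
#' `"near"` below the first cut-point, `"mid"` between the two, `"far"` beyond
#' the second. With the default geometry the four locations around current
#' fixation are near (5.05 dva), the inner opposite-side location is mid
#' (15.03 dva) and the remaining opposite-side locations are far
#' (20.7-25.1 dva).
#'
#' @param location_id Stimulus location id(s), 1-8.
#' @param side Current fixation side, `"left"` or `"right"` (recycled).
#' @param geometry Geometry list as returned by [default_geometry()].
#' @return Character vector in `c("near", "mid", "far")`.
#' @export
eccentricity_group <- function(location_id, side, geometry = default_geometry()) {
  d <- location_distance(geometry, location_id, side)
  br <- geometry$eccentricity_breaks
  dplyr::case_when(
    d < br[1] ~ "near",
    d < br[2] ~ "mid",
    TRUE ~ "far"
  )
}

# congruent partner across the saccade: 1-5, 2-6, 3-7, 4-8 (and symmetric)
congruent_location <- function(location_id) {
  ifelse(location_id <= 4, location_id + 4L, location_id - 4L)
}

# mirror partner at the same eccentricity (up<->down, outward<->inward)
mirror_location <- function(location_id) {
  c(2L, 1L, 4L, 3L, 6L, 5L, 8L, 7L)[location_id]
}

# incongruent partner: the congruent location of the mirror (train 1 -> 6)
incongruent_location <- function(location_id) {
  congruent_location(mirror_location(location_id))
}

#' Parafoveal locations for a fixation side
#' @noRd
parafoveal_locations <- function(side) {
  if (identical(side, "left")) 1:4 else 5:8
}

other_side <- function(side) ifelse(side == "left", "right", "left")
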