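# Line-scan (push-broom) acquisition geometry: a push-broom camera builds the
# along-track image dimension from platform motion, so the frame rate must
# match the ground pixel size for square pixels.

#' Scan configuration for a push-broom camera
#'
#' @param fov full field of view of the lens, degrees (0, 180).
#' @param distance lens-to-target distance, meters.
#' @param cross_track_pixels number of pixels across the swath.
#' @param speed platform speed, m/s.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(fov, distance, cross_track_pixels, speed) {
  if (fov <= 0 || fov >= 180) stop("fov must lie in (0, 180) degrees")
  if (distance <= 0 || cross_track_pixels <= 0 || speed <= 0)
    stop("distance, cross_track_pixels and speed must be positive")
  structure(list(fov = fov, distance = distance,
                 cross_track_pixels = as.integer(cross_track_pixels),
                 speed = speed),
            class = "scan_config")
}

#' Ground pixel size of a line-scan camera
#'
#' swath = 2 * distance * tan(fov / 2); pixel = swath / cross-track pixels.
#'
#' @param cfg a `scan_config`.
#' @return Ground pixel size in meters.
#' @export
ground_pixel_size <- function(cfg) {
  stopifnot(inherits(cfg, "scan_config"))
  swath <- 2 * cfg$distance * tan(cfg$fov * pi / 360)
  swath / cfg$cross_track_pixels
}

#' Frame rate for square pixels
#'
#' The along-track pixel length equals speed / frame rate, so square pixels
#' require frame rate = speed / ground pixel size. Both the exact value and
#' the nearest-integer reporting value are returned.
#'
#' @param cfg a `scan_config`.
#' @return A list with `exact` (frames per second) and `fps`
#'   (nearest integer).
#' @export
frame_rate <- function(cfg) {
  exact <- cfg$speed / ground_pixel_size(cfg)
  list(exact = exact, fps = as.integer(round(exact)))
}
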