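#' Swimbladder dimensions from fish body length
#'
#' When the swimbladder cannot be measured directly, the fish body is
#' approximated as a prolate spheroid with the body length as major axis and
#' `body_width_fraction` of the body length as minor axis; the swimbladder
#' volume is taken as `volume_fraction` of that body volume and shaped as a
#' prolate spheroid with the given length-to-width ratio.
#'
#' @param body_length Fish body length (mm).
#' @param sb_length_to_width Swimbladder L/2a ratio (>= 1; empirical default
#'   1.5).
#' @param volume_fraction Swimbladder volume as a fraction of body volume
#'   (default 0.025).
#' @param body_width_fraction Body minor axis as a fraction of body length
#'   (default 1/6).
#' @return A list with `semi_minor` and `semi_major` axes (mm), `length`
#'   (the swimbladder length `2 * semi_major`, mm) and `volume` (mm^3).
#' @examples
#' swimbladder_dims(10)  # a = 0.3868 mm
#' @export
swimbladder_dims <- function(body_length, sb_length_to_width = 1.5,
                             volume_fraction = 0.025,
                             body_width_fraction = 1 / 6) {
  if (body_length <= 0) stop("'body_length' must be positive (mm)")
  if (sb_length_to_width < 1) stop("'sb_length_to_width' must be >= 1")
  v_body <- (4 / 3) * pi * (body_length / 2) *
    (body_length * body_width_fraction / 2)^2
  v_sb <- volume_fraction * v_body
  a <- (v_sb / ((4 / 3) * pi * sb_length_to_width))^(1 / 3)
  list(semi_minor = a, semi_major = sb_length_to_width * a,
       length = 2 * sb_length_to_width * a, volume = v_sb)
}

#' Cross-section radius from a silhouette area
#'
#' Maps a measured silhouette (planar projection) area to the semi-minor axis
#' of the model shape with the same projected area: a rectangle for the
#' cylinder, an ellipse for the prolate spheroid, and a disc (for which the
#' organism length is not needed).
#'
#' @param area Silhouette area (mm^2).
#' @param length Body length (mm); required for `cylinder` and `spheroid`.
#' @param shape One of `"cylinder"`, `"spheroid"`, `"disc"`.
#' @return Radius `a` (mm). If the implied radius exceeds `length / 2` the
#'   value is still returned with attribute `flag = "radius_exceeds_half_length"`
#'   and a warning.
#' @examples
#' radius_from_silhouette(pi, shape = "disc")     # 1
#' radius_from_silhouette(2, 10, "cylinder")      # 0.1
#' @export
radius_from_silhouette <- function(area, length = NULL,
                                   shape = c("cylinder", "spheroid", "disc")) {
  shape <- match.arg(shape)
  if (area <= 0) stop("'area' must be positive (mm^2)")
  if (shape != "disc" && (is.null(length) || length <= 0))
    stop("'length' must be positive for cylinder/spheroid shapes")
  a <- switch(shape,
              cylinder = area / (2 * length),
              spheroid = 2 * area / (pi * length),
              disc = sqrt(area / pi))
  if (shape != "disc" && a > length / 2) {
    warning("silhouette implies a radius larger than half the body length")
    attr(a, "flag") <- "radius_exceeds_half_length"
  }
  a
}
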