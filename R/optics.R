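#' Illumination spot diameter of a butt-coupled optical fiber
#'
#' Light leaving a multimode fiber spreads inside the acceptance cone, so at
#' a distance `d` from the fiber tip the illuminated spot grows to
#' `fiber_diameter + 2 * d * tan(half_angle)`. For the 0.5 mm PMMA fibers
#' used to stimulate individual compartments (acceptance half-angle about
#' 26 degrees) held ~1 mm above the neurons, the spot receiving the vast
#' majority of the light is about 1.5 mm across.
#'
#' @param fiber_diameter_mm Fiber core diameter, mm.
#' @param distance_mm Fiber tip to sample distance, mm.
#' @param half_angle_deg Acceptance half-angle, degrees (must be < 90).
#' @return Spot diameter in mm.
#' @examples
#' compute_spot_diameter(0.5, 1, 26)  # ~1.5 mm
#' @export
compute_spot_diameter <- function(fiber_diameter_mm, distance_mm,
                                  half_angle_deg) {
  if (any(fiber_diameter_mm < 0) || any(distance_mm < 0) ||
      any(half_angle_deg < 0)) {
    stop("all optical arguments must be >= 0", call. = FALSE)
  }
  if (any(half_angle_deg >= 90)) {
    stop("'half_angle_deg' must be below 90 degrees", call. = FALSE)
  }
  fiber_diameter_mm + 2 * distance_mm * tan(half_angle_deg * pi / 180)
}
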