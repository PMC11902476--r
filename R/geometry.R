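#' Device geometry of a tape between two anchor points
#'
#' Static constants of one tape of an unstable-base training device. The
#' device frame has its origin mid-span between the anchors, the X axis
#' pointing forward along the tape, Y to the left, and Z upward, so the
#' anchors sit at `(-span_l_mm/2, 0, 0)` and `(+span_l_mm/2, 0, 0)`.
#'
#' @param span_l_mm Rest length between back and front anchor, mm.
#' @param spring_length_mm Unloaded length of the spring segment that
#'   connects the tape to each anchor, mm.
#' @param sensor_section_end_mm Distance from an anchor to the inner
#'   boundary of the instrumented (sensor) section, mm. On a Sensopro Luna
#'   the IMUs sit on the spring-covered end sections, so the default equals
#'   the spring length.
#' @param tape_width_mm Width of the tape, mm.
#'
#' @return An object of class `tape_geometry`: a list with the fields above
#'   plus `anchor_x_mm`, the pair of longitudinal anchor coordinates.
#' @seealso [luna_geometry()] for the default Sensopro Luna values.
#' @export
#' @examples
#' g <- device_geometry(span_l_mm = 1726)
#' g$anchor_x_mm
device_geometry <- function(span_l_mm,
                            spring_length_mm = 200,
                            sensor_section_end_mm = spring_length_mm,
                            tape_width_mm = 200) {
  stopifnot(
    is.numeric(span_l_mm), length(span_l_mm) == 1L, is.finite(span_l_mm),
    span_l_mm > 0,
    spring_length_mm > 0, spring_length_mm < span_l_mm / 2,
    sensor_section_end_mm > 0, sensor_section_end_mm <= span_l_mm / 2,
    tape_width_mm > 0
  )
  structure(
    list(
      span_l_mm = span_l_mm,
      anchor_x_mm = c(-span_l_mm / 2, span_l_mm / 2),
      spring_length_mm = spring_length_mm,
      sensor_section_end_mm = sensor_section_end_mm,
      tape_width_mm = tape_width_mm
    ),
    class = "tape_geometry"
  )
}

#' Sensopro Luna tape geometry
#'
#' Convenience constructor with the Luna Fitness constants: a 1726 mm
#' anchor span, approximately 200 mm unloaded spring segments, and a
#' 200 mm (20 cm) wide tape.
#'
#' @return A `tape_geometry` object.
#' @export
luna_geometry <- function() {
  device_geometry(span_l_mm = 1726, spring_length_mm = 200,
                  sensor_section_end_mm = 200, tape_width_mm = 200)
}

#' @export
print.tape_geometry <- function(x, ...) {
  cat("<tape_geometry>\n")
  cat(sprintf("  span L:             %g mm (anchors at %g / %g)\n",
              x$span_l_mm, x$anchor_x_mm[1], x$anchor_x_mm[2]))
  cat(sprintf("  spring length:      %g mm\n", x$spring_length_mm))
  cat(sprintf("  sensor section end: %g mm from anchor\n",
              x$sensor_section_end_mm))
  cat(sprintf("  tape width:         %g mm\n", x$tape_width_mm))
  invisible(x)
}

#' Tunable model parameters
#'
#' @param segment_ratio Dimensionless correction applied to the vertical
#'   displacement to account for the foot being a flat segment rather than
#'   a point mass (the ratio of the true lowest-point depth dR to the
#'   ray-intersection depth dM). Geometry gives `1 - LF/L` for a flat foot
#'   segment of length `LF`; the default 0.85 corresponds to `LF = 260` mm
#'   on a 1726 mm span. See [segment_ratio_flatfoot()].
#' @param spring_coeff Dimensionless twist-rate multiple `k` of the spring
#'   segment relative to the tape, used by the spring-corrected roll models
#'   (RS / RWS). There is no universal value; it should be calibrated per
#'   device with [calibrate_params()]. The shipped default `k = 1` reduces
#'   RS to the uncorrected linear-twist model RM.
#' @param small_angle_deg Small-angle guard threshold in degrees. Input
#'   angles strictly below this magnitude yield zero predictions (no
#'   displacement, X at mid-span); default 0.1 degrees.
#'
#' @return An object of class `tape_params`.
#' @export
model_params <- function(segment_ratio = 0.85,
                         spring_coeff = 1,
                         small_angle_deg = 0.1) {
  stopifnot(
    segment_ratio > 0, segment_ratio <= 1,
    spring_coeff > 0,
    small_angle_deg >= 0
  )
  structure(
    list(segment_ratio = segment_ratio,
         spring_coeff = spring_coeff,
         small_angle_deg = small_angle_deg),
    class = "tape_params"
  )
}

#' @export
print.tape_params <- function(x, ...) {
  cat("<tape_params>\n")
  cat(sprintf("  segment_ratio (dR/dM): %g\n", x$segment_ratio))
  cat(sprintf("  spring_coeff k:        %g%s\n", x$spring_coeff,
              if (x$spring_coeff == 1) "  (RS reduces to RM; calibrate!)" else ""))
  cat(sprintf("  small-angle guard:     %g deg\n", x$small_angle_deg))
  invisible(x)
}

#' Geometric flat-foot segment ratio
#'
#' Intercept-theorem ratio `dR/dM = 1 - LF/L` between the true lowest-point
#' displacement of a tape loaded by a horizontal flat segment of length
#' `LF` and the depth predicted by the point-mass ray-intersection model on
#' a span of length `L`. The ratio is independent of where the flat segment
#' sits along the span.
#'
#' @param flat_length_mm Length `LF` of the flat (foot) segment, mm.
#' @param geom A `tape_geometry`.
#' @return Dimensionless ratio in (0, 1].
#' @export
#' @examples
#' segment_ratio_flatfoot(260, luna_geometry())  # ~0.85
segment_ratio_flatfoot <- function(flat_length_mm, geom) {
  stopifnot(inherits(geom, "tape_geometry"),
            flat_length_mm >= 0, flat_length_mm < geom$span_l_mm)
  1 - flat_length_mm / geom$span_l_mm
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
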