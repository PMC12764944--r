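#' Reduce angles to the canonical axial range
#'
#' Orientations of fibres are axial quantities: `theta` and `theta + 180` name
#' the same axis. All angles in this package are degrees, measured
#' counter-clockwise from the image +x axis, and are stored in the half-open
#' canonical range \eqn{[-90, 90)}.
#'
#' @param theta_deg Numeric vector (or matrix) of angles in degrees.
#' @return Angles reduced modulo 180 into `[-90, 90)`, same shape as input.
#'   `NA`/`NaN` pass through.
#' @examples
#' canonical_axial(c(90, 135, 225, -90, 179.5))
#' @export
canonical_axial <- function(theta_deg) {
  out <- ((theta_deg + 90) %% 180) - 90
  # %% can return 180 - eps rounding to exactly 180; guard the boundary
  out[out >= 90] <- -90
  out
}

#' Signed smallest difference between two axial angles
#'
#' @param a,b Angles in degrees (axial, period 180).
#' @return Difference `a - b` wrapped into `[-90, 90)` degrees.
#' @export
axial_diff <- function(a, b) {
  canonical_axial(a - b)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
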