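#' Instrument geometry for a SAXS measurement
#'
#' Bundles the quantities needed to map detector pixels to momentum transfer:
#' the X-ray wavelength, the sample-to-detector distance, the beam centre on
#' the detector, and the pixel pitch. Defaults describe a laboratory Cu-anode
#' pinhole camera: Cu K-alpha radiation (0.154 nm) with the detector 2507 mm
#' downstream of the sample and a 0.172 mm hybrid-pixel detector pitch.
#'
#' @param wavelength_nm X-ray wavelength in nm. Must be positive.
#' @param distance_mm Sample-to-detector distance in mm. Must be positive.
#' @param beam_center_px Numeric length-2 vector `c(row, col)` giving the beam
#'   centre in pixel coordinates (1-based, fractional values allowed).
#' @param pixel_size_mm Detector pixel pitch in mm. Must be positive.
#'
#' @return An object of class `saxs_geometry` (a named list).
#' @examples
#' geom <- saxs_geometry(beam_center_px = c(100, 100))
#' q_from_angle(0.001, geom$wavelength_nm)
#' @export
saxs_geometry <- function(wavelength_nm = 0.154,
                          distance_mm = 2507,
                          beam_center_px = c(0, 0),
                          pixel_size_mm = 0.172) {
  if (!is.numeric(wavelength_nm) || length(wavelength_nm) != 1 ||
      !is.finite(wavelength_nm) || wavelength_nm <= 0) {
    stop("invalid geometry: `wavelength_nm` must be a single positive number")
  }
  if (!is.numeric(distance_mm) || length(distance_mm) != 1 ||
      !is.finite(distance_mm) || distance_mm <= 0) {
    stop("invalid geometry: `distance_mm` must be a single positive number")
  }
  if (!is.numeric(pixel_size_mm) || length(pixel_size_mm) != 1 ||
      !is.finite(pixel_size_mm) || pixel_size_mm <= 0) {
    stop("invalid geometry: `pixel_size_mm` must be a single positive number")
  }
  if (!is.numeric(beam_center_px) || length(beam_center_px) != 2 ||
      any(!is.finite(beam_center_px))) {
    stop("invalid geometry: `beam_center_px` must be two finite numbers")
  }
  structure(
    list(
      wavelength_nm = wavelength_nm,
      distance_mm = distance_mm,
      beam_center_px = as.numeric(beam_center_px),
      pixel_size_mm = pixel_size_mm
    ),
    class = "saxs_geometry"
  )
}

#' @export
print.saxs_geometry <- function(x, ...) {
  cat("<saxs_geometry>\n")
  cat(sprintf("  wavelength:  %.4g nm\n", x$wavelength_nm))
  cat(sprintf("  distance:    %.6g mm\n", x$distance_mm))
  cat(sprintf("  beam centre: (%.6g, %.6g) px\n",
              x$beam_center_px[1], x$beam_center_px[2]))
  cat(sprintf("  pixel size:  %.4g mm\n", x$pixel_size_mm))
  invisible(x)
}

#' Momentum transfer from scattering half-angle
#'
#' Converts the half scattering angle theta to the magnitude of the momentum
#' transfer vector, q = 4 pi sin(theta) / lambda. q is inversely related to
#' real-space length scales: features at repeat distance d scatter near
#' q = 2 pi / d.
#'
#' @param theta_rad Half of the scattering angle, in radians. Vectorised;
#'   each value must lie in `[0, pi/2)`.
#' @param wavelength_nm X-ray wavelength in nm (positive scalar).
#'
#' @return Momentum transfer in reciprocal nm, same length as `theta_rad`.
#' @examples
#' q_from_angle(pi / 6, 1) # 2 * pi
#' @seealso [bragg_spacing()] for the inverse length-scale relation.
#' @export
q_from_angle <- function(theta_rad, wavelength_nm = 0.154) {
  if (!is.numeric(wavelength_nm) || length(wavelength_nm) != 1 ||
      !is.finite(wavelength_nm) || wavelength_nm <= 0) {
    stop("invalid geometry: `wavelength_nm` must be a single positive number")
  }
  if (!is.numeric(theta_rad) || any(!is.finite(theta_rad)) ||
      any(theta_rad < 0) || any(theta_rad >= pi / 2)) {
    stop("`theta_rad` must be finite values in [0, pi/2)")
  }
  4 * pi * sin(theta_rad) / wavelength_nm
}

#' Bragg repeat distance from peak position
#'
#' The dominant periodic repeat distance of a quasi-ordered structure whose
#' scattering peak sits at momentum transfer `q` is d = 2 pi / q.
#'
#' @param q Momentum transfer in reciprocal nm; positive, vectorised.
#' @return Repeat distance in nm.
#' @examples
#' bragg_spacing(0.045) # ~139.6 nm
#' @export
bragg_spacing <- function(q) {
  if (!is.numeric(q) || any(!is.finite(q)) || any(q <= 0)) {
    stop("`q` must be positive and finite")
  }
  2 * pi / q
}
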