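#' Detector geometry description
#'
#' Bundles the experimental geometry needed to map detector pixels to
#' scattering vectors: beam center, sample-to-detector distance, sensor
#' dimensions, pixel size and the FIT2D-convention detector tilt.
#'
#' The coordinate convention used throughout the package is: row index =
#' vertical (slow axis), column index = horizontal (fast axis), 0-based,
#' origin at the top-left pixel of the stored image. Pixel positions are
#' evaluated at pixel centers, and the beam center is given in the same
#' center-based frame, so a beam center of `c(0, 0)` is the center of the
#' top-left pixel. Fractional beam-center positions are allowed.
#'
#' The detector tilt follows the FIT2D convention: `tilt_rotation` (phi) is
#' the in-plane angle of the steepest-tilt direction measured from the
#' horizontal detector axis, and `tilt_angle` (tau) is the angle between the
#' primary beam and the detector normal. Both are given in degrees, as in the
#' calibration file; computations convert to radians internally.
#'
#' @param beamcenter Numeric length-2, beam-center position `(vertical,
#'   horizontal)` in pixel units (fractional allowed).
#' @param detector_distance Sample-to-detector distance in mm.
#' @param image_size Integer length-2, sensor dimensions `(vertical,
#'   horizontal)` in pixels.
#' @param pixel_size Numeric length-2, pixel size `(vertical, horizontal)` in
#'   micrometres.
#' @param tilt_rotation Tilt rotation phi in degrees.
#' @param tilt_angle Tilt angle tau in degrees; must satisfy `abs(tau) < 90`.
#'
#' @return An object of class `saxs_geometry`.
#' @examples
#' geom <- saxs_geometry(c(128, 128), 1000, c(256, 256), c(172, 172))
#' geom
#' @export
saxs_geometry <- function(beamcenter, detector_distance, image_size,
                          pixel_size, tilt_rotation = 0, tilt_angle = 0) {
  stopifnot(length(beamcenter) == 2, length(image_size) == 2,
            length(pixel_size) == 2)
  if (any(image_size <= 0)) stop("image_size components must be > 0")
  if (any(pixel_size <= 0)) stop("pixel_size components must be > 0")
  if (detector_distance <= 0) stop("detector_distance must be > 0")
  if (abs(tilt_angle) >= 90) stop("tilt_angle must satisfy |tau| < 90 degrees")
  structure(
    list(
      beamcenter = as.numeric(beamcenter),
      detector_distance = as.numeric(detector_distance),
      image_size = as.integer(image_size),
      pixel_size = as.numeric(pixel_size),
      tilt_rotation = as.numeric(tilt_rotation),
      tilt_angle = as.numeric(tilt_angle)
    ),
    class = "saxs_geometry"
  )
}

#' @export
print.saxs_geometry <- function(x, ...) {
  cat("<saxs_geometry>\n")
  cat(sprintf("  image size  : %d x %d px (vertical x horizontal)\n",
              x$image_size[1], x$image_size[2]))
  cat(sprintf("  beam center : (%.3f, %.3f) px\n",
              x$beamcenter[1], x$beamcenter[2]))
  cat(sprintf("  distance    : %.2f mm\n", x$detector_distance))
  cat(sprintf("  pixel size  : %.1f x %.1f um\n",
              x$pixel_size[1], x$pixel_size[2]))
  cat(sprintf("  tilt        : phi = %.2f deg, tau = %.2f deg\n",
              x$tilt_rotation, x$tilt_angle))
  invisible(x)
}

# Physical displacement of pixel centers from the beam center, in mm.
# row0/col0 are 0-based (fractional allowed). Returns right-positive dx and
# up-positive dy so that psi = atan2(dy, dx) is counter-clockwise from the
# horizontal detector axis.
.pixel_displacement <- function(geom, row0, col0) {
  dx <- (col0 - geom$beamcenter[2]) * geom$pixel_size[2] * 1e-3
  dy <- (geom$beamcenter[1] - row0) * geom$pixel_size[1] * 1e-3
  list(dx = dx, dy = dy)
}

.full_grid <- function(geom) {
  nv <- geom$image_size[1]; nh <- geom$image_size[2]
  list(row0 = matrix(rep(0:(nv - 1), nh), nv, nh),
       col0 = matrix(rep(0:(nh - 1), each = nv), nv, nh))
}

#' Per-pixel polar coordinates on the detector
#'
#' Assigns to every detector pixel its distance `r` from the beam center (in
#' mm, measured in the detector plane) and its azimuthal angle `psi` (radians,
#' counter-clockwise from the horizontal detector axis). This reduces the 3D
#' tilt geometry to a per-pixel 2D problem.
#'
#' @param geom A [saxs_geometry()].
#' @param row0,col0 Optional 0-based pixel coordinates (fractional allowed).
#'   Default: the full pixel-center grid of the sensor.
#' @return A list of class `saxs_polar` with matrices (or vectors, when
#'   explicit coordinates are supplied) `r` (mm) and `psi` (radians in
#'   `[0, 2*pi)`).
#' @export
pixel_polar_coordinates <- function(geom, row0 = NULL, col0 = NULL) {
  if (is.null(row0) || is.null(col0)) {
    g <- .full_grid(geom); row0 <- g$row0; col0 <- g$col0
  }
  d <- .pixel_displacement(geom, row0, col0)
  r <- sqrt(d$dx^2 + d$dy^2)
  psi <- atan2(d$dy, d$dx) %% (2 * pi)
  structure(list(r = r, psi = psi), class = "saxs_polar")
}

#' Tilt distortion angle
#'
#' Combines the tilt rotation phi, the tilt angle tau and the pixel azimuth
#' psi into the single per-pixel distortion angle alpha that carries the full
#' effect of the detector tilt:
#' \deqn{\alpha = \arcsin(\sin\tau \, \cos(\psi - \varphi)).}
#' alpha vanishes for an untilted detector and along the tilt axis
#' (`psi - phi = +/-90` degrees), and reaches `+/-tau` along the
#' steepest-tilt direction `psi = phi`.
#'
#' @param polar A [pixel_polar_coordinates()] result.
#' @param geom A [saxs_geometry()].
#' @return A list of class `saxs_distortion` with element `alpha` (radians).
#' @export
distortion_angle <- function(polar, geom) {
  phi <- geom$tilt_rotation * pi / 180
  tau <- geom$tilt_angle * pi / 180
  alpha <- asin(sin(tau) * cos(polar$psi - phi))
  structure(list(alpha = alpha), class = "saxs_distortion")
}

#' Scattered light path
#'
#' Length of the sample-to-pixel ray. In the plane spanned by the beam, the
#' beam center and the pixel, the tilted detector line makes angle alpha with
#' the normal-incidence line, so by the law of cosines
#' \deqn{l = \sqrt{d^2 + r^2 + 2 d r \sin\alpha},}
#' which reduces to the Pythagorean `sqrt(d^2 + r^2)` for alpha = 0.
#'
#' @param polar A [pixel_polar_coordinates()] result.
#' @param dist A [distortion_angle()] result.
#' @param geom A [saxs_geometry()].
#' @return Per-pixel path length `l` in mm (same shape as `polar$r`).
#' @export
light_path <- function(polar, dist, geom) {
  d <- geom$detector_distance
  sqrt(d^2 + polar$r^2 + 2 * d * polar$r * sin(dist$alpha))
}

#' Scattering angle and scattering-vector magnitude
#'
#' Computes the per-pixel scattering angle `2*theta` and scattering-vector
#' magnitude `q`. With the distortion angle alpha,
#' \deqn{\tan 2\theta = \frac{r\cos\alpha}{d + r\sin\alpha}, \qquad
#'       q = \frac{4\pi}{\lambda}\sin\theta,}
#' reducing to `tan(2 theta) = r/d` for an untilted detector. `q` is reported
#' in inverse nanometres (`q[nm^-1] = 10 * q[A^-1]` for a wavelength in
#' Angstroem).
#'
#' @param polar A [pixel_polar_coordinates()] result.
#' @param dist A [distortion_angle()] result.
#' @param l Per-pixel light path from [light_path()], mm.
#' @param geom A [saxs_geometry()].
#' @param wavelength X-ray wavelength in Angstroem.
#' @return A list of class `saxs_qmap` with elements `r`, `psi`, `alpha`, `l`
#'   (mm), `two_theta` (radians) and `q` (nm^-1).
#' @export
scattering_vector <- function(polar, dist, l, geom, wavelength) {
  if (wavelength <= 0) stop("wavelength must be > 0")
  d <- geom$detector_distance
  two_theta <- atan2(polar$r * cos(dist$alpha), d + polar$r * sin(dist$alpha))
  q <- (4 * pi / wavelength) * sin(two_theta / 2) * 10
  structure(list(r = polar$r, psi = polar$psi, alpha = dist$alpha,
                 l = l, two_theta = two_theta, q = q),
            class = "saxs_qmap")
}

#' Per-pixel scattering-vector map
#'
#' Composes [pixel_polar_coordinates()], [distortion_angle()], [light_path()]
#' and [scattering_vector()] over the full sensor (or over supplied
#' fractional pixel coordinates, as used for subpixel oversampling). Results
#' for a full sensor are cached per calibration and reused across frames.
#'
#' @param geom A [saxs_geometry()].
#' @param wavelength X-ray wavelength in Angstroem.
#' @param row0,col0 Optional 0-based (fractional) pixel coordinates.
#' @return A `saxs_qmap` (see [scattering_vector()]).
#' @examples
#' geom <- saxs_geometry(c(128, 128), 1000, c(256, 256), c(172, 172))
#' qm <- build_qmap(geom, wavelength = 1.54)
#' range(qm$q)
#' @export
build_qmap <- function(geom, wavelength, row0 = NULL, col0 = NULL) {
  full <- is.null(row0) && is.null(col0)
  if (full) {
    key <- paste(c(unlist(geom), wavelength), collapse = "|")
    hit <- .qmap_cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  polar <- pixel_polar_coordinates(geom, row0, col0)
  dist <- distortion_angle(polar, geom)
  l <- light_path(polar, dist, geom)
  qm <- scattering_vector(polar, dist, l, geom, wavelength)
  if (full) .qmap_cache[[key]] <- qm
  qm
}

.qmap_cache <- new.env(parent = emptyenv())

#' @export
print.saxs_qmap <- function(x, ...) {
  cat("<saxs_qmap>\n")
  cat(sprintf("  pixels : %s\n", paste(dim(as.matrix(x$q)), collapse = " x ")))
  cat(sprintf("  q range: %.4f .. %.4f nm^-1\n", min(x$q), max(x$q)))
  invisible(x)
}
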