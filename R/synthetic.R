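#' Synthetic detector frames
#'
#' Generators for frames with known ground truth — flat fields, isotropic
#' analytic radial profiles (optionally Poisson-sampled) and sharp rings —
#' so the full reduction chain is testable without experimental data. All
#' generators are deterministic under a fixed seed.
#'
#' The default synthetic geometry ([default_geometry()]) is a 256 x 256
#' sensor with 172 um pixels (Pilatus-style), 1000 mm sample-to-detector
#' distance, Cu K-alpha wavelength 1.54 A and the beam center at pixel
#' (128, 128): small enough for sub-second tests, realistic in scale.
#'
#' @name synthetic-frames
NULL

#' @rdname synthetic-frames
#' @export
default_geometry <- function() {
  saxs_geometry(beamcenter = c(128, 128), detector_distance = 1000,
                image_size = c(256, 256), pixel_size = c(172, 172))
}

#' Flat frame
#'
#' @param shape Integer length-2 `(vertical, horizontal)`.
#' @param value Constant count value, `>= 0`.
#' @return A numeric matrix.
#' @export
make_flat_frame <- function(shape, value) {
  if (value < 0) stop("value must be >= 0")
  matrix(value, shape[1], shape[2])
}

#' Sphere form factor
#'
#' Normalized scattering intensity of a homogeneous sphere of radius `R`
#' (nm): `[3 (sin(qR) - qR cos(qR)) / (qR)^3]^2`, with the q -> 0 limit 1.
#'
#' @param q Scattering-vector magnitudes, nm^-1.
#' @param radius_nm Sphere radius in nm.
#' @return Intensities in `[0, 1]`.
#' @export
sphere_form_factor <- function(q, radius_nm) {
  x <- q * radius_nm
  out <- rep(1, length(x))
  nz <- x != 0
  out[nz] <- (3 * (sin(x[nz]) - x[nz] * cos(x[nz])) / x[nz]^3)^2
  dim(out) <- dim(q)
  out
}

#' Isotropic frame from an analytic radial profile
#'
#' Each pixel takes the value `profile(q(pixel))`, with `q` computed through
#' the geometry module, optionally followed by Poisson sampling under a
#' fixed seed.
#'
#' @param profile Function of `q` (nm^-1) returning non-negative intensities.
#' @param geom A [saxs_geometry()] (default [default_geometry()]).
#' @param wavelength Wavelength in Angstroem.
#' @param noise `"none"` or `"poisson"`.
#' @param seed Integer seed fixing the Poisson sampling.
#' @return A numeric count matrix.
#' @examples
#' fr <- make_isotropic_frame(function(q) 100 * sphere_form_factor(q, 5))
#' @export
make_isotropic_frame <- function(profile, geom = default_geometry(),
                                 wavelength = 1.54,
                                 noise = c("none", "poisson"), seed = 1L) {
  noise <- match.arg(noise)
  qm <- build_qmap(geom, wavelength)
  vals <- profile(qm$q)
  if (any(vals < 0)) stop("profile must be non-negative")
  frame <- matrix(vals, geom$image_size[1], geom$image_size[2])
  if (noise == "poisson")
    frame <- withr::with_seed(seed,
      matrix(rpois(length(frame), frame), nrow(frame), ncol(frame)))
  frame
}

#' Ring (annulus) frame
#'
#' Constant value inside an annulus of the given pixel radius and radial
#' width (measured from pixel centers, in pixel units), zero elsewhere.
#' A non-positive width yields an empty frame.
#'
#' @param shape Integer length-2 `(vertical, horizontal)`.
#' @param center Length-2 `(vertical, horizontal)` 0-based center, pixels.
#' @param radius_px Ring radius in pixels.
#' @param width_px Radial width in pixels.
#' @param value Count value inside the ring.
#' @return A numeric matrix.
#' @export
make_ring_frame <- function(shape, center, radius_px, width_px, value) {
  if (width_px <= 0) return(matrix(0, shape[1], shape[2]))
  row0 <- matrix(rep(0:(shape[1] - 1), shape[2]), shape[1], shape[2])
  col0 <- matrix(rep(0:(shape[2] - 1), each = shape[1]), shape[1], shape[2])
  r <- sqrt((row0 - center[1])^2 + (col0 - center[2])^2)
  ifelse(abs(r - radius_px) <= width_px / 2, value, 0)
}

#' Random mask plus its .msk file
#'
#' Builds the logical mask with exactly the given pixels excluded and writes
#' a bit-exact `.msk` file next to it — the round-trip oracle for the `.msk`
#' reader.
#'
#' @param shape Integer length-2 `(vertical, horizontal)`.
#' @param masked_pixels Two-column matrix of 0-based `(row, col)` indices, or
#'   `NULL` for an all-clear mask.
#' @param path Optional path of the `.msk` file to write.
#' @return The logical mask, with the written path (if any) as attribute
#'   `"path"`.
#' @export
make_mask <- function(shape, masked_pixels = NULL, path = NULL) {
  m <- matrix(FALSE, shape[1], shape[2])
  if (!is.null(masked_pixels) && nrow(masked_pixels) > 0)
    m[cbind(masked_pixels[, 1] + 1L, masked_pixels[, 2] + 1L)] <- TRUE
  if (!is.null(path)) {
    write_fit2d_mask(m, path)
    attr(m, "path") <- path
  }
  m
}

#' Brute-force reference integration
#'
#' The independent oracle for the sparse matrix-vector reduction at
#' `oversampling = 1`: an explicit per-pixel loop assigning each unmasked,
#' non-negative pixel to the bin containing its center q, then plain
#' averaging. No sparse algebra is involved.
#'
#' @param frame Numeric count matrix.
#' @param qmap Full-sensor [build_qmap()].
#' @param binning A [build_binning()].
#' @param mask Logical matrix or `NULL`.
#' @return A `saxs_curve` tibble (bins with zero area omitted).
#' @export
oracle_integrate <- function(frame, qmap, binning, mask = NULL) {
  n <- binning$n_bins
  sums <- numeric(n)
  counts <- numeric(n)
  nv <- nrow(frame); nh <- ncol(frame)
  for (i in seq_len(nv)) {
    for (j in seq_len(nh)) {
      if (!is.null(mask) && mask[i, j]) next
      v <- frame[i, j]
      if (v < 0) next
      q <- qmap$q[i, j]
      b <- findInterval(q, binning$q_edges, rightmost.closed = TRUE)
      if (b < 1 || b > n) next
      sums[b] <- sums[b] + v
      counts[b] <- counts[b] + 1
    }
  }
  ok <- counts > 0
  I <- sums[ok] / counts[ok]
  .new_curve(q = binning$q_centers[ok], I = I,
             E = poisson_errors(I, counts[ok]), A = counts[ok])
}

#' Generate a self-contained fixture set
#'
#' Writes a small synthetic measurement into a directory: TIFF frames of a
#' Poisson-noisy sphere-form-factor scatterer (with embedded acquisition
#' timestamps), an all-clear `.msk` mask and a matching calibration file.
#' Used by the command-line `make-fixtures` subcommand and by the pipeline
#' examples.
#'
#' @param dir Output directory (created if needed).
#' @param n_frames Number of frames.
#' @param geom A [saxs_geometry()].
#' @param wavelength Wavelength in Angstroem.
#' @param intensity Peak counts per pixel at q -> 0.
#' @param radius_nm Sphere radius, nm.
#' @param seed Integer seed.
#' @param dataset Data-set name used as the file-name prefix.
#' @return Invisibly, a list with the calibration path, frame paths and mask
#'   path.
#' @export
make_fixture_set <- function(dir, n_frames = 5, geom = default_geometry(),
                             wavelength = 1.54, intensity = 1000,
                             radius_nm = 5, seed = 1L, dataset = "sphere") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mask_path <- file.path(dir, "all_clear.msk")
  make_mask(geom$image_size, NULL, mask_path)
  frames <- character(n_frames)
  t0 <- as.POSIXct("2022-05-01 12:00:00", tz = "UTC")
  for (i in seq_len(n_frames)) {
    fr <- make_isotropic_frame(
      function(q) intensity * sphere_form_factor(q, radius_nm),
      geom, wavelength, noise = "poisson", seed = seed + i)
    frames[i] <- file.path(dir, sprintf("%s_%05d.tif", dataset, i))
    write_frame_tiff(fr, frames[i],
                     description = sprintf("acquired %s",
                       format(t0 + i, "%Y-%m-%dT%H:%M:%S")))
  }
  cal <- saxs_calibration(
    geometry = geom,
    masks = list(saxs_mask_spec(path_to_file = "all_clear.msk",
                                oversampling = 2L, pix_per_rad_element = 1,
                                q_start = 0.1, q_stop = 4)),
    wavelength = wavelength, directory = dir, threads = 1L)
  cal_path <- file.path(dir, "calibration.json")
  write_calibration(cal, cal_path)
  invisible(list(calibration = cal_path, frames = frames, mask = mask_path))
}
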