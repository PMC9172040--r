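#' Detector-coordinate q axis of a slice
#'
#' Maps pixel indices along a slice direction to the corresponding in-plane
#' scattering-vector component, deliberately in the detector coordinate
#' system: no Ewald-sphere distortion correction, no incidence-angle
#' correction and no detector tilt (the stated domain of validity of GISAXS
#' quick-look slices). For a signed in-detector displacement `x` from the
#' beam center along the axis, `q = sign(x) * (4 pi / lambda) *
#' sin(atan(|x| / d) / 2)`, in nm^-1 — identical to the radial `q` mapping
#' along the detector axes of an untilted geometry. Horizontal (`direction =
#' "x"`) slices are labelled `q_H` with rightward displacements positive;
#' vertical slices are labelled `q_V` with upward displacements positive.
#'
#' @param spec A [saxs_slice_spec()].
#' @param geom A [saxs_geometry()].
#' @param wavelength Wavelength in Angstroem.
#' @return Numeric vector of signed q values (nm^-1), one per pixel along the
#'   slice direction.
#' @export
slice_q_axis <- function(spec, geom, wavelength) {
  d <- geom$detector_distance
  if (spec$direction == "x") {
    idx0 <- seq_len(geom$image_size[2]) - 1
    x <- (idx0 - geom$beamcenter[2]) * geom$pixel_size[2] * 1e-3
  } else {
    idx0 <- seq_len(geom$image_size[1]) - 1
    x <- (geom$beamcenter[1] - idx0) * geom$pixel_size[1] * 1e-3  # up positive
  }
  sign(x) * (4 * pi / wavelength) * sin(atan(abs(x) / d) / 2) * 10
}

#' Extract a GISAXS line slice
#'
#' Averages a band of `2 * margin + 1` rows (for `direction = "x"`) or
#' columns (`direction = "y"`) centered on `position`, per point along the
#' slice. Masked pixels and negative sentinel counts never contribute; a
#' point whose band is fully masked is omitted rather than reported as zero.
#' Errors are the Poisson standard error `sqrt(I / A)` with `A` the number of
#' contributing pixels at that point.
#'
#' @param frame Numeric count matrix.
#' @param spec A [saxs_slice_spec()].
#' @param mask Logical matrix or `NULL`.
#' @param geom A [saxs_geometry()].
#' @param wavelength Wavelength in Angstroem.
#' @return A tibble of class `saxs_slice_curve` with columns `q`, `I`, `E`,
#'   `A`, and attributes `axis_label` (`"q_H"` or `"q_V"`),
#'   `thickness_pixels` and the slice spec.
#' @examples
#' geom <- saxs_geometry(c(32, 32), 500, c(64, 64), c(172, 172))
#' sl <- saxs_slice_spec("x", "InPlane", position = 10, margin = 1)
#' extract_slice(make_flat_frame(c(64, 64), 3), sl, NULL, geom, 1.54)
#' @export
extract_slice <- function(frame, spec, mask, geom, wavelength) {
  nv <- geom$image_size[1]; nh <- geom$image_size[2]
  if (nrow(frame) != nv || ncol(frame) != nh)
    stop("frame shape does not match calibration image size")
  band <- (spec$position - spec$margin):(spec$position + spec$margin)  # 0-based
  lim <- if (spec$direction == "x") nv else nh
  if (band[1] < 0 || band[length(band)] >= lim)
    stop("slice band (position +/- margin) outside image bounds")
  rows1 <- band + 1L
  sub <- if (spec$direction == "x") frame[rows1, , drop = FALSE]
         else t(frame[, rows1, drop = FALSE])
  msub <- if (is.null(mask)) {
    matrix(FALSE, nrow(sub), ncol(sub))
  } else if (spec$direction == "x") {
    mask[rows1, , drop = FALSE]
  } else {
    t(mask[, rows1, drop = FALSE])
  }
  use <- !msub & sub >= 0
  A <- colSums(use)
  S <- colSums(sub * use)
  qax <- slice_q_axis(spec, geom, wavelength)
  ok <- A > 0
  I <- S[ok] / A[ok]
  x <- tibble::tibble(q = qax[ok], I = I,
                      E = poisson_errors(I, A[ok]), A = A[ok])
  class(x) <- c("saxs_slice_curve", "saxs_curve", class(x))
  attr(x, "axis_label") <- if (spec$direction == "x") "q_H" else "q_V"
  attr(x, "thickness_pixels") <- 2L * spec$margin + 1L
  attr(x, "slice_spec") <- spec
  x
}

#' Write / read a slice curve
#'
#' Same three-column text layout as [write_chi()], with an extra header line
#' recording the slice's direction, plane, position and margin.
#'
#' @param curve A `saxs_slice_curve` from [extract_slice()].
#' @param path Output path.
#' @param source Optional source-image name for the header.
#' @return `path` invisibly; `read_slice_chi` returns the curve with the
#'   slice metadata re-attached.
#' @export
write_slice_chi <- function(curve, path, source = NULL) {
  spec <- attr(curve, "slice_spec")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    if (!is.null(source)) sprintf("# source: %s", source),
    sprintf("# slice: direction=%s plane=%s position=%d margin=%d",
            spec$direction, spec$plane, spec$position, spec$margin),
    sprintf("# axis: %s [nm^-1]  I [counts/pixel]  E  A [pixels]",
            attr(curve, "axis_label")),
    sprintf("# points: %d", nrow(curve)))
  writeLines(hdr, con, sep = "\n")
  if (nrow(curve))
    writeLines(sprintf("%.12e %.12e %.12e %.12e",
                       curve$q, curve$I, curve$E, curve$A), con, sep = "\n")
  invisible(path)
}

#' @rdname write_slice_chi
#' @export
read_slice_chi <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# slice:", lines, value = TRUE)
  curve <- read_chi(path)
  if (length(meta) == 1) {
    f <- function(key) sub(sprintf(".*%s=(\\S+).*", key), "\\1", meta)
    spec <- saxs_slice_spec(direction = f("direction"), plane = f("plane"),
                            position = as.integer(f("position")),
                            margin = as.integer(f("margin")))
    class(curve) <- c("saxs_slice_curve", class(curve))
    attr(curve, "slice_spec") <- spec
    attr(curve, "axis_label") <- if (spec$direction == "x") "q_H" else "q_V"
    attr(curve, "thickness_pixels") <- 2L * spec$margin + 1L
  }
  curve
}

#' @method autoplot saxs_slice_curve
#' @export
autoplot.saxs_slice_curve <- function(object, log = FALSE, ...) {
  df <- tidy(object)
  lab <- attr(object, "axis_label")
  p <- ggplot(df, aes(x = .data$q, y = .data$I)) +
    geom_ribbon(aes(ymin = .data$I - .data$E, ymax = .data$I + .data$E),
                alpha = 0.3) +
    geom_line() +
    labs(x = sprintf("%s (nm^-1)", lab), y = "I (counts / pixel)")
  if (log) p <- p + scale_y_log10()
  p
}
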