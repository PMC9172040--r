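#' Integration-mask specification
#'
#' One entry of the calibration's `masks` array: a pixel-mask file plus the
#' integration parameters tied to it.
#'
#' @param path_to_file Path to the mask file (FIT2D `.msk` or a single-channel
#'   TIFF/PNG image; `""` means no pixels masked).
#' @param oversampling Integer anti-aliasing factor `k >= 1`; each pixel is
#'   subdivided into `k x k` subpixels when the weighting matrix is built.
#' @param pix_per_rad_element Width of each radial step in units of detector
#'   pixels, `> 0`.
#' @param q_start,q_stop Window (nm^-1) over which the image classifiers are
#'   computed; `q_start < q_stop`.
#' @return An object of class `saxs_mask_spec`.
#' @export
saxs_mask_spec <- function(path_to_file = "", oversampling = 1L,
                           pix_per_rad_element = 1, q_start = 0,
                           q_stop = Inf) {
  if (oversampling < 1 || oversampling != round(oversampling))
    stop("oversampling must be an integer >= 1")
  if (pix_per_rad_element <= 0) stop("pix_per_rad_element must be > 0")
  if (!(q_start < q_stop)) stop("q_start must be < q_stop")
  structure(list(path_to_file = as.character(path_to_file),
                 oversampling = as.integer(oversampling),
                 pix_per_rad_element = as.numeric(pix_per_rad_element),
                 q_start = as.numeric(q_start),
                 q_stop = as.numeric(q_stop)),
            class = "saxs_mask_spec")
}

#' GISAXS slice specification
#'
#' One entry of the calibration's `slices` array. `direction = "x"` is a
#' horizontal cut (a band of rows averaged column-wise); `direction = "y"` is
#' a vertical cut. `position` indexes the coordinate perpendicular to the
#' slice direction (the row for an x slice, the column for a y slice),
#' 0-based. `plane` records whether the slice runs in-plane with the
#' scattering surface or perpendicular to it; it is orientation bookkeeping
#' only and never changes the numerics.
#'
#' @param direction `"x"` or `"y"`.
#' @param plane `"InPlane"` or `"Vertical"`.
#' @param position 0-based pixel index of the slice, perpendicular coordinate.
#' @param margin Number of pixels on each side of `position` to average;
#'   the band is `2 * margin + 1` pixels thick.
#' @param mask_reference 0-based index into the calibration's masks array.
#' @return An object of class `saxs_slice_spec`.
#' @export
saxs_slice_spec <- function(direction, plane = c("InPlane", "Vertical"),
                            position, margin = 0L, mask_reference = 0L) {
  direction <- match.arg(direction, c("x", "y"))
  plane <- match.arg(plane)
  if (margin < 0) stop("margin must be >= 0")
  if (mask_reference < 0) stop("mask_reference must be >= 0")
  structure(list(direction = direction, plane = plane,
                 position = as.integer(position), margin = as.integer(margin),
                 mask_reference = as.integer(mask_reference)),
            class = "saxs_slice_spec")
}

#' Full integration calibration
#'
#' The complete experiment description used by the reduction engine:
#' geometry, the list of integration masks, optional GISAXS slices, the X-ray
#' wavelength, the directories to watch and the worker count.
#'
#' @param geometry A [saxs_geometry()].
#' @param masks List of [saxs_mask_spec()] (at least one).
#' @param slices List of [saxs_slice_spec()] (may be empty).
#' @param wavelength X-ray wavelength in Angstroem, `> 0`.
#' @param directory Character vector of directories to watch for images.
#' @param threads Worker count, `>= 1`.
#' @param extra Named list of additional top-level calibration keys; they are
#'   preserved through [write_calibration()] but otherwise ignored.
#' @return An object of class `saxs_calibration`.
#' @examples
#' cal <- saxs_calibration(
#'   geometry = saxs_geometry(c(128, 128), 1000, c(256, 256), c(172, 172)),
#'   masks = list(saxs_mask_spec(q_start = 0.1, q_stop = 4)),
#'   wavelength = 1.54
#' )
#' cat(write_calibration(cal))
#' @export
saxs_calibration <- function(geometry, masks, slices = list(),
                             wavelength, directory = character(),
                             threads = 1L, extra = list()) {
  cal <- structure(list(geometry = geometry,
                        masks = masks,
                        slices = slices,
                        wavelength = as.numeric(wavelength),
                        directory = as.character(directory),
                        threads = as.integer(threads),
                        extra = extra),
                   class = "saxs_calibration")
  validate_calibration(cal)
}

#' Validate a calibration
#'
#' Checks all structural invariants of a [saxs_calibration()]: positive
#' geometry dimensions, `|tau| < 90` degrees, at least one mask with
#' `q_start < q_stop` and an integer oversampling factor, slice positions
#' inside the sensor, slice mask references pointing at existing masks,
#' positive wavelength and a worker count of at least one.
#'
#' @param cal A `saxs_calibration`.
#' @return `cal`, invisibly unchanged, if valid; otherwise an error naming
#'   the offending key.
#' @export
validate_calibration <- function(cal) {
  if (!inherits(cal$geometry, "saxs_geometry"))
    stop("calibration key 'geometry' is missing or invalid")
  if (length(cal$masks) < 1)
    stop("calibration key 'masks' must contain at least one mask")
  for (m in cal$masks) {
    if (!inherits(m, "saxs_mask_spec")) stop("invalid entry in 'masks'")
    if (!(m$q_start < m$q_stop)) stop("'q-start' must be < 'q-stop'")
    if (m$oversampling < 1) stop("'oversampling' must be >= 1")
    if (m$pix_per_rad_element <= 0) stop("'pix. p. rad. element' must be > 0")
  }
  nv <- cal$geometry$image_size[1]; nh <- cal$geometry$image_size[2]
  for (s in cal$slices) {
    if (!inherits(s, "saxs_slice_spec")) stop("invalid entry in 'slices'")
    lim <- if (s$direction == "x") nv else nh
    if (s$position < 0 || s$position >= lim)
      stop("slice 'position' outside image bounds")
    if (s$mask_reference < 0 || s$mask_reference >= length(cal$masks))
      stop("slice 'mask reference' does not point at an existing mask")
  }
  if (!is.finite(cal$wavelength) || cal$wavelength <= 0)
    stop("calibration key 'wavelength' must be > 0")
  if (is.na(cal$threads) || cal$threads < 1)
    stop("calibration key 'threads' must be >= 1")
  invisible(cal)
}

.need <- function(x, key, where = "calibration") {
  if (is.null(x[[key]]))
    stop(sprintf("missing mandatory %s key '%s'", where, key), call. = FALSE)
  x[[key]]
}

.known_top_keys <- c("geometry", "masks", "slices", "wavelength",
                     "directory", "threads")

#' Parse a calibration document
#'
#' Reads the JSON calibration format: a `geometry` object (`beamcenter`,
#' `detector distance`, `image size`, `pixel size`, `tilt`), a `masks` array,
#' an optional `slices` array, `wavelength`, `directory` and `threads`.
#' Units are those of the file format: mm, micrometres, Angstroem, nm^-1 and
#' degrees. Unknown top-level keys are preserved (see
#' [saxs_calibration()]'s `extra`) but ignored.
#'
#' @param text A JSON string (or anything [jsonlite::fromJSON()] accepts as
#'   literal JSON).
#' @return A validated [saxs_calibration()].
#' @seealso [read_calibration()] to read from a file, [write_calibration()]
#'   for the inverse.
#' @export
parse_calibration <- function(text) {
  doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  g <- .need(doc, "geometry")
  tilt <- g[["tilt"]]
  geom <- saxs_geometry(
    beamcenter = as.numeric(unlist(.need(g, "beamcenter", "geometry"))),
    detector_distance = as.numeric(.need(g, "detector distance", "geometry")),
    image_size = as.integer(unlist(.need(g, "image size", "geometry"))),
    pixel_size = as.numeric(unlist(.need(g, "pixel size", "geometry"))),
    tilt_rotation = if (is.null(tilt)) 0 else
      as.numeric(.need(tilt, "tilt rotation", "tilt")),
    tilt_angle = if (is.null(tilt)) 0 else
      as.numeric(.need(tilt, "tilt angle", "tilt"))
  )
  masks_doc <- .need(doc, "masks")
  masks <- lapply(masks_doc, function(m) {
    saxs_mask_spec(
      path_to_file = if (is.null(m[["path to file"]])) "" else
        as.character(m[["path to file"]]),
      oversampling = as.numeric(.need(m, "oversampling", "mask")),
      pix_per_rad_element = as.numeric(.need(m, "pix. p. rad. element", "mask")),
      q_start = as.numeric(.need(m, "q-start", "mask")),
      q_stop = as.numeric(.need(m, "q-stop", "mask"))
    )
  })
  slices <- lapply(doc[["slices"]], function(s) {
    saxs_slice_spec(
      direction = as.character(.need(s, "direction", "slice")),
      plane = as.character(.need(s, "plane", "slice")),
      position = as.integer(.need(s, "position", "slice")),
      margin = as.integer(.need(s, "margin", "slice")),
      mask_reference = as.integer(.need(s, "mask reference", "slice"))
    )
  })
  extra <- doc[setdiff(names(doc), .known_top_keys)]
  if (!length(extra)) extra <- list()
  saxs_calibration(
    geometry = geom, masks = masks, slices = slices,
    wavelength = as.numeric(.need(doc, "wavelength")),
    directory = as.character(unlist(doc[["directory"]])),
    threads = if (is.null(doc[["threads"]])) 1L else
      as.integer(doc[["threads"]]),
    extra = extra
  )
}

#' Read a calibration file
#'
#' @param path Path to a JSON calibration file.
#' @return A validated [saxs_calibration()].
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  parse_calibration(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

#' Serialize a calibration to JSON
#'
#' Inverse of [parse_calibration()]: `parse_calibration(write_calibration(x))`
#' reproduces `x` exactly, including mask order and any preserved extra keys.
#'
#' @param cal A [saxs_calibration()].
#' @param path Optional file path; when given the JSON is also written there.
#' @return The JSON document as a character scalar (invisibly when `path` is
#'   given).
#' @export
write_calibration <- function(cal, path = NULL) {
  validate_calibration(cal)
  g <- cal$geometry
  doc <- list(
    "geometry" = list(
      "beamcenter" = g$beamcenter,
      "detector distance" = jsonlite::unbox(g$detector_distance),
      "image size" = g$image_size,
      "pixel size" = g$pixel_size,
      "tilt" = list("tilt rotation" = jsonlite::unbox(g$tilt_rotation),
                    "tilt angle" = jsonlite::unbox(g$tilt_angle))
    ),
    "masks" = lapply(cal$masks, function(m) list(
      "path to file" = jsonlite::unbox(m$path_to_file),
      "oversampling" = jsonlite::unbox(m$oversampling),
      "pix. p. rad. element" = jsonlite::unbox(m$pix_per_rad_element),
      "q-start" = jsonlite::unbox(m$q_start),
      "q-stop" = jsonlite::unbox(m$q_stop)
    )),
    "slices" = lapply(cal$slices, function(s) list(
      "direction" = jsonlite::unbox(s$direction),
      "plane" = jsonlite::unbox(s$plane),
      "position" = jsonlite::unbox(s$position),
      "margin" = jsonlite::unbox(s$margin),
      "mask reference" = jsonlite::unbox(s$mask_reference)
    )),
    "wavelength" = jsonlite::unbox(cal$wavelength),
    "directory" = cal$directory,
    "threads" = jsonlite::unbox(cal$threads)
  )
  if (length(cal$extra)) doc <- c(doc, cal$extra)
  json <- jsonlite::toJSON(doc, digits = NA, pretty = TRUE, null = "null",
                           auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' @export
print.saxs_calibration <- function(x, ...) {
  cat("<saxs_calibration>\n")
  print(x$geometry)
  cat(sprintf("  wavelength  : %.4f A\n", x$wavelength))
  cat(sprintf("  masks       : %d\n", length(x$masks)))
  for (m in x$masks)
    cat(sprintf("    k=%d, step=%.2f px, q-window [%.3g, %.3g] nm^-1, file='%s'\n",
                m$oversampling, m$pix_per_rad_element, m$q_start, m$q_stop,
                m$path_to_file))
  cat(sprintf("  slices      : %d\n", length(x$slices)))
  cat(sprintf("  threads     : %d\n", x$threads))
  invisible(x)
}
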