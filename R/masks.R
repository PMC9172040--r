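#' Pixel masks
#'
#' A pixel mask is a logical matrix with the sensor's `(vertical, horizontal)`
#' shape in which `TRUE` marks a pixel EXCLUDED from integration (the FIT2D
#' convention: a set bit masks the pixel).
#'
#' The `.msk` binary layout implemented here is the de-facto FIT2D dialect:
#' a 1024-byte header beginning with the ASCII magic `"MASK"`, with the
#' horizontal (fast) and vertical (slow) dimensions stored as little-endian
#' 32-bit integers at byte offsets 16 and 20, followed by bit-packed rows.
#' Each row holds `ceil(nh / 8)` bytes padded to a multiple of 4 bytes, bits
#' least-significant-first within a byte, rows in storage order from the top
#' of the image.
#'
#' @name pixel-masks
NULL

.msk_row_bytes <- function(nh) 4L * ((ceiling(nh / 8) + 3L) %/% 4L)

#' Read a FIT2D .msk mask file
#'
#' @param path Path to the `.msk` file.
#' @param expected_shape Integer length-2 `(vertical, horizontal)`; the file's
#'   dimensions must match or an error is raised.
#' @return A logical `(vertical x horizontal)` matrix; `TRUE` = masked.
#' @seealso [write_fit2d_mask()], [pixel-masks] for the binary layout.
#' @export
read_fit2d_mask <- function(path, expected_shape) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 1024) stop("garbled .msk file (truncated header): ", path)
  if (rawToChar(raw[1:4]) != "MASK")
    stop("garbled .msk file (bad magic): ", path)
  nh <- readBin(raw[17:20], "integer", size = 4, endian = "little")
  nv <- readBin(raw[21:24], "integer", size = 4, endian = "little")
  if (nv != expected_shape[1] || nh != expected_shape[2])
    stop(sprintf("mask shape (%d, %d) does not match expected (%d, %d)",
                 nv, nh, expected_shape[1], expected_shape[2]))
  rb <- .msk_row_bytes(nh)
  need <- 1024L + nv * rb
  if (length(raw) < need) stop("garbled .msk file (truncated data): ", path)
  body <- raw[1025:need]
  # bit-unpack: rawToBits is LSB-first, matching the dialect
  bits <- as.integer(rawToBits(body))          # length nv * rb * 8
  bits <- matrix(bits, nrow = rb * 8L)          # one column per stored row
  grid <- t(bits[seq_len(nh), , drop = FALSE]) == 1L
  dim(grid) <- c(nv, nh)
  grid
}

#' Write a FIT2D .msk mask file
#'
#' Bit-exact writer for the dialect documented in [pixel-masks]; the
#' round-trip `read_fit2d_mask(write_fit2d_mask(m))` reproduces `m` exactly.
#'
#' @param mask Logical `(vertical x horizontal)` matrix; `TRUE` = masked.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit2d_mask <- function(mask, path) {
  nv <- nrow(mask); nh <- ncol(mask)
  header <- raw(1024)
  header[1:4] <- charToRaw("MASK")
  header[17:20] <- writeBin(as.integer(nh), raw(), size = 4, endian = "little")
  header[21:24] <- writeBin(as.integer(nv), raw(), size = 4, endian = "little")
  rb <- .msk_row_bytes(nh)
  bits <- matrix(0L, nrow = rb * 8L, ncol = nv)
  bits[seq_len(nh), ] <- t(ifelse(mask, 1L, 0L))
  body <- packBits(as.raw(bits), "raw")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, body), con)
  invisible(path)
}

#' Read a mask from an image file
#'
#' Convenience alternative to `.msk`: any nonzero pixel of a single-channel
#' TIFF or PNG image marks the pixel as masked. The numeric encoding (8- or
#' 16-bit) is irrelevant since only zero versus nonzero matters.
#'
#' @param path Path to a TIFF or PNG image.
#' @param expected_shape Integer length-2 `(vertical, horizontal)`.
#' @return A logical matrix; `TRUE` = masked.
#' @export
read_image_mask <- function(path, expected_shape) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    "tif" = , "tiff" = tiff::readTIFF(path),
    "png" = png::readPNG(path),
    stop("unsupported mask image format: ", ext)
  )
  if (length(dim(img)) == 3) img <- img[, , 1]
  if (nrow(img) != expected_shape[1] || ncol(img) != expected_shape[2])
    stop(sprintf("mask shape (%d, %d) does not match expected (%d, %d)",
                 nrow(img), ncol(img), expected_shape[1], expected_shape[2]))
  img != 0
}

#' Combine pixel masks
#'
#' Logical OR of exclusions: a pixel is masked if any input mask excludes it.
#' The operation is commutative, associative and idempotent.
#'
#' @param masks List of logical matrices of identical shape.
#' @return A single logical matrix.
#' @export
combine_masks <- function(masks) {
  if (length(masks) == 0) stop("no masks to combine")
  shp <- dim(masks[[1]])
  for (m in masks)
    if (!identical(dim(m), shp)) stop("mask shape mismatch in combine_masks")
  Reduce(`|`, masks)
}

#' Load and combine a mask-spec's pixel mask
#'
#' Resolves a [saxs_mask_spec()]'s `path_to_file` (dispatching on extension
#' between the `.msk` reader and the image reader) against a calibration's
#' image size. An empty path yields an all-clear mask.
#'
#' @param mask_spec A [saxs_mask_spec()].
#' @param geom A [saxs_geometry()].
#' @param base_dir Directory relative paths are resolved against.
#' @return A logical `(vertical x horizontal)` matrix.
#' @export
load_mask <- function(mask_spec, geom, base_dir = ".") {
  shape <- geom$image_size
  p <- mask_spec$path_to_file
  if (is.null(p) || !nzchar(p))
    return(matrix(FALSE, shape[1], shape[2]))
  if (!file.exists(p)) p <- file.path(base_dir, mask_spec$path_to_file)
  if (tolower(tools::file_ext(p)) == "msk")
    read_fit2d_mask(p, shape)
  else
    read_image_mask(p, shape)
}
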