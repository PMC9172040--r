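#' Detector-frame TIFF input/output
#'
#' Photon-counting detectors store frames as single-page uncompressed TIFF
#' with raw integer counts (32-bit on Pilatus-class detectors, with negative
#' sentinel values such as -1/-2 marking module gaps). These functions read
#' and write that layout directly, preserving counts exactly instead of
#' rescaling them to a display range.
#'
#' Supported on read: uncompressed, single-channel, 8/16/32-bit unsigned,
#' 32-bit signed and 32-bit float samples, little- or big-endian, one or more
#' strips. The writer emits little-endian single-strip files, 32-bit signed
#' integers for integer-valued frames and 32-bit floats otherwise, and can
#' embed an acquisition timestamp in the ImageDescription tag.
#'
#' @name frame-io
NULL

.tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)

.read_tiff_entry_values <- function(raw, entry_off, endian) {
  int <- function(off, size, signed = TRUE)
    readBin(raw[(off + 1):(off + size)], "integer", size = size,
            endian = endian, signed = signed)
  tag <- int(entry_off, 2, signed = FALSE)
  type <- int(entry_off + 2, 2, signed = FALSE)
  count <- int(entry_off + 4, 4)
  size <- .tiff_type_size[as.character(type)]
  if (is.na(size)) return(list(tag = tag, values = NULL))
  total <- size * count
  voff <- if (total <= 4) entry_off + 8 else int(entry_off + 8, 4)
  bytes <- raw[(voff + 1):(voff + total)]
  values <- if (type == 2) {
    rawToChar(bytes[bytes != as.raw(0)])
  } else if (size == 1) {
    as.integer(bytes)
  } else {
    readBin(bytes, "integer", n = count, size = size, endian = endian,
            signed = (size == 4))
  }
  list(tag = tag, values = values)
}

#' Read a detector frame from TIFF
#'
#' @param path Path to an uncompressed single-channel TIFF file.
#' @return A numeric `(vertical x horizontal)` matrix of counts, with the
#'   ImageDescription string (if present) attached as attribute
#'   `"description"`.
#' @export
read_frame_tiff <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) stop("not a TIFF file (truncated): ", path)
  order <- rawToChar(raw[1:2])
  endian <- switch(order, "II" = "little", "MM" = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path))
  int <- function(off, size, signed = TRUE)
    readBin(raw[(off + 1):(off + size)], "integer", size = size,
            endian = endian, signed = signed)
  if (int(2, 2, signed = FALSE) != 42L)
    stop("not a TIFF file (bad magic): ", path)
  ifd <- int(4, 4)
  n_entries <- int(ifd, 2, signed = FALSE)
  tags <- list()
  for (i in seq_len(n_entries)) {
    e <- .read_tiff_entry_values(raw, ifd + 2L + (i - 1L) * 12L, endian)
    tags[[as.character(e$tag)]] <- e$values
  }
  width <- tags[["256"]]; height <- tags[["257"]]
  if (is.null(width) || is.null(height))
    stop("TIFF missing image dimensions: ", path)
  bits <- if (is.null(tags[["258"]])) 1L else tags[["258"]][1]
  compression <- if (is.null(tags[["259"]])) 1L else tags[["259"]]
  if (compression != 1L)
    stop("only uncompressed TIFF frames are supported (compression tag ",
         compression, "): ", path)
  spp <- if (is.null(tags[["277"]])) 1L else tags[["277"]]
  if (spp != 1L) stop("only single-channel TIFF frames are supported: ", path)
  fmt <- if (is.null(tags[["339"]])) 1L else tags[["339"]][1]
  offsets <- tags[["273"]]; counts <- tags[["279"]]
  if (is.null(offsets)) stop("TIFF missing strip offsets: ", path)
  if (is.null(counts)) counts <- rep(width * height * bits / 8, length(offsets))
  data <- unlist(lapply(seq_along(offsets), function(i)
    raw[(offsets[i] + 1):(offsets[i] + counts[i])]))
  n <- width * height
  values <- if (fmt == 3L) {
    if (bits != 32L) stop("unsupported float bit depth: ", bits)
    readBin(data, "double", n = n, size = 4, endian = endian)
  } else if (bits == 32L) {
    v <- as.numeric(readBin(data, "integer", n = n, size = 4, endian = endian))
    if (fmt == 1L) v[v < 0] <- v[v < 0] + 2^32
    v
  } else if (bits %in% c(8L, 16L)) {
    as.numeric(readBin(data, "integer", n = n, size = bits / 8,
                       endian = endian, signed = (fmt == 2L)))
  } else stop("unsupported bit depth: ", bits)
  frame <- matrix(values, nrow = height, ncol = width, byrow = TRUE)
  if (!is.null(tags[["270"]])) attr(frame, "description") <- tags[["270"]]
  frame
}

.le2 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.le4 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.tiff_entry <- function(tag, type, count, value_raw) {
  stopifnot(length(value_raw) <= 4)
  c(.le2(tag), .le2(type), .le4(count),
    value_raw, raw(4 - length(value_raw)))
}

#' Write a detector frame to TIFF
#'
#' @param frame Numeric `(vertical x horizontal)` matrix of counts.
#' @param path Output path.
#' @param description Optional ImageDescription string (used to embed the
#'   acquisition timestamp, see [frame_acquisition_time()]).
#' @param format `"auto"` stores integer-valued frames as 32-bit signed
#'   integers and anything else as 32-bit floats; or force `"int32"` /
#'   `"float32"`.
#' @return `path`, invisibly.
#' @export
write_frame_tiff <- function(frame, path, description = NULL,
                             format = c("auto", "int32", "float32")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (all(is.finite(frame)) && all(frame == round(frame)) &&
                  all(abs(frame) < 2^31)) "int32" else "float32"
  nv <- nrow(frame); nh <- ncol(frame)
  pix <- as.vector(t(frame))  # TIFF is row-major
  data <- if (format == "int32") {
    writeBin(as.integer(pix), raw(), size = 4, endian = "little")
  } else {
    writeBin(as.numeric(pix), raw(), size = 4, endian = "little")
  }
  desc_raw <- if (!is.null(description))
    c(charToRaw(as.character(description)), as.raw(0)) else raw(0)
  tags <- list(
    list(256, 4, 1, .le4(nh)),
    list(257, 4, 1, .le4(nv)),
    list(258, 3, 1, .le2(32)),
    list(259, 3, 1, .le2(1)),
    list(262, 3, 1, .le2(1))
  )
  n_desc <- if (length(desc_raw)) 1L else 0L
  n_entries <- length(tags) + 5L + n_desc  # + offsets/spp/rows/counts/format [+ description]
  # layout: 8-byte header | IFD | external description | pixel data
  ifd_size <- 2L + n_entries * 12L + 4L
  desc_off <- 8L + ifd_size
  data_off <- desc_off + length(desc_raw)
  if (length(desc_raw)) {
    dval <- if (length(desc_raw) <= 4) desc_raw else .le4(desc_off)
    tags <- c(tags, list(list(270, 2, length(desc_raw), dval)))
  }
  tags <- c(tags, list(
    list(273, 4, 1, .le4(data_off)),
    list(277, 3, 1, .le2(1)),
    list(278, 4, 1, .le4(nv)),
    list(279, 4, 1, .le4(length(data)))
  ))
  tags <- c(tags, list(list(339, 3, 1, .le2(if (format == "int32") 2 else 3))))
  tags <- tags[order(vapply(tags, `[[`, numeric(1), 1))]
  ifd <- c(.le2(n_entries),
           unlist(lapply(tags, function(t)
             .tiff_entry(t[[1]], t[[2]], t[[3]], t[[4]]))),
           .le4(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), .le2(42), .le4(8), ifd, desc_raw, data), con)
  invisible(path)
}

#' Acquisition time of a frame
#'
#' Photon-counting detectors embed the acquisition timestamp in the TIFF
#' header comment; when present (any ISO-8601 `YYYY-MM-DD[ T]HH:MM:SS[.fff]`
#' substring of the ImageDescription tag) it is used, otherwise the file
#' modification time is returned.
#'
#' @param path Path to a frame file.
#' @return A `POSIXct` timestamp (UTC for embedded timestamps).
#' @export
frame_acquisition_time <- function(path) {
  desc <- tryCatch(attr(read_frame_tiff(path), "description"),
                   error = function(e) NULL)
  if (!is.null(desc)) {
    m <- regmatches(desc, regexpr(
      "\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}:\\d{2}(\\.\\d+)?", desc))
    if (length(m) == 1) {
      t <- as.POSIXct(sub("T", " ", m), tz = "UTC",
                      format = if (grepl("\\.", m)) "%Y-%m-%d %H:%M:%OS"
                               else "%Y-%m-%d %H:%M:%S")
      if (!is.na(t)) return(t)
    }
  }
  file.mtime(path)
}
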