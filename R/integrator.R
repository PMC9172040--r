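#' Radial binning
#'
#' Uniform bins in scattering-vector magnitude `q`, from zero to the largest
#' unmasked `q` on the sensor. The bin count is derived from the radial step
#' width in detector-pixel units: `n_bins = floor(r_max_px / step)` where
#' `r_max_px` is the largest unmasked pixel radius expressed in mean-pixel
#' units (the average of the vertical and horizontal pixel size defines the
#' pixel-radius unit for anisotropic pixels). At least one bin is always
#' produced.
#'
#' @param qmap A [build_qmap()] for the full sensor.
#' @param mask Logical matrix, `TRUE` = excluded; `NULL` for no mask.
#' @param pix_per_rad_element Radial step width in detector pixels, `> 0`.
#' @param geom The [saxs_geometry()] the qmap was built from (for the pixel
#'   size).
#' @return A list of class `saxs_binning` with `n_bins`, `q_edges`
#'   (length `n_bins + 1`, strictly increasing from 0) and `q_centers`.
#' @export
build_binning <- function(qmap, mask, pix_per_rad_element, geom) {
  if (pix_per_rad_element <= 0) stop("pix_per_rad_element must be > 0")
  keep <- if (is.null(mask)) TRUE else !mask
  if (!any(keep & TRUE) || (is.matrix(mask) && all(mask)))
    stop("fully masked frame: no unmasked pixels to bin")
  r_mm <- qmap$r[keep]
  q_sel <- qmap$q[keep]
  mean_pix_mm <- mean(geom$pixel_size) * 1e-3
  r_max_px <- max(r_mm) / mean_pix_mm
  n_bins <- max(1L, as.integer(floor(r_max_px / pix_per_rad_element)))
  q_max <- max(q_sel)
  if (q_max <= 0) stop("degenerate q range: all unmasked pixels at q = 0")
  edges <- seq(0, q_max, length.out = n_bins + 1L)
  structure(list(n_bins = n_bins, q_edges = edges,
                 q_centers = (edges[-1] + edges[-length(edges)]) / 2),
            class = "saxs_binning")
}

# Bin index (1..n_bins) for q values; 0 for out-of-range.
.bin_of <- function(q, binning) {
  idx <- findInterval(q, binning$q_edges, rightmost.closed = TRUE,
                      left.open = FALSE)
  idx[idx > binning$n_bins] <- 0L
  idx
}

#' Sparse pixel-to-bin weighting matrix
#'
#' Builds the `n_bins x n_pixels` sparse weighting matrix `C` whose
#' matrix-vector product with a flattened frame performs the azimuthal
#' integration, together with the per-bin effective area `A = C %*% 1`.
#'
#' Anti-aliasing works by oversampling: each unmasked pixel is split into
#' `k x k` equal subpixels, the `q` of every subpixel center is computed via
#' the geometry module, and each subpixel deposits weight `1/k^2` into its
#' containing bin. Pixels straddling a bin edge thus contribute fractionally
#' to both bins, and every unmasked pixel fully inside the binned range has
#' column sum exactly 1, so intensity is conserved by the averaging. Masked
#' pixels have structurally empty columns. Pixels are addressed column-major
#' (R's native vector order), i.e. `C %*% as.vector(frame)`.
#'
#' @param qmap Full-sensor [build_qmap()] (only used for its shape here; the
#'   subpixel `q` values are recomputed from `geom` and `wavelength`).
#' @param binning A [build_binning()].
#' @param mask Logical matrix or `NULL`.
#' @param oversampling Integer factor `k >= 1`; `k = 1` reproduces plain
#'   nearest-bin assignment of pixel centers.
#' @param geom The [saxs_geometry()].
#' @param wavelength Wavelength in Angstroem.
#' @return A list of class `saxs_weights`: `C` (a `dgCMatrix`), `A` (numeric
#'   length `n_bins`), plus the `binning`, `geom` and mask used.
#' @export
build_weight_matrix <- function(qmap, binning, mask, oversampling, geom,
                                wavelength) {
  k <- as.integer(oversampling)
  if (k < 1) stop("oversampling must be >= 1")
  nv <- geom$image_size[1]; nh <- geom$image_size[2]
  n_pix <- nv * nh
  keep_idx <- if (is.null(mask)) seq_len(n_pix) else which(!as.vector(mask))
  row0 <- (keep_idx - 1L) %% nv          # 0-based row
  col0 <- (keep_idx - 1L) %/% nv         # 0-based col
  offs <- (seq_len(k) - 0.5) / k - 0.5   # subpixel center offsets in [-.5,.5)
  ii <- integer(0); jj <- integer(0)
  parts <- vector("list", k * k)
  p <- 0L
  for (ov in offs) for (oh in offs) {
    p <- p + 1L
    qsub <- build_qmap(geom, wavelength, row0 = row0 + ov, col0 = col0 + oh)$q
    parts[[p]] <- .bin_of(qsub, binning)
  }
  bins <- unlist(parts)
  pix <- rep.int(keep_idx, k * k)
  in_range <- bins > 0L
  C <- Matrix::sparseMatrix(i = bins[in_range], j = pix[in_range],
                            x = 1 / k^2, dims = c(binning$n_bins, n_pix),
                            repr = "C")
  structure(list(C = C, A = bin_areas_raw(C), binning = binning,
                 geom = geom, wavelength = wavelength,
                 mask = mask, oversampling = k),
            class = "saxs_weights")
}

bin_areas_raw <- function(C) as.numeric(C %*% rep(1, ncol(C)))

#' Per-bin effective integration area
#'
#' `A_j = sum_i C_ji`: the matrix-vector product of the weighting matrix with
#' a unit vector, giving the number of (fractional) pixels contributing to
#' each radial element. Summed over bins it equals the number of unmasked
#' pixels inside the binned range.
#'
#' @param W A [build_weight_matrix()] result.
#' @return Numeric vector of length `n_bins`.
#' @export
bin_areas <- function(W) bin_areas_raw(W$C)

.new_curve <- function(q, I, E, A, extra_attrs = list()) {
  x <- tibble::tibble(q = q, I = I, E = E, A = A)
  class(x) <- c("saxs_curve", class(x))
  for (nm in names(extra_attrs)) attr(x, nm) <- extra_attrs[[nm]]
  x
}

#' Azimuthally integrate one frame
#'
#' Reduces a 2D count frame to a 1D curve: `I_j = (C p)_j / A_j` over bins
#' with positive area, with the Poisson standard error of the bin mean
#' `E_j = sqrt(I_j / A_j)`. Detector sentinel values (negative counts, e.g.
#' the -1/-2 gap markers of photon-counting modules) are excluded per frame
#' in addition to the static mask. Bins with zero effective area are omitted
#' from the output.
#'
#' @param frame Numeric `(vertical x horizontal)` matrix matching the
#'   calibration's image size.
#' @param W A [build_weight_matrix()] result.
#' @return A `saxs_curve` tibble with columns `q` (nm^-1, bin centers), `I`
#'   (mean counts per pixel), `E` (standard error of the mean) and `A`
#'   (effective bin area in pixels).
#' @examples
#' geom <- saxs_geometry(c(32, 32), 500, c(64, 64), c(172, 172))
#' qm <- build_qmap(geom, 1.54)
#' bn <- build_binning(qm, NULL, 1, geom)
#' W <- build_weight_matrix(qm, bn, NULL, 1, geom, 1.54)
#' integrate_frame(make_flat_frame(c(64, 64), 5), W)
#' @export
integrate_frame <- function(frame, W) {
  gsz <- W$geom$image_size
  if (nrow(frame) != gsz[1] || ncol(frame) != gsz[2])
    stop(sprintf("frame shape (%d, %d) does not match calibration (%d, %d)",
                 nrow(frame), ncol(frame), gsz[1], gsz[2]))
  if (!all(is.finite(frame))) stop("frame contains non-finite counts")
  p <- as.vector(frame)
  A <- W$A
  neg <- which(p < 0)
  if (length(neg)) {
    # per-frame sentinel exclusion: remove those pixels' weights from A too
    A <- A - as.numeric(W$C[, neg, drop = FALSE] %*% rep(1, length(neg)))
    p[neg] <- 0
  }
  S <- as.numeric(W$C %*% p)
  ok <- A > 0
  I <- S[ok] / A[ok]
  .new_curve(q = W$binning$q_centers[ok], I = I,
             E = poisson_errors(I, A[ok]), A = A[ok])
}

#' Poisson error of the bin mean
#'
#' The counting-statistics standard error of the azimuthal mean: a bin
#' averaging `A_j` independent Poisson pixels of mean `I_j` has variance
#' `I_j / A_j`, so `E_j = sqrt(I_j / A_j)`, computed elementwise from the
#' mean intensity and the integration area of each radial slice.
#'
#' @param I Per-bin mean intensities (counts per pixel).
#' @param A Per-bin effective areas (pixels), `> 0`.
#' @return Numeric vector of errors, `>= 0`.
#' @export
poisson_errors <- function(I, A) sqrt(pmax(I, 0) / A)

#' Write / read a reduced curve as a .chi file
#'
#' Plain-text three-column format: `#`-prefixed header lines, then one
#' `q I E` row per point (a fourth `A` column carries the bin area so the
#' round-trip is lossless). `read_chi(write_chi(x))` reproduces the curve to
#' float precision.
#'
#' @param curve A `saxs_curve` (from [integrate_frame()]).
#' @param path Output path.
#' @param source Optional source-image name recorded in the header.
#' @return `path` invisibly; `read_chi` returns a `saxs_curve`.
#' @export
write_chi <- function(curve, path, source = NULL) {
  con <- file(path, "wb")  # binary mode: byte-identical output across platforms
  on.exit(close(con))
  hdr <- c(
    if (!is.null(source)) sprintf("# source: %s", source),
    "# q [nm^-1]  I [counts/pixel]  E  A [pixels]",
    sprintf("# points: %d", nrow(curve)))
  writeLines(hdr, con, sep = "\n")
  if (nrow(curve))
    writeLines(sprintf("%.12e %.12e %.12e %.12e",
                       curve$q, curve$I, curve$E, curve$A), con, sep = "\n")
  invisible(path)
}

#' @rdname write_chi
#' @export
read_chi <- function(path) {
  lines <- readLines(path)
  data <- lines[!startsWith(lines, "#")]
  if (!length(data))
    return(.new_curve(numeric(0), numeric(0), numeric(0), numeric(0)))
  m <- do.call(rbind, lapply(strsplit(trimws(data), "\\s+"), as.numeric))
  A <- if (ncol(m) >= 4) m[, 4] else rep(NA_real_, nrow(m))
  .new_curve(q = m[, 1], I = m[, 2], E = m[, 3], A = A)
}

#' @export
print.saxs_curve <- function(x, ...) {
  cat(sprintf("<saxs_curve> %d points, q in [%.4g, %.4g] nm^-1\n",
              nrow(x), if (nrow(x)) min(x$q) else NA, if (nrow(x)) max(x$q) else NA))
  NextMethod()
}

#' Tidy a reduced curve
#'
#' `tidy()` returns the plain per-point tibble; `glance()` a one-row summary
#' (point count, q range, total and peak intensity).
#'
#' @param x A `saxs_curve`.
#' @param ... Unused.
#' @method tidy saxs_curve
#' @export
tidy.saxs_curve <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("q", "I", "E", "A")])
}

#' @rdname tidy.saxs_curve
#' @method glance saxs_curve
#' @export
glance.saxs_curve <- function(x, ...) {
  tibble::tibble(n_points = nrow(x),
                 q_min = if (nrow(x)) min(x$q) else NA_real_,
                 q_max = if (nrow(x)) max(x$q) else NA_real_,
                 total_counts = sum(x$I * x$A),
                 peak_I = if (nrow(x)) max(x$I) else NA_real_)
}

#' Plot a reduced curve
#'
#' Log-log intensity versus `q` with the Poisson error band.
#'
#' @param object A `saxs_curve`.
#' @param log Use log-log axes (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot saxs_curve
#' @export
autoplot.saxs_curve <- function(object, log = TRUE, ...) {
  df <- tidy(object)
  p <- ggplot(df, aes(x = .data$q, y = .data$I)) +
    geom_ribbon(aes(ymin = pmax(.data$I - .data$E, .Machine$double.xmin),
                    ymax = .data$I + .data$E), alpha = 0.3) +
    geom_line() +
    labs(x = expression(q ~ (nm^-1)), y = "I (counts / pixel)")
  if (log) p <- p + scale_x_log10() + scale_y_log10()
  p
}

#' @importFrom rlang .data
NULL
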