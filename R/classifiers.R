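#' Scalar image classifiers
#'
#' Quick-look integral parameters of a reduced curve, evaluated on the
#' configured q window `[q1, q2]` only (no extrapolation to q -> 0 or
#' q -> Inf): the integral intensity `int I dq`, the Porod invariant
#' `int q^2 I dq` and the correlation length `pi * int q I dq / int q^2 I dq`
#' (in nm). All integrals are trapezoidal over the curve points falling
#' inside the window; fewer than two in-window points, or a vanishing
#' invariant for the correlation length, yields `NA`.
#'
#' @param curve A `saxs_curve` (or anything with `q` and `I` columns).
#' @param q1,q2 Window bounds in nm^-1, `q1 < q2`.
#' @return A scalar; `NA_real_` when undefined.
#' @examples
#' curve <- tibble::tibble(q = seq(1, 2, length.out = 101), I = 2)
#' integral_intensity(curve, 1, 2)   # 2
#' porod_invariant(curve, 1, 2)      # 14/3
#' correlation_length(curve, 1, 2)   # 9*pi/14
#' @name classifiers
NULL

.window_points <- function(curve, q1, q2) {
  if (!(q1 < q2)) stop("q1 must be < q2")
  sel <- curve$q >= q1 & curve$q <= q2
  list(q = curve$q[sel], I = curve$I[sel], n = sum(sel))
}

#' @rdname classifiers
#' @export
integral_intensity <- function(curve, q1, q2) {
  w <- .window_points(curve, q1, q2)
  if (w$n < 2) return(NA_real_)
  pracma::trapz(w$q, w$I)
}

#' @rdname classifiers
#' @export
porod_invariant <- function(curve, q1, q2) {
  w <- .window_points(curve, q1, q2)
  if (w$n < 2) return(NA_real_)
  pracma::trapz(w$q, w$q^2 * w$I)
}

#' @rdname classifiers
#' @export
correlation_length <- function(curve, q1, q2) {
  w <- .window_points(curve, q1, q2)
  if (w$n < 2) return(NA_real_)
  inv <- pracma::trapz(w$q, w$q^2 * w$I)
  if (!is.finite(inv) || inv <= 0) return(NA_real_)
  pi * pracma::trapz(w$q, w$q * w$I) / inv
}

#' Compute all classifiers for one image
#'
#' Evaluates the three [classifiers] on the `[q_start, q_stop]` window of a
#' [saxs_mask_spec()] and packages them with the image identity and
#' acquisition time as a one-row record.
#'
#' @param curve A `saxs_curve`.
#' @param mask_spec A [saxs_mask_spec()] supplying the q window.
#' @param source Image identifier (typically the file name).
#' @param acquired_at Acquisition timestamp (`POSIXct`).
#' @return A one-row tibble of class `saxs_classifier_record` with columns
#'   `source`, `acquired_at`, `integral_intensity`, `invariant`,
#'   `correlation_length`.
#' @export
compute_classifiers <- function(curve, mask_spec, source = NA_character_,
                                acquired_at = Sys.time()) {
  rec <- tibble::tibble(
    source = as.character(source),
    acquired_at = as.POSIXct(acquired_at),
    integral_intensity = integral_intensity(curve, mask_spec$q_start,
                                            mask_spec$q_stop),
    invariant = porod_invariant(curve, mask_spec$q_start, mask_spec$q_stop),
    correlation_length = correlation_length(curve, mask_spec$q_start,
                                            mask_spec$q_stop)
  )
  class(rec) <- c("saxs_classifier_record", class(rec))
  rec
}

#' Classifier time history
#'
#' An append-only, time-sorted collection of classifier records, one per
#' processed image, supporting non-destructive queries by data set (the
#' file-name prefix before the trailing frame number, the serial-acquisition
#' naming convention at beamlines).
#'
#' @param records Optional list of `saxs_classifier_record` rows (or a tibble
#'   of them) to initialize from.
#' @return A tibble of class `saxs_history`, sorted by `acquired_at`.
#' @export
classifier_history <- function(records = NULL) {
  if (is.list(records) && !is.data.frame(records) && length(records) == 0)
    records <- NULL
  h <- if (is.null(records)) {
    tibble::tibble(source = character(), acquired_at = as.POSIXct(character()),
                   integral_intensity = numeric(), invariant = numeric(),
                   correlation_length = numeric())
  } else if (is.data.frame(records)) {
    tibble::as_tibble(records)
  } else {
    dplyr::bind_rows(records)
  }
  h <- dplyr::arrange(h, .data$acquired_at)
  class(h) <- unique(c("saxs_history", class(h)))
  h
}

#' @rdname classifier_history
#' @param history A `saxs_history`.
#' @param record A `saxs_classifier_record` (or several rows).
#' @export
history_add <- function(history, record) {
  classifier_history(dplyr::bind_rows(tibble::as_tibble(history),
                                      tibble::as_tibble(record)))
}

#' Data-set identifier of an image file
#'
#' The file-name prefix before the trailing frame number (extension and
#' any separating `_`/`-` stripped): `"lyso_00123.tif"` and
#' `"lyso_00124.tif"` belong to data set `"lyso"`.
#'
#' @param source Character vector of image names or paths.
#' @return Character vector of data-set identifiers.
#' @export
dataset_id <- function(source) {
  base <- tools::file_path_sans_ext(basename(source))
  sub("[._-]?[0-9]+$", "", base)
}

#' Query the classifier history
#'
#' Non-destructive, time-ordered subset of the history. With no selector the
#' full history is returned.
#'
#' @param history A `saxs_history`.
#' @param dataset Optional data-set identifier(s) to keep (matched via
#'   [dataset_id()] of each record's source).
#' @param filter Optional predicate taking the history tibble and returning
#'   a logical vector.
#' @return A `saxs_history` subset.
#' @export
query_history <- function(history, dataset = NULL, filter = NULL) {
  keep <- rep(TRUE, nrow(history))
  if (!is.null(dataset)) keep <- keep & dataset_id(history$source) %in% dataset
  if (!is.null(filter)) keep <- keep & filter(history)
  classifier_history(history[keep, , drop = FALSE])
}

#' Export / import a classifier history as delimited text
#'
#' Tab-separated, one row per record, ISO-8601 timestamps.
#'
#' @param history A `saxs_history`.
#' @param path Output path.
#' @return `path` invisibly; `read_history` returns a `saxs_history`.
#' @export
write_history <- function(history, path) {
  df <- tibble::as_tibble(history)
  df$acquired_at <- format(df$acquired_at, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_history
#' @export
read_history <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$acquired_at <- as.POSIXct(df$acquired_at, tz = "UTC",
                               format = "%Y-%m-%dT%H:%M:%OS")
  classifier_history(tibble::as_tibble(df))
}

#' Plot the classifier history
#'
#' The three classifiers against acquisition time, one panel each — the
#' quick-look monitor view of an ongoing measurement series.
#'
#' @param object A `saxs_history`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot saxs_history
#' @export
autoplot.saxs_history <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("integral_intensity", "invariant",
                              "correlation_length"),
                            names_to = "classifier", values_to = "value")
  ggplot(df, aes(x = .data$acquired_at, y = .data$value)) +
    geom_point() + geom_line(alpha = 0.5) +
    facet_wrap(~classifier, scales = "free_y", ncol = 1) +
    labs(x = "acquisition time", y = NULL)
}
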