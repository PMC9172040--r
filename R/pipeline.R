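#' Reduction engine state
#'
#' Everything derived from a calibration that is reused across frames: the
#' per-pixel q map, and for every integration mask the combined pixel mask,
#' the radial binning and the sparse weighting matrix. Built once per
#' calibration; rebuilding only happens when a new calibration is supplied
#' (the `"new"` queue command).
#'
#' @param cal A [saxs_calibration()].
#' @param base_dir Directory that relative mask paths are resolved against.
#' @return An object of class `saxs_engine`.
#' @export
saxs_engine <- function(cal, base_dir = ".") {
  validate_calibration(cal)
  geom <- cal$geometry
  qmap <- build_qmap(geom, cal$wavelength)
  units <- lapply(cal$masks, function(ms) {
    mask <- load_mask(ms, geom, base_dir)
    binning <- build_binning(qmap, mask, ms$pix_per_rad_element, geom)
    W <- build_weight_matrix(qmap, binning, mask, ms$oversampling, geom,
                             cal$wavelength)
    list(spec = ms, mask = mask, binning = binning, W = W)
  })
  structure(list(cal = cal, geom = geom, qmap = qmap, units = units),
            class = "saxs_engine")
}

#' Reduce one image file
#'
#' Reads a frame, integrates it once per calibration mask (writing
#' `<image>.chi`, and `<image>_m2.chi` etc. for further masks), extracts any
#' configured slices (`<image>_slice_<direction><position>.chi`) and returns
#' the classifier record computed from the first mask's curve on its
#' q window.
#'
#' @param engine A [saxs_engine()].
#' @param path Path to the image file (TIFF).
#' @param out_dir Output directory for `.chi` files.
#' @return A `saxs_classifier_record` (one row), invisibly.
#' @export
process_frame <- function(engine, path, out_dir = dirname(path)) {
  frame <- read_frame_tiff(path)
  base <- tools::file_path_sans_ext(basename(path))
  curves <- vector("list", length(engine$units))
  for (i in seq_along(engine$units)) {
    u <- engine$units[[i]]
    curves[[i]] <- integrate_frame(frame, u$W)
    suffix <- if (i == 1) "" else sprintf("_m%d", i)
    write_chi(curves[[i]], file.path(out_dir, paste0(base, suffix, ".chi")),
              source = basename(path))
  }
  for (s in engine$cal$slices) {
    u <- engine$units[[s$mask_reference + 1L]]
    sc <- extract_slice(frame, s, u$mask, engine$geom, engine$cal$wavelength)
    write_slice_chi(sc, file.path(out_dir, sprintf("%s_slice_%s%d.chi", base,
                                                   s$direction, s$position)),
                    source = basename(path))
  }
  rec <- compute_classifiers(curves[[1]], engine$units[[1]]$spec,
                             source = basename(path),
                             acquired_at = frame_acquisition_time(path))
  invisible(rec)
}

#' Picture queue
#'
#' The central register of images awaiting processing: FIFO with
#' per-path deduplication, completion/failure counters and an activity flag.
#' Events arriving on an inactive (aborted) queue are dropped with a logged
#' warning. Implemented as an environment so workers share state.
#'
#' @return An object of class `saxs_queue`.
#' @export
saxs_queue <- function() {
  q <- new.env(parent = emptyenv())
  q$pending <- character()
  q$seen <- new.env(parent = emptyenv())
  q$completed <- 0L
  q$failed <- 0L
  q$active <- TRUE
  q$log <- character()
  q$t_start <- Sys.time()
  class(q) <- "saxs_queue"
  q
}

queue_log <- function(queue, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"), msg)
  queue$log <- c(queue$log, line)
  if (isTRUE(getOption("saxsdr.verbose", FALSE))) message(line)
  invisible(line)
}

#' Recursively find unprocessed images
#'
#' The directory walker: a deterministic (lexicographically sorted) recursive
#' listing of image files under the given roots, minus those already known.
#'
#' @param roots Character vector of existing directories.
#' @param known Character vector of already-processed paths to exclude.
#' @param extensions File extensions treated as images.
#' @return Character vector of paths.
#' @export
directory_walk <- function(roots, known = character(),
                           extensions = c("tif", "tiff")) {
  for (r in roots) if (!dir.exists(r)) stop("missing root directory: ", r)
  files <- unlist(lapply(roots, list.files, recursive = TRUE,
                         full.names = TRUE))
  files <- files[tolower(tools::file_ext(files)) %in% extensions]
  files <- sort(unique(normalizePath(files)))
  setdiff(files, normalizePath(known, mustWork = FALSE))
}

#' File events
#'
#' A `"new file"` event is the two-field record `{command, argument}` that a
#' feeder publishes when an image has been completely written; the argument
#' is the image path on storage.
#'
#' @param path Path to the image file.
#' @return A list of class `saxs_file_event`.
#' @export
file_event <- function(path) {
  if (!nzchar(path)) stop("'new file' event requires a non-empty argument")
  structure(list(command = "new file", argument = as.character(path)),
            class = "saxs_file_event")
}

#' Enqueue a file event
#'
#' FIFO append with deduplication: a path already enqueued (pending or
#' processed) is ignored. Events on an inactive queue are dropped with a
#' logged warning.
#'
#' @param queue A [saxs_queue()].
#' @param event A [file_event()] (or a bare path).
#' @return The queue, invisibly.
#' @export
enqueue <- function(queue, event) {
  path <- if (inherits(event, "saxs_file_event")) event$argument else event
  if (!queue$active) {
    queue_log(queue, paste("dropped event on inactive queue:", path))
    return(invisible(queue))
  }
  if (!is.null(queue$seen[[path]])) return(invisible(queue))
  queue$seen[[path]] <- TRUE
  queue$pending <- c(queue$pending, path)
  invisible(queue)
}

#' Queue status
#'
#' @param queue A [saxs_queue()].
#' @return A one-row tibble: `pending`, `completed`, `failed`, `rate`
#'   (frames per second since the queue started) and `active`.
#' @export
queue_status <- function(queue) {
  dt <- as.numeric(difftime(Sys.time(), queue$t_start, units = "secs"))
  tibble::tibble(pending = length(queue$pending),
                 completed = queue$completed, failed = queue$failed,
                 rate = if (dt > 0) queue$completed / dt else NA_real_,
                 active = queue$active)
}

#' Process one queued image
#'
#' Takes the next image off the picture queue, integrates it and writes its
#' `.chi` outputs. Failures (unreadable or corrupt images) increment the
#' failure counter and are logged; they never stop the queue.
#'
#' @param queue A [saxs_queue()].
#' @param engine A [saxs_engine()].
#' @param out_dir Output directory.
#' @return The classifier record on success, `NULL` on failure or empty
#'   queue.
#' @export
worker_step <- function(queue, engine, out_dir) {
  if (!length(queue$pending)) return(invisible(NULL))
  path <- queue$pending[1]
  queue$pending <- queue$pending[-1]
  rec <- tryCatch(process_frame(engine, path, out_dir), error = function(e) {
    queue_log(queue, sprintf("FAILED %s: %s", path, conditionMessage(e)))
    NULL
  })
  if (is.null(rec)) {
    queue$failed <- queue$failed + 1L
  } else {
    queue$completed <- queue$completed + 1L
    queue_log(queue, paste("done", path))
  }
  invisible(rec)
}

# Drain all pending items with a worker pool of the given size. Frames are
# independent, so outputs do not depend on the worker count.
queue_drain <- function(queue, engine, out_dir, workers = 1L) {
  recs <- list()
  done <- character()
  while (length(queue$pending)) {
    batch <- queue$pending
    queue$pending <- character()
    res <- if (workers > 1L) {
      parallel::mclapply(batch, function(p)
        tryCatch(process_frame(engine, p, out_dir),
                 error = function(e) structure(conditionMessage(e),
                                               class = "saxs_fail")),
        mc.cores = workers)
    } else {
      lapply(batch, function(p)
        tryCatch(process_frame(engine, p, out_dir),
                 error = function(e) structure(conditionMessage(e),
                                               class = "saxs_fail")))
    }
    for (i in seq_along(res)) {
      if (inherits(res[[i]], "saxs_fail") || inherits(res[[i]], "try-error") ||
          is.null(res[[i]])) {
        queue$failed <- queue$failed + 1L
        queue_log(queue, sprintf("FAILED %s: %s", batch[i],
                                 as.character(res[[i]])))
      } else {
        queue$completed <- queue$completed + 1L
        recs <- c(recs, list(res[[i]]))
        done <- c(done, batch[i])
        queue_log(queue, paste("done", batch[i]))
      }
    }
  }
  list(records = recs, done = done)
}

.processed_file <- function(out_dir) file.path(out_dir, "processed.txt")

read_processed_set <- function(out_dir) {
  f <- .processed_file(out_dir)
  if (file.exists(f)) readLines(f) else character()
}

append_processed_set <- function(out_dir, paths) {
  if (length(paths)) cat(paths, file = .processed_file(out_dir), sep = "\n",
                         append = TRUE)
}

#' Run the offline (local-server) reduction
#'
#' The standalone mode: the directory walker fills the picture queue with
#' every image under the working directory, a worker pool drains it, and the
#' classifier history is written alongside the `.chi` files. Already
#' processed images (recorded in a `processed.txt` sidecar in the output
#' directory) are skipped unless `reintegrate = TRUE`.
#'
#' @param working_directory Root directory to walk for images.
#' @param cal A [saxs_calibration()] (its `threads` sets the worker count
#'   unless overridden).
#' @param out_dir Output directory (default: the working directory).
#' @param workers Worker-pool size; default `cal$threads`.
#' @param reintegrate Reprocess images already in the processed set.
#' @return A list with `status` (final [queue_status()] row), `history`
#'   (a `saxs_history`) and `queue`.
#' @export
run_local_server <- function(working_directory, cal,
                             out_dir = working_directory,
                             workers = cal$threads, reintegrate = FALSE) {
  if (!dir.exists(working_directory))
    stop("working directory does not exist: ", working_directory)
  validate_calibration(cal)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  engine <- saxs_engine(cal, base_dir = working_directory)
  queue <- saxs_queue()
  known <- if (reintegrate) character() else read_processed_set(out_dir)
  for (f in directory_walk(working_directory, known)) enqueue(queue, f)
  drained <- queue_drain(queue, engine, out_dir, workers)
  append_processed_set(out_dir, drained$done)
  history <- classifier_history(drained$records)
  write_history(history, file.path(out_dir, "history.tsv"))
  list(status = queue_status(queue), history = history, queue = queue)
}
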