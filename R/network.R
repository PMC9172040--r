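#' File-backed message spool
#'
#' The feeder/server transport: a publish-subscribe message queue realized as
#' a spool directory of JSON message files, written atomically (temp file +
#' rename) and consumed in publication order. Messages carry exactly the
#' two-field `"new file"` event contract `{command, argument}`; when a shared
#' secret is configured each message additionally carries a keyed digest of
#' its body (see [hmac_md5()]), and messages failing the check are rejected.
#'
#' @param dir Spool directory (created if needed).
#' @return An object of class `saxs_endpoint`.
#' @export
saxs_endpoint <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  structure(list(dir = normalizePath(dir)), class = "saxs_endpoint")
}

.spool_counter <- new.env(parent = emptyenv())

spool_write <- function(endpoint, payload, kind = "event") {
  n <- (.spool_counter[[endpoint$dir]] %||% 0L) + 1L
  .spool_counter[[endpoint$dir]] <- n
  name <- sprintf("%017.6f-%06d-%06d.%s", as.numeric(Sys.time()),
                  Sys.getpid() %% 1e6, n, kind)
  tmp <- tempfile(tmpdir = endpoint$dir, fileext = ".tmp")
  writeLines(payload, tmp)
  file.rename(tmp, file.path(endpoint$dir, name))
  invisible(name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

spool_take <- function(endpoint, kind = "event") {
  files <- sort(list.files(endpoint$dir, pattern = paste0("\\.", kind, "$"),
                           full.names = TRUE))
  msgs <- lapply(files, function(f) paste(readLines(f, warn = FALSE),
                                          collapse = "\n"))
  unlink(files)
  msgs
}

#' Keyed message digest
#'
#' HMAC-MD5 over a message body, built on the MD5 primitive available in
#' base R (`tools::md5sum`). Used to tag spool messages with a shared secret
#' so that a receiver can reject unauthenticated commands; it provides
#' integrity/authenticity tagging, not encryption.
#'
#' @param key Shared secret (character).
#' @param message Message body (character).
#' @return Lower-case hex digest (32 characters).
#' @export
hmac_md5 <- function(key, message) {
  md5_raw <- function(bytes) {
    f <- tempfile()
    on.exit(unlink(f))
    writeBin(bytes, f)
    hex <- unname(tools::md5sum(f))
    as.raw(strtoi(substring(hex, seq(1, 31, 2), seq(2, 32, 2)), 16L))
  }
  k <- charToRaw(key)
  if (length(k) > 64) k <- md5_raw(k)
  k <- c(k, raw(64 - length(k)))
  rawxor <- function(a, b) as.raw(bitwXor(as.integer(a), as.integer(b)))
  ipad <- as.raw(rep(0x36, 64)); opad <- as.raw(rep(0x5c, 64))
  inner <- md5_raw(c(rawxor(k, ipad), charToRaw(message)))
  paste(format(md5_raw(c(rawxor(k, opad), inner))), collapse = "")
}

encode_message <- function(body_list, secret = NULL) {
  body <- as.character(jsonlite::toJSON(body_list, auto_unbox = TRUE))
  if (is.null(secret)) return(body)
  as.character(jsonlite::toJSON(list(body = body,
                                     hmac = hmac_md5(secret, body)),
                                auto_unbox = TRUE))
}

decode_message <- function(text, secret = NULL) {
  doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  if (!is.null(secret)) {
    if (is.null(doc$body) || is.null(doc$hmac) ||
        !identical(hmac_md5(secret, doc$body), doc$hmac))
      stop("message failed authentication")
    doc <- jsonlite::fromJSON(doc$body, simplifyVector = FALSE)
  } else if (!is.null(doc$body) && !is.null(doc$hmac)) {
    doc <- jsonlite::fromJSON(doc$body, simplifyVector = FALSE)
  }
  doc
}

#' Publish a "new file" event
#'
#' The feeder side: once an image is completely written (its size is stable
#' across two polls) the event `{"command": "new file", "argument": path}` is
#' encoded to JSON and published on the endpoint. Publishing for a file that
#' is still growing is withheld until its size stabilizes.
#'
#' @param endpoint A [saxs_endpoint()].
#' @param image_path Path to the image on storage.
#' @param secret Optional shared secret; adds a keyed digest to the message.
#' @param stable_ms Interval (ms) between the two size polls.
#' @param max_wait_s Give up (with an error) if the file keeps changing for
#'   this long.
#' @return The published event, invisibly.
#' @export
feeder_publish <- function(endpoint, image_path, secret = NULL,
                           stable_ms = 100, max_wait_s = 10) {
  if (!file.exists(image_path)) stop("image does not exist: ", image_path)
  deadline <- Sys.time() + max_wait_s
  repeat {
    s1 <- file.size(image_path)
    Sys.sleep(stable_ms / 1000)
    s2 <- file.size(image_path)
    if (identical(s1, s2) && s1 > 0) break
    if (Sys.time() > deadline)
      stop("file size did not stabilize: ", image_path)
  }
  ev <- file_event(image_path)
  spool_write(endpoint, encode_message(unclass(ev), secret), "event")
  invisible(ev)
}

#' Send a queue command to a server
#'
#' The four control commands: `"new"` (carries a full calibration and
#' replaces the engine state), `"reintegrate"` (re-walks the watch
#' directories), `"abort"` (clears pending items and deactivates the queue)
#' and `"status"` (asks for a status report, written as a `.status` reply in
#' the control spool).
#'
#' @param control A [saxs_endpoint()].
#' @param command One of `"new"`, `"reintegrate"`, `"abort"`, `"status"`.
#' @param cal A [saxs_calibration()]; required for `"new"`.
#' @param secret Optional shared secret.
#' @return Invisibly, the spooled message name.
#' @export
server_command <- function(control, command = c("new", "reintegrate",
                                                "abort", "status"),
                           cal = NULL, secret = NULL) {
  command <- match.arg(command)
  body <- list(command = command)
  if (command == "new") {
    if (is.null(cal)) stop("'new' command requires a calibration")
    body$calibration <- jsonlite::fromJSON(write_calibration(cal),
                                           simplifyVector = FALSE)
  }
  invisible(spool_write(control, encode_message(body, secret), "cmd"))
}

#' Fetch status replies from the control spool
#'
#' @param control A [saxs_endpoint()].
#' @return A tibble of status rows (possibly empty).
#' @export
read_status_replies <- function(control) {
  msgs <- spool_take(control, "status")
  if (!length(msgs)) return(tibble::tibble())
  dplyr::bind_rows(lapply(msgs, function(m)
    tibble::as_tibble(jsonlite::fromJSON(m))))
}

#' Run the event-fed (remote-server) reduction
#'
#' The online mode: the server consumes `"new file"` events from the
#' subscription endpoint and queue commands from the control endpoint,
#' integrating frames as they are announced. The loop polls both spools; it
#' stops after `idle_polls` consecutive empty polls with an empty queue, or
#' after `max_polls` polls. Malformed or unauthenticated messages are
#' logged and skipped. Without an initial calibration the server idles until
#' a `"new"` command supplies one.
#'
#' @param subscribe A [saxs_endpoint()] events are received on.
#' @param control A [saxs_endpoint()] commands are received on.
#' @param cal Optional initial [saxs_calibration()].
#' @param out_dir Output directory for `.chi` files and the history.
#' @param secret Optional shared secret; when set, messages without a valid
#'   digest are rejected.
#' @param workers Worker-pool size; defaults to the calibration's `threads`.
#' @param idle_polls Stop after this many consecutive idle polls.
#' @param max_polls Hard poll limit.
#' @param poll_s Sleep between polls, seconds.
#' @return A list with `status`, `history` and `queue`, as
#'   [run_local_server()].
#' @export
run_remote_server <- function(subscribe, control, cal = NULL, out_dir,
                              secret = NULL, workers = NULL,
                              idle_polls = 3L, max_polls = 1000L,
                              poll_s = 0.02) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cal_base <- function(cal) if (length(cal$directory)) cal$directory[1] else out_dir
  engine <- if (!is.null(cal)) saxs_engine(cal, base_dir = cal_base(cal))
  queue <- saxs_queue()
  recs <- list()
  idle <- 0L
  polls <- 0L
  while (polls < max_polls && idle < idle_polls) {
    polls <- polls + 1L
    busy <- FALSE
    for (m in spool_take(control, "cmd")) {
      busy <- TRUE
      doc <- tryCatch(decode_message(m, secret), error = function(e) {
        queue_log(queue, paste("rejected command:", conditionMessage(e)))
        NULL
      })
      if (is.null(doc)) next
      cmd <- doc$command %||% ""
      if (cmd == "new") {
        newcal <- tryCatch(
          parse_calibration(jsonlite::toJSON(doc$calibration,
                                             auto_unbox = TRUE)),
          error = function(e) NULL)
        if (is.null(newcal)) {
          queue_log(queue, "malformed 'new' command: bad calibration")
        } else {
          engine <- saxs_engine(newcal, base_dir = cal_base(newcal))
          queue$active <- TRUE
          queue_log(queue, "engine state replaced by 'new' calibration")
        }
      } else if (cmd == "reintegrate") {
        if (!is.null(engine))
          for (f in directory_walk(engine$cal$directory)) enqueue(queue, f)
        queue_log(queue, "reintegrate: directory walker refilled the queue")
      } else if (cmd == "abort") {
        queue$pending <- character()
        queue$active <- FALSE
        queue_log(queue, "abort: queue cleared and deactivated")
      } else if (cmd == "status") {
        st <- queue_status(queue)
        spool_write(control, as.character(jsonlite::toJSON(st)), "status")
      } else {
        queue_log(queue, paste("unknown command skipped:", cmd))
      }
    }
    for (m in spool_take(subscribe, "event")) {
      busy <- TRUE
      doc <- tryCatch(decode_message(m, secret), error = function(e) {
        queue_log(queue, paste("rejected event:", conditionMessage(e)))
        NULL
      })
      if (is.null(doc)) next
      if (!identical(doc$command, "new file") || is.null(doc$argument) ||
          !nzchar(doc$argument)) {
        queue_log(queue, "malformed event skipped")
        next
      }
      enqueue(queue, file_event(doc$argument))
    }
    if (!is.null(engine) && length(queue$pending)) {
      busy <- TRUE
      drained <- queue_drain(queue, engine, out_dir,
                             workers %||% engine$cal$threads)
      recs <- c(recs, drained$records)
    }
    if (busy) idle <- 0L else {
      idle <- idle + 1L
      Sys.sleep(poll_s)
    }
  }
  history <- classifier_history(recs)
  write_history(history, file.path(out_dir, "history.tsv"))
  list(status = queue_status(queue), history = history, queue = queue)
}

#' Read the network configuration file
#'
#' Plain `key=value` lines (comments with `#`), conventionally at
#' `~/.saxsdognetwork`, listing the feeder and server addresses and the
#' optional shared secret.
#'
#' @param path Path to the configuration file.
#' @return Named list of configuration values.
#' @export
read_network_config <- function(path = "~/.saxsdognetwork") {
  if (!file.exists(path)) stop("network configuration not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(x) trimws(paste(x[-1], collapse = "="))),
                  trimws(vapply(kv, `[[`, "", 1)))
}
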