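# The append-only JSONL event log is the system's persistence and analytics
# substrate: one event per line, UTF-8, ISO-8601 timestamps with zone offset.
# Audio content is never stored by the core -- only a descriptor and the
# duration in seconds (privacy by minimization).

EVENT_DIRECTIONS <- c("inbound", "outbound", "system")
EVENT_KINDS <- c("text", "audio", "state_transition", "snooze",
                 "expiry_notice", "acknowledgment")

#' Construct one event record
#'
#' @param ts Numeric timestamp (seconds; interpreted as UTC wall time).
#' @param participant_id Opaque participant identifier.
#' @param direction `"inbound"`, `"outbound"` or `"system"`.
#' @param kind One of `r paste0('\x60', EVENT_KINDS, '\x60', collapse = ", ")`.
#' @param body Text content or audio descriptor.
#' @param audio_duration Seconds of audio (required iff `kind == "audio"`).
#' @param day_index Protocol day 0..14, or `NA` for unprompted events.
#' @param excluded Day-0 exclusion flag.
#' @return A one-row `data.frame`.
#' @export
event_record <- function(ts, participant_id, direction, kind, body = "",
                         audio_duration = NA_real_, day_index = NA_integer_,
                         excluded = FALSE) {
  stopifnot(direction %in% EVENT_DIRECTIONS, kind %in% EVENT_KINDS)
  if (kind == "audio" && (is.na(audio_duration) || audio_duration <= 0))
    stop("audio events require a positive audio_duration", call. = FALSE)
  data.frame(ts = as.numeric(ts), participant_id = participant_id,
             direction = direction, kind = kind, body = body,
             audio_duration = as.numeric(audio_duration),
             day_index = as.integer(day_index), excluded = excluded,
             stringsAsFactors = FALSE)
}

# Internal growing accumulator (parallel column vectors in a closure frame,
# doubling growth). Columns are touched only through in-frame superassignment
# so subassignment stays in place; avoids quadratic copying in long runs.
new_event_acc <- function(size = 1024L) {
  n <- 0L
  cap <- size
  c_ts <- numeric(size)
  c_pid <- character(size)
  c_dir <- character(size)
  c_kind <- character(size)
  c_body <- character(size)
  c_dur <- numeric(size)
  c_day <- integer(size)
  c_excl <- logical(size)
  acc <- environment()
  acc$add <- function(ts, pid, direction, kind, body, audio_duration,
                      day_index, excluded) {
    m <- n + 1L
    if (m > cap) {
      cap <<- cap * 2L
      length(c_ts) <<- cap; length(c_pid) <<- cap
      length(c_dir) <<- cap; length(c_kind) <<- cap
      length(c_body) <<- cap; length(c_dur) <<- cap
      length(c_day) <<- cap; length(c_excl) <<- cap
    }
    c_ts[m] <<- ts; c_pid[m] <<- pid; c_dir[m] <<- direction
    c_kind[m] <<- kind; c_body[m] <<- body; c_dur[m] <<- audio_duration
    c_day[m] <<- day_index; c_excl[m] <<- excluded
    n <<- m
  }
  acc
}

acc_add <- function(acc, ts, pid, direction, kind, body = "",
                    audio_duration = NA_real_, day_index = NA_integer_,
                    excluded = FALSE) {
  acc$add(ts, pid, direction, kind, body, audio_duration,
          as.integer(day_index), excluded)
  invisible(acc)
}

acc_events <- function(acc) {
  if (acc$n == 0L) return(empty_events())
  i <- seq_len(acc$n)
  data.frame(ts = acc$c_ts[i], participant_id = acc$c_pid[i],
             direction = acc$c_dir[i], kind = acc$c_kind[i],
             body = acc$c_body[i], audio_duration = acc$c_dur[i],
             day_index = as.integer(acc$c_day[i]),
             excluded = as.logical(acc$c_excl[i]),
             stringsAsFactors = FALSE)
}

empty_events <- function() {
  event_record(0, "x", "system", "text")[0L, ]
}

#' @noRd
event_to_json <- function(row) {
  x <- list(timestamp = format_ts(row$ts),
            participant_id = row$participant_id,
            direction = row$direction,
            kind = row$kind,
            body = row$body)
  if (!is.na(row$audio_duration)) x$audio_duration <- round(row$audio_duration, 1)
  if (!is.na(row$day_index)) x$day_index <- row$day_index
  x$excluded <- row$excluded
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
}

#' Write / append / read a JSONL event log
#'
#' `write_event_log()` serializes a whole event table; `append_event()` adds
#' one event to an existing log; `read_event_log()` parses and validates,
#' reporting the line number and field of any malformed record. The
#' write-read round trip is lossless.
#'
#' @param events An event `data.frame` (as produced by the engine, simulator
#'   or [event_record()]).
#' @param path Log file path.
#' @return `read_event_log()` returns the event `data.frame`, time-ordered
#'   per participant.
#' @export
write_event_log <- function(events, path) {
  lines <- vapply(seq_len(nrow(events)),
                  function(i) event_to_json(events[i, ]), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_event_log
#' @param event A one-row event `data.frame`.
#' @export
append_event <- function(path, event) {
  stopifnot(nrow(event) == 1L)
  cat(event_to_json(event[1, ]), "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stop("event log not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_events())
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    x <- tryCatch(jsonlite::fromJSON(lines[i]),
                  error = function(e) stop("malformed JSON at line ", i, ": ",
                                           conditionMessage(e), call. = FALSE))
    for (f in c("timestamp", "participant_id", "direction", "kind")) {
      if (is.null(x[[f]]))
        stop("event at line ", i, " is missing field '", f, "'", call. = FALSE)
    }
    if (!x$direction %in% EVENT_DIRECTIONS)
      stop("invalid direction at line ", i, ": ", x$direction, call. = FALSE)
    if (!x$kind %in% EVENT_KINDS)
      stop("invalid kind at line ", i, ": ", x$kind, call. = FALSE)
    if (x$kind == "audio" &&
        (is.null(x$audio_duration) || x$audio_duration <= 0))
      stop("audio event at line ", i, " lacks a positive audio_duration",
           call. = FALSE)
    rows[[i]] <- list(
      ts = parse_ts(x$timestamp),
      participant_id = x$participant_id,
      direction = x$direction,
      kind = x$kind,
      body = if (is.null(x$body)) "" else x$body,
      audio_duration = if (is.null(x$audio_duration)) NA_real_ else as.numeric(x$audio_duration),
      day_index = if (is.null(x$day_index)) NA_integer_ else as.integer(x$day_index),
      excluded = isTRUE(x$excluded))
  }
  out <- data.table::rbindlist(rows)
  data.table::setDF(out)
  ord <- order(out$participant_id, out$ts)
  if (is.unsorted(ord)) out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mock message transport
#'
#' The transport contract is minimal: `deliver(body, participant_id, delay)`
#' returns a receipt and the transport preserves per-participant order. The
#' mock records every delivery for inspection; `fail_next()` arms a one-shot
#' delivery failure to exercise the engine's error path (delivery failures
#' are logged as system events and are retriable -- the engine state is never
#' advanced on failure).
#'
#' @return An environment with `deliver`, `fail_next`, and `sent` (a list of
#'   delivered messages in order).
#' @export
mock_transport <- function() {
  self <- new.env(parent = emptyenv())
  self$sent <- list()
  self$fail_armed <- FALSE
  self$fail_next <- function() self$fail_armed <- TRUE
  self$deliver <- function(body, participant_id, delay = 0) {
    if (self$fail_armed) {
      self$fail_armed <- FALSE
      stop("transport adapter failure", call. = FALSE)
    }
    self$sent[[length(self$sent) + 1L]] <-
      list(body = body, participant_id = participant_id, delay = delay)
    list(ok = TRUE, seq = length(self$sent))
  }
  class(self) <- "ema_transport"
  self
}

#' Deliver a message through a transport, logging failures as system events
#'
#' @param transport A transport (see [mock_transport()]).
#' @param event A one-row outbound event.
#' @param acc Optional internal event accumulator for the failure log.
#' @return `TRUE` on delivery, `FALSE` on a (retriable) adapter failure.
#' @export
deliver <- function(transport, event, acc = NULL) {
  ok <- tryCatch({
    transport$deliver(event$body, event$participant_id, 0)
    TRUE
  }, error = function(e) {
    if (!is.null(acc))
      acc_add(acc, event$ts, event$participant_id, "system", "text",
              body = paste("delivery failure:", conditionMessage(e)),
              day_index = event$day_index)
    FALSE
  })
  ok
}
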