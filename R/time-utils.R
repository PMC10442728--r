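# Internal wall-clock helpers. All protocol times are local wall times in a
# single deployment time zone; internally the virtual clock is numeric seconds
# since the epoch, interpreted in UTC so that arithmetic is DST-free.

.hm_cache <- new.env(parent = emptyenv())

#' Parse an "HH:MM" wall time to seconds after midnight (memoized)
#' @noRd
hm_to_sec <- function(hm) {
  hit <- .hm_cache[[hm]]
  if (!is.null(hit)) return(hit)
  m <- regmatches(hm, regexec("^([0-9]{1,2}):([0-9]{2})$", hm))[[1]]
  if (length(m) != 3L) stop("invalid time of day: '", hm, "' (expected HH:MM)", call. = FALSE)
  h <- as.integer(m[2]); mi <- as.integer(m[3])
  if (h > 23L || mi > 59L) stop("invalid time of day: '", hm, "'", call. = FALSE)
  .hm_cache[[hm]] <- h * 3600 + mi * 60
}

#' Numeric timestamp for a calendar date at a wall time (UTC-interpreted,
#' so midnight is exactly days-since-epoch * 86400)
#' @noRd
at_time <- function(date, hm) {
  as.numeric(as.Date(date)) * 86400 + hm_to_sec(hm)
}

#' Midnight of the calendar day containing a numeric timestamp
#' @noRd
ts_date <- function(ts) {
  as.Date(as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"))
}

#' Seconds after midnight of a numeric timestamp
#' @noRd
ts_tod <- function(ts) {
  ts - as.numeric(as.POSIXct(ts_date(ts), tz = "UTC"))
}

#' Format a numeric timestamp as ISO-8601 with explicit zone offset
#' @noRd
format_ts <- function(ts) {
  format(as.POSIXct(round(ts), origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%S+00:00")
}

#' Parse an ISO-8601 timestamp (as written by [format_ts()]) to numeric seconds
#' @noRd
parse_ts <- function(x) {
  out <- as.numeric(as.POSIXct(sub("\\+00:00$", "", x), tz = "UTC",
                               format = "%Y-%m-%dT%H:%M:%S"))
  if (anyNA(out)) stop("unparseable timestamp: ", x[which(is.na(out))[1]], call. = FALSE)
  out
}

#' Round half up to a fixed number of decimals (the reporting convention)
#' @noRd
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
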