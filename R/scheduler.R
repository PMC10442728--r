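# Virtual-clock timer service for one daily cycle. The engine never consults
# the system clock: `now` is injected (numeric seconds, UTC-interpreted wall
# time), so a whole 15-day protocol can run deterministically in test time.

CYCLE_STATUSES <- c("PENDING", "PROMPTED", "SNOOZED", "IN_PROGRESS",
                    "COMPLETED", "EXPIRED")

# Directed transition graph of the cycle state machine.
CYCLE_TRANSITIONS <- list(
  PENDING     = c("PROMPTED"),
  PROMPTED    = c("PROMPTED", "SNOOZED", "IN_PROGRESS", "EXPIRED"),
  SNOOZED     = c("PROMPTED", "IN_PROGRESS", "EXPIRED"),
  IN_PROGRESS = c("IN_PROGRESS", "SNOOZED", "COMPLETED", "EXPIRED"),
  COMPLETED   = character(0),
  EXPIRED     = character(0)
)

#' Create the clock state for one daily cycle
#'
#' @param cycle_date Calendar date on which the cycle opens (its first prompt
#'   fires on this date; the response window extends into the next morning).
#' @return A `cycle_clock` list: `cycle_date`, `status`, `prompts_sent`,
#'   `snoozed_until`, `last_prompt_at`.
#' @export
cycle_clock <- function(cycle_date) {
  structure(list(cycle_date = as.Date(cycle_date), status = "PENDING",
                 prompts_sent = 0L, snoozed_until = NULL,
                 last_prompt_at = NULL),
            class = "cycle_clock")
}

#' @noRd
clock_transition <- function(clock, to) {
  if (!to %in% CYCLE_TRANSITIONS[[clock$status]])
    stop("illegal cycle transition ", clock$status, " -> ", to, call. = FALSE)
  clock$status <- to
  clock
}

#' Next timer event for a daily cycle
#'
#' Decides what the scheduler fires next for a cycle and when: the first
#' prompt at the configured daily time, reminders at the configured interval
#' while a prompt is unanswered (never after the response window closes), the
#' snooze wake-up prompt, or the expiry notice the next morning when the
#' window closed without completion.
#'
#' @param state A [cycle_clock()] state.
#' @param config An [protocol_config()].
#' @param now Current virtual time (numeric seconds).
#' @return A list `(kind, at)` with `kind` one of `FIRST_PROMPT`, `REMINDER`,
#'   `SNOOZE_PROMPT`, `EXPIRY_NOTICE`, or `NULL` when the cycle is terminal or
#'   past its expiry notice (the no-event signal).
#' @export
next_event <- function(state, config, now) {
  if (state$status %in% c("COMPLETED", "EXPIRED")) return(NULL)
  next_day <- state$cycle_date + 1L
  window_end <- at_time(next_day, config$response_window_end)
  expiry_at <- at_time(next_day, config$expiry_notice_time)
  if (now >= expiry_at) return(NULL)
  switch(state$status,
    PENDING = list(kind = "FIRST_PROMPT",
                   at = at_time(state$cycle_date, config$first_prompt_time)),
    SNOOZED = list(kind = "SNOOZE_PROMPT", at = state$snoozed_until),
    PROMPTED = {
      t <- state$last_prompt_at + config$reminder_interval * 60
      if (t < window_end) list(kind = "REMINDER", at = t)
      else list(kind = "EXPIRY_NOTICE", at = expiry_at)
    },
    IN_PROGRESS = list(kind = "EXPIRY_NOTICE", at = expiry_at)
  )
}

#' Apply a snooze request to a cycle
#'
#' Accepts a requested wake-up time, clamping it to the allowed interval
#' `(now, next day at the snooze limit]`. A request in the past is rejected
#' (the caller re-prompts) rather than clamped forward.
#'
#' @param state A [cycle_clock()] state with status `PROMPTED` or
#'   `IN_PROGRESS`.
#' @param requested_time Requested wake-up time (numeric seconds).
#' @param config An [protocol_config()].
#' @param now Current virtual time.
#' @return A list with `state` (updated), `accepted` (logical) and, when
#'   accepted, `snoozed_until` (possibly clamped).
#' @export
apply_snooze <- function(state, requested_time, config, now) {
  if (!state$status %in% c("PROMPTED", "IN_PROGRESS"))
    stop("snooze applies only to a prompted or in-progress cycle", call. = FALSE)
  if (requested_time <= now)
    return(list(state = state, accepted = FALSE,
                reason = "requested time is in the past"))
  limit <- at_time(state$cycle_date + 1L, config$snooze_limit_time)
  su <- min(requested_time, limit)
  state <- clock_transition(state, "SNOOZED")
  state$snoozed_until <- su
  list(state = state, accepted = TRUE, snoozed_until = su)
}

#' Is a time inside a cycle's response window?
#'
#' The window is half-open: it opens at the cycle date's first prompt time and
#' closes at (excludes) the next day's window-end instant.
#'
#' @param cycle_date Cycle calendar date.
#' @param now Numeric timestamp.
#' @param config An [protocol_config()].
#' @return Logical.
#' @export
within_response_window <- function(cycle_date, now, config) {
  cycle_date <- as.Date(cycle_date)
  at_time(cycle_date, config$first_prompt_time) <= now &
    now < at_time(cycle_date + 1L, config$response_window_end)
}

#' Parse a snooze request time against the current clock
#'
#' "snooze" alone defers by the reminder interval; "snooze HH:MM" requests
#' that wall time, interpreted as today if still ahead and otherwise as
#' tomorrow (subject to the snooze limit clamp in [apply_snooze()]).
#'
#' @param hm `NULL` or an "HH:MM" string.
#' @param now Current virtual time.
#' @param config An [protocol_config()].
#' @return Requested numeric timestamp.
#' @export
resolve_snooze_time <- function(hm, now, config) {
  if (is.null(hm) || !nzchar(hm)) return(now + config$reminder_interval * 60)
  cand <- at_time(ts_date(now), hm)
  if (cand <= now) cand <- cand + 86400
  cand
}
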