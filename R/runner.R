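# Orchestration: drives one participant's full protocol on the virtual
# clock. A "message source" abstracts where inbound traffic comes from -- the
# behavior simulator, a scripted replay of a recorded log, or a console user.
#
# Source contract (a list/environment of functions):
#   activation()                -> NULL, or list(ts, msg) activating day 0
#   begin_day(day_index, cycle) -> called once when a cycle is created
#   unprompted_before(t)        -> NULL, or list(ts, msg) with ts < t, sent
#                                  while no dialog slot is pending
#   reply(cycle, session, now, horizon) -> NULL (ignore the prompt), or
#                                  list(ts, msg) with now < ts < horizon
#   on_complete(cycle, now)     -> optional notification hook

#' Run one participant's full protocol session
#'
#' Executes the complete multi-day protocol for one participant against a
#' message source, producing the session's event log: day-0 onboarding, then
#' one daily cycle per scorable day, each driven by the scheduler (first
#' prompt, reminder train, snooze, window closure, expiry notice) and the
#' dialog engine. Fully deterministic given the source.
#'
#' @param source A message source (see [sim_respondent()] for the simulator
#'   implementation of the contract).
#' @param participant_id,name Participant identity.
#' @param config An [protocol_config()].
#' @param schedule A [build_schedule()] schedule.
#' @param start_date Calendar date of day 0.
#' @param acc Optional event accumulator to append to.
#' @return The event `data.frame` for this participant (empty if the
#'   participant never activates the chatbot).
#' @export
run_session <- function(source, participant_id, name = participant_id,
                        config = protocol_config(),
                        schedule = build_schedule(config),
                        start_date = as.Date("2021-09-01"),
                        acc = NULL) {
  own_acc <- is.null(acc)
  if (own_acc) acc <- new_event_acc()
  start_date <- as.Date(start_date)
  session <- new_session(participant_id, name)

  act <- source$activation()
  if (is.null(act)) return(if (own_acc) acc_events(acc) else invisible(NULL))
  res <- session_handle(session, NULL, act$msg, act$ts, config, schedule, acc)
  session <- res$session

  terminal <- function(cycle) cycle$clock$status %in% c("COMPLETED", "EXPIRED")
  drain_unprompted <- function(session, cycle, upto) {
    repeat {
      u <- source$unprompted_before(upto)
      if (is.null(u)) break
      r <- session_handle(session, cycle, u$msg, u$ts, config, schedule, acc)
      session <- r$session
      if (!is.null(r$cycle)) cycle <- r$cycle
    }
    list(session = session, cycle = cycle)
  }

  for (d in seq_len(config$n_days - 1L)) {
    plan <- schedule[[d + 1L]]
    cycle <- new_cycle(plan, start_date + d)
    if (!is.null(source$begin_day)) source$begin_day(d, cycle)
    now <- at_time(start_date + d, "00:00")
    repeat {
      ne <- next_event(cycle$clock, config, now)
      if (is.null(ne)) break
      dr <- drain_unprompted(session, cycle, ne$at)
      session <- dr$session; cycle <- dr$cycle
      now <- ne$at
      cycle <- fire_timer(session, cycle, ne, config, acc)
      now <- cycle$fire_now
      if (terminal(cycle)) break
      # dialog loop: feed replies until the engine stops expecting one
      repeat {
        horizon <- dialog_horizon(cycle, config, now)
        r <- source$reply(cycle, session, now, horizon)
        if (is.null(r)) break
        h <- session_handle(session, cycle, r$msg, r$ts, config, schedule, acc)
        session <- h$session; cycle <- h$cycle; now <- h$now
        if (!h$expects_reply) break
      }
      if (terminal(cycle) && cycle$clock$status == "COMPLETED" &&
          !is.null(source$on_complete)) {
        source$on_complete(cycle, now)
      }
    }
    session$cycles[[as.character(d)]] <- cycle
  }
  dr <- drain_unprompted(session, NULL, Inf)
  if (own_acc) acc_events(acc) else invisible(session)
}

# Time of the next scheduler event if the participant stays silent; used by
# sources to decide whether a queued inbound message answers this prompt.
dialog_horizon <- function(cycle, config, now) {
  ne <- next_event(cycle$clock, config, now)
  if (is.null(ne)) Inf else ne$at
}

#' Replay an event log through the engine
#'
#' Re-runs the engine against only the *inbound* messages of a recorded log.
#' Because the scheduler and dialog engine are deterministic, the replay
#' regenerates every outbound and system event; on a valid log the result is
#' identical to the original (the event-sourcing round trip). Used to verify
#' log integrity and engine determinism.
#'
#' @param events An event `data.frame` (e.g. from [read_event_log()]).
#' @param config,schedule Protocol configuration and schedule used originally.
#' @return The regenerated event `data.frame`.
#' @export
replay_log <- function(events, config = protocol_config(),
                       schedule = build_schedule(config)) {
  acc <- new_event_acc()
  for (pid in unique(events$participant_id)) {
    pe <- events[events$participant_id == pid, , drop = FALSE]
    inbound <- pe[pe$direction == "inbound", , drop = FALSE]
    inbound <- inbound[order(inbound$ts), , drop = FALSE]
    d0 <- pe$ts[!is.na(pe$day_index) & pe$day_index == 0L &
                  pe$direction == "inbound"]
    if (!length(d0)) next
    start_date <- ts_date(min(d0))
    src <- replay_source(inbound)
    run_session(src, pid, name = pid, config = config, schedule = schedule,
                start_date = start_date, acc = acc)
  }
  acc_events(acc)
}

#' @noRd
replay_source <- function(inbound) {
  i <- 1L
  n <- nrow(inbound)
  row_msg <- function(r) {
    if (r$kind == "audio") chat_message(r$body, "audio", r$audio_duration)
    else chat_message(r$body)
  }
  pop <- function() {
    r <- inbound[i, , drop = FALSE]
    i <<- i + 1L
    list(ts = r$ts[[1]], msg = row_msg(as.list(r)))
  }
  list(
    activation = function() if (n >= 1L) pop() else NULL,
    begin_day = function(d, cycle) NULL,
    unprompted_before = function(t) {
      if (i <= n && inbound$ts[i] < t) pop() else NULL
    },
    reply = function(cycle, session, now, horizon) {
      if (i <= n && inbound$ts[i] >= now && inbound$ts[i] < horizon) pop()
      else NULL
    },
    on_complete = NULL
  )
}
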