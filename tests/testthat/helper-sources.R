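# Deterministic message sources for driving the engine in tests.

DAY0 <- as.Date("2021-09-01")

noon_ts <- function(date) as.numeric(as.Date(date)) * 86400 + 12 * 3600

# A fully compliant respondent: activates at noon on day 0, accepts every
# availability prompt immediately, and answers every slot via the supplied
# generators. `audio` and `item_answer` may be constants or functions of
# (slot/cursor, day_index).
compliant_source <- function(item_answer = 1, audio = 90, gate_day3 = "yes",
                             gate_fu2 = "no", latency = 60,
                             start_date = DAY0) {
  f_item <- if (is.function(item_answer)) item_answer
            else function(cursor, day) item_answer
  f_audio <- if (is.function(audio)) audio else function(slot, day) audio
  list(
    activation = function() list(ts = noon_ts(start_date),
                                 msg = chat_message("hi")),
    begin_day = function(d, cycle) NULL,
    unprompted_before = function(t) NULL,
    reply = function(cycle, session, now, horizon) {
      aw <- cycle$awaiting
      if (is.null(aw)) return(NULL)
      msg <- switch(aw,
        availability = chat_message("ready"),
        item = chat_message(as.character(f_item(cycle$item_cursor,
                                                cycle$day_index))),
        yesno = chat_message(if (cycle$slot == "fu2gate") gate_fu2
                             else gate_day3),
        audio = chat_message("[rec]", "audio",
                             f_audio(cycle$slot, cycle$day_index)),
        chat_message("ready"))
      list(ts = now + latency, msg = msg)
    },
    on_complete = NULL
  )
}

# Replays a fixed list of replies in order, whatever the engine asks;
# elements may be strings or chat_message objects. NULL entries skip one
# prompt (stay silent).
scripted_source <- function(replies, latency = 60, start_date = DAY0) {
  i <- 0L
  as_msg <- function(x) if (inherits(x, "chat_message")) x else chat_message(x)
  list(
    activation = function() {
      i <<- i + 1L
      list(ts = noon_ts(start_date), msg = as_msg(replies[[i]]))
    },
    begin_day = function(d, cycle) NULL,
    unprompted_before = function(t) NULL,
    reply = function(cycle, session, now, horizon) {
      if (i >= length(replies)) return(NULL)
      i <<- i + 1L
      if (is.null(replies[[i]])) return(NULL)
      list(ts = now + latency, msg = as_msg(replies[[i]]))
    },
    on_complete = NULL
  )
}

# Run one source through the full protocol, returning both the event log and
# the final session state.
run_with_session <- function(source, config = protocol_config(),
                             schedule = build_schedule(config),
                             start_date = DAY0, pid = "t001") {
  # the display name must equal the participant id for replay round trips
  # (the log records no display name)
  acc <- emachat:::new_event_acc()
  session <- run_session(source, pid, name = pid, config = config,
                         schedule = schedule, start_date = start_date,
                         acc = acc)
  list(events = emachat:::acc_events(acc), session = session)
}

# Outbound questionnaire item prompts are recognizable by the anchor
# reminder appended to every item.
ANCHOR <- "0=no, 1=sometimes, 2=yes"

count_item_prompts <- function(events, day) {
  sum(events$direction == "outbound" & !is.na(events$day_index) &
        events$day_index == day & grepl(ANCHOR, events$body, fixed = TRUE))
}
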