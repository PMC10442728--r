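# The conversation state machine. All functions are pure in the sense that
# time (`now`) is injected and outbound events are appended to an explicit
# accumulator, so a session is fully reproducible from its inbound messages.

#' Construct a chat message
#'
#' @param body Text content (for audio, a short descriptor).
#' @param type `"text"` or `"audio"`.
#' @param duration Audio duration in seconds (audio only).
#' @return A `chat_message` list.
#' @export
chat_message <- function(body, type = "text", duration = NA_real_) {
  stopifnot(type %in% c("text", "audio"))
  if (type == "audio" && (is.na(duration) || duration <= 0))
    stop("audio messages require a positive duration", call. = FALSE)
  structure(list(type = type, body = body, duration = as.numeric(duration)),
            class = "chat_message")
}

#' Create a participant session
#'
#' @param participant_id Opaque identifier.
#' @param name Display name used in rendered prompts.
#' @return An `ema_session` list.
#' @export
new_session <- function(participant_id, name = participant_id) {
  structure(list(participant_id = participant_id, name = name,
                 onboarded_at = NULL, cycles = list(),
                 unprompted_events = list()),
            class = "ema_session")
}

#' Create the state of one daily cycle
#'
#' @param plan A day plan from [build_schedule()].
#' @param cycle_date Calendar date the cycle opens on.
#' @return An `ema_cycle` list wrapping a [cycle_clock()] plus dialog state.
#' @export
new_cycle <- function(plan, cycle_date) {
  structure(list(day_index = plan$day_index, mode = plan$mode,
                 cycle_date = as.Date(cycle_date), prompts = plan$prompts,
                 clock = cycle_clock(cycle_date),
                 awaiting = NULL, slot = NULL, pending_prompt = NULL,
                 item_cursor = 0L, corr_target = NA_integer_,
                 audio_seconds = 0, followups_sent = 0L,
                 response = smfq_response(), answers = list(),
                 engaged = FALSE, snooze_count = 0L,
                 reprompted = character(0)),
            class = "ema_cycle")
}

#' @noRd
normalize_text <- function(x) {
  x <- tolower(trimws(x))
  sub("[.!?,;:]+$", "", x)
}

#' @noRd
is_emoji_only <- function(x) {
  has_emoji <- grepl(":[a-z_]+:", x) || grepl("[^\x01-\x7f]", x, useBytes = TRUE)
  stripped <- gsub(":[a-z_]+:", "", x)
  stripped <- gsub("[^\x01-\x7f]", "", stripped, useBytes = TRUE)
  has_emoji && !nzchar(trimws(stripped))
}

YES_WORDS <- c("yes", "y", "yeah", "yep", "sure")
NO_WORDS <- c("no", "n", "nope", "nah")

#' Classify an inbound message in its dialog context
#'
#' Implements the exact-match reply rules: normalization is lowercasing,
#' trimming and stripping terminal punctuation; closure is an exact match
#' against the configured closure vocabulary (emoji-only replies count as
#' closure when enabled); `0`/`1`/`2` are numeric answers in questionnaire
#' context; yes/no words resolve a yes/no gate; audio payloads carry their
#' duration. Free text arriving in a slot that expects structured input is
#' `UNSUPPORTED` (the engine re-prompts). The function is total: every
#' message maps to some intent.
#'
#' @param text_or_audio A [chat_message()].
#' @param context Dialog position: `NULL` (no pending slot),
#'   `"availability"`, `"item"`, `"yesno"`, `"audio"`, `"correction_which"`,
#'   `"correction_value"`.
#' @param config An [protocol_config()].
#' @return A `reply_intent` list with `kind` and, where relevant, `value` or
#'   `duration`.
#' @export
#' @examples
#' cfg <- protocol_config()
#' classify_reply(chat_message("Thank you!"), NULL, cfg)$kind
#' classify_reply(chat_message("1"), "item", cfg)$kind
classify_reply <- function(text_or_audio, context, config) {
  msg <- text_or_audio
  intent <- function(kind, value = NULL, duration = NA_real_)
    structure(list(kind = kind, value = value, duration = duration),
              class = "reply_intent")
  if (msg$type == "audio") return(intent("AUDIO", duration = msg$duration))
  n <- normalize_text(msg$body)
  if (startsWith(n, "snooze")) {
    m <- regmatches(n, regexec("^snooze( +([0-9]{1,2}:[0-9]{2}))?$", n))[[1]]
    if (length(m)) return(intent("SNOOZE_REQUEST",
                                 value = if (nzchar(m[3])) m[3] else NULL))
  }
  if (n %in% config$closure_words) return(intent("CLOSURE"))
  if (config$emoji_closure && is_emoji_only(msg$body)) return(intent("CLOSURE"))
  if (identical(context, "item") || identical(context, "correction_value")) {
    if (grepl("^[012]$", n)) return(intent("NUMERIC_ANSWER", value = as.integer(n)))
    if (n %in% config$correction_keywords) return(intent("CORRECTION_REQUEST"))
    return(intent("UNSUPPORTED"))
  }
  if (identical(context, "yesno")) {
    if (n %in% YES_WORDS) return(intent("YES"))
    if (n %in% NO_WORDS) return(intent("NO"))
    return(intent("UNSUPPORTED"))
  }
  if (identical(context, "audio")) return(intent("UNSUPPORTED"))
  if (identical(context, "correction_which")) {
    if (grepl("^([1-9]|1[0-3])$", n))
      return(intent("FREE_TEXT", value = as.integer(n)))
    return(intent("UNSUPPORTED"))
  }
  intent("FREE_TEXT")
}

#' Typing delay for an outbound message
#'
#' Outbound messages are delayed proportionally to their length to mimic a
#' human typing: `delay = base + rate * nchar`, clamped to `[base, max]`.
#'
#' @param outbound_text_length Character count (>= 0).
#' @param config An [protocol_config()].
#' @return Delay in seconds.
#' @export
#' @examples
#' typing_delay(40, protocol_config())  # 0.5 + 0.05 * 40 = 2.5
typing_delay <- function(outbound_text_length, config) {
  stopifnot(outbound_text_length >= 0)
  min(config$typing_max,
      max(config$typing_base,
          config$typing_base + config$typing_rate * outbound_text_length))
}

# Emit an outbound text event after its typing delay; returns the new clock
# position. `env` is a small mutable context shared within one handle call.
emit_out <- function(env, body, kind = "text", day_index = NA_integer_,
                     excluded = FALSE, expects = FALSE, pending = FALSE) {
  body <- render_prompt(body, env$name)
  env$now <- ceiling(env$now + typing_delay(nchar(body), env$config))
  acc_add(env$acc, env$now, env$pid, "outbound", kind, body = body,
          day_index = day_index, excluded = excluded)
  env$expects_reply <- expects
  if (pending) env$pending_prompt <- body
  invisible(env)
}

#' Accumulate daily audio and decide on follow-up probes
#'
#' Called once both primary audio questions have been answered, with each new
#' recording's duration. While the daily total stays below the audio target,
#' the first shortfall triggers the first standard follow-up probe and the
#' second triggers the yes/no-gated second probe; after that (or as soon as
#' the target is met) the cycle completes.
#'
#' @param cycle An `ema_cycle` (audio-question day).
#' @param new_audio Duration in seconds of the newly received recording
#'   (>= 0; zero is used when a text answer is accepted in an audio slot).
#' @param config An [protocol_config()].
#' @return A list with `cycle` (updated `audio_seconds`) and `decision`: one
#'   of `"followup1"`, `"followup2"`, `"complete"`.
#' @export
accumulate_audio <- function(cycle, new_audio, config) {
  if (is.na(new_audio) || new_audio < 0)
    stop("audio duration must be a non-negative number", call. = FALSE)
  cycle$audio_seconds <- cycle$audio_seconds + new_audio
  decision <-
    if (cycle$audio_seconds >= config$audio_target) "complete"
    else if (cycle$followups_sent == 0L && config$max_followups >= 1L) "followup1"
    else if (cycle$followups_sent == 1L && config$max_followups >= 2L) "followup2"
    else "complete"
  list(cycle = cycle, decision = decision)
}

#' Onboard a participant (day 0)
#'
#' Any first inbound message (any content) activates the protocol: the
#' engine replies with the day-0 introduction reviewing functionality,
#' stating that audio is not listened to immediately and that the bot is not
#' a help channel. All day-0 events carry the `excluded` flag so downstream
#' analysis can drop them without losing auditability. Re-activation is
#' idempotent: a later message falls through to the unprompted handler.
#'
#' @param session An [new_session()].
#' @param first_message A [chat_message()].
#' @param now Virtual time of the inbound message.
#' @param config,schedule Protocol configuration and schedule.
#' @param acc Event accumulator (internal; tests can pass `new_event_acc()`).
#' @return List with updated `session` and `expects_reply = FALSE`.
#' @export
run_onboarding <- function(session, first_message, now, config, schedule,
                           acc = new_event_acc()) {
  if (!is.null(session$onboarded_at))
    return(handle_unprompted(session, first_message, now, config, acc))
  pid <- session$participant_id
  kind <- if (first_message$type == "audio") "audio" else "text"
  acc_add(acc, now, pid, "inbound", kind, body = first_message$body,
          audio_duration = first_message$duration, day_index = 0L,
          excluded = TRUE)
  env <- list2env(list(now = now, pid = pid, name = session$name,
                       config = config, acc = acc, expects_reply = FALSE,
                       pending_prompt = NULL))
  emit_out(env, schedule[[1L]]$prompts$intro, day_index = 0L, excluded = TRUE)
  emit_out(env, paste(
    "Two important things: your audio messages are not listened to right",
    "away by the team, and I'm an automated script, so I can't help in an",
    "emergency. If you need support, please contact the research team",
    "directly."), day_index = 0L, excluded = TRUE)
  emit_out(env, paste0("See you tomorrow at ", config$first_prompt_time,
                       "! You can also send me audio messages on your own at ",
                       "any time."), day_index = 0L, excluded = TRUE)
  session$onboarded_at <- now
  list(session = session, cycle = NULL, expects_reply = FALSE, now = env$now)
}

#' Handle a message outside any scheduled dialog slot
#'
#' Unprompted audio is acknowledged and logged (it never counts toward the
#' daily audio target); a closure word is logged silently; any other text
#' receives a single clarification asking for an audio message.
#'
#' @inheritParams run_onboarding
#' @param message A [chat_message()].
#' @export
handle_unprompted <- function(session, message, now, config,
                              acc = new_event_acc()) {
  pid <- session$participant_id
  int <- classify_reply(message, NULL, config)
  env <- list2env(list(now = now, pid = pid, name = session$name,
                       config = config, acc = acc, expects_reply = FALSE,
                       pending_prompt = NULL))
  if (int$kind == "AUDIO") {
    acc_add(acc, now, pid, "inbound", "audio", body = message$body,
            audio_duration = message$duration)
    session$unprompted_events[[length(session$unprompted_events) + 1L]] <-
      list(ts = now, kind = "audio", duration = message$duration)
    emit_out(env, "Thank you for sending this audio!")
  } else if (int$kind == "CLOSURE") {
    acc_add(acc, now, pid, "inbound", "acknowledgment", body = message$body)
  } else {
    acc_add(acc, now, pid, "inbound", "text", body = message$body)
    session$unprompted_events[[length(session$unprompted_events) + 1L]] <-
      list(ts = now, kind = "text")
    emit_out(env, paste("Could you send that as an audio message? That way",
                        "we can really hear about your day!"))
  }
  list(session = session, cycle = NULL, expects_reply = FALSE, now = env$now)
}

#' @noRd
cycle_terminal <- function(cycle) cycle$clock$status %in% c("COMPLETED", "EXPIRED")

#' @noRd
awaiting_context <- function(cycle) {
  if (is.null(cycle$awaiting)) NULL else cycle$awaiting
}

# Fire a scheduler timer event: availability prompt, reminder, snooze wake-up
# or expiry notice. Returns the updated cycle.
fire_timer <- function(session, cycle, ev, config, acc) {
  pid <- session$participant_id
  env <- list2env(list(now = ev$at, pid = pid, name = session$name,
                       config = config, acc = acc, expects_reply = FALSE,
                       pending_prompt = NULL))
  if (ev$kind == "EXPIRY_NOTICE") {
    emit_out(env, paste0("We couldn't finish this daily cycle, so it is now ",
                         "closed. A new cycle starts today - I'll message ",
                         "you at ", config$first_prompt_time, "."),
             kind = "expiry_notice", day_index = cycle$day_index)
    acc_add(acc, env$now, pid, "system", "state_transition", body = "EXPIRED",
            day_index = cycle$day_index)
    cycle$clock <- clock_transition(cycle$clock, "EXPIRED")
    cycle$awaiting <- NULL
    return(cycle)
  }
  resume_mid_dialog <- ev$kind == "SNOOZE_PROMPT" &&
    !is.null(cycle$awaiting) && cycle$awaiting != "availability"
  if (resume_mid_dialog) {
    cycle$clock <- clock_transition(cycle$clock, "IN_PROGRESS")
    emit_out(env, paste("Here I am again, as promised! We were in the middle",
                        "of something:"), day_index = cycle$day_index)
    emit_out(env, cycle$pending_prompt, day_index = cycle$day_index,
             expects = TRUE, pending = TRUE)
  } else {
    cycle$clock <- clock_transition(cycle$clock, "PROMPTED")
    body <- switch(ev$kind,
      FIRST_PROMPT = paste0("Hi {name}! Are you available to answer today's ",
                            "questions? If now is a bad time, reply 'snooze ",
                            "HH:MM' and I'll come back later."),
      REMINDER = paste0("Just checking in again, {name} - are you available ",
                        "now? (You can also reply 'snooze HH:MM'.)"),
      SNOOZE_PROMPT = "Here I am again, as promised! Shall we start?")
    emit_out(env, body, day_index = cycle$day_index, expects = TRUE,
             pending = TRUE)
    cycle$awaiting <- "availability"
  }
  cycle$clock$prompts_sent <- cycle$clock$prompts_sent + 1L
  cycle$clock$last_prompt_at <- ev$at
  cycle$fire_now <- env$now
  cycle
}

# Close a cycle successfully: closing message + terminal transition.
complete_cycle <- function(env, cycle) {
  emit_out(env, "That's all for today, {name}! Thank you so much. See you tomorrow!",
           day_index = cycle$day_index)
  acc_add(env$acc, env$now, env$pid, "system", "state_transition",
          body = "COMPLETED", day_index = cycle$day_index)
  cycle$clock <- clock_transition(cycle$clock, "COMPLETED")
  cycle$awaiting <- NULL
  cycle
}

# Start the day's dialog after the participant signalled availability.
start_day_dialog <- function(env, cycle) {
  if (cycle$mode == "AUDIO_QUESTIONS") {
    gated <- !is.null(cycle$prompts$q1_yes)
    emit_out(env, cycle$prompts$q1, day_index = cycle$day_index,
             expects = TRUE, pending = TRUE)
    if (gated) {
      cycle$awaiting <- "yesno"; cycle$slot <- "q1gate"
    } else {
      cycle$awaiting <- "audio"; cycle$slot <- "q1"
    }
  } else if (cycle$mode == "QUESTIONNAIRE") {
    form <- smfq_form(vapply(cycle$prompts, identity, character(1)),
                      env$config$smfq_anchors)
    cycle$form <- form
    emit_out(env, paste("Time for today's questionnaire! Answer each",
                        "statement by typing 0, 1 or 2."),
             day_index = cycle$day_index)
    emit_out(env, item_prompt(form, 0L, env$name),
             day_index = cycle$day_index, expects = TRUE, pending = TRUE)
    cycle$awaiting <- "item"; cycle$item_cursor <- 0L
  } else {
    cycle <- complete_cycle(env, cycle)
  }
  cycle
}

# Advance an audio day after a recording (or accepted text) filled `slot`.
advance_audio_slot <- function(env, cycle, duration) {
  slot <- cycle$slot
  cycle$answers[[slot]] <- duration
  if (slot == "q1") {
    cycle$audio_seconds <- cycle$audio_seconds + duration
    emit_out(env, cycle$prompts$q2, day_index = cycle$day_index,
             expects = TRUE, pending = TRUE)
    cycle$awaiting <- "audio"; cycle$slot <- "q2"
    return(cycle)
  }
  res <- accumulate_audio(cycle, duration, env$config)
  cycle <- res$cycle
  scripts <- env$config$day_scripts
  if (res$decision == "followup1") {
    cycle$followups_sent <- 1L
    emit_out(env, scripts$followup1, day_index = cycle$day_index,
             expects = TRUE, pending = TRUE)
    cycle$awaiting <- "audio"; cycle$slot <- "fu1"
  } else if (res$decision == "followup2") {
    cycle$followups_sent <- 2L
    emit_out(env, scripts$followup2, day_index = cycle$day_index,
             expects = TRUE, pending = TRUE)
    cycle$awaiting <- "yesno"; cycle$slot <- "fu2gate"
  } else {
    cycle <- complete_cycle(env, cycle)
  }
  cycle
}

#' Advance a session with one inbound message
#'
#' The single entry point for inbound traffic: routes to onboarding when the
#' session is not yet activated, to the active daily dialog when a prompt is
#' pending, and to the unprompted handler otherwise. Outbound replies are
#' appended to `acc` after their typing delays.
#'
#' @param session An `ema_session`.
#' @param cycle The current `ema_cycle`, or `NULL` outside any cycle.
#' @param msg A [chat_message()].
#' @param now Inbound timestamp (numeric virtual time).
#' @param config,schedule Protocol configuration and schedule.
#' @param acc Event accumulator.
#' @return List with `session`, `cycle`, `expects_reply` (is the engine
#'   waiting for the next reply in an open dialog slot?) and `now` (clock
#'   after the last outbound message).
#' @export
session_handle <- function(session, cycle, msg, now, config, schedule,
                           acc = new_event_acc()) {
  if (is.null(session$onboarded_at)) {
    res <- run_onboarding(session, msg, now, config, schedule, acc)
    res$cycle <- cycle
    return(res)
  }
  active <- !is.null(cycle) &&
    cycle$clock$status %in% c("PROMPTED", "IN_PROGRESS") &&
    !is.null(cycle$awaiting)
  if (!active) {
    res <- handle_unprompted(session, msg, now, config, acc)
    res$cycle <- cycle
    return(res)
  }
  handle_cycle_message(session, cycle, msg, now, config, acc)
}

#' @noRd
handle_cycle_message <- function(session, cycle, msg, now, config, acc) {
  pid <- session$participant_id
  int <- classify_reply(msg, awaiting_context(cycle), config)
  in_kind <- switch(int$kind, AUDIO = "audio", SNOOZE_REQUEST = "snooze",
                    CLOSURE = "acknowledgment", "text")
  acc_add(acc, now, pid, "inbound", in_kind, body = msg$body,
          audio_duration = msg$duration, day_index = cycle$day_index)
  if (in_kind %in% c("audio", "text")) cycle$engaged <- TRUE
  env <- list2env(list(now = now, pid = pid, name = session$name,
                       config = config, acc = acc, expects_reply = FALSE,
                       pending_prompt = cycle$pending_prompt))
  aw <- cycle$awaiting

  if (aw == "availability") {
    if (int$kind == "SNOOZE_REQUEST") {
      req <- resolve_snooze_time(int$value, now, config)
      sn <- apply_snooze(cycle$clock, req, config, now)
      if (sn$accepted) {
        cycle$clock <- sn$state
        cycle$snooze_count <- cycle$snooze_count + 1L
        emit_out(env, paste0("Ok! I'll message you again at ",
                             format(as.POSIXct(sn$snoozed_until,
                                               origin = "1970-01-01",
                                               tz = "UTC"), "%H:%M"), "."),
                 day_index = cycle$day_index)
      } else {
        emit_out(env, "That time has already passed - when should I come back?",
                 day_index = cycle$day_index, expects = TRUE, pending = TRUE)
      }
    } else {
      cycle$clock <- clock_transition(cycle$clock, "IN_PROGRESS")
      cycle <- start_day_dialog(env, cycle)
    }
  } else if (aw == "yesno" && cycle$slot == "q1gate") {
    if (int$kind == "YES" || int$kind == "NO") {
      arm <- if (int$kind == "YES") cycle$prompts$q1_yes else cycle$prompts$q1_no
      emit_out(env, arm, day_index = cycle$day_index, expects = TRUE,
               pending = TRUE)
      cycle$awaiting <- "audio"; cycle$slot <- "q1"
    } else if (int$kind == "AUDIO") {
      cycle$slot <- "q1"
      cycle <- advance_audio_slot(env, cycle, int$duration)
    } else {
      emit_out(env, "Please answer 'yes' or 'no'.",
               day_index = cycle$day_index, expects = TRUE)
    }
  } else if (aw == "yesno" && cycle$slot == "fu2gate") {
    if (int$kind == "YES") {
      emit_out(env, "Great! Go ahead, I'm listening.",
               day_index = cycle$day_index, expects = TRUE, pending = TRUE)
      cycle$awaiting <- "audio"; cycle$slot <- "fu2a"
    } else if (int$kind == "NO") {
      cycle <- complete_cycle(env, cycle)
    } else if (int$kind == "AUDIO") {
      cycle$slot <- "fu2a"
      cycle <- advance_audio_slot(env, cycle, int$duration)
    } else {
      emit_out(env, "Please answer 'yes' or 'no'.",
               day_index = cycle$day_index, expects = TRUE)
    }
  } else if (aw == "audio") {
    if (int$kind == "AUDIO") {
      cycle <- advance_audio_slot(env, cycle, int$duration)
    } else if (cycle$slot %in% cycle$reprompted) {
      # gentle reprompt already used: keep the text as a free-text data point
      cycle <- advance_audio_slot(env, cycle, 0)
    } else {
      cycle$reprompted <- c(cycle$reprompted, cycle$slot)
      emit_out(env, "If you can, send it as an audio message - I'd love to hear it!",
               day_index = cycle$day_index, expects = TRUE)
    }
  } else if (aw == "item") {
    form <- cycle$form
    if (int$kind == "NUMERIC_ANSWER") {
      rec <- record_answer(cycle$response, cycle$item_cursor, int, now)
      cycle$response <- rec$response
      cycle$item_cursor <- cycle$item_cursor + 1L
      if (cycle$item_cursor >= 13L) {
        cycle <- complete_cycle(env, cycle)
      } else {
        emit_out(env, item_prompt(form, cycle$item_cursor, session$name),
                 day_index = cycle$day_index, expects = TRUE, pending = TRUE)
      }
    } else if (int$kind == "CORRECTION_REQUEST") {
      emit_out(env, "Which question would you like to correct? (1-13)",
               day_index = cycle$day_index, expects = TRUE)
      cycle$awaiting <- "correction_which"
    } else {
      emit_out(env, paste("Please answer by typing 0, 1 or 2.",
                          anchor_reminder(config$smfq_anchors)),
               day_index = cycle$day_index, expects = TRUE)
    }
  } else if (aw == "correction_which") {
    if (int$kind == "FREE_TEXT" && !is.null(int$value)) {
      target <- int$value - 1L
      if (target < cycle$item_cursor && !is.na(cycle$response$answers[target + 1L])) {
        cycle$corr_target <- target
        form <- cycle$form
        emit_out(env, paste("Ok, send the new answer for:",
                            item_prompt(form, target, session$name)),
                 day_index = cycle$day_index, expects = TRUE)
        cycle$awaiting <- "correction_value"
      } else {
        emit_out(env, "You haven't answered that one yet - which answered question (1-13)?",
                 day_index = cycle$day_index, expects = TRUE)
      }
    } else {
      emit_out(env, "Please send the question number (1-13).",
               day_index = cycle$day_index, expects = TRUE)
    }
  } else if (aw == "correction_value") {
    if (int$kind == "NUMERIC_ANSWER") {
      rec <- record_answer(cycle$response, cycle$corr_target, int, now)
      cycle$response <- rec$response
      cycle$corr_target <- NA_integer_
      form <- cycle$form
      emit_out(env, "Got it, answer updated!", day_index = cycle$day_index)
      emit_out(env, item_prompt(form, cycle$item_cursor, session$name),
               day_index = cycle$day_index, expects = TRUE, pending = TRUE)
      cycle$awaiting <- "item"
    } else {
      emit_out(env, paste("Please answer with 0, 1 or 2.",
                          anchor_reminder(config$smfq_anchors)),
               day_index = cycle$day_index, expects = TRUE)
    }
  }
  if (!is.null(env$pending_prompt)) cycle$pending_prompt <- env$pending_prompt
  list(session = session, cycle = cycle, expects_reply = env$expects_reply,
       now = env$now)
}
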