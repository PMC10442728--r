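#' Protocol configuration
#'
#' Builds the immutable configuration of the 15-day assessment protocol: the
#' daily prompt time, the reminder train, the snooze and response-window
#' limits, the daily audio target, the closure vocabulary, the typing-delay
#' constants and the scripted prompt texts.
#'
#' The default timing constants implement the deployed protocol: the first
#' prompt of each daily cycle goes out at 13:30 local time, unanswered prompts
#' are repeated every 3 hours, snoozing is allowed up to 03:00 of the next
#' day, responses are accepted until 06:00 of the next day, and an expiry
#' notice is sent at 10:00 of the next day if the cycle was not completed.
#'
#' @param first_prompt_time Wall time "HH:MM" of the first daily prompt.
#' @param reminder_interval Minutes between repeated prompts while unanswered.
#' @param snooze_limit_time Wall time "HH:MM" on the *next* day up to which a
#'   snooze may be scheduled; later requests are clamped to this limit.
#' @param response_window_end Wall time "HH:MM" on the next day at which the
#'   response window closes (half-open: the instant itself is outside).
#' @param expiry_notice_time Wall time "HH:MM" on the next day at which the
#'   participant is told the cycle ended without completion.
#' @param audio_target Daily audio target in seconds over the two scheduled
#'   audio questions; shorter totals trigger up to `max_followups` probes.
#' @param n_days Number of protocol days including the onboarding day 0.
#' @param closure_words Normalized words treated as conversation closure.
#' @param emoji_closure Treat an emoji-only reply in closure position as
#'   closure.
#' @param max_followups Maximum number of follow-up audio probes per day.
#' @param typing_base,typing_rate,typing_max Typing-delay constants (seconds,
#'   seconds per character, cap) used by [typing_delay()].
#' @param correction_keywords Words that open the answer-correction dialog
#'   during the questionnaire.
#' @param smfq_items Character vector of 13 day-framed questionnaire item
#'   statements. The shipped wording is placeholder text; deployments
#'   substitute the licensed instrument.
#' @param smfq_anchors Named character vector mapping answers 0/1/2 to their
#'   verbal anchors.
#' @param day_scripts Named list of audio-day scripts as produced by
#'   [default_day_scripts()].
#'
#' @return An object of class `ema_config` (a validated list).
#' @export
#' @examples
#' cfg <- protocol_config()
#' cfg$first_prompt_time
protocol_config <- function(first_prompt_time = "13:30",
                            reminder_interval = 180,
                            snooze_limit_time = "03:00",
                            response_window_end = "06:00",
                            expiry_notice_time = "10:00",
                            audio_target = 60,
                            n_days = 15,
                            closure_words = c("ok", "okay", "see you", "bye",
                                              "thank you", "thanks", "thx"),
                            emoji_closure = TRUE,
                            max_followups = 2,
                            typing_base = 0.5,
                            typing_rate = 0.05,
                            typing_max = 6,
                            correction_keywords = c("correct", "fix"),
                            smfq_items = default_smfq_items(),
                            smfq_anchors = c("0" = "no", "1" = "sometimes",
                                             "2" = "yes"),
                            day_scripts = default_day_scripts()) {
  cfg <- structure(list(
    first_prompt_time = first_prompt_time,
    reminder_interval = as.numeric(reminder_interval),
    snooze_limit_time = snooze_limit_time,
    response_window_end = response_window_end,
    expiry_notice_time = expiry_notice_time,
    audio_target = as.numeric(audio_target),
    n_days = as.integer(n_days),
    closure_words = as.character(closure_words),
    emoji_closure = isTRUE(emoji_closure),
    max_followups = as.integer(max_followups),
    typing_base = as.numeric(typing_base),
    typing_rate = as.numeric(typing_rate),
    typing_max = as.numeric(typing_max),
    correction_keywords = as.character(correction_keywords),
    smfq_items = as.character(smfq_items),
    smfq_anchors = smfq_anchors,
    day_scripts = day_scripts
  ), class = "ema_config")
  validate_config(cfg)
  cfg
}

#' @noRd
validate_config <- function(cfg) {
  fail <- function(...) stop("invalid protocol configuration: ", ..., call. = FALSE)
  for (f in c("first_prompt_time", "snooze_limit_time", "response_window_end",
              "expiry_notice_time")) {
    hm_to_sec(cfg[[f]])
  }
  if (!(hm_to_sec(cfg$snooze_limit_time) < hm_to_sec(cfg$response_window_end)))
    fail("snooze_limit_time must precede response_window_end")
  if (!(hm_to_sec(cfg$response_window_end) < hm_to_sec(cfg$expiry_notice_time)))
    fail("response_window_end must precede expiry_notice_time")
  if (!(cfg$audio_target > 0)) fail("audio_target must be > 0")
  if (!(cfg$n_days >= 2)) fail("n_days must be >= 2")
  if (!(cfg$reminder_interval > 0)) fail("reminder_interval must be > 0")
  if (length(cfg$smfq_items) != 13L) fail("smfq_items must have exactly 13 items")
  if (!identical(sort(names(cfg$smfq_anchors)), c("0", "1", "2")))
    fail("smfq_anchors must be named exactly 0, 1, 2")
  if (cfg$max_followups < 0) fail("max_followups must be >= 0")
  if (cfg$typing_max < cfg$typing_base) fail("typing_max must be >= typing_base")
  invisible(cfg)
}

#' @export
print.ema_config <- function(x, ...) {
  cat("<ema_config>\n")
  cat("  days:", x$n_days, "(day 0 +", x$n_days - 1L, "scorable)\n")
  cat("  first prompt", x$first_prompt_time,
      "| reminders every", x$reminder_interval, "min",
      "| snooze until", x$snooze_limit_time,
      "| window closes", x$response_window_end,
      "| expiry notice", x$expiry_notice_time, "\n")
  cat("  audio target:", x$audio_target, "s; closure words:",
      paste(x$closure_words, collapse = ", "), "\n")
  invisible(x)
}

# Scripted audio-day questions. Prompts are data, not code: `{name}` is the
# participant-name placeholder and `:emoji_name:` tokens stand for emojis.
# Day 3's first question branches on a yes/no reply.

#' Default audio-day scripts
#'
#' The scripted open questions for the seven audio days (1, 3, 5, 7, 9, 11,
#' 13): two primary questions per day about daily life, social interactions
#' and preferences, plus the two standard follow-up probes used when the daily
#' audio total falls short of the target.
#'
#' @return A named list with elements `days` (scripts keyed by day index) and
#'   `followup1` / `followup2` (probe texts; the second carries a yes/no gate).
#' @export
default_day_scripts <- function() {
  list(
    days = list(
      "1" = list(
        q1 = "Can you introduce yourself?",
        q2 = "What have you done today? Is your day going according to your usual routine?"
      ),
      "3" = list(
        q1 = "Are you at home?",
        q1_yes = "What are you doing? Is someone else around?",
        q1_no = "Who do you live with? Do you get along with the people you live with?",
        q2 = "Can you tell me more about your house? Do you like living there?"
      ),
      "5" = list(
        q1 = "Did you go outside today at all, {name}? Do you spend more time inside, or do you sometimes go out? When you're out, what do you normally do?",
        q2 = "And how's your neighborhood? Are there nice things around?"
      ),
      "7" = list(
        q1 = "Today I want to know about your favorite story. What is it? You can choose a movie, a series, a book... whatever you want!",
        q2 = "And why is this your favorite story, {name}?"
      ),
      "9" = list(
        q1 = "Do you use your mobile phone a lot, {name}? What are your favorite things to do on the mobile phone?",
        q2 = "And how much time do you think you spend on the internet each day? Do you use the internet mostly during the day or at night? Why?"
      ),
      "11" = list(
        q1 = "Not counting the audio recordings you send here :grinning_face_with_sweat:, who do you talk to about things that happen in your life? How's your relationship with this person?",
        q2 = "And why do you trust this person?"
      ),
      "13" = list(
        q1 = "It's been almost 2 weeks since we started talking, {name}! How did you feel about answering these questions?",
        q2 = "And how have you been in these last 2 weeks? Has anything different happened?"
      )
    ),
    followup1 = "Thank you for sending this audio! Tell us a little bit more about it, {name}!",
    followup2 = "It would be very important if you could tell us a little more, okay? You can choose whether to send another audio recording: type 'yes' or 'no' before sending it."
  )
}

#' Default day-framed questionnaire items
#'
#' Thirteen mood statements re-framed to cover the current day. This wording
#' is placeholder text shipped so the engine runs out of the box; research
#' deployments replace it with the licensed instrument items.
#'
#' @return Character vector of length 13.
#' @export
default_smfq_items <- function() {
  c("I feel sad today.",
    "I didn't enjoy anything today.",
    "I felt so tired that I just sat around today.",
    "I was very restless today.",
    "I felt I was no good today.",
    "I cried a lot today.",
    "I found it hard to think or concentrate today.",
    "I hated myself today.",
    "I felt I was a bad person today.",
    "I felt lonely today.",
    "I thought nobody really loved me today.",
    "I thought I could never be as good as others today.",
    "I felt I did everything wrong today.")
}

#' Build the 15-day protocol schedule
#'
#' Expands a configuration into one `DayPlan` per protocol day: day 0 is the
#' onboarding introduction, odd days 1-13 carry the scripted audio questions,
#' and the remaining even days 2-14 administer the 13-item questionnaire. A
#' `MOOD_RATING` mode is reserved in the mode set but never scheduled by
#' default.
#'
#' @param config An [protocol_config()] object.
#' @return An object of class `ema_schedule`: a list of day plans, each with
#'   `day_index`, `mode` and `prompts`.
#' @export
#' @examples
#' sched <- build_schedule(protocol_config())
#' table(vapply(sched, `[[`, "", "mode"))
build_schedule <- function(config = protocol_config()) {
  validate_config(config)
  scripts <- config$day_scripts
  plans <- lapply(seq_len(config$n_days) - 1L, function(d) {
    if (d == 0L) {
      mode <- "INTRODUCTION"
      prompts <- list(intro = paste0(
        "Hi {name}! Over the next ", config$n_days - 1L, " days I'll message you ",
        "once a day, starting at ", config$first_prompt_time, ", to ask about ",
        "your day and your mood. Some days I'll ask for short audio messages, ",
        "other days a quick questionnaire answered with 0, 1 or 2."))
      } else if (d %% 2L == 1L) {
      mode <- "AUDIO_QUESTIONS"
      key <- as.character(d)
      prompts <- scripts$days[[key]]
      if (is.null(prompts)) {
        # beyond the scripted range (custom n_days): reuse the generic day-1 script
        prompts <- scripts$days[["1"]]
      }
    } else {
      mode <- "QUESTIONNAIRE"
      prompts <- as.list(config$smfq_items)
    }
    structure(list(day_index = d, mode = mode, prompts = prompts),
              class = "ema_day_plan")
  })
  structure(plans, class = "ema_schedule")
}

#' @export
print.ema_schedule <- function(x, ...) {
  cat("<ema_schedule> ", length(x), " days\n", sep = "")
  for (p in x) cat(sprintf("  day %2d  %s\n", p$day_index, p$mode))
  invisible(x)
}

#' Render a prompt template for a participant
#'
#' Substitutes the `{name}` placeholder and checks that no placeholder
#' remains. Emoji tokens (`:emoji_name:`) are preserved verbatim.
#'
#' @param template Prompt template string.
#' @param participant_name Display name substituted into `{name}`.
#' @return The rendered prompt text.
#' @export
#' @examples
#' render_prompt("And why is this your favorite story, {name}?", "Ana")
render_prompt <- function(template, participant_name) {
  if (!grepl("{", template, fixed = TRUE)) return(template)
  out <- gsub("{name}", participant_name, template, fixed = TRUE)
  if (grepl("\\{[a-z_]+\\}", out))
    stop("unresolved placeholder in template: ", out, call. = FALSE)
  out
}

#' Write / read a protocol configuration file
#'
#' The configuration (including all prompt scripts and questionnaire items)
#' is serialized as YAML; `read_protocol_config()` validates on load, so a
#' round trip reproduces the configuration exactly.
#'
#' @param config An `ema_config` object.
#' @param path File path.
#' @return `read_protocol_config()` returns a validated `ema_config`.
#' @export
write_protocol_config <- function(config, path) {
  validate_config(config)
  x <- unclass(config)
  x$smfq_anchors <- as.list(x$smfq_anchors)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_protocol_config
#' @export
read_protocol_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  x <- yaml::read_yaml(path)
  known <- names(formals(protocol_config))
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop("unknown configuration field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (!is.null(x$smfq_anchors)) x$smfq_anchors <- unlist(x$smfq_anchors)
  do.call(protocol_config, x)
}
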