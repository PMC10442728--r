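cfg <- protocol_config()
sched <- build_schedule(cfg)

test_that("classify_reply implements the exact-match rules", {
  k <- function(body, ctx = NULL) classify_reply(chat_message(body), ctx, cfg)$kind

  # closure vocabulary, after normalization (case, trailing punctuation)
  expect_identical(k("thank you"), "CLOSURE")
  expect_identical(k("Thanks!!"), "CLOSURE")
  expect_identical(k("  OK."), "CLOSURE")
  expect_identical(k("see you"), "CLOSURE")
  # emoji-only replies close the conversation too (configurable)
  expect_identical(k(":thumbs_up:"), "CLOSURE")
  cfg2 <- protocol_config(emoji_closure = FALSE)
  expect_identical(classify_reply(chat_message(":thumbs_up:"), NULL, cfg2)$kind,
                   "FREE_TEXT")

  # questionnaire context
  expect_identical(k("1", "item"), "NUMERIC_ANSWER")
  expect_identical(classify_reply(chat_message("2"), "item", cfg)$value, 2L)
  expect_identical(k("maybe", "item"), "UNSUPPORTED")
  expect_identical(k("five", "item"), "UNSUPPORTED")
  expect_identical(k("correct", "item"), "CORRECTION_REQUEST")

  # yes/no gates
  expect_identical(k("Yes", "yesno"), "YES")
  expect_identical(k("nope", "yesno"), "NO")
  expect_identical(k("dunno", "yesno"), "UNSUPPORTED")

  # audio payloads carry duration; free text in an audio slot is unsupported
  a <- classify_reply(chat_message("[rec]", "audio", 42), "audio", cfg)
  expect_identical(a$kind, "AUDIO")
  expect_identical(a$duration, 42)
  expect_identical(k("it was fun", "audio"), "UNSUPPORTED")

  # snooze requests, with and without a time
  s <- classify_reply(chat_message("snooze 22:15"), "availability", cfg)
  expect_identical(s$kind, "SNOOZE_REQUEST")
  expect_identical(s$value, "22:15")
  expect_null(classify_reply(chat_message("snooze"), "availability", cfg)$value)

  expect_identical(k("hello there"), "FREE_TEXT")
})

test_that("typing delay is proportional to length within clamps", {
  expect_identical(typing_delay(0, cfg), 0.5)
  expect_identical(typing_delay(40, cfg), 2.5)   # 0.5 + 0.05 * 40
  # linear term doubles with length inside the clamps
  expect_equal(typing_delay(80, cfg) - 0.5, 2 * (typing_delay(40, cfg) - 0.5))
  expect_identical(typing_delay(1e6, cfg), 6)    # cap
})

test_that("audio accumulation triggers the documented probe ladder", {
  plan <- sched[[2]]  # day 1
  cy <- new_cycle(plan, as.Date("2021-09-02"))

  # 25 + 20 = 45 s < 60 s after the two primary questions -> first probe
  cy$audio_seconds <- 25
  r <- accumulate_audio(cy, 20, cfg)
  expect_identical(r$decision, "followup1")
  expect_identical(r$cycle$audio_seconds, 45)

  # 40 + 30 = 70 s >= 60 s -> no probe
  cy2 <- new_cycle(plan, as.Date("2021-09-02"))
  cy2$audio_seconds <- 40
  expect_identical(accumulate_audio(cy2, 30, cfg)$decision, "complete")

  # 10 + 10, then 20 after probe 1 -> probe 2 (yes/no gated)
  cy3 <- new_cycle(plan, as.Date("2021-09-02"))
  cy3$audio_seconds <- 10
  r <- accumulate_audio(cy3, 10, cfg)
  expect_identical(r$decision, "followup1")
  r$cycle$followups_sent <- 1L
  r <- accumulate_audio(r$cycle, 20, cfg)
  expect_identical(r$decision, "followup2")
  expect_identical(r$cycle$audio_seconds, 40)
  # after the second probe the ladder is exhausted whatever the total
  r$cycle$followups_sent <- 2L
  expect_identical(accumulate_audio(r$cycle, 5, cfg)$decision, "complete")

  expect_error(accumulate_audio(cy, -3, cfg), "non-negative")
})

test_that("short recordings walk the full probe ladder; 90 s days never probe", {
  # constant 15 s: q1+q2 = 30 < 60 -> probe 1; +15 = 45 < 60 -> probe 2
  # (yes/no gate); gate "no" -> cycle completes at 45 s.
  res <- run_with_session(compliant_source(audio = 15, gate_fu2 = "no"))
  ev <- res$events
  fu1 <- sum(grepl("Tell us a little bit more", ev$body))
  fu2 <- sum(grepl("very important if you could tell us", ev$body))
  expect_identical(fu1, 7L)  # one per audio day
  expect_identical(fu2, 7L)
  for (d in c(1, 3, 5, 7, 9, 11, 13)) {
    expect_identical(res$session$cycles[[as.character(d)]]$clock$status,
                     "COMPLETED")
    expect_identical(res$session$cycles[[as.character(d)]]$followups_sent, 2L)
    expect_identical(res$session$cycles[[as.character(d)]]$audio_seconds, 45)
  }

  # constant 90 s: target met on the primary answers, no probes at all
  res <- run_with_session(compliant_source(audio = 90))
  expect_identical(sum(grepl("Tell us a little bit more", res$events$body)), 0L)
  expect_identical(sum(grepl("very important", res$events$body)), 0L)
})

test_that("at most two follow-up probes per audio day over random streams", {
  set.seed(99)
  for (rep in seq_len(20)) {
    src <- compliant_source(
      audio = function(slot, day) round(stats::rlnorm(1, log(15), 0.8), 1),
      gate_fu2 = if (rep %% 2) "yes" else "no")
    res <- run_with_session(src)
    for (d in c(1, 3, 5, 7, 9, 11, 13)) {
      cyc <- res$session$cycles[[as.character(d)]]
      expect_lte(cyc$followups_sent, 2L)
      expect_identical(cyc$clock$status, "COMPLETED")
      # completion is only ever reached with the target met or the ladder
      # exhausted
      expect_true(cyc$audio_seconds >= 60 || cyc$followups_sent > 0L)
    }
  }
})

test_that("onboarding activates once and flags day 0 as excluded", {
  acc <- emachat:::new_event_acc()
  s <- new_session("p1", "Ana")
  r <- run_onboarding(s, chat_message("hi"), noon_ts(DAY0), cfg, sched, acc)
  expect_false(is.null(r$session$onboarded_at))
  ev <- emachat:::acc_events(acc)
  expect_true(all(ev$excluded))
  expect_true(all(ev$day_index == 0L))
  expect_gte(sum(ev$direction == "outbound"), 2L)
  expect_match(paste(ev$body, collapse = " "), "not listened")

  # a second activation message is treated as unprompted, not re-onboarding
  acc2 <- emachat:::new_event_acc()
  r2 <- run_onboarding(r$session, chat_message("hi"), noon_ts(DAY0) + 60,
                       cfg, sched, acc2)
  expect_identical(r2$session$onboarded_at, r$session$onboarded_at)
  ev2 <- emachat:::acc_events(acc2)
  expect_false(any(ev2$excluded))
  expect_true(all(is.na(ev2$day_index)))
})

test_that("unprompted messages follow the audio/closure/clarification rules", {
  s <- new_session("p1", "Ana")
  s$onboarded_at <- noon_ts(DAY0)

  acc <- emachat:::new_event_acc()
  handle_unprompted(s, chat_message("[rec]", "audio", 30), noon_ts(DAY0) + 10,
                    cfg, acc)
  ev <- emachat:::acc_events(acc)
  expect_identical(ev$kind, c("audio", "text"))
  expect_match(ev$body[2], "Thank you for sending this audio")

  # closure word: logged silently, no probe
  acc <- emachat:::new_event_acc()
  handle_unprompted(s, chat_message("ok"), noon_ts(DAY0) + 20, cfg, acc)
  ev <- emachat:::acc_events(acc)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$kind, "acknowledgment")
  expect_identical(ev$direction, "inbound")

  # free text: a single clarification requesting an audio message
  acc <- emachat:::new_event_acc()
  handle_unprompted(s, chat_message("i had a weird day"), noon_ts(DAY0) + 30,
                    cfg, acc)
  ev <- emachat:::acc_events(acc)
  expect_identical(sum(ev$direction == "outbound"), 1L)
  expect_match(ev$body[ev$direction == "outbound"], "audio message")
})

test_that("day 3 branches on the yes/no gate", {
  res <- run_with_session(compliant_source(audio = 90, gate_day3 = "yes"))
  d3 <- res$events[!is.na(res$events$day_index) & res$events$day_index == 3, ]
  expect_true(any(grepl("What are you doing", d3$body)))
  expect_false(any(grepl("Who do you live with", d3$body)))

  res <- run_with_session(compliant_source(audio = 90, gate_day3 = "no"))
  d3 <- res$events[!is.na(res$events$day_index) & res$events$day_index == 3, ]
  expect_true(any(grepl("Who do you live with", d3$body)))
})

test_that("text in an audio slot is gently reprompted then kept as data", {
  # day 1: availability, then text where audio expected (reprompt), text
  # again (accepted as free-text), then audio for q2 meeting the target
  src <- scripted_source(list(
    "hi",                                  # activation
    "ready",                               # day-1 availability
    "i would rather type",                 # q1 -> gentle reprompt
    "typing anyway",                       # q1 accepted as free text
    chat_message("[rec]", "audio", 70)     # q2 -> target met, complete
  ))
  res <- run_with_session(src)
  ev <- res$events
  expect_true(any(grepl("send it as an audio message", ev$body)))
  cyc <- res$session$cycles[["1"]]
  expect_identical(cyc$clock$status, "COMPLETED")
  expect_identical(cyc$audio_seconds, 70)
  # the typed answer is in the log as an inbound text data point
  expect_true(any(ev$direction == "inbound" & ev$kind == "text" &
                    ev$body == "typing anyway" & ev$day_index == 1))
})

test_that("an ignored day expires with a single 10:00 notice", {
  src <- scripted_source(list("hi"))  # activates, then never replies
  res <- run_with_session(src)
  ev <- res$events
  d1 <- ev[!is.na(ev$day_index) & ev$day_index == 1, ]
  notices <- d1[d1$kind == "expiry_notice", ]
  expect_identical(nrow(notices), 1L)
  tod <- notices$ts - as.numeric(as.Date("2021-09-03")) * 86400
  # the notice goes out at 10:00 plus its typing delay (< 10 s)
  expect_gte(tod, 10 * 3600)
  expect_lt(tod, 10 * 3600 + 10)
  expect_identical(res$session$cycles[["1"]]$clock$status, "EXPIRED")
  # prompts: 13:30 first + reminders every 3 h, none after 06:00
  prompts <- d1[d1$direction == "outbound" & d1$kind == "text", ]
  expect_identical(nrow(prompts), 6L)  # 13:30,16:30,19:30,22:30,01:30,04:30
})

test_that("replaying a log reconstructs the event stream exactly", {
  set.seed(4)
  src <- compliant_source(
    audio = function(slot, day) round(stats::rlnorm(1, log(25), 0.6), 1),
    item_answer = function(cursor, day) sample(0:2, 1))
  res <- run_with_session(src)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_event_log(res$events, f1)
  rg <- replay_log(read_event_log(f1), cfg, sched)
  write_event_log(rg, f2)
  expect_identical(readLines(f1), readLines(f2))
})
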