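test_that("profiles are validated", {
  expect_error(respondent_profile(p_engage = 1.2), "p_engage")
  expect_error(respondent_profile(mood_rho = 1), "mood_rho")
  expect_error(respondent_profile(mood_sigma = 0), "mood_sigma")
  expect_error(respondent_profile(thresholds = c(2, 1)), "thresholds")
})

test_that("identical (n, profile, seed) give byte-identical logs", {
  p <- respondent_profile()
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_event_log(simulate_cohort(6, p, seed = 11), f1)
  write_event_log(simulate_cohort(6, p, seed = 11), f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed gives a different log
  f3 <- withr::local_tempfile()
  write_event_log(simulate_cohort(6, p, seed = 12), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("per-participant streams are stable under cohort growth", {
  p <- respondent_profile()
  small <- simulate_cohort(4, p, seed = 5)
  big <- simulate_cohort(8, p, seed = 5)
  small_ids <- sprintf("p%04d", 1:4)
  attr(small, "eligible_ids") <- NULL
  attr(big, "eligible_ids") <- NULL
  expect_identical(small, big[big$participant_id %in% small_ids, ])
})

test_that("full engagement yields 100% compliance", {
  p <- respondent_profile(p_accept = 1, p_dropout_after_day0 = 0,
                          p_engage = 1, p_unprompted_audio = 0)
  ev <- simulate_cohort(10, p, seed = 3)
  expect_identical(compute_compliance(ev)$percentage, 100)
  expect_identical(engagement_report(ev)$full_completion_pct, 100)
})

test_that("degenerate audio distributions produce the expected probe traces", {
  # point mass at 90 s: the target is met on the primary answers every day
  p90 <- respondent_profile(p_accept = 1, p_dropout_after_day0 = 0,
                            p_engage = 1, p_snooze = 0, p_closure = 0,
                            p_unprompted_audio = 0,
                            audio_meanlog = log(90), audio_sdlog = 1e-9)
  ev <- simulate_cohort(2, p90, seed = 9)
  expect_identical(sum(grepl("Tell us a little bit more", ev$body)), 0L)

  # point mass at 20 s: 20+20 = 40 < 60 triggers probe 1; its answer brings
  # the total to exactly the 60 s target, so probe 2 is never reached
  p20 <- respondent_profile(p_accept = 1, p_dropout_after_day0 = 0,
                            p_engage = 1, p_snooze = 0, p_closure = 0,
                            p_unprompted_audio = 0,
                            audio_meanlog = log(20), audio_sdlog = 1e-9)
  ev <- simulate_cohort(2, p20, seed = 9)
  expect_identical(sum(grepl("Tell us a little bit more", ev$body)), 14L)
  expect_identical(sum(grepl("very important if you could", ev$body)), 0L)

  # point mass at 15 s stays short at both checkpoints: both probes fire on
  # every audio day for every participant
  p15 <- respondent_profile(p_accept = 1, p_dropout_after_day0 = 0,
                            p_engage = 1, p_snooze = 0, p_closure = 0,
                            p_unprompted_audio = 0,
                            audio_meanlog = log(15), audio_sdlog = 1e-9)
  ev <- simulate_cohort(2, p15, seed = 9)
  expect_identical(sum(grepl("Tell us a little bit more", ev$body)), 14L)
  expect_identical(sum(grepl("very important if you could", ev$body)), 14L)
})

test_that("extreme latent moods pin the questionnaire answers", {
  p_low <- respondent_profile(mood_mu = -50, mood_sigma = 0.1,
                              item_noise_sd = 0.1)
  set.seed(1)
  expect_identical(sim_item_answer(p_low, -50), 0L)
  p_high <- respondent_profile(mood_mu = 50, mood_sigma = 0.1)
  expect_identical(sim_item_answer(p_high, 50), 2L)

  # end to end: a cohort with mood far below the lowest threshold answers 0
  # everywhere -> every questionnaire total is 0
  p <- respondent_profile(p_accept = 1, p_dropout_after_day0 = 0,
                          p_engage = 1, p_snooze = 0, p_unprompted_audio = 0,
                          mood_mu = -50, mood_sigma = 0.1, item_noise_sd = 0.1)
  ev <- simulate_cohort(1, p, seed = 2)
  answers <- ev$body[ev$direction == "inbound" & ev$kind == "text" &
                       grepl("^[012]$", ev$body)]
  expect_true(length(answers) == 7 * 13)
  expect_true(all(answers == "0"))
})

test_that("simulated logs validate against the transport schema", {
  ev <- simulate_cohort(4, respondent_profile(), seed = 21)
  f <- withr::local_tempfile()
  write_event_log(ev, f)
  back <- read_event_log(f)   # read_event_log validates every line
  expect_identical(nrow(back), nrow(ev))
  expect_true(all(back$kind %in% c("text", "audio", "state_transition",
                                   "snooze", "expiry_notice", "acknowledgment")))
  # per-participant timestamps are non-decreasing
  for (pid in unique(back$participant_id)) {
    expect_false(is.unsorted(back$ts[back$participant_id == pid]))
  }
})

test_that("no simulated prompt fires outside the scheduler's windows", {
  ev <- simulate_cohort(6, respondent_profile(p_accept = 1), seed = 31)
  # scheduler-initiated messages only: availability prompts, reminders,
  # snooze wake-ups and expiry notices (dialog continuations are replies)
  prompts <- ev[ev$direction == "outbound" &
                  (ev$kind == "expiry_notice" |
                     grepl("available to answer|checking in again|as promised",
                           ev$body)), ]
  tod <- prompts$ts %% 86400
  cycle_day <- as.numeric(as.Date("2021-09-01")) + prompts$day_index
  same_day <- floor(prompts$ts / 86400) == cycle_day
  open_s <- 13.5 * 3600
  close_s <- 6 * 3600
  notice_s <- 10 * 3600
  margin <- 30  # typing delays push a message a few seconds past the tick
  ok <- ifelse(prompts$kind == "expiry_notice",
               !same_day & tod >= notice_s & tod <= notice_s + margin,
               (same_day & tod >= open_s) | (!same_day & tod < close_s + margin))
  expect_true(all(ok))
})

test_that("questionnaire totals inherit the latent AR(1) autocorrelation", {
  # pooled (stacked-pairs) lag-1 autocorrelation of daily 13-item totals
  # across 500 participants x 14 days; thresholding attenuates the latent
  # rho by the totals' reliability (~0.9), so the pooled estimate must land
  # within 0.1 of rho
  p <- respondent_profile()
  set.seed(123)
  totals <- matrix(0, 500, 14)
  for (i in 1:500) {
    mood <- sim_mood_path(p, 14)
    for (d in 1:14) {
      totals[i, d] <- sum(vapply(1:13, function(j) sim_item_answer(p, mood[d]),
                                 integer(1)))
    }
  }
  x <- as.vector(totals[, 1:13])
  y <- as.vector(totals[, 2:14])
  expect_lt(abs(stats::cor(x, y) - p$mood_rho), 0.1)
})
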