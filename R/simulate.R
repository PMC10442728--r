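# Respondent behavior simulator. The simulator emulates the statistical
# structure the analytics layer assumes -- per-day engagement, response
# latency, snooze propensity, per-answer audio durations, and 0/1/2
# questionnaire answers driven by a latent AR(1) daily mood -- and drives the
# *real* engine and scheduler on the virtual clock. It is explicitly
# synthetic scaffolding: no attempt is made to model any real cohort's
# behavior beyond the published engagement rates.

#' Respondent behavior profile
#'
#' Parameters of one simulated respondent class. Defaults reproduce the
#' engagement levels observed in the first deployment wave of the protocol:
#' acceptance 80.7%, initial attrition 0.9%, daily engagement 91.4%, snooze
#' use on about 39% of participant-days, and roughly 65 s of audio per audio
#' day (two answers drawn from a lognormal with median 30 s).
#'
#' @param p_accept Probability of completing onboarding after invitation.
#' @param p_dropout_after_day0 Probability of never interacting again after
#'   day 0 (initial attrition).
#' @param p_engage Per-day probability of responding within the window.
#' @param p_snooze Per-day probability that the first prompt is snoozed.
#' @param p_closure Probability of sending a closure word after a completed
#'   day.
#' @param p_unprompted_audio Per-day probability of a spontaneous (morning)
#'   unprompted audio message.
#' @param latency_meanlog,latency_sdlog Lognormal response latency, minutes.
#' @param latency_cap Upper truncation of latency, minutes.
#' @param snooze_offset_meanlog,snooze_offset_sdlog Lognormal requested
#'   snooze delay, minutes.
#' @param audio_meanlog,audio_sdlog Lognormal per-answer audio duration,
#'   seconds.
#' @param mood_mu,mood_rho,mood_sigma Latent daily mood AR(1): mean,
#'   autocorrelation, innovation SD.
#' @param item_noise_sd SD of the per-item probit noise added to the latent
#'   mood before thresholding.
#' @param thresholds Strictly increasing thresholds mapping latent value to
#'   answers 0/1/2.
#' @return A validated `respondent_profile` list.
#' @export
respondent_profile <- function(p_accept = 0.807,
                               p_dropout_after_day0 = 0.009,
                               p_engage = 0.914,
                               p_snooze = 0.39,
                               p_closure = 0.5,
                               p_unprompted_audio = 0.05,
                               latency_meanlog = log(5),
                               latency_sdlog = 1,
                               latency_cap = 10,
                               snooze_offset_meanlog = log(180),
                               snooze_offset_sdlog = 0.5,
                               audio_meanlog = log(30),
                               audio_sdlog = 0.5,
                               mood_mu = 0,
                               mood_rho = 0.5,
                               mood_sigma = 1,
                               item_noise_sd = 0.8,
                               thresholds = c(-0.6, 1.4)) {
  p <- structure(as.list(environment()), class = "respondent_profile")
  for (f in c("p_accept", "p_dropout_after_day0", "p_engage", "p_snooze",
              "p_closure", "p_unprompted_audio")) {
    if (!is.numeric(p[[f]]) || p[[f]] < 0 || p[[f]] > 1)
      stop("invalid respondent profile: ", f, " must be in [0, 1]", call. = FALSE)
  }
  if (abs(p$mood_rho) >= 1)
    stop("invalid respondent profile: mood_rho must be in (-1, 1)", call. = FALSE)
  if (p$mood_sigma <= 0)
    stop("invalid respondent profile: mood_sigma must be > 0", call. = FALSE)
  if (length(p$thresholds) != 2L || diff(p$thresholds) <= 0)
    stop("invalid respondent profile: thresholds must be strictly increasing",
         call. = FALSE)
  if (p$latency_cap <= 0 || p$item_noise_sd <= 0)
    stop("invalid respondent profile: latency_cap and item_noise_sd must be > 0",
         call. = FALSE)
  p
}

#' Latent daily mood path
#'
#' Stationary AR(1): the initial value is drawn from the stationary
#' distribution, then `m_d = mu + rho (m_{d-1} - mu) + eps_d`.
#'
#' @param profile A [respondent_profile()].
#' @param n_days Number of days.
#' @return Numeric vector of daily latent moods.
#' @export
sim_mood_path <- function(profile, n_days) {
  s0 <- profile$mood_sigma / sqrt(1 - profile$mood_rho^2)
  m <- numeric(n_days)
  m[1] <- stats::rnorm(1, profile$mood_mu, s0)
  for (d in seq_len(n_days - 1L)) {
    m[d + 1L] <- profile$mood_mu + profile$mood_rho * (m[d] - profile$mood_mu) +
      stats::rnorm(1, 0, profile$mood_sigma)
  }
  m
}

#' Ordinal item answer from a latent mood value
#'
#' Ordered-threshold (probit-style) mapping: the item's latent value is the
#' daily mood plus item noise; the answer is the number of thresholds
#' exceeded (0, 1 or 2).
#'
#' @param profile A [respondent_profile()].
#' @param mood Latent mood value for the day.
#' @return Integer answer in 0..2.
#' @export
sim_item_answer <- function(profile, mood) {
  latent <- mood + stats::rnorm(1, 0, profile$item_noise_sd)
  sum(latent > profile$thresholds)
}

#' Simulated respondent message source
#'
#' Builds the message-source implementation (see [run_session()]) for one
#' simulated participant. All stochastic draws use the current RNG stream,
#' in a fixed order, so a seeded call is fully reproducible.
#'
#' @param profile A [respondent_profile()].
#' @param config An [protocol_config()].
#' @param start_date Calendar date of day 0.
#' @return A message source.
#' @export
sim_respondent <- function(profile, config = protocol_config(),
                           start_date = as.Date("2021-09-01")) {
  start_date <- as.Date(start_date)
  st <- new.env(parent = emptyenv())
  st$dropout <- FALSE
  st$mood <- NA_real_
  st$queue <- list()   # pending self-initiated messages (unprompted, closure)

  latency <- function() {
    max(1, round(60 * min(profile$latency_cap,
                          stats::rlnorm(1, profile$latency_meanlog,
                                        profile$latency_sdlog))))
  }
  push <- function(ts, msg) st$queue[[length(st$queue) + 1L]] <- list(ts = ts, msg = msg)

  list(
    activation = function() {
      if (stats::runif(1) >= profile$p_accept) return(NULL)
      st$dropout <- stats::runif(1) < profile$p_dropout_after_day0
      st$mood <- profile$mood_mu +
        stats::rnorm(1) * profile$mood_sigma / sqrt(1 - profile$mood_rho^2)
      ts <- at_time(start_date, "12:00") + round(stats::runif(1, 0, 6 * 3600))
      list(ts = ts, msg = chat_message("hi"))
    },
    begin_day = function(d, cycle) {
      st$mood <- profile$mood_mu + profile$mood_rho * (st$mood - profile$mood_mu) +
        stats::rnorm(1, 0, profile$mood_sigma)
      st$engage <- stats::runif(1) < profile$p_engage
      st$snooze <- stats::runif(1) < profile$p_snooze
      st$snooze_used <- FALSE
      if (st$snooze)
        st$snooze_offset <- 60 * stats::rlnorm(1, profile$snooze_offset_meanlog,
                                               profile$snooze_offset_sdlog)
      if (!st$dropout && stats::runif(1) < profile$p_unprompted_audio) {
        ts <- at_time(cycle$cycle_date, "10:00") + round(stats::runif(1, 0, 2 * 3600))
        dur <- round(stats::rlnorm(1, profile$audio_meanlog, profile$audio_sdlog), 1)
        push(ts, chat_message("[unprompted audio]", "audio", dur))
      }
    },
    unprompted_before = function(t) {
      if (!length(st$queue)) return(NULL)
      ts <- vapply(st$queue, `[[`, 0, "ts")
      k <- which.min(ts)
      if (ts[k] >= t) return(NULL)
      out <- st$queue[[k]]
      st$queue[[k]] <- NULL
      out
    },
    reply = function(cycle, session, now, horizon) {
      if (st$dropout) return(NULL)
      aw <- cycle$awaiting
      if (is.null(aw)) return(NULL)
      if (aw == "availability") {
        if (st$snooze && !st$snooze_used) {
          st$snooze_used <- TRUE
          req <- now + st$snooze_offset
          hm <- format(as.POSIXct(req, origin = "1970-01-01", tz = "UTC"), "%H:%M")
          return(list(ts = now + latency(),
                      msg = chat_message(paste("snooze", hm))))
        }
        if (!st$engage) return(NULL)
        return(list(ts = now + latency(), msg = chat_message("I'm here!")))
      }
      if (!st$engage) return(NULL)
      ts <- now + latency()
      msg <- switch(aw,
        item = chat_message(as.character(sim_item_answer(profile, st$mood))),
        yesno = chat_message(if (stats::runif(1) < 0.5) "yes" else "no"),
        audio = chat_message("[audio answer]", "audio",
                             round(stats::rlnorm(1, profile$audio_meanlog,
                                                 profile$audio_sdlog), 1)),
        chat_message("ok"))
      list(ts = ts, msg = msg)
    },
    on_complete = function(cycle, now) {
      if (stats::runif(1) < profile$p_closure)
        push(now + latency(), chat_message("thank you"))
    }
  )
}

#' Simulate a cohort through the full protocol
#'
#' Runs `n` independent simulated participants through the real engine and
#' scheduler. Each participant's pseudo-random stream is derived from
#' `(seed, participant index)`, so enlarging the cohort never perturbs the
#' trajectories of existing participants, and identical `(n, profile, seed)`
#' yield byte-identical event logs.
#'
#' @param n Number of participants (all are "eligible"; whether each
#'   activates the chatbot is governed by `profile$p_accept`).
#' @param profile A [respondent_profile()].
#' @param config An [protocol_config()].
#' @param schedule A [build_schedule()] schedule.
#' @param seed Integer master seed.
#' @param start_date Calendar date of day 0.
#' @return The cohort event `data.frame` (attribute `eligible_ids` carries
#'   all generated participant ids, including never-activated ones).
#' @export
#' @examples
#' ev <- simulate_cohort(3, respondent_profile(p_accept = 1), seed = 42)
#' table(ev$direction)
simulate_cohort <- function(n, profile = respondent_profile(),
                            config = protocol_config(),
                            schedule = build_schedule(config),
                            seed = 1L, start_date = as.Date("2021-09-01")) {
  stopifnot(n >= 1)
  acc <- new_event_acc()
  ids <- sprintf("p%04d", seq_len(n))
  for (i in seq_len(n)) {
    set.seed(participant_seed(seed, i))
    src <- sim_respondent(profile, config, start_date)
    run_session(src, ids[i], name = ids[i], config = config,
                schedule = schedule, start_date = start_date, acc = acc)
  }
  ev <- acc_events(acc)
  attr(ev, "eligible_ids") <- ids
  ev
}

#' @noRd
participant_seed <- function(seed, i) {
  (as.integer(seed) %% 100000L) * 20011L + i * 7919L
}
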