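---
title: "emachat: protocol engine, behavior simulator and engagement analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{emachat: protocol engine, behavior simulator and engagement analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emachat)
```

## What this package is

`emachat` is a re-implementation, as a tested engine, of a rule-based chatbot
protocol for 15-day intensive longitudinal mood assessment in adolescents:
time-contingent daily prompts delivered over a chat transport, open audio
questions on alternating days, a day-framed 13-item mood questionnaire on the
remaining days, snooze and reminder handling, and the cohort-level usability
indicators (acceptance, initial attrition, compliance, audio volume) used to
evaluate such deployments.

The package contains no messaging-platform integration. The transport is an
adapter contract (`mock_transport()` implements it); persistence is an
append-only JSONL event log; and time is always injected (a *virtual clock*),
so the full multi-day protocol runs deterministically in milliseconds of test
time. A real deployment would supply a real transport and a wall clock behind
the same interfaces.

## The protocol model

A protocol run for one participant is one onboarding day plus 14 scorable
daily cycles:

* **Day 0 (onboarding).** Any first inbound message activates the bot, which
  reviews its functionality, states that audio is not listened to
  immediately, and that it is not a help channel. Day-0 events carry an
  `excluded` flag: they are logged for auditability but dropped from every
  indicator.
* **Daily cycle (days 1-14).** The first prompt goes out at 13:30 local
  time; unanswered prompts repeat every 3 h. The participant may *snooze*
  to any time up to 03:00 of the next day (later requests are clamped to
  that limit, not rejected). Responses are accepted in the half-open window
  [13:30, 06:00) of the next morning; at 10:00 an expiry notice closes any
  unfinished cycle. Each cycle therefore reaches exactly one terminal state,
  `COMPLETED` or `EXPIRED`, before 10:00 the following day.
* **Audio days (1, 3, 5, 7, 9, 11, 13).** Two scripted open questions about
  daily life; answers are audio recordings (the engine stores duration only,
  never content). If the two answers total less than the 60 s daily target,
  up to two standard follow-up probes are sent, the second gated by a typed
  yes/no. Day 3's first question branches on a yes/no reply ("Are you at
  home?") — the only scripted branch.
* **Questionnaire days (2, 4, ..., 14).** Thirteen day-framed mood
  statements answered by typing 0, 1 or 2. Every item prompt repeats the
  anchor meanings (0 = no, 1 = sometimes, 2 = yes) — a fix that emerged from
  piloting. A configured keyword ("correct"/"fix") opens a short correction
  dialog naming the item to change. The total score is the sum, 0-26.
* **Closure and unprompted traffic.** A reply drawn from a configured
  closure vocabulary ("ok", "thanks", ... or an emoji-only message) closes
  the conversation without triggering a probe. Unprompted audio at any time
  is acknowledged and logged; unprompted free text receives one
  clarification asking for audio.

The wording shipped for the questionnaire items is deliberately generic
placeholder text; research deployments substitute the licensed instrument.
All prompts, including the audio-day scripts, are configuration data
(`write_protocol_config()` / `read_protocol_config()`), not code.

### Timing parameters

| parameter | default | meaning |
|---|---|---|
| `first_prompt_time` | 13:30 | first daily prompt (moved from 10:30 after piloting) |
| `reminder_interval` | 180 min | spacing of repeat prompts while unanswered |
| `snooze_limit_time` | 03:00 (+1 d) | latest allowed snooze wake-up; later requests clamp |
| `response_window_end` | 06:00 (+1 d) | response window close (half-open) |
| `expiry_notice_time` | 10:00 (+1 d) | expiry notice for unfinished cycles |
| `audio_target` | 60 s | daily audio target over the two primary answers |
| `typing_base`, `typing_rate`, `typing_max` | 0.5 s, 0.05 s/char, 6 s | outbound typing delay `base + rate × nchar`, clamped |

Numerical conventions worth stating: the response window is half-open
(06:00:00 itself is outside), because the source material says only "until
6 AM" and half-open intervals avoid double-counting at the boundary; a
dialog begun inside the window is allowed to finish past 06:00 (grace
continuation) rather than being truncated mid-questionnaire; reminders are
suppressed while snoozed (the snooze replaces the reminder train); and a
reminder that would fall after the window close is replaced by the expiry
notice. All times are local wall times in one deployment time zone; the
engine does no DST arithmetic.

## Event sourcing and determinism

Every message and state change is one JSONL line: timestamp (ISO-8601 with
zone offset), participant, direction (`inbound`/`outbound`/`system`), kind
(`text`, `audio`, `snooze`, `acknowledgment`, `expiry_notice`,
`state_transition`), body, optional audio duration, day index, excluded
flag. Inbound closure messages are logged as `acknowledgment` so analytics
can distinguish them from data points without re-parsing text; terminal
cycle transitions are logged as `system`/`state_transition` events.

Because the scheduler and the dialog engine are deterministic functions of
the inbound messages and the clock, a log can be *replayed*:
`replay_log()` re-runs the engine against only the inbound half of a log and
regenerates every outbound and system event byte-for-byte. The test suite
uses this round trip as the integrity check of the whole engine.

## The respondent simulator

`simulate_cohort()` drives the real engine (never a shortcut path) with
simulated participants. Per participant, the random stream is seeded from
`(master seed, participant index)`, so enlarging a cohort never changes
existing trajectories, and identical inputs give byte-identical logs.

A `respondent_profile()` states the behavioral world:

* `p_accept = 0.807`, `p_dropout_after_day0 = 0.009`, `p_engage = 0.914`,
  `p_snooze = 0.39` — the first deployment wave's printed engagement rates
  (acceptance 113/140, attrition 1/113, compliance 91.4%, 609 snooze uses
  over 112 × 14 participant-days).
* Audio durations per answer are lognormal, `meanlog = log(30)`,
  `sdlog = 0.5` (mean ≈ 34 s), giving roughly 65-70 s of prompted audio per
  audio day — the published per-day volume.
* Response latencies and requested snooze delays are lognormal in minutes
  (medians 5 min and 3 h). These are not published quantities; they were
  chosen once as plausible for adolescents answering on their phones and
  are not calibrated further.
* Questionnaire answers come from a latent daily mood: a stationary AR(1)
  process (`mu = 0`, `rho = 0.5`, `sigma = 1`) mapped to each 0/1/2 answer
  by an ordered-probit rule — item value `mood + N(0, 0.8²)` cut at
  thresholds `(-0.6, 1.4)`.

### Why those thresholds

The threshold geometry was derived, not tuned by eye. Two constraints: (a)
simulated totals should have a realistic level for *this* population — the
cohort is risk-enriched, with a third of participants in a current
depressive episode, so a mean total near 10 of 26 is reasonable where a
floor-hugging 3 of 26 would not be; (b) the totals must inherit the latent
day-to-day autocorrelation to within 0.1, the package's stated consistency
property. Discretizing a Gaussian AR(1) through thresholds attenuates lag-1
correlation by more than the classical reliability ratio, because the
nonlinear threshold map pushes variance into higher Hermite components whose
correlation decays as ρ^k. A numeric scan of pooled lag-1 correlation over
threshold placement and item noise shows the attenuated value is ≈ 0.92 × ρ
at `(-0.6, 1.4)` with noise 0.8 (pooled r ≈ 0.46 for ρ = 0.5), against
≈ 0.82 × ρ for tail-heavy thresholds — which would sit exactly on the 0.1
boundary. The test suite estimates the autocorrelation by pooling the
500 × 13 adjacent-day pairs rather than averaging per-participant ACFs: at
14 time points the per-series estimator carries an O(1/n) bias of about
−0.18, larger than the tolerance itself.

### What the simulator does and does not establish

The simulator reproduces the *rates* the analytics consume — engagement,
snooze propensity, audio volume, answer marginals and their day-to-day
dependence. It does not model content (audio is a duration, text is a
token), circadian response-time structure, weekday effects, learning or
fatigue across the 15 days, or any real participant's behavior. A green
simulation-based test therefore establishes that the engine, scheduler, log
and metrics are mutually consistent and correctly calibrated — not that the
behavioral model is true.

## Usability indicators

From a set of logs (and the eligible-id list), `engagement_report()`
computes:

* **acceptance** — share of eligible participants with a day-0 interaction;
* **initial attrition** — share of onboarded participants with no
  non-excluded inbound event after day 0;
* **compliance** — mean engaged days / 14, where an engaged day has at
  least one *data point*: a non-excluded inbound text or audio response.
  Closure acknowledgments and snooze requests alone do not count. The
  denominator is fixed at 14 because the published arithmetic (12.8 of 14
  possible days = 91.4%) fixes it, even though the indicator is described
  as "over the 15 days" — day 0 is excluded by design;
* **full completion** — share of onboarded participants with data on every
  scorable day;
* **audio volume** — mean seconds per participant-day with audio
  (unprompted audio counts here, though it never counts toward the 60 s
  in-cycle target, which is defined over the two daily questions), and mean
  total minutes per participant;
* **snooze usage** — request count, and completions attributed per cycle
  (a cycle with ≥ 1 snooze that reached `COMPLETED`), the reading adopted
  for the ambiguous published "609 uses, 331 completed interactions".

Percentages are rounded half-up to one decimal, matching the reporting
style of the source deployment.

## Design choices where the ground was open

* **Questionnaire day placement.** The audio days are fixed by the
  published day scripts (1, 3, ..., 13); the questionnaire occupies "the
  days without audio prompts", so even days 2-14 are the only consistent
  deterministic arrangement. Standalone mood-rating days are mentioned in
  the source material but never scheduled; a `MOOD_RATING` mode exists in
  the enum and is deliberately left unscheduled.
* **Closure vocabulary.** The published fix names "ok", "see you",
  "thank you" "or variations"; the full list was never published. The
  default set adds obvious variants (okay, bye, thanks, thx) and is
  configurable; matching is exact after normalization (lowercase, trim,
  strip terminal punctuation), never fuzzy. Emoji-only replies count as
  closure (the pilot problem was triggered by "thanking it or sending an
  emoji") but this is switchable.
* **Text where audio is expected** gets one gentle reprompt, then is kept
  as a free-text data point (it counts toward engagement, never toward
  audio seconds). Participant data is never discarded.
* **Snooze between 03:00 and 06:00.** A reminder due in that interval
  after a late snooze is sent (it is inside the response window); the
  source is silent on this corner.
* **Corrections after completion.** The correction dialog is available
  until the 13th answer closes the cycle; because completion is immediate,
  a later "correct" falls through to the unprompted handler. The
  alternative (holding the cycle open) would conflict with the cycle
  reaching its terminal state at the moment the form is complete.
* **Audio-probe arithmetic.** Follow-up answers count toward the daily
  total, and the cycle completes as soon as the total reaches the target —
  so a constant-20 s respondent (20+20 → probe 1; +20 = 60) sees exactly
  one probe. The probe ladder is exercised end-to-end in tests with
  streams that stay short at every checkpoint.

## Worked example

```{r, eval = FALSE}
library(emachat)
cfg <- protocol_config()
profile <- respondent_profile()           # wave-2 engagement world
ev <- simulate_cohort(140, profile, cfg, seed = 1)
engagement_report(ev, attr(ev, "eligible_ids"))
```

The same run is available from a shell:

```sh
emachat simulate --n 140 --seed 1 --out runs/demo
emachat report --logs runs/demo
```

`scripts/acceptance.R --seed <s> --out <path>` recomputes the protocol's
structural quantities (audio-day count in the default schedule; item prompts
per questionnaire cycle for a fully compliant respondent) by building the
schedule and running a simulated session, and writes them as JSON.

## Known limitations

* Single time zone, no DST arithmetic; wall-clock times are taken at face
  value.
* The engine models one conversation per participant; concurrent
  multi-device traffic and message-ordering failures of a real platform are
  out of scope (the transport contract requires per-participant ordering).
* No content understanding: classification is exact-match by design, as in
  the deployed system; anything unexpected falls into reprompt/clarify
  paths.
* The behavior simulator is synthetic scaffolding (see above), not a fitted
  model of the source cohort.
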