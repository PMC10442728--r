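# emachat

A rule-based, transport-agnostic chatbot engine for **15-day intensive
longitudinal mood assessment** (ecological momentary assessment, EMA) in
adolescents, with a deterministic virtual-clock scheduler, a respondent
behavior simulator, and an analytics layer for the usability indicators used
to judge such deployments.

It is aimed at digital mental-health researchers who want to test, adapt or
power an EMA chat protocol without touching a real messaging platform: the
engine is pure logic behind a transport adapter and an append-only JSONL
event log, so every run — including a full simulated cohort — is
reproducible to the byte.

## The protocol

One onboarding day (day 0, excluded from analysis) plus 14 scorable daily
cycles. Each cycle: first prompt at 13:30, reminders every 3 h while
unanswered, snooze allowed up to 03:00 of the next day, responses accepted
in the half-open window [13:30, 06:00), expiry notice at 10:00. Odd days
carry two scripted open questions answered by audio, with a 60 s daily
target and up to two follow-up probes on shortfall (the second gated by a
typed yes/no). Even days administer a 13-item day-framed mood questionnaire
answered by typing 0/1/2, every prompt repeating the anchors
(0 = no, 1 = sometimes, 2 = yes), with an answer-correction dialog.
Replies matching a closure vocabulary ("ok", "thanks", emoji-only, ...)
close the conversation without triggering a probe.

The cohort indicators computed from event logs are

- **acceptance** = onboarded / eligible,
- **initial attrition** = onboarded participants with no interaction after
  day 0,
- **compliance** = mean engaged days / 14, an engaged day being one with at
  least one data point (inbound text or audio; closures alone do not
  count),

plus full-completion rate, audio volume (s/day and min/participant) and
snooze usage.

## Worked example

```r
library(emachat)

cfg     <- protocol_config()          # 13:30 prompts, 3 h reminders, 60 s target...
profile <- respondent_profile()       # published wave-level engagement rates
ev      <- simulate_cohort(140, profile, cfg, seed = 1)

engagement_report(ev, attr(ev, "eligible_ids"))
#> <engagement_report>
#>   eligible                 140
#>   onboarded (acceptance)   115 (82.1%)
#>   initial attrition        0 (0.0%)
#>   engaged days (of 14)     mean 12.71 (SD 0.96)
#>   compliance               90.8%
#>   full completion          20.9%
#>   audio per audio-day      84.7 s
#>   audio total per person   9.2 min
#>   snooze uses/completed    623 / 559
```

Reading it: of 140 invited (simulated) adolescents, 115 activated the bot
(the profile's acceptance probability is 0.807); none dropped out right
after onboarding in this draw; the continuing participants produced data on
12.71 of 14 scorable days — a 90.8% compliance rate, matching the profile's
per-day engagement probability of 0.914 up to binomial noise; and they sent
about 85 s of audio on each day with any audio. Identical
`(n, profile, seed)` always reproduce this table exactly.

The same engine can be driven interactively or from a shell via the bundled
wrapper (`inst/cli/emachat`): `simulate`, `report`, `chat` (a console
walk-through of the protocol on an accelerated clock) and
`validate-config`. Event logs are plain JSONL, one event per line;
`replay_log()` regenerates all outbound traffic from the inbound half of a
log, which is the package's integrity check of its own determinism.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package, the protocol's
structural quantities: it builds the default schedule and counts the
audio-question days, and runs a fully compliant simulated respondent
through the protocol to count the questionnaire item prompts emitted in one
cycle, writing both as JSON.

## Layout

- `R/` — protocol/config, scheduler, dialog engine, JSONL transport & log,
  session runner + replay, simulator, analytics, command entry points
- `tests/testthat/` — unit, property and acceptance suites
- `vignettes/emachat-methods.Rmd` — the model, its assumptions, parameter
  derivations and design decisions
- `inst/extdata/` — example protocol configuration and simulation scenario
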