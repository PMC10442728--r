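Package: emachat
Title: Rule-Based Chatbot Engine for Intensive Longitudinal Mood Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A messaging-platform-agnostic engine for running a 15-day
    ecological momentary assessment (EMA) protocol over a chat transport:
    a deterministic virtual-clock scheduler (time-contingent daily prompts,
    3-hour reminders, snooze, response-window closure), a rule-based dialog
    state machine (audio-question days with a 60-second audio target and
    follow-up probes, day-framed 13-item mood questionnaire with 0/1/2
    anchors and answer correction, closure-word handling, unprompted audio),
    an append-only JSONL event log, a respondent behavior simulator driven
    by a latent AR(1) daily mood process, and an analytics layer computing
    cohort usability indicators (acceptance, initial attrition, compliance,
    audio volume, snooze usage).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
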