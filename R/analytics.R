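# Cohort usability indicators computed from event logs. Conventions:
#  * "data point" = a non-excluded inbound response of kind text or audio
#    (numeric answers, yes/no, free text, recordings); closure
#    acknowledgments and snooze requests alone do not count.
#  * day 0 is excluded everywhere; the compliance denominator is the 14
#    scorable days (the published arithmetic, 12.8/14 = 91.4%, fixes the
#    denominator even though the indicator is described "over the 15 days").
#  * percentages are rounded half-up to 1 decimal, the reporting convention.

#' @noRd
onboarded_ids <- function(logs) {
  unique(logs$participant_id[logs$direction == "inbound" &
                               !is.na(logs$day_index) & logs$day_index == 0L])
}

#' @noRd
data_points <- function(logs) {
  logs[logs$direction == "inbound" & logs$kind %in% c("text", "audio") &
         !logs$excluded & !is.na(logs$day_index) & logs$day_index >= 1L, ,
       drop = FALSE]
}

#' Acceptance: eligible participants who activated the chatbot
#'
#' A participant "accepted" if their log contains a day-0 (onboarding)
#' inbound interaction.
#'
#' @param eligible_ids Character vector of invited/eligible participant ids.
#' @param logs Event `data.frame` (see [read_event_log()]).
#' @return List with `count` and `percentage` (1 decimal, of eligible).
#' @export
compute_acceptance <- function(eligible_ids, logs) {
  stopifnot(length(eligible_ids) > 0)
  ob <- onboarded_ids(logs)
  stray <- setdiff(ob, eligible_ids)
  if (length(stray))
    warning("onboarded participant(s) not in the eligible set: ",
            paste(stray, collapse = ", "), call. = FALSE)
  count <- length(intersect(ob, eligible_ids))
  list(count = count,
       percentage = round_half_up(100 * count / length(eligible_ids), 1))
}

#' Initial attrition: day-0-only participants
#'
#' Counts onboarded participants who never interacted again after the
#' onboarding day (no non-excluded inbound event of any kind).
#'
#' @param logs Event `data.frame`.
#' @return List with `count` and `percentage` (1 decimal, of onboarded).
#' @export
compute_initial_attrition <- function(logs) {
  ob <- onboarded_ids(logs)
  later <- unique(logs$participant_id[logs$direction == "inbound" &
                                        !logs$excluded])
  count <- length(setdiff(ob, later))
  pct <- if (length(ob)) round_half_up(100 * count / length(ob), 1) else 0
  list(count = count, percentage = pct)
}

#' Compliance: engaged days over the scorable protocol days
#'
#' An engaged day is a scorable day (1..`scorable_days`) with at least one
#' data point. Computed over participants who continued past day 0 (i.e.
#' onboarded minus initial attrition).
#'
#' @param logs Event `data.frame`.
#' @param scorable_days Denominator (14 by default: day 0 is excluded).
#' @return List with `mean_engaged_days`, `sd_engaged_days`, `percentage`
#'   (1 decimal), `n` (continuing participants) and `per_participant`.
#' @export
compute_compliance <- function(logs, scorable_days = 14L) {
  dp <- data_points(logs)
  dp <- dp[dp$day_index <= scorable_days, , drop = FALSE]
  ob <- onboarded_ids(logs)
  continuing <- intersect(ob, unique(dp$participant_id))
  if (!length(continuing))
    return(list(mean_engaged_days = 0, sd_engaged_days = NA_real_,
                percentage = 0, n = 0L,
                per_participant = data.frame(participant_id = character(0),
                                             engaged_days = integer(0))))
  dt <- data.table::as.data.table(dp[dp$participant_id %in% continuing, ])
  per <- dt[, list(engaged_days = data.table::uniqueN(day_index)),
            by = "participant_id"]
  data.table::setorder(per, participant_id)
  m <- mean(per$engaged_days)
  list(mean_engaged_days = m,
       sd_engaged_days = stats::sd(per$engaged_days),
       percentage = round_half_up(100 * m / scorable_days, 1),
       n = nrow(per),
       per_participant = data.table::setDF(per))
}

#' Audio volume statistics
#'
#' Mean audio seconds per day is pooled over participant-days with at least
#' one audio event (prompted or unprompted, day 0 excluded); the total is
#' averaged over participants with any audio.
#'
#' @param logs Event `data.frame`.
#' @return List with `mean_seconds_per_day`, `mean_total_minutes`,
#'   `n_audio_days`, `zero_audio` (flag: no audio events at all).
#' @export
compute_audio_stats <- function(logs) {
  au <- logs[logs$direction == "inbound" & logs$kind == "audio" &
               !logs$excluded, , drop = FALSE]
  if (!nrow(au))
    return(list(mean_seconds_per_day = 0, mean_total_minutes = 0,
                n_audio_days = 0L, zero_audio = TRUE))
  dt <- data.table::as.data.table(au)
  dt[, day := as.integer(as.numeric(ts) %/% 86400)]
  per_day <- dt[, list(sec = sum(audio_duration)),
                by = c("participant_id", "day")]
  per_part <- dt[, list(sec = sum(audio_duration)), by = "participant_id"]
  list(mean_seconds_per_day = mean(per_day$sec),
       mean_total_minutes = mean(per_part$sec) / 60,
       n_audio_days = nrow(per_day), zero_audio = FALSE)
}

#' Snooze usage statistics
#'
#' `uses` counts inbound snooze events; a completion is attributed per
#' cycle: a (participant, day) cycle containing at least one snooze that
#' reached `COMPLETED`.
#'
#' @param logs Event `data.frame`.
#' @return List with `uses` and `completed`.
#' @export
compute_snooze_stats <- function(logs) {
  sn <- logs[logs$direction == "inbound" & logs$kind == "snooze", , drop = FALSE]
  if (!nrow(sn)) return(list(uses = 0L, completed = 0L))
  comp <- logs[logs$kind == "state_transition" & logs$body == "COMPLETED", ,
               drop = FALSE]
  sn_cycles <- unique(paste(sn$participant_id, sn$day_index))
  comp_cycles <- unique(paste(comp$participant_id, comp$day_index))
  list(uses = nrow(sn),
       completed = length(intersect(sn_cycles, comp_cycles)))
}

#' Cohort engagement report
#'
#' Computes all usability indicators from a set of session logs: acceptance,
#' initial attrition, compliance (mean/SD engaged days and rate), full
#' completion (participants with data on every scorable day), audio volume
#' and snooze usage.
#'
#' @param logs Event `data.frame` for the whole cohort.
#' @param eligible_ids Ids of all invited participants; defaults to the
#'   onboarded set (making acceptance 100%).
#' @param scorable_days Compliance denominator (default 14).
#' @return An `engagement_report` object (a named list of indicator values).
#' @export
engagement_report <- function(logs, eligible_ids = NULL, scorable_days = 14L) {
  ob <- onboarded_ids(logs)
  if (is.null(eligible_ids)) eligible_ids <- ob
  acc <- compute_acceptance(eligible_ids, logs)
  att <- compute_initial_attrition(logs)
  cmp <- compute_compliance(logs, scorable_days)
  aud <- compute_audio_stats(logs)
  sns <- compute_snooze_stats(logs)
  full <- sum(cmp$per_participant$engaged_days == scorable_days)
  structure(list(
    n_eligible = length(eligible_ids),
    n_onboarded = acc$count,
    acceptance_pct = acc$percentage,
    n_initial_attrition = att$count,
    initial_attrition_pct = att$percentage,
    mean_engaged_days = cmp$mean_engaged_days,
    sd_engaged_days = cmp$sd_engaged_days,
    compliance_pct = cmp$percentage,
    full_completion_pct = if (length(ob))
      round_half_up(100 * full / length(ob), 1) else 0,
    mean_audio_seconds_per_day = aud$mean_seconds_per_day,
    mean_total_audio_minutes = aud$mean_total_minutes,
    snooze_uses = sns$uses,
    snooze_completed = sns$completed,
    per_participant = cmp$per_participant
  ), class = "engagement_report")
}

#' @export
print.engagement_report <- function(x, ...) {
  cat("<engagement_report>\n")
  cat(sprintf("  eligible                 %d\n", x$n_eligible))
  cat(sprintf("  onboarded (acceptance)   %d (%.1f%%)\n", x$n_onboarded,
              x$acceptance_pct))
  cat(sprintf("  initial attrition        %d (%.1f%%)\n",
              x$n_initial_attrition, x$initial_attrition_pct))
  cat(sprintf("  engaged days (of 14)     mean %.2f (SD %.2f)\n",
              x$mean_engaged_days,
              ifelse(is.na(x$sd_engaged_days), 0, x$sd_engaged_days)))
  cat(sprintf("  compliance               %.1f%%\n", x$compliance_pct))
  cat(sprintf("  full completion          %.1f%%\n", x$full_completion_pct))
  cat(sprintf("  audio per audio-day      %.1f s\n",
              x$mean_audio_seconds_per_day))
  cat(sprintf("  audio total per person   %.1f min\n",
              x$mean_total_audio_minutes))
  cat(sprintf("  snooze uses/completed    %d / %d\n", x$snooze_uses,
              x$snooze_completed))
  invisible(x)
}

#' Serialize an engagement report
#'
#' @param report An [engagement_report()].
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    x <- unclass(report)
    x$per_participant <- NULL
    jsonlite::write_json(x, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(report$per_participant, csv_path, row.names = FALSE)
  }
  invisible(report)
}
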