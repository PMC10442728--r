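#' Day-framed 13-item mood questionnaire
#'
#' Constructors and operations for administering the short mood questionnaire
#' over chat: each item is a statement about the current day answered by
#' typing 0, 1 or 2, with a verbal anchor reminder appended to every prompt
#' (a fix that emerged from piloting: respondents wanted the meaning of the
#' numbers restated at each item).
#'
#' @param items Character vector of exactly 13 item statements.
#' @param anchors Named character vector mapping `"0"`, `"1"`, `"2"` to their
#'   verbal anchors.
#' @return `smfq_form()` returns an `smfq_form` object.
#' @export
smfq_form <- function(items = default_smfq_items(),
                      anchors = c("0" = "no", "1" = "sometimes", "2" = "yes")) {
  if (length(items) != 13L) stop("a form must have exactly 13 items", call. = FALSE)
  if (!identical(sort(names(anchors)), c("0", "1", "2")))
    stop("anchors must be named exactly 0, 1, 2", call. = FALSE)
  structure(list(items = as.character(items), anchors = anchors),
            class = "smfq_form")
}

#' @noRd
anchor_reminder <- function(anchors) {
  sprintf("Remember: 0=%s, 1=%s, 2=%s.", anchors[["0"]], anchors[["1"]],
          anchors[["2"]])
}

#' Prompt text for one questionnaire item
#'
#' @param form An [smfq_form()].
#' @param index Zero-based item index (0..12).
#' @param participant_name Name substituted into any `{name}` placeholder.
#' @return The outbound prompt: the item statement followed by the 0/1/2
#'   anchor reminder.
#' @export
#' @examples
#' item_prompt(smfq_form(), 0, "Ana")
item_prompt <- function(form, index, participant_name = "") {
  if (!is.numeric(index) || index < 0 || index > 12)
    stop("item index out of range: ", index, call. = FALSE)
  index <- as.integer(index)
  paste(render_prompt(form$items[index + 1L], participant_name),
        anchor_reminder(form$anchors))
}

#' Empty questionnaire response
#'
#' @return An `smfq_response`: 13 `NA` answers, per-item timestamps, and an
#'   empty correction list.
#' @export
smfq_response <- function() {
  structure(list(answers = rep(NA_integer_, 13L),
                 answered_at = rep(NA_real_, 13L),
                 corrections = list()),
            class = "smfq_response")
}

#' Record (or correct) a questionnaire answer
#'
#' A `NUMERIC_ANSWER` intent is stored at the item; answering an item that
#' already holds a value is a correction and is appended to the correction
#' log before overwriting. Any other intent leaves the response unchanged and
#' signals that the item must be re-prompted with its anchor reminder.
#'
#' @param response An [smfq_response()].
#' @param index Zero-based item index (0..12).
#' @param value A reply intent as returned by [classify_reply()].
#' @param now Timestamp to record with the answer.
#' @return A list with `response` (updated) and `action`, one of
#'   `"accepted"`, `"corrected"`, `"reprompt"`.
#' @export
record_answer <- function(response, index, value, now = NA_real_) {
  if (index < 0 || index > 12) stop("item index out of range: ", index, call. = FALSE)
  i <- as.integer(index) + 1L
  if (!identical(value$kind, "NUMERIC_ANSWER"))
    return(list(response = response, action = "reprompt"))
  v <- as.integer(value$value)
  stopifnot(v %in% 0:2)
  if (!is.na(response$answers[i])) {
    response$corrections[[length(response$corrections) + 1L]] <-
      list(index = as.integer(index), old = response$answers[i], new = v,
           at = now)
    response$answers[i] <- v
    response$answered_at[i] <- now
    return(list(response = response, action = "corrected"))
  }
  response$answers[i] <- v
  response$answered_at[i] <- now
  list(response = response, action = "accepted")
}

#' Total questionnaire score
#'
#' Sum of the 13 answers; range 0-26. Scoring an incomplete response is an
#' error.
#'
#' @param response An [smfq_response()].
#' @return Integer total.
#' @export
smfq_score <- function(response) {
  if (anyNA(response$answers))
    stop("cannot score an incomplete response (",
         sum(is.na(response$answers)), " unanswered items)", call. = FALSE)
  sum(response$answers)
}

#' @noRd
smfq_complete <- function(response) !anyNA(response$answers)
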