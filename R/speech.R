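#' Code speaking and listening periods from speech annotations
#'
#' Turns a time-ordered annotation stream (speech-on / speech-off /
#' interruption / resume-second-sentence events, tagged with the speaker:
#' the participant or the conversational partner) into coded speech periods:
#'
#' * the speaking period starts at the first speech-on and is cropped at
#'   `config$speech_crop_s` (30 s) per task so every participant contributes a
#'   similar amount of data;
#' * an interruption after at least `config$interruption_min_s` (20 s) of
#'   coded speech ends coding at the instant just preceding the interruption;
#' * an interruption before 20 s discards the insufficient first segment and a
#'   single second segment is coded from the resume-second-sentence event
#'   (the second sentence is used because speakers typically avert their gaze
#'   right at speech onset), again cropped at 30 s; no third segment is ever
#'   coded;
#' * listening periods are coded symmetrically from the partner's speech
#'   events.
#'
#' @param events annotation rows for one participant x task: columns `t`
#'   (ms), `event` (one of `"speech-on"`, `"speech-off"`, `"interruption"`,
#'   `"resume-second-sentence"`) and `speaker` (`"participant"` or
#'   `"partner"`).
#' @param config an [analysis_config()].
#' @return a tibble of coded periods: `role` (`"speaking"` for the
#'   participant's own speech, `"listening"` for the partner's), `t_start`,
#'   `t_end` (ms), `segment_index` (1, or 2 when the first segment was
#'   discarded after an early interruption).
#' @examples
#' ev <- data.frame(t = c(0, 45000), event = c("speech-on", "speech-off"),
#'                  speaker = "participant")
#' code_speech_periods(ev)  # one 30 s speaking period
#' @export
code_speech_periods <- function(events, config = analysis_config()) {
  stopifnot(all(c("t", "event", "speaker") %in% names(events)))
  if (nrow(events) == 0) return(empty_period_table())
  if (is.unsorted(events$t)) {
    stop_dyad("annotation-error", "speech events must be time-ordered")
  }
  bad <- setdiff(unique(events$event),
                 c("speech-on", "speech-off", "interruption", "resume-second-sentence"))
  if (length(bad)) {
    stop_dyad("annotation-error", "unknown speech event type: ",
              paste(bad, collapse = ", "))
  }
  out <- list()
  for (sp in c("participant", "partner")) {
    ev <- events[events$speaker == sp, , drop = FALSE]
    per <- code_one_speaker(ev, config)
    if (nrow(per)) {
      per$role <- if (sp == "participant") "speaking" else "listening"
      out[[sp]] <- per
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(empty_period_table())
  res[, c("role", "t_start", "t_end", "segment_index")]
}

empty_period_table <- function() {
  tibble::tibble(role = character(), t_start = numeric(), t_end = numeric(),
                 segment_index = integer())
}

# coding rules for one speaker's event stream
code_one_speaker <- function(ev, config) {
  crop_ms <- config$speech_crop_s * 1000
  min_ms <- config$interruption_min_s * 1000
  on_i <- which(ev$event == "speech-on")
  if (length(on_i) == 0) {
    if (nrow(ev) > 0) {
      stop_dyad("annotation-error", "speech event '", ev$event[1], "' at t=",
                ev$t[1], " ms occurs before any speech-on")
    }
    return(empty_period_table()[, c("t_start", "t_end", "segment_index")])
  }
  if (on_i[1] != 1) {
    stop_dyad("annotation-error", "speech event '", ev$event[1], "' at t=",
              ev$t[1], " ms occurs before any speech-on")
  }
  code_segment <- function(from_i, t0, segment_index) {
    # walk events after index from_i until the segment ends
    i <- from_i + 1
    while (i <= nrow(ev)) {
      e <- ev$event[i]
      if (e == "speech-off" || e == "interruption") {
        t1 <- ev$t[i]
        if (t1 <= t0) {
          stop_dyad("annotation-error", "speech event '", e, "' at t=", ev$t[i],
                    " ms does not follow its segment start")
        }
        return(list(end = t1, end_event = e, end_i = i, index = segment_index))
      }
      i <- i + 1
    }
    # no terminating event: speech runs to the last annotated time; the crop
    # rule below still bounds the coded period
    list(end = Inf, end_event = "speech-off", end_i = nrow(ev), index = segment_index)
  }
  t0 <- ev$t[on_i[1]]
  seg <- code_segment(on_i[1], t0, 1L)
  if (seg$end_event == "interruption" && (seg$end - t0) < min_ms) {
    # insufficient first segment: discard it, code one second segment from the
    # second sentence after resumption
    res_i <- which(ev$event == "resume-second-sentence" & seq_len(nrow(ev)) > seg$end_i)
    if (length(res_i) == 0) {
      # interrupted early and never resumed: nothing codeable
      return(empty_period_table()[, c("t_start", "t_end", "segment_index")])
    }
    t0 <- ev$t[res_i[1]]
    seg <- code_segment(res_i[1], t0, 2L)
  }
  t1 <- min(seg$end, t0 + crop_ms)
  tibble::tibble(t_start = t0, t_end = t1, segment_index = seg$index)
}

#' Code speech periods for every participant x task of an annotation table
#'
#' @param speech a speech annotation table (see [read_speech_table()]).
#' @param config an [analysis_config()].
#' @return a tibble of periods keyed by `participant` and `task`.
#' @export
code_speech_table <- function(speech, config = analysis_config()) {
  keys <- dplyr::distinct(speech, .data$participant, .data$task)
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- speech[speech$participant == keys$participant[i] &
                    speech$task == keys$task[i], , drop = FALSE]
    per <- code_speech_periods(sub, config)
    if (nrow(per)) {
      out[[i]] <- tibble::tibble(participant = keys$participant[i],
                                 task = keys$task[i], per)
    }
  }
  dplyr::bind_rows(out)
}
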