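#' Run the full region-of-interest pipeline on a cohort
#'
#' Convenience driver composing the stages on the tables of a (synthetic or
#' read-in) cohort: fixation detection per stream, face-region
#' classification against the per-frame boxes, speech coding, proportional
#' looking-time outcomes joined with group labels, and optionally the
#' speech-state density maps.
#'
#' @param cohort a list with `gaze`, `boxes`, `speech`, `traits` tables (as
#'   from [generate_cohort()] or [read_cohort()]).
#' @param config an [analysis_config()].
#' @param density also build smoothed per-participant density maps per
#'   speech state (slower).
#' @return a list: `fixations`, `labeled`, `periods`, `outcomes` (with
#'   `group`), `valid_time`, and — when `density = TRUE` — `maps` (per
#'   speech state) and `map_groups` (group label per participant).
#' @export
run_roi_pipeline <- function(cohort, config = analysis_config(),
                             density = FALSE) {
  det <- detect_fixations_table(cohort$gaze, config)
  labeled <- classify_fixations_table(det$fixations, cohort$boxes, config)
  periods <- code_speech_table(cohort$speech, config)
  outcomes <- compute_proportions(labeled, periods, gaze = cohort$gaze, config)
  outcomes <- dplyr::left_join(outcomes,
                               cohort$traits[, c("participant", "group")],
                               by = "participant")
  out <- list(fixations = det$fixations, labeled = labeled, periods = periods,
              outcomes = outcomes, valid_time = det$valid_time)
  if (density) {
    tpl <- face_template(config)
    out$maps <- build_density_maps(labeled, cohort$boxes, periods, tpl, config)
    grp <- setNames(cohort$traits$group, cohort$traits$participant)
    out$map_groups <- grp
  }
  out
}
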