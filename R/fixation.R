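#' Dispersion-based (I-DT) fixation detection
#'
#' Detects fixations in a single time-ordered 60 Hz gaze stream using the
#' classic dispersion-threshold algorithm: a temporal window is grown while
#' its spatial dispersion stays within `config$max_dispersion_deg` and emitted
#' as a fixation once it spans at least `config$min_fixation_ms`. Dispersion
#' is measured in degrees of visual angle (per-axis linear pixel-to-degree
#' scale) as the larger side of the window's bounding box by default (see
#' `dispersion_metric`). A single invalid sample (blink / track loss) closes
#' any open window: loss periods are excluded from valid time, never bridged
#' or interpolated.
#'
#' @param samples a data frame with columns `t` (ms), `x`, `y` (scene px) and
#'   logical `valid`; rows must be time-ordered.
#' @param config an [analysis_config()].
#' @return a list with
#'   \describe{
#'     \item{fixations}{a tibble with `t_start`, `t_end`, `duration` (ms),
#'       `x`, `y` (centroid, scene px), `dispersion` (deg) and `frame` (scene
#'       frame index at the fixation's temporal midpoint), time-ordered and
#'       non-overlapping.}
#'     \item{valid_time}{total time (ms) covered by valid samples, counting
#'       one sampling interval per valid sample.}
#'   }
#' @examples
#' cfg <- analysis_config()
#' s <- data.frame(t = (0:9) * 1000 / 60, x = 640, y = 480, valid = TRUE)
#' detect_fixations(s, cfg)$fixations
#' @export
detect_fixations <- function(samples, config = analysis_config()) {
  stopifnot(all(c("t", "x", "y", "valid") %in% names(samples)))
  dt <- 1000 / config$sampling_rate_hz
  if (nrow(samples) == 0) {
    return(list(fixations = empty_fixation_table(), valid_time = 0))
  }
  if (is.unsorted(samples$t)) {
    stop_dyad("invalid-argument", "gaze samples must be time-ordered")
  }
  valid <- as.logical(samples$valid)
  valid[is.na(valid)] <- FALSE
  valid_time <- sum(valid) * dt

  # detect within each maximal run of valid samples
  r <- rle(valid)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  s <- deg_per_px(config)
  wins <- vector("list", length(r$values))
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    idx <- run_start[k]:run_end[k]
    win <- .idt_scan(samples$t[idx], samples$x[idx] * s[1],
                     samples$y[idx] * s[2], config$min_fixation_ms,
                     config$max_dispersion_deg,
                     config$dispersion_metric == "sum")
    if (nrow(win)) wins[[k]] <- win + (run_start[k] - 1L)  # to global indices
  }
  win_all <- do.call(rbind, wins)
  fx <- if (is.null(win_all) || nrow(win_all) == 0) empty_fixation_table() else
    fixation_rows(samples, seq_len(nrow(samples)), win_all, s, config)
  list(fixations = fx, valid_time = valid_time)
}

fixation_rows <- function(samples, idx, win, s, config) {
  nw <- nrow(win)
  t0 <- t1 <- cx <- cy <- disp <- numeric(nw)
  for (r in seq_len(nw)) {
    sel <- idx[win[r, 1]:win[r, 2]]
    xs <- samples$x[sel]
    ys <- samples$y[sel]
    dx <- (max(xs) - min(xs)) * s[1]
    dy <- (max(ys) - min(ys)) * s[2]
    disp[r] <- if (config$dispersion_metric == "sum") dx + dy else max(dx, dy)
    t0[r] <- samples$t[sel[1]]
    t1[r] <- samples$t[sel[length(sel)]]
    cx[r] <- mean(xs)
    cy[r] <- mean(ys)
  }
  tibble::tibble(
    t_start = t0, t_end = t1, duration = t1 - t0,
    x = cx, y = cy, dispersion = disp,
    frame = frame_at_time((t0 + t1) / 2, config)
  )
}

empty_fixation_table <- function() {
  tibble::tibble(t_start = numeric(), t_end = numeric(), duration = numeric(),
                 x = numeric(), y = numeric(), dispersion = numeric(),
                 frame = integer())
}

#' Detect fixations for every participant x task stream of a gaze table
#'
#' Applies [detect_fixations()] within each `participant` x `task` group of a
#' long gaze table and binds the results, carrying a per-stream valid-time
#' accounting table alongside.
#'
#' @param gaze a gaze table (see [read_gaze_table()]): columns `participant`,
#'   `task`, `t`, `x`, `y`, `valid`.
#' @param config an [analysis_config()].
#' @return a list with `fixations` (tibble keyed by participant and task) and
#'   `valid_time` (tibble: participant, task, valid_time ms).
#' @export
detect_fixations_table <- function(gaze, config = analysis_config()) {
  stopifnot(all(c("participant", "task") %in% names(gaze)))
  keys <- dplyr::distinct(gaze, .data$participant, .data$task)
  fx <- vector("list", nrow(keys))
  vt <- numeric(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- gaze[gaze$participant == keys$participant[i] &
                  gaze$task == keys$task[i], , drop = FALSE]
    res <- detect_fixations(sub, config)
    vt[i] <- res$valid_time
    if (nrow(res$fixations)) {
      fx[[i]] <- tibble::tibble(participant = keys$participant[i],
                                task = keys$task[i], res$fixations)
    }
  }
  list(
    fixations = dplyr::bind_rows(fx),
    valid_time = tibble::tibble(keys, valid_time = vt)
  )
}
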