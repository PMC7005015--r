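#' Synthetic two-group cohorts with known ground truth
#'
#' The study's scene videos are not public, so the pipeline is exercised end
#' to end on synthetic cohorts that emulate their data model: 60 Hz gaze
#' streams in scene-camera pixels with occlusion-driven validity runs,
#' per-frame face quadrilaterals moved by smooth head motion with tracked
#' point correspondences, speech annotations for both members of the dyad,
#' and per-participant trait scores. Every generator records the ground truth
#' it used (fixation intervals, template locations, region labels, speech
#' periods), so downstream stages can be validated against it.
#'
#' @name synthetic-data
NULL

# evaluate code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# small deterministic seed derivation, kept inside 32-bit integer range
derive_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed)
  for (v in ix) s <- (s * 7919 + as.double(v) * 104729 + 17) %% 2147483629
  as.integer(s)
}

#' Cohort specification
#'
#' Parameters of a synthetic cohort. The defaults are the study conditions
#' the generator emulates: two groups of 28 participants (standing in for the
#' 29 + 27 design), two conversational tasks, 70 s of interaction per task
#' (enough to crop 30 s of speech per role), a data-loss rate of 8 percent
#' (between the two groups' reported means), and smooth head motion moving
#' the face box by up to 30 scene pixels.
#'
#' @param n_per_group participants per group (at least 2).
#' @param tasks task labels.
#' @param session_duration_s seconds of interaction per task.
#' @param loss_rate fraction of invalid gaze samples in `[0, 1)`.
#' @param motion_amplitude_px face-box drift amplitude in scene pixels.
#' @param seed integer seed; all cohort randomness derives from it.
#' @param file optional YAML file of overrides (flat keys matching the
#'   arguments); explicit arguments take precedence.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 28,
                        tasks = c("introduction", "storytelling"),
                        session_duration_s = 70,
                        loss_rate = 0.08,
                        motion_amplitude_px = 30,
                        seed = 1L,
                        file = NULL) {
  if (!is.null(file)) {
    ov <- yaml::read_yaml(file)
    known <- c("n_per_group", "tasks", "session_duration_s", "loss_rate",
               "motion_amplitude_px", "seed")
    bad <- setdiff(names(ov), known)
    if (length(bad)) {
      stop_dyad("config-error", "unknown cohort field(s): ",
                paste(bad, collapse = ", "))
    }
    given <- names(match.call())[-1]
    for (nm in setdiff(intersect(names(ov), known), given)) {
      assign(nm, ov[[nm]])
    }
  }
  if (n_per_group < 2) stop_dyad("invalid-argument", "n_per_group must be >= 2")
  if (session_duration_s <= 0) {
    stop_dyad("invalid-argument", "session_duration_s must be positive")
  }
  if (loss_rate < 0 || loss_rate >= 1) {
    stop_dyad("invalid-argument", "loss_rate must lie in [0, 1)")
  }
  structure(list(n_per_group = n_per_group, tasks = tasks,
                 session_duration_s = session_duration_s,
                 loss_rate = loss_rate,
                 motion_amplitude_px = motion_amplitude_px,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Gaze profile: where a participant looks on the face
#'
#' A mixture of isotropic Gaussian components in template coordinates
#' (degrees; the template spans 11 x 14 degrees, y increasing downwards from
#' the forehead) plus an off-face weight, together with the fixation-duration
#' distribution and a nominal saccade rate. Component weights and the
#' off-face weight must be nonnegative and sum to one.
#'
#' @param components list of components, each
#'   `list(center = c(x_deg, y_deg), spread = deg, weight = w)`.
#' @param off_face_weight fraction of fixations directed off the face.
#' @param fixation_duration_dist `c(mean_ms, sd_ms)` of a lognormal
#'   fixation-duration distribution.
#' @param saccade_rate nominal saccades per second implied by the alternating
#'   fixation/saccade synthesis.
#' @return an object of class `gaze_profile`.
#' @export
gaze_profile <- function(components, off_face_weight = 0.2,
                         fixation_duration_dist = c(300, 150),
                         saccade_rate = 3) {
  w <- vapply(components, function(cc) cc$weight, numeric(1))
  sp <- vapply(components, function(cc) cc$spread, numeric(1))
  if (any(w < 0) || off_face_weight < 0) {
    stop_dyad("invalid-argument", "profile weights must be nonnegative")
  }
  if (abs(sum(w) + off_face_weight - 1) > 1e-8) {
    stop_dyad("invalid-argument",
              "component weights and off_face_weight must sum to 1")
  }
  if (any(sp <= 0)) stop_dyad("invalid-argument", "component spreads must be positive")
  structure(list(components = components, off_face_weight = off_face_weight,
                 fixation_duration_dist = fixation_duration_dist,
                 saccade_rate = saccade_rate),
            class = "gaze_profile")
}

# build a profile from relative on-face weights over the three canonical
# regions (eyes ~4.5 deg down, centre ~7, mouth ~10.5 on the 14-deg template)
make_face_profile <- function(eye_w, center_w, mouth_w, off_face_weight,
                              spread = c(eyes = 1.0, center = 1.0, mouth = 0.9)) {
  on <- 1 - off_face_weight
  tot <- eye_w + center_w + mouth_w
  gaze_profile(
    components = list(
      list(center = c(5.5, 4.5), spread = unname(spread["eyes"]),
           weight = on * eye_w / tot),
      list(center = c(5.5, 7.0), spread = unname(spread["center"]),
           weight = on * center_w / tot),
      list(center = c(5.5, 10.5), spread = unname(spread["mouth"]),
           weight = on * mouth_w / tot)
    ),
    off_face_weight = off_face_weight
  )
}

#' Default group gaze profiles
#'
#' Two-group, speech-state-dependent profiles emulating the contrast the
#' pipeline is designed to detect: group A is mouth-biased (more lower-face
#' scanning), group B is eye/centre-biased (more upper and central face
#' scanning). Both groups orient to the face far more when listening than
#' when speaking (off-face weight 0.45 speaking vs 0.12 listening).
#'
#' @return a nested list: `profiles$A$speaking`, `profiles$A$listening`,
#'   `profiles$B$speaking`, `profiles$B$listening`.
#' @export
default_profiles <- function() {
  list(
    A = list(speaking = make_face_profile(0.35, 0.15, 0.50, 0.45),
             listening = make_face_profile(0.35, 0.15, 0.50, 0.12)),
    B = list(speaking = make_face_profile(0.45, 0.35, 0.20, 0.45),
             listening = make_face_profile(0.45, 0.35, 0.20, 0.12))
  )
}

#' Add a localised effect component to a gaze profile
#'
#' Injects an extra mixture component (e.g. over the mouth) with the given
#' weight, scaling all existing weights (including off-face) down by
#' `1 - magnitude` so the mixture still sums to one. Used to create cohorts
#' with a known, recoverable group difference.
#'
#' @param profile a [gaze_profile()] (or a speaking/listening list of them).
#' @param effect `list(center = c(x_deg, y_deg), magnitude = w,
#'   spread = deg)`; `spread` defaults to 0.8.
#' @return the modified profile(s).
#' @export
profile_with_effect <- function(profile, effect) {
  if (!inherits(profile, "gaze_profile") && is.list(profile)) {
    return(lapply(profile, profile_with_effect, effect = effect))
  }
  m <- effect$magnitude
  # the new component takes weight m; everything else (including the off-face
  # weight) is scaled by 1 - m so the mixture still sums to one
  comps <- lapply(profile$components, function(cc) {
    cc$weight <- cc$weight * (1 - m)
    cc
  })
  comps[[length(comps) + 1]] <- list(
    center = effect$center,
    spread = if (is.null(effect$spread)) 0.8 else effect$spread,
    weight = m)
  gaze_profile(comps, off_face_weight = profile$off_face_weight * (1 - m),
               fixation_duration_dist = profile$fixation_duration_dist,
               saccade_rate = profile$saccade_rate)
}

# ---- face track --------------------------------------------------------------

#' Generate a synthetic face track (boxes, transforms, point correspondences)
#'
#' Builds a per-frame sequence of face quadrilaterals moved by smooth head
#' motion (a sum of slow sinusoids bounding the per-frame step), together
#' with tracked point correspondences that are the exact images of fixed
#' face-anchored points under each frame's similarity transform. A dropout
#' schedule can force frames with fewer tracked points, exercising the
#' minimum-point re-detection rule downstream.
#'
#' @param n_frames number of scene frames (>= 1).
#' @param motion_amplitude_px face drift amplitude in scene pixels (0 gives a
#'   static box; at most 300 so the box stays inside the scene).
#' @param dropout_schedule optional integer vector (length `n_frames`) of
#'   visible point counts per frame; defaults to all points visible.
#' @param seed integer seed.
#' @param n_points number of face-anchored tracked points.
#' @param config an [analysis_config()].
#' @return a list: `boxes` (tibble: frame 0-based, vertex columns, source),
#'   `points` (per-frame matrices of correspondences), `transforms`
#'   (per-frame similarity as complex `a`, `b`), `anchors` (frame-0 points),
#'   `n_frames`.
#' @export
generate_face_track <- function(n_frames, motion_amplitude_px = 30,
                                dropout_schedule = NULL, seed = NULL,
                                n_points = 30, config = analysis_config()) {
  if (length(n_frames) != 1 || !is.finite(n_frames) || n_frames < 1) {
    stop_dyad("invalid-argument", "n_frames must be a positive count")
  }
  n_frames <- as.integer(n_frames)
  if (motion_amplitude_px < 0 || motion_amplitude_px > 300) {
    stop_dyad("invalid-argument", "motion_amplitude_px must lie in [0, 300]")
  }
  if (is.null(dropout_schedule)) {
    dropout_schedule <- rep(n_points, n_frames)
  }
  if (length(dropout_schedule) != n_frames) {
    stop_dyad("invalid-argument", "dropout_schedule must have one count per frame")
  }
  with_seed(seed, {
    res <- config$scene_resolution_px
    ctr <- res / 2
    size_px <- degrees_to_pixels(config$face_extent_deg[1],
                                 config$face_extent_deg[2], config)
    hw <- size_px[1] / 2
    hh <- size_px[2] / 2
    base_box <- rbind(ctr + c(-hw, -hh), ctr + c(hw, -hh),
                      ctr + c(hw, hh), ctr + c(-hw, hh))
    anchors <- cbind(runif(n_points, ctr[1] - hw, ctr[1] + hw),
                     runif(n_points, ctr[2] - hh, ctr[2] + hh))
    # smooth motion: three slow sinusoids per channel (periods 15-40 s at the
    # scene frame rate) so the per-frame step stays well under a pixel
    smooth_wave <- function() {
      periods <- runif(3, 15, 40) * config$scene_fps
      phases <- runif(3, 0, 2 * pi)
      f <- seq_len(n_frames) - 1
      rowMeans(sapply(1:3, function(k) sin(2 * pi * f / periods[k] + phases[k])))
    }
    amp <- motion_amplitude_px
    tx <- amp * smooth_wave()
    ty <- amp * smooth_wave()
    theta <- 0.0004 * amp * smooth_wave()
    scl <- 1 + 0.0004 * amp * smooth_wave()
    cc <- complex(real = ctr[1], imaginary = ctr[2])
    a <- scl * exp(1i * theta)
    b <- cc + complex(real = tx, imaginary = ty) - a * cc
    transforms <- lapply(seq_len(n_frames), function(f) list(a = a[f], b = b[f]))
    az <- complex(real = anchors[, 1], imaginary = anchors[, 2])
    bz <- complex(real = base_box[, 1], imaginary = base_box[, 2])
    # all frames at once: vertices as 4 complex vectors over frames
    vz <- lapply(1:4, function(v) a * bz[v] + b)
    box_mat <- cbind(Re(vz[[1]]), Im(vz[[1]]), Re(vz[[2]]), Im(vz[[2]]),
                     Re(vz[[3]]), Im(vz[[3]]), Re(vz[[4]]), Im(vz[[4]]))
    colnames(box_mat) <- box_cols
    pz_all <- outer(az, a) + matrix(b, n_points, n_frames, byrow = TRUE)
    points <- lapply(seq_len(n_frames), function(f) {
      k <- min(dropout_schedule[f], n_points)
      cbind(Re(pz_all[seq_len(k), f]), Im(pz_all[seq_len(k), f]))
    })
    boxes <- tibble::tibble(frame = 0:(n_frames - 1L),
                            tibble::as_tibble(box_mat), source = "detected")
    list(boxes = boxes, box_mat = box_mat, points = points,
         transforms = transforms, anchors = anchors, n_frames = n_frames)
  })
}

# true box matrix at a 0-based frame index of a track
track_box_at <- function(track, frame) {
  if (!is.null(track$box_mat)) {
    matrix(track$box_mat[frame + 1L, ], 4, 2, byrow = TRUE)
  } else {
    box_from_row(track$boxes[frame + 1L, ])
  }
}

# ---- session (gaze stream) ---------------------------------------------------

#' Generate a 60 Hz gaze session over a face track
#'
#' Synthesises gaze as alternating fixation/saccade segments (so the
#' dispersion detector has true positives): fixation durations are lognormal
#' (profile `fixation_duration_dist`), fixation targets are drawn from the
#' profile mixture active at the fixation's midpoint (speaking, listening, or
#' the listening profile during uncoded time), on-face targets follow the
#' moving face through each frame's true box, and saccades are 1-3 sample
#' ballistic jumps. Blinks and track loss are contiguous runs with geometric
#' lengths (mean 8 samples) whose stationary fraction matches `loss_rate`.
#'
#' @param face_track a [generate_face_track()] result; its length fixes the
#'   session duration.
#' @param profile a [gaze_profile()], or `list(speaking =, listening =)`.
#' @param speech_schedule data frame of intended states: `t_start`, `t_end`
#'   (ms), `state` in `"speaking"`/`"listening"`.
#' @param loss_rate fraction of invalid samples in `[0, 1)`.
#' @param seed integer seed.
#' @param config an [analysis_config()].
#' @return a list: `gaze` (tibble: `t`, `x`, `y`, `valid`, exactly 60 Hz) and
#'   `ground_truth` (tibble of generated fixations: `t_start`, `t_end`,
#'   `state`, `template_x_deg`, `template_y_deg`, `label`).
#' @export
generate_session <- function(face_track, profile, speech_schedule = NULL,
                             loss_rate = 0, seed = NULL,
                             config = analysis_config()) {
  if (is.null(face_track) || face_track$n_frames < 1) {
    stop_dyad("invalid-argument", "face_track must contain at least one frame")
  }
  if (loss_rate < 0 || loss_rate >= 1) {
    stop_dyad("invalid-argument", "loss_rate must lie in [0, 1)")
  }
  profiles <- if (inherits(profile, "gaze_profile")) {
    list(speaking = profile, listening = profile)
  } else profile
  with_seed(seed, {
    dt <- 1000 / config$sampling_rate_hz
    dur_ms <- face_track$n_frames / config$scene_fps * 1000
    n <- floor(dur_ms / dt)
    t <- (seq_len(n) - 1) * dt
    x <- numeric(n)
    y <- numeric(n)
    state_at <- function(tm) {
      if (is.null(speech_schedule)) return("listening")
      hit <- which(speech_schedule$t_start <= tm & tm < speech_schedule$t_end)
      if (length(hit)) speech_schedule$state[hit[1]] else "listening"
    }
    s <- deg_per_px(config)
    tpl <- face_template(config)
    # per-state mixture weights and lognormal parameters, hoisted out of the loop
    state_par <- lapply(profiles, function(prof) {
      md <- prof$fixation_duration_dist[1]
      sdd <- prof$fixation_duration_dist[2]
      sdlog <- sqrt(log(1 + (sdd / md)^2))
      list(wts = c(vapply(prof$components, function(cc) cc$weight, numeric(1)),
                   prof$off_face_weight),
           meanlog = log(md) - sdlog^2 / 2, sdlog = sdlog)
    })
    gt_start <- gt_end <- gt_tx <- gt_ty <- numeric(0)
    gt_state <- gt_label <- character(0)
    i <- 1L
    prev_end_xy <- NULL
    pending_sacc <- 0L
    last_filled <- 0L
    while (i <= n) {
      mid_state <- state_at(t[i])
      prof <- profiles[[mid_state]]
      par <- state_par[[mid_state]]
      dur <- min(max(rlnorm(1, par$meanlog, par$sdlog), 80), 1500)
      k <- max(5L, as.integer(round(dur / dt)))
      k <- min(k, n - i + 1L)
      idx <- i:(i + k - 1L)
      comp <- sample.int(length(par$wts), 1, prob = par$wts)
      if (comp <= length(prof$components)) {
        cc <- prof$components[[comp]]
        txy <- rnorm(2, cc$center, cc$spread)
        txy[1] <- min(max(txy[1], 0.3), config$face_extent_deg[1] - 0.3)
        txy[2] <- min(max(txy[2], 0.3), config$face_extent_deg[2] - 0.3)
        u <- txy[1] / config$face_extent_deg[1]
        v <- txy[2] / config$face_extent_deg[2]
        frames <- pmin(frame_at_time(t[idx], config), face_track$n_frames - 1L)
        bm <- face_track$box_mat[frames + 1L, , drop = FALSE]
        x[idx] <- (1 - u) * (1 - v) * bm[, 1] + u * (1 - v) * bm[, 3] +
          u * v * bm[, 5] + (1 - u) * v * bm[, 7]
        y[idx] <- (1 - u) * (1 - v) * bm[, 2] + u * (1 - v) * bm[, 4] +
          u * v * bm[, 6] + (1 - u) * v * bm[, 8]
        label <- if (txy[2] < config$face_extent_deg[2] / 2) "upper" else "lower"
        gt_t <- c(txy[1], txy[2])
      } else {
        mid_frame <- min(frame_at_time(mean(t[idx]), config), face_track$n_frames - 1L)
        box <- track_box_at(face_track, mid_frame)
        for (try in 1:20) {
          p0 <- c(runif(1, 40, config$scene_resolution_px[1] - 40),
                  runif(1, 40, config$scene_resolution_px[2] - 40))
          if (!points_in_quad(p0[1], p0[2], box)) break
        }
        x[idx] <- p0[1]
        y[idx] <- p0[2]
        label <- "outside"
        gt_t <- c(NA_real_, NA_real_)
      }
      # within-fixation jitter, small relative to the dispersion threshold
      x[idx] <- x[idx] + rnorm(k, 0, 0.05 / s[1])
      y[idx] <- y[idx] + rnorm(k, 0, 0.05 / s[2])
      gt_start <- c(gt_start, t[idx[1]])
      gt_end <- c(gt_end, t[idx[k]])
      gt_tx <- c(gt_tx, gt_t[1])
      gt_ty <- c(gt_ty, gt_t[2])
      gt_state <- c(gt_state, mid_state)
      gt_label <- c(gt_label, label)
      if (!is.null(prev_end_xy) && pending_sacc > 0L) {
        # fill the saccade gap with a ballistic sweep towards this fixation
        gap_idx <- (i - pending_sacc):(i - 1L)
        fr <- seq_along(gap_idx) / (pending_sacc + 1)
        x[gap_idx] <- prev_end_xy[1] + fr * (x[idx[1]] - prev_end_xy[1])
        y[gap_idx] <- prev_end_xy[2] + fr * (y[idx[1]] - prev_end_xy[2])
      }
      prev_end_xy <- c(x[idx[k]], y[idx[k]])
      last_filled <- idx[k]
      pending_sacc <- sample(1:3, 1)
      i <- i + k + pending_sacc
    }
    # trailing gap after the last fixation holds its final position
    if (last_filled < n && !is.null(prev_end_xy)) {
      x[(last_filled + 1L):n] <- prev_end_xy[1]
      y[(last_filled + 1L):n] <- prev_end_xy[2]
    }
    valid <- rep(TRUE, n)
    if (loss_rate > 0) {
      li <- 8
      lv <- li * (1 - loss_rate) / loss_rate
      pos <- 1L
      is_valid_run <- runif(1) > loss_rate
      while (pos <= n) {
        len <- 1L + stats::rgeom(1, 1 / (if (is_valid_run) lv else li))
        to <- min(n, pos + len - 1L)
        if (!is_valid_run) valid[pos:to] <- FALSE
        pos <- to + 1L
        is_valid_run <- !is_valid_run
      }
    }
    list(
      gaze = tibble::tibble(t = t, x = x, y = y, valid = valid),
      ground_truth = tibble::tibble(
        t_start = gt_start, t_end = gt_end, state = gt_state,
        template_x_deg = gt_tx, template_y_deg = gt_ty, label = gt_label)
    )
  })
}

# ---- speech annotation events ------------------------------------------------

#' Generate a simple dyadic speech annotation for one task
#'
#' The participant speaks first, then the partner, each for about 33 s (so
#' the 30 s crop binds), with small seeded jitter in the onsets. Events carry
#' the annotation vocabulary consumed by [code_speech_periods()].
#'
#' @param session_duration_s task duration in seconds.
#' @param seed integer seed.
#' @return a tibble: `t` (ms), `event`, `speaker`.
#' @export
generate_speech_events <- function(session_duration_s = 70, seed = NULL) {
  with_seed(seed, {
    speak_len <- min(33, (session_duration_s - 3) / 2) * 1000
    j <- runif(3, 0, 500)
    t_on_p <- 400 + j[1]
    t_off_p <- t_on_p + speak_len
    t_on_q <- t_off_p + 800 + j[2]
    t_off_q <- min(t_on_q + speak_len, session_duration_s * 1000 - 200)
    tibble::tibble(
      t = c(t_on_p, t_off_p, t_on_q, t_off_q),
      event = c("speech-on", "speech-off", "speech-on", "speech-off"),
      speaker = c("participant", "participant", "partner", "partner")
    )
  })
}

# ---- cohort ------------------------------------------------------------------

#' Generate a complete two-group synthetic cohort
#'
#' Produces the full balanced dataset (every participant x task): gaze
#' tables, true and tracked face boxes, point correspondences, speech
#' annotations, trait scores, and ground truth. With `injected_effect = NULL`
#' both groups draw from the same profiles only if identical profiles are
#' passed; passing one shared profile pair for both groups yields a null
#' cohort whose group labels are exchangeable by construction.
#'
#' Participant heterogeneity: each participant's component weights are
#' jittered on the log scale (sd 0.25) and the off-face weight on the logit
#' scale (sd 0.3) around the group profile, driven by a latent factor that
#' can optionally be linked to the trait scores (`trait_links`), making
#' trait-gaze correlations injectable.
#'
#' @param spec a [cohort_spec()].
#' @param profile_group_A,profile_group_B per-group profiles:
#'   `list(speaking =, listening =)` of [gaze_profile()]s.
#' @param injected_effect optional `list(center, magnitude, spread)` added to
#'   group B's profiles (both speech states) via [profile_with_effect()].
#' @param trait_links optional `c(aq = r, lsas = r)` correlations between the
#'   participant's latent eye-bias factor and the trait scores.
#' @param config an [analysis_config()].
#' @return a list of tables: `gaze`, `boxes` (true per-frame boxes),
#'   `tracks` (per participant x task point-track objects), `speech`,
#'   `traits`, `ground_truth`, plus the resolved `profiles` and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            profile_group_A = default_profiles()$A,
                            profile_group_B = default_profiles()$B,
                            injected_effect = NULL,
                            trait_links = c(aq = 0, lsas = 0),
                            config = analysis_config()) {
  if (!is.null(injected_effect)) {
    profile_group_B <- profile_with_effect(profile_group_B, injected_effect)
  }
  groups <- list(A = profile_group_A, B = profile_group_B)
  trait_base <- list(A = list(aq = c(14.0, 6.28), lsas = c(36.45, 16.32)),
                     B = list(aq = c(21.59, 8.65), lsas = c(48.19, 21.07)))
  trait_range <- list(aq = c(0, 50), lsas = c(0, 144))
  gaze <- list(); boxes <- list(); speech <- list(); gt <- list()
  traits <- list(); tracks <- list()
  n_frames <- as.integer(ceiling(spec$session_duration_s * config$scene_fps))
  pid <- 0L
  for (gname in names(groups)) {
    for (i in seq_len(spec$n_per_group)) {
      pid <- pid + 1L
      part <- sprintf("%s%02d", gname, i)
      pseed <- derive_seed(spec$seed, pid)
      z <- with_seed(pseed, rnorm(1))
      prof <- with_seed(derive_seed(pseed, 2),
                        perturb_profiles(groups[[gname]], z))
      for (tr in names(trait_range)) {
        mu <- trait_base[[gname]][[tr]][1]
        sdv <- trait_base[[gname]][[tr]][2]
        r <- if (tr %in% names(trait_links)) trait_links[[tr]] else 0
        val <- with_seed(derive_seed(pseed, 3, match(tr, names(trait_range))), {
          v <- mu + sdv * (r * z + sqrt(max(1 - r^2, 0)) * rnorm(1))
          min(max(v, trait_range[[tr]][1]), trait_range[[tr]][2])
        })
        if (tr == "aq") aq <- val else lsas <- val
      }
      traits[[part]] <- tibble::tibble(participant = part, group = gname,
                                       aq = round(aq), lsas = round(lsas))
      for (k in seq_along(spec$tasks)) {
        task <- spec$tasks[k]
        tseed <- derive_seed(pseed, 10 + k)
        track <- generate_face_track(n_frames, spec$motion_amplitude_px,
                                     seed = tseed, config = config)
        ev <- generate_speech_events(spec$session_duration_s,
                                     seed = derive_seed(tseed, 1))
        sched <- schedule_from_events(ev)
        ses <- generate_session(track, prof, sched, spec$loss_rate,
                                seed = derive_seed(tseed, 2), config = config)
        key <- paste(part, task, sep = ".")
        tracks[[key]] <- track
        gaze[[key]] <- tibble::tibble(participant = part, task = task, ses$gaze)
        boxes[[key]] <- tibble::tibble(participant = part, task = task,
                                       track$boxes)
        speech[[key]] <- tibble::tibble(participant = part, task = task, ev)
        gt[[key]] <- tibble::tibble(participant = part, task = task,
                                    ses$ground_truth)
      }
    }
  }
  list(gaze = dplyr::bind_rows(gaze),
       boxes = dplyr::bind_rows(boxes),
       tracks = tracks,
       speech = dplyr::bind_rows(speech),
       traits = dplyr::bind_rows(traits),
       ground_truth = dplyr::bind_rows(gt),
       profiles = groups,
       injected_effect = injected_effect,
       spec = spec)
}

# intended speaking/listening schedule implied by a clean annotation: the
# participant's own speech is "speaking", the partner's is "listening"
schedule_from_events <- function(ev) {
  out <- list()
  for (sp in unique(ev$speaker)) {
    on <- ev$t[ev$speaker == sp & ev$event == "speech-on"]
    off <- ev$t[ev$speaker == sp & ev$event == "speech-off"]
    m <- min(length(on), length(off))
    if (m > 0) {
      out[[sp]] <- tibble::tibble(
        t_start = on[seq_len(m)], t_end = off[seq_len(m)],
        state = if (sp == "participant") "speaking" else "listening")
    }
  }
  dplyr::bind_rows(out)
}

# jitter a speaking/listening profile pair around the group profile; the
# latent factor z shifts eye weight against mouth weight
perturb_profiles <- function(profiles, z) {
  noise <- rnorm(8, 0, 0.25)
  off_shift <- rnorm(1, 0, 0.3)
  lapply(profiles, function(pr) {
    w <- vapply(pr$components, function(cc) cc$weight, numeric(1))
    lw <- log(pmax(w, 1e-12)) + noise[seq_along(w)]
    lw[1] <- lw[1] + 0.3 * z     # z is the latent eye-bias factor
    if (length(lw) >= 3) lw[3] <- lw[3] - 0.3 * z  # mouth trades off against it
    off <- stats::plogis(stats::qlogis(min(max(pr$off_face_weight, 1e-6), 1 - 1e-6)) +
                           off_shift)
    w2 <- exp(lw) / sum(exp(lw)) * (1 - off)
    comps <- pr$components
    for (j in seq_along(comps)) comps[[j]]$weight <- w2[j]
    gaze_profile(comps, off_face_weight = off,
                 fixation_duration_dist = pr$fixation_duration_dist,
                 saccade_rate = pr$saccade_rate)
  })
}

#' Generate the detector-validation gaze stream
#'
#' A 60 Hz stream of stationary segments of graded spans (17, 33, 50, 100,
#' 250 and 500 ms by default) separated by 500-pixel saccadic jumps, repeated
#' with positional jitter. Segments shorter than the minimum fixation
#' duration must yield no fixation; every emitted fixation must respect the
#' duration and dispersion bounds. Used to validate the I-DT contracts.
#'
#' @param seed integer seed.
#' @param segments_ms segment spans in ms (mapped to 60 Hz sample counts).
#' @param repeats how many times the segment cycle repeats.
#' @param jump_px horizontal jump between consecutive segments.
#' @param jitter_px per-sample positional jitter (sd, pixels).
#' @param config an [analysis_config()].
#' @return a gaze-sample tibble (`t`, `x`, `y`, `valid`).
#' @export
generate_idt_stream <- function(seed = 1, segments_ms = c(17, 33, 50, 100, 250, 500),
                                repeats = 100, jump_px = 500, jitter_px = 1,
                                config = analysis_config()) {
  with_seed(seed, {
    dt <- 1000 / config$sampling_rate_hz
    n_per_seg <- round(segments_ms / dt) + 1L
    xs <- list(); ys <- list()
    base_x <- 300
    for (r in seq_len(repeats)) {
      for (k in seq_along(n_per_seg)) {
        nk <- n_per_seg[k]
        cx <- base_x + rnorm(1, 0, 5)
        cy <- 480 + rnorm(1, 0, 5)
        xs[[length(xs) + 1]] <- cx + rnorm(nk, 0, jitter_px)
        ys[[length(ys) + 1]] <- cy + rnorm(nk, 0, jitter_px)
        base_x <- if (base_x == 300) 300 + jump_px else 300
      }
    }
    x <- unlist(xs); y <- unlist(ys)
    tibble::tibble(t = (seq_along(x) - 1) * dt, x = x, y = y, valid = TRUE)
  })
}

# ---- direct template-level map simulation ------------------------------------

#' Simulate smoothed density maps directly on the template
#'
#' Draws per-participant maps from a profile's on-face mixture without
#' simulating gaze streams: fixation template locations come from the
#' mixture (off-face weight ignored, renormalised), durations from the
#' profile's lognormal, deposited and smoothed exactly as the pipeline does.
#' This is the generator's null-cohort path: identical profiles across
#' participants give maps drawn from one common generating distribution.
#'
#' @param n number of maps (participants).
#' @param profile a [gaze_profile()].
#' @param n_fixations face-directed fixations per participant.
#' @param template a [face_template()].
#' @param config an [analysis_config()].
#' @param seed integer seed.
#' @param perturb apply the same per-participant profile heterogeneity as
#'   [generate_cohort()] (log-scale weight jitter driven by a latent factor);
#'   `FALSE` (default) gives exchangeable participants from one distribution.
#' @return a list of smoothed `density_map`s.
#' @export
simulate_template_maps <- function(n, profile, n_fixations = 200,
                                   template = face_template(),
                                   config = analysis_config(), seed = NULL,
                                   perturb = FALSE) {
  with_seed(seed, {
    md <- profile$fixation_duration_dist[1]
    sdd <- profile$fixation_duration_dist[2]
    sdlog <- sqrt(log(1 + (sdd / md)^2))
    meanlog <- log(md) - sdlog^2 / 2
    lapply(seq_len(n), function(i) {
      prof_i <- if (perturb) {
        perturb_profiles(list(p = profile), rnorm(1))$p
      } else profile
      w <- vapply(prof_i$components, function(cc) cc$weight, numeric(1))
      w <- w / sum(w)
      vals <- matrix(0, template$height_px, template$width_px)
      comp <- sample.int(length(w), n_fixations, replace = TRUE, prob = w)
      dur <- rlnorm(n_fixations, meanlog, sdlog)
      for (j in seq_len(n_fixations)) {
        cc <- prof_i$components[[comp[j]]]
        txy <- rnorm(2, cc$center, cc$spread)
        txy[1] <- min(max(txy[1], 0), template$extent_deg[1] - 1e-9)
        txy[2] <- min(max(txy[2], 0), template$extent_deg[2] - 1e-9)
        px <- template_pixel(txy[1] / template$scale_deg_px,
                             txy[2] / template$scale_deg_px, template)
        vals[px[1, "row"], px[1, "col"]] <- vals[px[1, "row"], px[1, "col"]] + dur[j]
      }
      m <- new_density_map(vals, template, participant = i)
      attr(m, "missing") <- FALSE
      smooth_map(m, template, config)
    })
  })
}
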