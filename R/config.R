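#' Analysis configuration
#'
#' Central container for every numeric constant of the pipeline. Defaults are
#' the recording and analysis settings of the head-mounted eye-tracking study
#' the pipeline implements: eye-tracking glasses sampling gaze at 60 Hz against a
#' 24 fps, 1280 x 960 scene camera with a 60 x 46 degree field of view;
#' fixations detected with a 50 ms minimum duration and 0.5 degree maximum
#' dispersion; speech coded with a 30 s per-task crop and a 20 s interruption
#' rule; face tracking propagated from a minimum of 15 point correspondences
#' for at most 150 frames; an 11 x 14 degree face area normalised onto a
#' 110 x 140 pixel template (0.1 degree per template pixel); density maps
#' smoothed with a 2 degree isotropic Gaussian; cluster-based permutation
#' inference with a cluster-forming p of 0.01, 10,000 iterations and a 0.05
#' family-wise alpha.
#'
#' @param ... named overrides of any default listed below.
#' @param file optional path to a YAML file of overrides (flat keys matching
#'   the field names); explicit `...` arguments take precedence over the file.
#'
#' @details Fields and defaults:
#' \describe{
#'   \item{sampling_rate_hz = 60}{gaze sampling rate.}
#'   \item{scene_fps = 24}{scene-camera frame rate; gaze time t (ms) maps to
#'     frame index `floor(t * scene_fps / 1000)`.}
#'   \item{scene_resolution_px = c(1280, 960)}{scene-camera resolution (x, y).}
#'   \item{scene_fov_deg = c(60, 46)}{scene-camera field of view (x, y).}
#'   \item{min_fixation_ms = 50}{I-DT minimum fixation duration.}
#'   \item{max_dispersion_deg = 0.5}{I-DT maximum dispersion.}
#'   \item{dispersion_metric = "max"}{dispersion of a window: `"max"` = larger
#'     of the x and y ranges in degrees; `"sum"` = their sum.}
#'   \item{speech_crop_s = 30}{speech coded per task is cropped at 30 s.}
#'   \item{interruption_min_s = 20}{an interruption after at least this much
#'     coded speech ends coding; before it, a second segment is used.}
#'   \item{min_track_points = 15}{minimum point correspondences to propagate
#'     the face box; fewer triggers re-detection.}
#'   \item{max_track_frames = 150}{frames propagated from one detection before
#'     mandatory re-detection.}
#'   \item{face_extent_deg = c(11, 14)}{angular size of the face area.}
#'   \item{template_px = c(110, 140)}{face-template raster size (x, y); its
#'     aspect must match `face_extent_deg`.}
#'   \item{kernel_width_deg = 2}{Gaussian smoothing width.}
#'   \item{kernel_width_type = "sigma"}{whether `kernel_width_deg` is the
#'     Gaussian sigma (default) or its FWHM (`"fwhm"`).}
#'   \item{cluster_forming_p = 0.01}{two-sided pixelwise p threshold defining
#'     t_crit.}
#'   \item{n_permutations = 10000}{Monte Carlo iterations.}
#'   \item{cluster_alpha = 0.05}{family-wise significance level for clusters.}
#'   \item{connectivity = 8}{pixel neighbourhood for clustering (4 or 8).}
#'   \item{cluster_statistic = "size"}{cluster-level statistic; `"size"`
#'     (pixel count, default) or `"mass"` (sum of |t|).}
#'   \item{deposit = "fixation"}{density deposition: duration-weighted fixation
#'     centroids (default) or raw `"sample"` deposition.}
#'   \item{frame_tolerance = 6}{when no face box exists at a fixation's frame,
#'     the nearest box within this many frames is used; beyond it the fixation
#'     is unclassifiable.}
#'   \item{transform_family = "similarity"}{box-propagation fit: least-squares
#'     similarity (translation + rotation + isotropic scale) or `"affine"`.}
#'   \item{pooled_t = TRUE}{group trait t-tests pooled (classical df
#'     n1 + n2 - 2) rather than Welch.}
#'   \item{rng_seed = NULL}{seed applied by stochastic pipeline stages.}
#' }
#'
#' @return an object of class `dyad_config` (a validated named list).
#' @examples
#' cfg <- analysis_config()
#' cfg$max_dispersion_deg
#' analysis_config(max_dispersion_deg = 1)$max_dispersion_deg
#' @export
analysis_config <- function(..., file = NULL) {
  defaults <- list(
    sampling_rate_hz   = 60,
    scene_fps          = 24,
    scene_resolution_px = c(1280, 960),
    scene_fov_deg      = c(60, 46),
    min_fixation_ms    = 50,
    max_dispersion_deg = 0.5,
    dispersion_metric  = "max",
    speech_crop_s      = 30,
    interruption_min_s = 20,
    min_track_points   = 15,
    max_track_frames   = 150,
    face_extent_deg    = c(11, 14),
    template_px        = c(110, 140),
    kernel_width_deg   = 2,
    kernel_width_type  = "sigma",
    cluster_forming_p  = 0.01,
    n_permutations     = 10000,
    cluster_alpha      = 0.05,
    connectivity       = 8,
    cluster_statistic  = "size",
    deposit            = "fixation",
    frame_tolerance    = 6,
    transform_family   = "similarity",
    pooled_t           = TRUE,
    rng_seed           = NULL
  )
  overrides <- list(...)
  if (!is.null(file)) {
    from_file <- yaml::read_yaml(file)
    if (!is.list(from_file)) {
      stop_dyad("config-error", "config file must contain a YAML mapping")
    }
    # coerce length-2 fields written as YAML sequences
    overrides <- c(overrides, from_file[setdiff(names(from_file), names(overrides))])
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop_dyad("config-error", "unknown config field(s): ",
              paste(unknown, collapse = ", "))
  }
  cfg <- defaults
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  for (nm in c("scene_resolution_px", "scene_fov_deg", "face_extent_deg", "template_px")) {
    cfg[[nm]] <- as.numeric(unlist(cfg[[nm]]))
  }
  validate_config(cfg)
  structure(cfg, class = "dyad_config")
}

validate_config <- function(cfg) {
  pos_scalar <- c("sampling_rate_hz", "scene_fps", "min_fixation_ms",
                  "max_dispersion_deg", "speech_crop_s", "interruption_min_s",
                  "min_track_points", "max_track_frames", "kernel_width_deg",
                  "cluster_forming_p", "n_permutations", "cluster_alpha",
                  "frame_tolerance")
  for (nm in pos_scalar) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop_dyad("config-error", "config field '", nm,
                "' must be a single positive number")
    }
  }
  for (nm in c("scene_resolution_px", "scene_fov_deg", "face_extent_deg", "template_px")) {
    v <- cfg[[nm]]
    if (length(v) != 2 || any(!is.finite(v)) || any(v <= 0)) {
      stop_dyad("config-error", "config field '", nm,
                "' must be two positive numbers (x, y)")
    }
  }
  if (cfg$cluster_forming_p >= 1 || cfg$cluster_alpha >= 1) {
    stop_dyad("config-error", "p thresholds must lie in (0, 1)")
  }
  if (!cfg$connectivity %in% c(4, 8)) {
    stop_dyad("config-error", "connectivity must be 4 or 8")
  }
  if (!cfg$dispersion_metric %in% c("max", "sum")) {
    stop_dyad("config-error", "dispersion_metric must be 'max' or 'sum'")
  }
  if (!cfg$kernel_width_type %in% c("sigma", "fwhm")) {
    stop_dyad("config-error", "kernel_width_type must be 'sigma' or 'fwhm'")
  }
  if (!cfg$cluster_statistic %in% c("size", "mass")) {
    stop_dyad("config-error", "cluster_statistic must be 'size' or 'mass'")
  }
  if (!cfg$deposit %in% c("fixation", "sample")) {
    stop_dyad("config-error", "deposit must be 'fixation' or 'sample'")
  }
  if (!cfg$transform_family %in% c("similarity", "affine")) {
    stop_dyad("config-error", "transform_family must be 'similarity' or 'affine'")
  }
  aspect_tpl <- cfg$template_px[1] / cfg$template_px[2]
  aspect_face <- cfg$face_extent_deg[1] / cfg$face_extent_deg[2]
  if (abs(aspect_tpl - aspect_face) > 1e-8) {
    stop_dyad("config-error",
              "template_px aspect ratio must match face_extent_deg aspect ratio")
  }
  invisible(cfg)
}

#' @export
print.dyad_config <- function(x, ...) {
  cat("<dyad_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = " x ")))
  }
  invisible(x)
}

# degrees of visual angle per scene pixel, per axis (small-angle linear scale)
deg_per_px <- function(config) {
  config$scene_fov_deg / config$scene_resolution_px
}

#' Convert scene-pixel offsets to degrees of visual angle
#'
#' Linear per-axis scaling using the scene camera's field of view over its
#' resolution (60 deg / 1280 px horizontally, 46 deg / 960 px vertically at the
#' defaults). A small-angle linear scale, not a trigonometric camera model:
#' the dispersion threshold the pipeline inherits presupposes a fixed
#' degrees-per-pixel factor.
#'
#' @param dx,dy pixel offsets (vectorised).
#' @param config an [analysis_config()].
#' @return a two-column matrix of (x, y) offsets in degrees.
#' @examples
#' pixels_to_degrees(1280, 960)  # the full field of view
#' @export
pixels_to_degrees <- function(dx, dy, config = analysis_config()) {
  s <- deg_per_px(config)
  cbind(x_deg = dx * s[1], y_deg = dy * s[2])
}

#' @rdname pixels_to_degrees
#' @param dx_deg,dy_deg offsets in degrees.
#' @export
degrees_to_pixels <- function(dx_deg, dy_deg, config = analysis_config()) {
  s <- deg_per_px(config)
  cbind(x_px = dx_deg / s[1], y_px = dy_deg / s[2])
}

# scene-frame index shown at gaze time t_ms
frame_at_time <- function(t_ms, config) {
  as.integer(floor(t_ms * config$scene_fps / 1000))
}

# classed error helper: condition class "dyadscan_<what>"
stop_dyad <- function(what, ...) {
  msg <- paste0(...)
  cond <- structure(
    class = c(paste0("dyadscan_", what), "dyadscan_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}
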