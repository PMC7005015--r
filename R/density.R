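#' The normalised face template
#'
#' A fixed raster coordinate frame (default 110 x 140 px at 0.1 degree per
#' pixel, i.e. the 11 x 14 degree face area) onto which the moving face
#' quadrilateral of every scene frame is mapped, so gaze can be aggregated
#' across time and participants. Template x runs left to right, y from the
#' top of the face (forehead) down to the chin; the upper/lower midline sits
#' at half the template height.
#'
#' @param config an [analysis_config()].
#' @return an object of class `face_template`: `width_px`, `height_px`,
#'   `scale_deg_px`, `extent_deg`.
#' @export
face_template <- function(config = analysis_config()) {
  structure(list(
    width_px = config$template_px[1],
    height_px = config$template_px[2],
    scale_deg_px = config$face_extent_deg[1] / config$template_px[1],
    extent_deg = config$face_extent_deg
  ), class = "face_template")
}

#' Remap a scene point onto the face template
#'
#' Maps a scene-pixel point through the frame's face quadrilateral onto the
#' normalised template: the four box vertices map exactly onto the four
#' template corners (TL to (0,0), BR to (width, height)) and interior points
#' map by inverse bilinear interpolation, which reduces to an affine map for
#' parallelogram boxes. Points outside the quadrilateral map to `NA`.
#'
#' @param px,py scene coordinates (vectorised).
#' @param box 4x2 vertex matrix (TL, TR, BR, BL).
#' @param template a [face_template()].
#' @return a two-column matrix of template coordinates (`NA` rows for points
#'   outside the face).
#' @examples
#' box <- rbind(c(500, 300), c(740, 300), c(740, 600), c(500, 600))
#' remap_to_template(620, 450, box)
#' @export
remap_to_template <- function(px, py, box, template = face_template()) {
  inside <- points_in_quad(px, py, box)
  out <- matrix(NA_real_, length(px), 2,
                dimnames = list(NULL, c("tx", "ty")))
  for (i in which(inside)) {
    uv <- inverse_bilinear(px[i], py[i], box)
    out[i, ] <- c(uv[1] * template$width_px, uv[2] * template$height_px)
  }
  out
}

# template coordinates -> 1-based pixel indices (col = x, row = y); the pixel
# grid covers [0, W) x [0, H), with the far edges folded into the last pixel
template_pixel <- function(tx, ty, template) {
  cbind(
    col = pmin(pmax(floor(tx), 0), template$width_px - 1) + 1,
    row = pmin(pmax(floor(ty), 0), template$height_px - 1) + 1
  )
}

new_density_map <- function(values, template, participant = NA, condition = NA) {
  structure(values, class = c("density_map", "matrix", "array"),
            participant = participant, condition = condition,
            scale_deg_px = template$scale_deg_px)
}

#' Accumulate a raw gaze density map on the face template
#'
#' Each face-directed fixation (label `"upper"` or `"lower"`) deposits weight
#' equal to its duration in ms (or its supplied `weight`, e.g. the
#' within-period clipped duration) at the template pixel containing its
#' remapped centroid. Off-face and unclassifiable fixations contribute
#' nothing. The face box at the fixation's frame (nearest within
#' `config$frame_tolerance`) provides the remapping.
#'
#' @param fixations labelled fixation table for one stream: columns `frame`,
#'   `x`, `y`, `duration`, `label`, optionally `weight`.
#' @param boxes face-box table for the stream.
#' @param template a [face_template()].
#' @param config an [analysis_config()].
#' @return a `density_map` (height x width matrix, rows = template y); the
#'   attribute `missing` is `TRUE` when no face gaze was deposited.
#' @export
accumulate_density <- function(fixations, boxes, template = face_template(),
                               config = analysis_config()) {
  vals <- matrix(0, template$height_px, template$width_px)
  w <- if ("weight" %in% names(fixations)) fixations$weight else fixations$duration
  on_face <- which(fixations$label %in% c("upper", "lower") & w > 0)
  if (nrow(boxes) == 0) on_face <- integer(0)
  bm <- as.matrix(boxes[, box_cols])
  jn <- nearest_sorted_index(boxes$frame, fixations$frame)
  for (i in on_face) {
    j <- jn[i]
    if (abs(boxes$frame[j] - fixations$frame[i]) > config$frame_tolerance) next
    tp <- remap_to_template(fixations$x[i], fixations$y[i],
                            matrix(bm[j, ], 4, 2, byrow = TRUE), template)
    if (is.na(tp[1, 1])) next
    px <- template_pixel(tp[1, 1], tp[1, 2], template)
    vals[px[1, "row"], px[1, "col"]] <- vals[px[1, "row"], px[1, "col"]] + w[i]
  }
  m <- new_density_map(vals, template)
  attr(m, "missing") <- sum(vals) <= 0
  m
}

#' Smooth a density map with an isotropic Gaussian and normalise it
#'
#' Convolves the map with a two-dimensional isotropic Gaussian kernel. The
#' kernel width is `config$kernel_width_deg` interpreted as the Gaussian
#' sigma by default (`kernel_width_type = "fwhm"` divides by 2*sqrt(2*log 2)),
#' converted to template pixels via the template scale. Near the map boundary
#' the truncated kernel is renormalised per source pixel so total mass is
#' conserved exactly; afterwards the map is normalised to unit total mass
#' (per participant) unless it carries no mass, in which case it stays zero
#' and keeps its `missing` flag.
#'
#' @param map a `density_map` from [accumulate_density()] (or a plain matrix).
#' @param template a [face_template()].
#' @param config an [analysis_config()].
#' @param normalize divide by total mass after smoothing (default `TRUE`).
#' @return the smoothed `density_map`.
#' @export
smooth_map <- function(map, template = face_template(),
                       config = analysis_config(), normalize = TRUE) {
  sigma_deg <- config$kernel_width_deg
  if (config$kernel_width_type == "fwhm") sigma_deg <- sigma_deg / (2 * sqrt(2 * log(2)))
  sigma_px <- sigma_deg / template$scale_deg_px
  sm <- gaussian_blur(unclass(map), sigma_px)
  miss <- isTRUE(attr(map, "missing")) || sum(sm) <= 0
  if (normalize && !miss) sm <- sm / sum(sm)
  out <- new_density_map(sm, template, attr(map, "participant"),
                         attr(map, "condition"))
  attr(out, "missing") <- miss
  out
}

# mass-conserving Gaussian blur: zero-padded FFT convolution with a truncated
# kernel, renormalised per source pixel by the in-bounds kernel mass
gaussian_blur <- function(A, sigma_px) {
  R <- max(1L, as.integer(ceiling(3 * sigma_px)))
  g <- exp(-((-R:R)^2) / (2 * sigma_px^2))
  K <- outer(g, g)
  K <- K / sum(K)
  W <- conv2_full(matrix(1, nrow(A), ncol(A)), K, R)
  out <- conv2_full(A / W, K, R)
  out[out < 0] <- 0  # clip FFT round-off
  out
}

conv2_full <- function(A, K, R) {
  nr <- nrow(A); nc <- ncol(A)
  pr <- nr + 2 * R; pc <- nc + 2 * R
  PA <- matrix(0, pr, pc); PA[1:nr, 1:nc] <- A
  PK <- matrix(0, pr, pc); PK[1:(2 * R + 1), 1:(2 * R + 1)] <- K
  full <- Re(stats::fft(stats::fft(PA) * stats::fft(PK), inverse = TRUE)) / (pr * pc)
  full[(R + 1):(R + nr), (R + 1):(R + nc)]
}

#' Build per-participant, per-speech-state density maps for a cohort
#'
#' The density stage of the pipeline: face-directed fixations are restricted
#' to the coded speaking/listening periods (duration clipped to the period
#' boundaries), collapsed across the tasks, remapped through the per-frame
#' face boxes onto the template, accumulated and smoothed. Participants with
#' no face gaze in a state yield a `missing` map, excluded from group
#' statistics.
#'
#' @param labeled_fixations labelled fixation table keyed by `participant`,
#'   `task`.
#' @param boxes face-box table keyed the same way.
#' @param periods coded speech periods from [code_speech_table()].
#' @param template a [face_template()].
#' @param config an [analysis_config()].
#' @return a list with one element per speech state (`speaking`,
#'   `listening`), each a named list of smoothed `density_map`s keyed by
#'   participant.
#' @export
build_density_maps <- function(labeled_fixations, boxes, periods,
                               template = face_template(),
                               config = analysis_config()) {
  participants <- sort(unique(labeled_fixations$participant))
  out <- list()
  for (state in c("speaking", "listening")) {
    maps <- list()
    for (p in participants) {
      raw <- matrix(0, template$height_px, template$width_px)
      any_mass <- FALSE
      for (tk in unique(labeled_fixations$task[labeled_fixations$participant == p])) {
        fx <- labeled_fixations[labeled_fixations$participant == p &
                                  labeled_fixations$task == tk, , drop = FALSE]
        per <- periods[periods$participant == p & periods$task == tk &
                         periods$role == state, , drop = FALSE]
        if (nrow(fx) == 0 || nrow(per) == 0) next
        fx$weight <- clip_to_intervals(fx$t_start, fx$t_end, per$t_start, per$t_end)
        bsub <- boxes[boxes$participant == p & boxes$task == tk, , drop = FALSE]
        m <- accumulate_density(fx, bsub, template, config)
        raw <- raw + unclass(m)
        any_mass <- any_mass || !attr(m, "missing")
      }
      m <- new_density_map(raw, template, participant = p, condition = state)
      attr(m, "missing") <- !any_mass
      maps[[as.character(p)]] <- smooth_map(m, template, config)
    }
    out[[state]] <- maps
  }
  out
}

# stack a list of maps into an n x p matrix (rows = participants), dropping
# missing maps; keeps the map dimensions as an attribute
maps_to_matrix <- function(maps) {
  keep <- !vapply(maps, function(m) isTRUE(attr(m, "missing")), logical(1))
  maps <- maps[keep]
  if (length(maps) == 0) {
    stop_dyad("insufficient-data", "no non-missing density maps")
  }
  d <- dim(maps[[1]])
  M <- do.call(rbind, lapply(maps, as.vector))
  rownames(M) <- names(maps)
  attr(M, "map_dim") <- d
  M
}

#' Pixelwise two-sample t-map between two sets of density maps
#'
#' Pooled-variance two-sample t statistic per template pixel, with
#' `df = n_A + n_B - 2`, and the two-sided critical value `t_crit` at the
#' cluster-forming p threshold. Pixels with zero pooled variance get t = 0
#' when the group means agree and a +/-Inf sentinel (always supra-threshold)
#' otherwise.
#'
#' @param maps_A,maps_B lists of `density_map`s (missing maps are dropped).
#' @param config an [analysis_config()].
#' @return a list: `t_map` (matrix), `t_crit`, `df`, `n_A`, `n_B`.
#' @export
pixelwise_t <- function(maps_A, maps_B, config = analysis_config()) {
  MA <- maps_to_matrix(maps_A)
  MB <- maps_to_matrix(maps_B)
  if (nrow(MA) < 2 || nrow(MB) < 2) {
    stop_dyad("insufficient-data", "need at least 2 maps per group")
  }
  d <- attr(MA, "map_dim")
  tv <- t_from_sums(colSums(MA), colSums(MA^2), nrow(MA),
                    colSums(MB), colSums(MB^2), nrow(MB))
  df <- nrow(MA) + nrow(MB) - 2
  list(t_map = matrix(tv, d[1], d[2]),
       t_crit = qt(1 - config$cluster_forming_p / 2, df),
       df = df, n_A = nrow(MA), n_B = nrow(MB))
}

# pooled-variance two-sample t from per-group sums and sums of squares
t_from_sums <- function(SA, QA, nA, SB, QB, nB) {
  mA <- SA / nA
  mB <- SB / nB
  ssA <- pmax(QA - SA^2 / nA, 0)
  ssB <- pmax(QB - SB^2 / nB, 0)
  sp2 <- (ssA + ssB) / (nA + nB - 2)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  tv <- (mA - mB) / se
  zero <- se == 0
  if (any(zero)) {
    tv[zero] <- ifelse(mA[zero] == mB[zero], 0, sign(mA[zero] - mB[zero]) * Inf)
  }
  tv
}

#' Find supra-threshold clusters in a t-map
#'
#' Positive clusters are connected components (under
#' `config$connectivity`-neighbour adjacency) of pixels with `t > t_crit`,
#' negative clusters of pixels with `t < -t_crit`. The cluster statistic is
#' the pixel count (`cluster_statistic = "size"`, default) or the sum of |t|
#' (`"mass"`).
#'
#' @param t_map a t-statistic matrix.
#' @param t_crit the cluster-forming critical value.
#' @param config an [analysis_config()].
#' @return a list: `clusters` (tibble: `id`, `sign`, `size`, `mass`, `stat`)
#'   and `labels` (integer matrix; positive ids for positive clusters,
#'   negative ids for negative ones, 0 background).
#' @export
find_clusters <- function(t_map, t_crit, config = analysis_config()) {
  pos <- .label_components(matrix(as.integer(t_map > t_crit), nrow(t_map)),
                           config$connectivity)
  neg <- .label_components(matrix(as.integer(t_map < -t_crit), nrow(t_map)),
                           config$connectivity)
  labels <- pos - neg  # disjoint supports
  rows <- list()
  for (sgn in c(1, -1)) {
    lab <- if (sgn == 1) pos else neg
    k <- max(lab)
    if (k == 0) next
    for (id in seq_len(k)) {
      sel <- lab == id
      rows[[length(rows) + 1]] <- tibble::tibble(
        id = sgn * id,
        sign = if (sgn == 1) "positive" else "negative",
        size = sum(sel),
        mass = sum(abs(t_map[sel]))
      )
    }
  }
  clusters <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(id = integer(), sign = character(), size = integer(),
                   mass = numeric())
  clusters$stat <- if (config$cluster_statistic == "mass") clusters$mass else
    as.numeric(clusters$size)
  list(clusters = clusters, labels = labels)
}
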