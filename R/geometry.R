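#' Face-box geometry: propagation and region classification
#'
#' The conversational partner's face is represented per scene frame by a
#' convex quadrilateral (vertices ordered TL, TR, BR, BL in scene pixels),
#' detected periodically and propagated between detections from tracked point
#' correspondences. The quadrilateral is split at the midline joining the
#' midpoints of its left and right edges into an upper and a lower half, used
#' as proxies for the eye and mouth regions.
#'
#' @name face-geometry
NULL

# ---- quadrilateral utilities -------------------------------------------------

cross2 <- function(ax, ay, bx, by) ax * by - ay * bx

# box: 4x2 numeric matrix, rows TL, TR, BR, BL
check_box <- function(box) {
  if (!is.matrix(box) || !identical(dim(box), c(4L, 2L)) || any(!is.finite(box))) {
    stop_dyad("invalid-argument", "a face box must be a finite 4x2 matrix (TL, TR, BR, BL)")
  }
  nxt <- c(2, 3, 4, 1)
  prv <- c(4, 1, 2, 3)
  cr <- vapply(1:4, function(i) {
    cross2(box[i, 1] - box[prv[i], 1], box[i, 2] - box[prv[i], 2],
           box[nxt[i], 1] - box[i, 1], box[nxt[i], 2] - box[i, 2])
  }, numeric(1))
  if (any(abs(cr) < 1e-9) || length(unique(sign(cr))) != 1) {
    stop_dyad("invalid-argument", "face box must be a convex, non-degenerate quadrilateral")
  }
  invisible(sign(cr[1]))
}

# vectorised point-in-convex-quad, boundary counts as inside
points_in_quad <- function(px, py, box) {
  orient <- check_box(box)
  nxt <- c(2, 3, 4, 1)
  inside <- rep(TRUE, length(px))
  for (i in 1:4) {
    ex <- box[nxt[i], 1] - box[i, 1]
    ey <- box[nxt[i], 2] - box[i, 2]
    s <- cross2(ex, ey, px - box[i, 1], py - box[i, 2]) * orient
    inside <- inside & (s >= -1e-9)
  }
  inside
}

#' Classify scene points as upper face, lower face or outside
#'
#' A point is `"outside"` if it does not fall within the face quadrilateral
#' (boundary points count as inside); interior points are split by the midline
#' segment joining the midpoints of the left (TL-BL) and right (TR-BR) edges.
#' Points exactly on the midline are assigned to the upper region.
#'
#' @param px,py point coordinates in scene pixels (vectorised).
#' @param box a 4x2 matrix of vertices ordered TL, TR, BR, BL.
#' @return a character vector with values `"upper"`, `"lower"`, `"outside"`.
#' @examples
#' box <- rbind(c(0, 0), c(100, 0), c(100, 140), c(0, 140))
#' classify_point(c(50, 50, 500), c(35, 105, 500), box)
#' @export
classify_point <- function(px, py, box) {
  inside <- points_in_quad(px, py, box)
  lx <- (box[1, 1] + box[4, 1]) / 2  # midpoint of TL-BL edge
  ly <- (box[1, 2] + box[4, 2]) / 2
  rx <- (box[2, 1] + box[3, 1]) / 2  # midpoint of TR-BR edge
  ry <- (box[2, 2] + box[3, 2]) / 2
  s <- cross2(rx - lx, ry - ly, px - lx, py - ly)
  s_top <- cross2(rx - lx, ry - ly, box[1, 1] - lx, box[1, 2] - ly)
  lab <- ifelse(s == 0 | sign(s) == sign(s_top), "upper", "lower")
  ifelse(inside, lab, "outside")
}

# ---- transforms --------------------------------------------------------------

# least-squares similarity (translation + rotation + isotropic scale) mapping
# X -> Y, via the complex-regression closed form; no reflection
fit_similarity <- function(X, Y) {
  z <- complex(real = X[, 1], imaginary = X[, 2])
  w <- complex(real = Y[, 1], imaginary = Y[, 2])
  zc <- mean(z); wc <- mean(w)
  denom <- sum(Mod(z - zc)^2)
  if (denom < 1e-12) stop_dyad("invalid-argument", "degenerate point set for similarity fit")
  a <- sum((w - wc) * Conj(z - zc)) / denom
  b <- wc - a * zc
  list(kind = "similarity", a = a, b = b)
}

fit_affine <- function(X, Y) {
  A <- cbind(X, 1)
  coefs <- qr.solve(A, Y)  # 3x2
  list(kind = "affine", M = t(coefs[1:2, , drop = FALSE]), v = coefs[3, ])
}

apply_transform <- function(tr, P) {
  if (tr$kind == "similarity") {
    z <- complex(real = P[, 1], imaginary = P[, 2])
    w <- tr$a * z + tr$b
    cbind(Re(w), Im(w))
  } else {
    t(tr$M %*% t(P)) + matrix(tr$v, nrow(P), 2, byrow = TRUE)
  }
}

# ---- box propagation ---------------------------------------------------------

#' Propagate the face box to the next frame from point correspondences
#'
#' Fits a least-squares similarity transform (translation, rotation, isotropic
#' scale; configurable to affine) to the index-matched point correspondences
#' between the previous and current frame and maps the previous box's vertices
#' through it. Propagation is refused — a re-detection signal is returned —
#' when fewer than `config$min_track_points` (15) correspondences are
#' available or when `frames_since_detection` has reached
#' `config$max_track_frames` (150), mirroring the tracking-quality budget of
#' the semi-automatic coding procedure.
#'
#' @param points_prev,points_curr n x 2 matrices of corresponding tracked
#'   points in the previous and current frame.
#' @param box_prev the previous frame's 4x2 vertex matrix (TL, TR, BR, BL).
#' @param frames_since_detection frames already propagated since the last
#'   detection (0 immediately after a detection).
#' @param config an [analysis_config()].
#' @return the propagated 4x2 vertex matrix, or an object of class
#'   `"redetect_signal"` (test with [is_redetect()]) carrying the reason.
#' @examples
#' box <- rbind(c(500, 300), c(740, 300), c(740, 600), c(500, 600))
#' pts <- cbind(runif(20, 500, 740), runif(20, 300, 600))
#' propagate_box(pts, pts + 5, box, 0)  # pure translation
#' @export
propagate_box <- function(points_prev, points_curr, box_prev,
                          frames_since_detection, config = analysis_config()) {
  points_prev <- as.matrix(points_prev)
  points_curr <- as.matrix(points_curr)
  if (!identical(dim(points_prev), dim(points_curr))) {
    stop_dyad("invalid-argument", "point correspondences must be index-matched")
  }
  n <- nrow(points_prev)
  if (n < 3) {
    stop_dyad("invalid-argument",
              "at least 3 point correspondences are required (got ", n, ")")
  }
  check_box(box_prev)
  if (frames_since_detection >= config$max_track_frames) {
    return(redetect_signal("frame-budget",
                           frames_since_detection = frames_since_detection))
  }
  if (n < config$min_track_points) {
    return(redetect_signal("too-few-points", n_points = n))
  }
  tr <- if (config$transform_family == "affine") {
    fit_affine(points_prev, points_curr)
  } else {
    fit_similarity(points_prev, points_curr)
  }
  apply_transform(tr, box_prev)
}

redetect_signal <- function(reason, ...) {
  structure(list(reason = reason, ...), class = "redetect_signal")
}

#' @rdname propagate_box
#' @param x an object returned by [propagate_box()].
#' @export
is_redetect <- function(x) inherits(x, "redetect_signal")

#' Run box propagation along a whole track and report re-detection cadence
#'
#' Convenience driver over [propagate_box()]: walks a per-frame point-track
#' sequence from a detection at the first frame, propagating until a
#' re-detection signal occurs, then re-seeds from the supplied per-frame boxes
#' (standing in for the detector) and continues. Produces the per-frame box
#' table used downstream plus a validation report of frames that required
#' re-detection — the programmatic replacement for manual moderation.
#'
#' @param track a face track as produced by [generate_face_track()] (fields
#'   `boxes`, `points`).
#' @param config an [analysis_config()].
#' @return a list with `boxes` (tibble: frame, vertex coordinates, source =
#'   detected/propagated) and `redetections` (tibble: frame, reason).
#' @export
propagate_track <- function(track, config = analysis_config()) {
  n <- length(track$points)
  det_boxes <- track$boxes
  box <- box_from_row(det_boxes[1, ])
  out <- vector("list", n)
  out[[1]] <- box_to_row(box, det_boxes$frame[1], "detected")
  redet <- list()
  since <- 0L
  for (i in 2:n) {
    # correspondences are index-aligned; dropout trims to the common prefix
    k <- min(nrow(track$points[[i - 1]]), nrow(track$points[[i]]))
    res <- propagate_box(track$points[[i - 1]][seq_len(k), , drop = FALSE],
                         track$points[[i]][seq_len(k), , drop = FALSE],
                         box, since, config)
    if (is_redetect(res)) {
      redet[[length(redet) + 1]] <-
        tibble::tibble(frame = det_boxes$frame[i], reason = res$reason)
      box <- box_from_row(det_boxes[i, ])  # re-seed from detection
      since <- 0L
      out[[i]] <- box_to_row(box, det_boxes$frame[i], "detected")
    } else {
      box <- res
      since <- since + 1L
      out[[i]] <- box_to_row(box, det_boxes$frame[i], "propagated")
    }
  }
  list(boxes = dplyr::bind_rows(out), redetections = dplyr::bind_rows(redet))
}

# ---- box table <-> matrix ----------------------------------------------------

box_cols <- c("x_tl", "y_tl", "x_tr", "y_tr", "x_br", "y_br", "x_bl", "y_bl")

box_from_row <- function(row) {
  matrix(as.numeric(row[box_cols]), 4, 2, byrow = TRUE)
}

box_to_row <- function(box, frame, source) {
  v <- as.numeric(t(box))
  names(v) <- box_cols
  tibble::tibble(frame = frame, !!!as.list(v), source = source)
}

# ---- fixation classification -------------------------------------------------

#' Classify fixations into face regions
#'
#' Looks up the face box at each fixation's scene frame (or the nearest
#' available frame within `config$frame_tolerance`) and labels the fixation
#' centroid `"upper"`, `"lower"` or `"outside"` via [classify_point()].
#' Fixations with no box within tolerance are labelled `"unclassifiable"` and
#' count as data loss downstream.
#'
#' @param fixations a fixation table (needs columns `frame`, `x`, `y`).
#' @param boxes a face-box table for the same stream: column `frame` plus the
#'   eight vertex coordinate columns `x_tl` ... `y_bl`.
#' @param config an [analysis_config()].
#' @return the fixation table with an added `label` column.
#' @export
classify_fixations <- function(fixations, boxes, config = analysis_config()) {
  if (nrow(fixations) == 0) {
    return(dplyr::mutate(fixations, label = character(0)))
  }
  lab <- character(nrow(fixations))
  if (nrow(boxes) == 0) {
    return(dplyr::mutate(fixations, label = "unclassifiable"))
  }
  bm <- as.matrix(boxes[, box_cols])
  j <- nearest_sorted_index(boxes$frame, fixations$frame)
  d <- abs(boxes$frame[j] - fixations$frame)
  for (i in seq_len(nrow(fixations))) {
    if (d[i] > config$frame_tolerance) {
      lab[i] <- "unclassifiable"
    } else {
      lab[i] <- classify_point(fixations$x[i], fixations$y[i],
                               matrix(bm[j[i], ], 4, 2, byrow = TRUE))
    }
  }
  dplyr::mutate(fixations, label = lab)
}

# index of the nearest element of a sorted vector for each x
nearest_sorted_index <- function(sorted, x) {
  pos <- findInterval(x, sorted)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(sorted))
  ifelse(abs(sorted[lo] - x) <= abs(sorted[hi] - x), lo, hi)
}

#' Classify fixations for every participant x task stream
#'
#' @param fixations fixation table keyed by `participant`, `task`.
#' @param boxes face-box table keyed the same way.
#' @param config an [analysis_config()].
#' @return the fixation table with a `label` column.
#' @export
classify_fixations_table <- function(fixations, boxes, config = analysis_config()) {
  keys <- dplyr::distinct(fixations, .data$participant, .data$task)
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    fsub <- fixations[fixations$participant == keys$participant[i] &
                        fixations$task == keys$task[i], , drop = FALSE]
    bsub <- boxes[boxes$participant == keys$participant[i] &
                    boxes$task == keys$task[i], , drop = FALSE]
    out[[i]] <- classify_fixations(fsub, bsub, config)
  }
  dplyr::bind_rows(out)
}

# ---- bilinear quad <-> unit square maps (used by the template remap) --------

# forward bilinear: (u, v) in [0,1]^2 -> scene point inside the quad
forward_bilinear <- function(u, v, box) {
  x <- (1 - u) * (1 - v) * box[1, 1] + u * (1 - v) * box[2, 1] +
    u * v * box[3, 1] + (1 - u) * v * box[4, 1]
  y <- (1 - u) * (1 - v) * box[1, 2] + u * (1 - v) * box[2, 2] +
    u * v * box[3, 2] + (1 - u) * v * box[4, 2]
  cbind(x, y)
}

# inverse bilinear for a single point known to lie inside the convex quad;
# returns c(u, v) in [0,1]^2
inverse_bilinear <- function(px, py, box) {
  ex <- box[2, 1] - box[1, 1]; ey <- box[2, 2] - box[1, 2]        # E = TR - TL
  fx <- box[4, 1] - box[1, 1]; fy <- box[4, 2] - box[1, 2]        # F = BL - TL
  gx <- box[1, 1] - box[2, 1] + box[3, 1] - box[4, 1]             # G = TL-TR+BR-BL
  gy <- box[1, 2] - box[2, 2] + box[3, 2] - box[4, 2]
  hx <- px - box[1, 1]; hy <- py - box[1, 2]                       # H = p - TL
  # (H - vF) x (E + vG) = 0  ->  A v^2 + B v + C = 0
  A <- -cross2(fx, fy, gx, gy)
  B <- cross2(hx, hy, gx, gy) - cross2(fx, fy, ex, ey)
  C <- cross2(hx, hy, ex, ey)
  if (abs(A) < 1e-12) {
    v <- -C / B
  } else {
    disc <- B * B - 4 * A * C
    disc <- max(disc, 0)
    roots <- c((-B + sqrt(disc)) / (2 * A), (-B - sqrt(disc)) / (2 * A))
    v <- roots[which.min(abs(roots - 0.5))]
    inb <- roots >= -1e-9 & roots <= 1 + 1e-9
    if (sum(inb) == 1) v <- roots[inb]
  }
  dx <- ex + v * gx
  dy <- ey + v * gy
  u <- (hx * dx + hy * dy - v * (fx * dx + fy * dy)) / (dx * dx + dy * dy)
  c(u = min(max(u, 0), 1), v = min(max(v, 0), 1))
}
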