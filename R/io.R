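#' Table input/output with schema validation
#'
#' All pipeline tables travel as comma-separated UTF-8 text with one header
#' line and dot decimals. Readers validate the column schema, coerce types,
#' and report malformed rows with their line numbers; ordering invariants
#' (non-decreasing timestamps within a participant x task stream) are
#' enforced on read.
#'
#' @name table-io
NULL

dyad_schemas <- list(
  gaze = list(
    cols = c(participant = "character", task = "character", t = "numeric",
             x = "numeric", y = "numeric", valid = "logical"),
    ordered_by = "t"
  ),
  boxes = list(
    cols = c(participant = "character", task = "character", frame = "integer",
             x_tl = "numeric", y_tl = "numeric", x_tr = "numeric",
             y_tr = "numeric", x_br = "numeric", y_br = "numeric",
             x_bl = "numeric", y_bl = "numeric"),
    ordered_by = "frame"
  ),
  speech = list(
    cols = c(participant = "character", task = "character", t = "numeric",
             event = "character", speaker = "character"),
    ordered_by = "t",
    levels = list(event = c("speech-on", "speech-off", "interruption",
                            "resume-second-sentence"),
                  speaker = c("participant", "partner"))
  ),
  traits = list(
    cols = c(participant = "character", group = "character", aq = "numeric",
             lsas = "numeric"),
    ordered_by = NULL
  ),
  fixations = list(
    cols = c(participant = "character", task = "character",
             t_start = "numeric", t_end = "numeric", duration = "numeric",
             x = "numeric", y = "numeric", dispersion = "numeric",
             frame = "integer"),
    ordered_by = "t_start"
  )
)

read_dyad_table <- function(path, schema_name) {
  if (!file.exists(path)) stop_dyad("schema-error", "file not found: ", path)
  schema <- dyad_schemas[[schema_name]]
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(names(schema$cols), names(raw))
  if (length(missing_cols)) {
    stop_dyad("schema-error", "missing column(s) in ", basename(path), ": ",
              paste(missing_cols, collapse = ", "))
  }
  out <- list()
  for (col in names(schema$cols)) {
    v <- raw[[col]]
    type <- schema$cols[[col]]
    parsed <- switch(type,
      character = v,
      numeric = suppressWarnings(as.numeric(v)),
      integer = suppressWarnings(as.integer(v)),
      logical = parse_flag(v)
    )
    bad <- which(is.na(parsed) & !(is.na(v) | v %in% c("", "NA")))
    if (length(bad)) {
      stop_dyad("schema-error", "unparsable ", type, " in field '", col,
                "' of ", basename(path), " at line(s) ",
                paste(head(bad + 1, 5), collapse = ", "))
    }
    lv <- schema$levels[[col]]
    if (!is.null(lv)) {
      bad <- which(!parsed %in% lv)
      if (length(bad)) {
        stop_dyad("schema-error", "out-of-range value in field '", col,
                  "' of ", basename(path), " at line(s) ",
                  paste(head(bad + 1, 5), collapse = ", "))
      }
    }
    out[[col]] <- parsed
  }
  tb <- tibble::as_tibble(out)
  ob <- schema$ordered_by
  if (!is.null(ob) && all(c("participant", "task") %in% names(tb))) {
    keys <- paste(tb$participant, tb$task)
    for (k in unique(keys)) {
      tv <- tb[[ob]][keys == k]
      if (is.unsorted(tv)) {
        stop_dyad("schema-error", "field '", ob, "' is not non-decreasing ",
                  "within stream ", k, " of ", basename(path))
      }
    }
  }
  tb
}

parse_flag <- function(v) {
  up <- toupper(trimws(v))
  out <- rep(NA, length(v))
  out[up %in% c("TRUE", "T", "1")] <- TRUE
  out[up %in% c("FALSE", "F", "0")] <- FALSE
  out
}

#' @rdname table-io
#' @param path file path.
#' @return the validated table as a tibble.
#' @export
read_gaze_table <- function(path) read_dyad_table(path, "gaze")

#' @rdname table-io
#' @export
read_facebox_table <- function(path) read_dyad_table(path, "boxes")

#' @rdname table-io
#' @export
read_speech_table <- function(path) read_dyad_table(path, "speech")

#' @rdname table-io
#' @export
read_trait_table <- function(path) read_dyad_table(path, "traits")

#' @rdname table-io
#' @export
read_fixation_table <- function(path) read_dyad_table(path, "fixations")

#' @rdname table-io
#' @param x a table to write.
#' @export
write_dyad_table <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read density maps as portable text arrays
#'
#' A density map is stored as a headerless CSV of its height x width values
#' together with a JSON sidecar (`<path>.json`) holding the template extent
#' in degrees, the template scale, the participant and condition, and the
#' missing flag. The round trip is lossless to full double precision.
#'
#' @param map a `density_map` (from [accumulate_density()]/[smooth_map()]).
#' @param path output path for the CSV values; the sidecar gets `.json`
#'   appended.
#' @param template the [face_template()] the map must match.
#' @return `path`, invisibly.
#' @export
write_density_map <- function(map, path, template = face_template()) {
  if (nrow(map) != template$height_px || ncol(map) != template$width_px) {
    stop_dyad("invalid-argument", "map dimensions (", nrow(map), " x ",
              ncol(map), ") do not match the template (",
              template$height_px, " x ", template$width_px, ")")
  }
  utils::write.table(format(unclass(map), digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- list(
    width_px = template$width_px, height_px = template$height_px,
    scale_deg_px = template$scale_deg_px,
    extent_deg = template$extent_deg,
    participant = attr(map, "participant"),
    condition = attr(map, "condition"),
    missing = isTRUE(attr(map, "missing"))
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_density_map
#' @return for `read_density_map`, the `density_map` with its metadata
#'   restored.
#' @export
read_density_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(read.csv(path, header = FALSE))
  dimnames(vals) <- NULL
  if (nrow(vals) != meta$height_px || ncol(vals) != meta$width_px) {
    stop_dyad("schema-error", "density map values do not match sidecar dimensions")
  }
  tpl <- list(width_px = meta$width_px, height_px = meta$height_px,
              scale_deg_px = meta$scale_deg_px, extent_deg = meta$extent_deg)
  class(tpl) <- "face_template"
  m <- new_density_map(vals, tpl,
                       participant = meta$participant %||% NA,
                       condition = meta$condition %||% NA)
  attr(m, "missing") <- isTRUE(meta$missing)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write or read a whole synthetic cohort as a directory of tables
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir directory (created if needed).
#' @return `dir` (write) or a list of tables (read).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dyad_table(cohort$gaze, file.path(dir, "gaze.csv"))
  write_dyad_table(cohort$boxes[, c("participant", "task", "frame", box_cols)],
                   file.path(dir, "boxes.csv"))
  write_dyad_table(cohort$speech, file.path(dir, "speech.csv"))
  write_dyad_table(cohort$traits, file.path(dir, "traits.csv"))
  write_dyad_table(cohort$ground_truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  list(
    gaze = read_gaze_table(file.path(dir, "gaze.csv")),
    boxes = read_facebox_table(file.path(dir, "boxes.csv")),
    speech = read_speech_table(file.path(dir, "speech.csv")),
    traits = read_trait_table(file.path(dir, "traits.csv"))
  )
}
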