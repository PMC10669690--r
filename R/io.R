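# Tabular formats
#
# Trajectory file: UTF-8 TSV, one row per (frame, joint, side) with columns
# animal_id, session, species, sex, condition, side, joint, frame, x, y.
# Metadata header lines are prefixed '#': fps, y_axis_direction, and a note
# fixing the frame-index dialect (0-based frames; step ranges half-open).
# Annotation file: TSV with animal_id, session, side, step_id, start_frame,
# end_frame. Calibration file: JSON with "src" and "dst", four [x, y]
# points each, per camera.

TRAJ_COLUMNS <- c("animal_id", "session", "species", "sex", "condition",
                  "side", "joint", "frame", "x", "y")
ANN_COLUMNS <- c("animal_id", "session", "side", "step_id", "start_frame",
                 "end_frame")

# minimum half-open step width: >= 4 frames, the support a cubic
# interpolating spline needs
MIN_STEP_FRAMES <- 4L

#' Write landmark trajectories
#'
#' Writes the package's tabular trajectory format: a TSV with `#`-prefixed
#' metadata header lines (`fps`, `y_axis_direction`) followed by one row per
#' frame per joint per limb. Coordinates are written in full double
#' precision, so a write/read round trip is lossless.
#'
#' @param trajectories Data frame with columns
#'   `animal_id, session, species, sex, condition, side, joint, frame, x, y`.
#' @param path Output file.
#' @param fps Frames per second recorded in the header (default: the
#'   `fps` attribute of `trajectories`).
#' @param y_axis_direction `"up"` (analysis convention: vertical displacement
#'   increases upward) or `"down"` (image convention; readers flip it).
#' @return Invisibly, `path`.
#' @export
write_trajectories <- function(trajectories, path,
                               fps = attr(trajectories, "fps"),
                               y_axis_direction = "up") {
  stopifnot(is.data.frame(trajectories),
            all(TRAJ_COLUMNS %in% names(trajectories)))
  if (is.null(fps)) stop("fps must be supplied or attached as an attribute",
                         call. = FALSE)
  y_axis_direction <- match.arg(y_axis_direction, c("up", "down"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fps=%.10g", fps),
    sprintf("# y_axis_direction=%s", y_axis_direction),
    "# frames are 0-based; step annotations are half-open [start_frame, end_frame)"
  ), con)
  df <- trajectories[, TRAJ_COLUMNS]
  df$x <- sprintf("%.17g", df$x)
  df$y <- sprintf("%.17g", df$y)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write step annotations
#'
#' @param annotations Data frame with columns
#'   `animal_id, session, side, step_id, start_frame, end_frame`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(is.data.frame(annotations), all(ANN_COLUMNS %in% names(annotations)))
  utils::write.table(annotations[, ANN_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# parse '# key=value' metadata headers; returns list(meta, n_header_lines)
read_tsv_headers <- function(path) {
  meta <- list()
  n <- 0L
  con <- file(path, open = "rt", encoding = "UTF-8")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || !startsWith(line, "#")) break
    n <- n + 1L
    body <- sub("^#\\s*", "", line)
    if (grepl("=", body, fixed = TRUE)) {
      kv <- strsplit(body, "=", fixed = TRUE)[[1]]
      meta[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  list(meta = meta, n_header = n)
}

stop_row <- function(path, file_line, msg) {
  stop(sprintf("%s, line %d: %s", basename(path), file_line, msg),
       call. = FALSE)
}

#' Read landmark trajectories (and optionally step annotations)
#'
#' Parses the tabular trajectory format written by [write_trajectories()],
#' validating every row: known enum levels, strictly increasing frame
#' indices within each trajectory, and session/condition consistency
#' (pre-injury `day0` recordings are controls; `day7` recordings are the
#' lesioned condition). Malformed rows are rejected with their file line
#' number. If the header declares `y_axis_direction=down` (image
#' convention), the vertical coordinate is flipped so that the in-memory
#' convention is always y-up.
#'
#' @param path Trajectory TSV file.
#' @param ann_path Optional annotation TSV ([read_annotations()] is applied).
#' @return A data frame of trajectories with attribute `fps`; if `ann_path`
#'   is given, a list with elements `trajectories` and `annotations`.
#' @export
read_trajectories <- function(path, ann_path = NULL) {
  hdr <- read_tsv_headers(path)
  fps <- suppressWarnings(as.numeric(hdr$meta$fps))
  if (is.null(hdr$meta$fps) || is.na(fps) || fps <= 0) {
    stop(basename(path), ": missing or invalid '# fps=' header", call. = FALSE)
  }
  # enum columns must not be type-inferred (sex "F" would become logical)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = c(animal_id = "character",
                                         session = "character",
                                         species = "character",
                                         sex = "character",
                                         condition = "character",
                                         side = "character",
                                         joint = "character"))
  missing_cols <- setdiff(TRAJ_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop(basename(path), ": missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  # data row r lives on file line n_header + 1 (column header) + r
  line_of <- function(r) hdr$n_header + 1L + r
  check_enum <- function(col, levels) {
    bad <- which(!df[[col]] %in% levels)
    if (length(bad) > 0L) {
      stop_row(path, line_of(bad[1]),
               sprintf("unknown %s '%s' (expected one of: %s)",
                       col, df[[col]][bad[1]], paste(levels, collapse = ", ")))
    }
  }
  check_enum("session", SESSIONS)
  check_enum("species", SPECIES)
  check_enum("sex", SEXES)
  check_enum("condition", CONDITIONS)
  check_enum("side", SIDES)
  check_enum("joint", JOINTS)
  if (any(!is.finite(df$frame)) || any(df$frame < 0) ||
      any(df$frame != floor(df$frame))) {
    bad <- which(!is.finite(df$frame) | df$frame < 0 | df$frame != floor(df$frame))[1]
    stop_row(path, line_of(bad), "frame must be a non-negative integer")
  }
  bad_xy <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(bad_xy) > 0L) {
    stop_row(path, line_of(bad_xy[1]), "non-finite coordinate")
  }
  mismatch <- which((df$session == "day0" & df$condition != "control") |
                    (df$session == "day7" & df$condition != "lesioned"))
  if (length(mismatch) > 0L) {
    stop_row(path, line_of(mismatch[1]),
             "session/condition mismatch (day0 is control, day7 is lesioned)")
  }
  key <- interaction(df$animal_id, df$session, df$side, df$joint, drop = TRUE)
  for (k in levels(key)) {
    idx <- which(key == k)
    fr <- df$frame[idx]
    if (any(diff(fr) <= 0)) {
      bad <- idx[which(diff(fr) <= 0)[1] + 1L]
      stop_row(path, line_of(bad),
               sprintf("frame indices not strictly increasing within trajectory %s", k))
    }
  }
  if (identical(hdr$meta$y_axis_direction, "down")) df$y <- -df$y
  attr(df, "fps") <- fps
  if (is.null(ann_path)) return(df)
  list(trajectories = df, annotations = read_annotations(ann_path))
}

#' Read step annotations
#'
#' Validates that each annotation is a half-open `[start_frame, end_frame)`
#' range at least 4 frames wide (the minimum support for cubic-spline
#' time normalization); violations are reported with the offending line.
#'
#' @param path Annotation TSV file.
#' @return Data frame with columns
#'   `animal_id, session, side, step_id, start_frame, end_frame`.
#' @export
read_annotations <- function(path) {
  hdr <- read_tsv_headers(path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = c(animal_id = "character",
                                         session = "character",
                                         side = "character"))
  missing_cols <- setdiff(ANN_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop(basename(path), ": missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  line_of <- function(r) hdr$n_header + 1L + r
  bad <- which(df$end_frame - df$start_frame < MIN_STEP_FRAMES)
  if (length(bad) > 0L) {
    r <- bad[1]
    stop_row(path, line_of(r),
             sprintf("annotation %s/%s/%s step %s: [%d, %d) spans %d frame(s); at least %d required",
                     df$animal_id[r], df$session[r], df$side[r], df$step_id[r],
                     df$start_frame[r], df$end_frame[r],
                     df$end_frame[r] - df$start_frame[r], MIN_STEP_FRAMES))
  }
  if (any(df$start_frame < 0)) {
    stop_row(path, line_of(which(df$start_frame < 0)[1]),
             "start_frame must be >= 0")
  }
  df
}

#' Read a four-point homography calibration file
#'
#' The file is JSON with members `src` and `dst`, each an array of four
#' `[x, y]` points (observed image points and their true positions).
#'
#' @param path Calibration JSON file.
#' @return List with 4x2 numeric matrices `src` and `dst`.
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("src", "dst")) {
    m <- obj[[nm]]
    if (is.null(m) || !is.numeric(m <- as.matrix(m)) || !all(dim(m) == c(4, 2))) {
      stop(basename(path), ": '", nm, "' must be four [x, y] points",
           call. = FALSE)
    }
    obj[[nm]] <- m
  }
  list(src = obj$src, dst = obj$dst)
}
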