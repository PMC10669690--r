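# Step extraction and time normalization to the 100-bin step cycle.

N_BINS <- 100L

#' Extract one annotated step from a trajectory
#'
#' Cuts the frames of the half-open range `[start_frame, end_frame)` out of
#' a single-joint trajectory and attaches time in seconds (`t = frame/fps`).
#'
#' @param traj Data frame of one trajectory (one animal/session/side/joint),
#'   columns `frame`, `x`, `y`, with an `fps` attribute or `fps` argument.
#' @param ann List or one-row data frame with `start_frame` and `end_frame`.
#' @param fps Frames per second; defaults to the `fps` attribute of `traj`.
#' @return Data frame with columns `t`, `x`, `y` (one row per frame).
#' @export
extract_step <- function(traj, ann, fps = attr(traj, "fps")) {
  stopifnot(is.data.frame(traj), all(c("frame", "x", "y") %in% names(traj)))
  if (is.null(fps) || !is.numeric(fps) || fps <= 0) {
    stop("fps must be a positive number (argument or attribute)", call. = FALSE)
  }
  start <- as.integer(ann$start_frame)
  end <- as.integer(ann$end_frame)
  if (end - start < MIN_STEP_FRAMES) {
    stop(sprintf("step [%d, %d) spans %d frame(s); at least %d required for spline normalization",
                 start, end, end - start, MIN_STEP_FRAMES), call. = FALSE)
  }
  if (start < min(traj$frame) || end - 1L > max(traj$frame)) {
    stop(sprintf("step [%d, %d) exceeds trajectory extent [%d, %d]",
                 start, end, min(traj$frame), max(traj$frame)), call. = FALSE)
  }
  keep <- traj$frame >= start & traj$frame < end
  seg <- data.frame(t = traj$frame[keep] / fps, x = traj$x[keep],
                    y = traj$y[keep])
  if (nrow(seg) < MIN_STEP_FRAMES) {
    stop(sprintf("step [%d, %d) contains only %d sampled frame(s)",
                 start, end, nrow(seg)), call. = FALSE)
  }
  seg
}

#' Time-normalize a step to the 100-bin step cycle
#'
#' Fits a natural cubic interpolating spline to each coordinate over
#' normalized time `u = (t - t_start)/(t_end - t_start)` and evaluates it at
#' the 100 cycle bins `u_i = (i - 1)/99`, `i = 1..100` (bin 1 is step start,
#' bin 100 step end). This is interpolation, not smoothing: the curve passes
#' through every original sample, endpoints are preserved exactly, and the
#' result is invariant to uniform rescaling of the time axis. Amplitude is
#' left in AU; set `standardize_amplitude = TRUE` to additionally rescale
#' each coordinate to zero mean and unit SD across the cycle.
#'
#' @param segment Data frame from [extract_step()] (columns `t`, `x`, `y`),
#'   at least 4 samples with strictly increasing `t`.
#' @param standardize_amplitude Logical; default `FALSE` (time-only
#'   normalization).
#' @return An object of class `step_curve`: list with numeric `x` and `y` of
#'   length 100 plus a `bin` index `1:100`.
#' @export
normalize_step <- function(segment, standardize_amplitude = FALSE) {
  stopifnot(is.data.frame(segment), all(c("t", "x", "y") %in% names(segment)))
  n <- nrow(segment)
  if (n < MIN_STEP_FRAMES) {
    stop("segment must contain at least ", MIN_STEP_FRAMES, " samples",
         call. = FALSE)
  }
  dt <- diff(segment$t)
  if (any(dt == 0)) stop("duplicate timestamps in segment", call. = FALSE)
  if (any(dt < 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  u <- (segment$t - segment$t[1]) / (segment$t[n] - segment$t[1])
  u_out <- (seq_len(N_BINS) - 1) / (N_BINS - 1)
  x <- stats::spline(u, segment$x, xout = u_out, method = "natural")$y
  y <- stats::spline(u, segment$y, xout = u_out, method = "natural")$y
  if (standardize_amplitude) {
    std <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v - mean(v)
    x <- std(x); y <- std(y)
  }
  structure(list(bin = seq_len(N_BINS), x = x, y = y), class = "step_curve")
}

#' @export
print.step_curve <- function(x, ...) {
  cat(sprintf("<step_curve> 100 bins; x range [%.3g, %.3g], y range [%.3g, %.3g] AU\n",
              min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' Normalize every annotated step of a cohort
#'
#' Applies [extract_step()] and [normalize_step()] to each (annotation,
#' joint) combination, producing the long table of normalized step curves
#' on which the dissimilarity and bin-wise analyses operate. Step
#' annotations are per limb and shared by the three joints tracked on it.
#'
#' @param trajectories Trajectory data frame (see [read_trajectories()]).
#' @param annotations Annotation data frame (see [read_annotations()]).
#' @param fps Frames per second; defaults to the `fps` attribute.
#' @param standardize_amplitude Passed to [normalize_step()].
#' @return Data frame with one row per (curve, bin): `curve_id, animal_id,
#'   session, species, sex, condition, group, side, joint, step_id, bin, x,
#'   y`, 100 rows per curve. `group` is the compact label from
#'   [group_label()].
#' @export
normalize_cohort <- function(trajectories, annotations,
                             fps = attr(trajectories, "fps"),
                             standardize_amplitude = FALSE) {
  stopifnot(is.data.frame(trajectories), is.data.frame(annotations))
  if (is.null(fps)) stop("fps must be supplied or attached", call. = FALSE)
  traj_split <- split(trajectories,
                      interaction(trajectories$animal_id, trajectories$session,
                                  trajectories$side, trajectories$joint,
                                  drop = TRUE))
  out <- vector("list", nrow(annotations) * length(JOINTS))
  k <- 0L
  for (tr in traj_split) {
    meta <- tr[1, c("animal_id", "session", "species", "sex", "condition",
                    "side", "joint")]
    ann_rows <- annotations[annotations$animal_id == meta$animal_id &
                            annotations$session == meta$session &
                            annotations$side == meta$side, , drop = FALSE]
    for (r in seq_len(nrow(ann_rows))) {
      seg <- extract_step(tr, ann_rows[r, ], fps = fps)
      curve <- normalize_step(seg, standardize_amplitude)
      k <- k + 1L
      out[[k]] <- data.frame(
        curve_id = paste(meta$animal_id, meta$session, meta$side, meta$joint,
                         ann_rows$step_id[r], sep = "_"),
        animal_id = meta$animal_id, session = meta$session,
        species = meta$species, sex = meta$sex, condition = meta$condition,
        group = group_label(meta$species, meta$sex, meta$condition),
        side = meta$side, joint = meta$joint, step_id = ann_rows$step_id[r],
        bin = curve$bin, x = curve$x, y = curve$y
      )
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

# reshape a long curve table (one joint/side slice) into 100 x n_curves
# matrices; curves keep their column order
curves_to_matrices <- function(curves) {
  stopifnot(all(c("curve_id", "bin", "x", "y") %in% names(curves)))
  ids <- unique(curves$curve_id)
  ord <- order(match(curves$curve_id, ids), curves$bin)
  curves <- curves[ord, ]
  if (nrow(curves) != length(ids) * N_BINS ||
      !all(curves$bin == rep(seq_len(N_BINS), length(ids)))) {
    stop("each curve must have exactly one row per bin 1..100", call. = FALSE)
  }
  first <- curves[curves$bin == 1L, , drop = FALSE]
  list(
    x = matrix(curves$x, nrow = N_BINS, dimnames = list(NULL, ids)),
    y = matrix(curves$y, nrow = N_BINS, dimnames = list(NULL, ids)),
    meta = first
  )
}
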