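# Four-point planar homography estimation and application, used to undo
# lens-induced distortion of the tunnel-walk image plane before any
# kinematic measurement.

collinear_triple <- function(pts, tol = 1e-9) {
  combs <- utils::combn(nrow(pts), 3)
  for (j in seq_len(ncol(combs))) {
    p <- pts[combs[, j], , drop = FALSE]
    # twice the signed triangle area, scaled by the point spread
    area2 <- abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
                 (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2]))
    scale <- max(abs(p)) + 1
    if (area2 <= tol * scale^2) return(TRUE)
  }
  FALSE
}

#' Estimate a homography from four point correspondences
#'
#' Solves the minimal four-point problem exactly: the eight projective
#' equations `dst_k ~ H src_k` are assembled into an 8x8 linear system in
#' the first eight entries of `H` (with `H[3,3]` fixed at 1) and solved
#' directly. Four correspondences in general position determine the
#' homography uniquely; each correspondence is reproduced to numerical
#' precision.
#'
#' @param src,dst 4x2 numeric matrices of corresponding points (rows are
#'   `(x, y)`); no three points of either set may be collinear.
#' @return A 3x3 matrix normalized so that `H[3,3] = 1`.
#' @examples
#' sq <- matrix(c(0,0, 1,0, 1,1, 0,1), ncol = 2, byrow = TRUE)
#' H <- estimate_homography(sq, 2 * sq) # diag(2, 2, 1)
#' @export
estimate_homography <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (!all(dim(src) == c(4, 2)) || !all(dim(dst) == c(4, 2)) ||
      !is.numeric(src) || !is.numeric(dst)) {
    stop("src and dst must be 4x2 numeric matrices", call. = FALSE)
  }
  if (collinear_triple(src) || collinear_triple(dst)) {
    stop("degenerate configuration: three of the four points are collinear",
         call. = FALSE)
  }
  A <- matrix(0, 8, 8)
  b <- numeric(8)
  for (k in 1:4) {
    x <- src[k, 1]; y <- src[k, 2]
    u <- dst[k, 1]; v <- dst[k, 2]
    A[2 * k - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * k, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * k - 1] <- u
    b[2 * k] <- v
  }
  h <- tryCatch(solve(A, b),
                error = function(e) stop("degenerate configuration: ",
                                         conditionMessage(e), call. = FALSE))
  H <- matrix(c(h, 1), 3, 3, byrow = TRUE)
  if (abs(det(H)) < .Machine$double.eps) {
    stop("estimated homography is singular", call. = FALSE)
  }
  H
}

#' Project points through a homography
#'
#' Maps each row `(x, y)` projectively: `(x', y', w') = H (x, y, 1)`,
#' returning `(x'/w', y'/w')`.
#'
#' @param H 3x3 invertible matrix.
#' @param pts n x 2 numeric matrix.
#' @return n x 2 matrix of projected points.
#' @export
project_points <- function(H, pts) {
  stopifnot(is.matrix(H), all(dim(H) == c(3, 3)))
  if (abs(det(H)) < .Machine$double.eps) {
    stop("homography must be invertible", call. = FALSE)
  }
  pts <- as.matrix(pts)
  hom <- cbind(pts, 1) %*% t(H)
  w <- hom[, 3]
  bad <- which(abs(w) < .Machine$double.eps)
  if (length(bad) > 0L) {
    stop("point ", bad[1], " maps to the line at infinity (w' = 0)",
         call. = FALSE)
  }
  hom[, 1:2] / w
}

#' Apply a homography to landmark trajectories
#'
#' Replaces each frame's `(x, y)` by its projective image under `H`; frame
#' indices and all metadata columns are unchanged. A frame mapping to the
#' line at infinity (`w' = 0`) is an error naming the frame.
#'
#' @param H 3x3 invertible matrix, e.g. from [estimate_homography()].
#' @param trajectories Trajectory data frame (columns `x`, `y`, `frame`).
#' @return The data frame with corrected coordinates.
#' @export
apply_homography <- function(H, trajectories) {
  stopifnot(is.data.frame(trajectories),
            all(c("x", "y", "frame") %in% names(trajectories)))
  pts <- cbind(trajectories$x, trajectories$y)
  hom <- cbind(pts, 1) %*% t(H)
  w <- hom[, 3]
  bad <- which(abs(w) < .Machine$double.eps)
  if (length(bad) > 0L) {
    stop(sprintf("frame %d (row %d) maps to the line at infinity (w' = 0)",
                 trajectories$frame[bad[1]], bad[1]), call. = FALSE)
  }
  out <- trajectories
  out$x <- hom[, 1] / w
  out$y <- hom[, 2] / w
  out
}
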