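# The dissimilarity factor (DF): the curve-comparison statistic of the
# analysis. For two normalized step curves a and b,
#
#   DF(a, b) = (1/200) [ sum_i (x_a(i) - x_b(i))^2 + sum_i (y_a(i) - y_b(i))^2 ]
#
# i.e. the mean of the 200 squared coordinate differences over the 100
# cycle bins and both axes. Note: although the quantity is often described
# as a Euclidean distance, the defining formula is a mean of SQUARED
# differences (no square root); that formula is implemented verbatim.
# Units are therefore AU^2, DF >= 0, and DF = 0 iff the curves coincide at
# all 200 coordinates.

#' Dissimilarity factor between two normalized step curves
#'
#' Computes the mean of the 200 squared coordinate differences between two
#' 100-bin step curves (both axes). Symmetric in its arguments and
#' non-negative; zero exactly when the curves are identical.
#'
#' @param a,b `step_curve` objects ([normalize_step()]) or lists with
#'   numeric `x` and `y` of length 100.
#' @param check_meta If both curves carry `joint`/`side` fields, require
#'   them to match (curves of different joints are not comparable).
#' @return A single non-negative number, AU squared.
#' @examples
#' a <- list(x = rep(0, 100), y = rep(0, 100))
#' b <- list(x = rep(0, 100), y = rep(2, 100))
#' dissimilarity_factor(a, b) # 2^2 * 100 / 200 = 2
#' @export
dissimilarity_factor <- function(a, b, check_meta = TRUE) {
  for (cur in list(a, b)) {
    if (!is.numeric(cur$x) || !is.numeric(cur$y) ||
        length(cur$x) != 100L || length(cur$y) != 100L) {
      stop("curves must have numeric x and y of length 100", call. = FALSE)
    }
  }
  if (check_meta) {
    for (fld in c("joint", "side")) {
      if (!is.null(a[[fld]]) && !is.null(b[[fld]]) &&
          !identical(a[[fld]], b[[fld]])) {
        stop("curves differ in ", fld, " (", a[[fld]], " vs ", b[[fld]],
             "); DF compares like with like", call. = FALSE)
      }
    }
  }
  (sum((a$x - b$x)^2) + sum((a$y - b$y)^2)) / 200
}

#' All cross-animal DF records for a set of curves
#'
#' Computes the dissimilarity factor for every unordered pair of curves
#' whose animals differ: steps of the same animal are never compared with
#' each other, and each pair appears once. With animals `u` having `n_u`
#' curves, the number of records is `sum_{u<v} n_u n_v`.
#'
#' The input is a slice of the long curve table for ONE joint and side
#' (typically also one group; pass curves of several groups to obtain
#' cross-condition pairs as well).
#'
#' @param curves Long-format curve table (see [normalize_cohort()]) with a
#'   single `joint` and `side`; at least two distinct animals.
#' @return Data frame of DF records: `curve_id_a, curve_id_b, animal_id_a,
#'   animal_id_b, group_a, group_b, joint, side, df`.
#' @examples
#' # 2 animals x 2 curves each -> 4 cross-animal records
#' @export
pairwise_df <- function(curves) {
  stopifnot(is.data.frame(curves))
  if (length(unique(curves$joint)) != 1L || length(unique(curves$side)) != 1L) {
    stop("curves must belong to a single joint and side", call. = FALSE)
  }
  m <- curves_to_matrices(curves)
  n <- ncol(m$x)
  animals <- m$meta$animal_id
  if (length(unique(animals)) < 2L) {
    stop("cross-animal DF needs curves from at least 2 distinct animals",
         call. = FALSE)
  }
  # pairwise mean squared coordinate differences via the Gram trick
  sq <- colSums(m$x^2) + colSums(m$y^2)
  G <- crossprod(m$x) + crossprod(m$y)
  D <- (outer(sq, sq, "+") - 2 * G) / 200
  D[D < 0] <- 0 # numerical floor

  pair <- which(upper.tri(D), arr.ind = TRUE)
  keep <- animals[pair[, 1]] != animals[pair[, 2]]
  pair <- pair[keep, , drop = FALSE]
  i <- pair[, 1]; j <- pair[, 2]
  grp <- if ("group" %in% names(m$meta)) m$meta$group else
    rep(NA_character_, n)
  data.frame(
    curve_id_a = m$meta$curve_id[i], curve_id_b = m$meta$curve_id[j],
    animal_id_a = animals[i], animal_id_b = animals[j],
    group_a = grp[i], group_b = grp[j],
    joint = m$meta$joint[1], side = m$meta$side[1],
    df = D[cbind(i, j)]
  )
}

#' DF distributions per group for one joint and side
#'
#' Builds the within-group cross-animal DF distribution for each group
#' present in `curves` (same joint/side), the unit of the group-level
#' Kruskal-Wallis/Dunn comparison. Optionally adds, for each lesioned
#' group, the distribution of pairs between its curves and the matching
#' control group's curves (`cross_condition = TRUE`).
#'
#' @param curves Long curve table restricted to one joint and side.
#' @param cross_condition Also compute lesioned-vs-control pair
#'   distributions (named `"<lesioned>:<control>"`). Default `FALSE`
#'   (within-group only).
#' @return Named list of data frames of DF records, one per group.
#' @export
group_df_distributions <- function(curves, cross_condition = FALSE) {
  groups <- unique(curves$group)
  out <- list()
  for (g in groups) {
    sub <- curves[curves$group == g, , drop = FALSE]
    if (length(unique(sub$animal_id)) >= 2L) out[[g]] <- pairwise_df(sub)
  }
  if (cross_condition) {
    for (g in groups) {
      info <- parse_group_label(g)
      if (info$condition != "lesioned") next
      ctrl <- group_label(info$species, info$sex, "control")
      if (!ctrl %in% groups) next
      sub <- curves[curves$group %in% c(g, ctrl), , drop = FALSE]
      rec <- pairwise_df(sub)
      rec <- rec[rec$group_a != rec$group_b, , drop = FALSE]
      out[[paste(g, ctrl, sep = ":")]] <- rec
    }
  }
  out
}
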