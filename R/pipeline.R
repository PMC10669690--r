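# End-to-end orchestration: simulate/ingest -> homography correction ->
# step normalization -> DF distributions + Kruskal-Wallis/Dunn -> bin-wise
# contrasts, emitting a machine-readable report plus TSV tables.

# drop S3 classes recursively so arbitrary configs serialize to JSON
strip_classes <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  x
}

# FNV-1a 32-bit hash of a string; cheap provenance fingerprint for configs
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (b < 256); h itself exceeds integer range
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Analysis run configuration
#'
#' Bundles everything one end-to-end run needs: the input source (a
#' synthetic [cohort_config()] or file paths), the group contrasts to test
#' bin-wise, the joints/sides to analyse, and the statistical settings.
#'
#' @param cohort A [cohort_config()] for synthetic input, or `NULL` when
#'   reading files.
#' @param trajectories_path,annotations_path Input TSV paths (ignored when
#'   `cohort` is given).
#' @param calibration_path Optional four-point calibration JSON; when given,
#'   the estimated homography is applied to all trajectories before
#'   analysis.
#' @param contrasts List of length-2 character vectors of group labels
#'   (e.g. `c("CMR", "LMR")`). `NULL` (default) auto-builds the
#'   control-vs-lesioned contrast for every species/sex present.
#' @param joints,sides Subsets of joints/sides to analyse (default: all
#'   present).
#' @param axis,alpha,tail,p_adjust,animal_means Passed to
#'   [binwise_compare()].
#' @param cross_condition Passed to [group_df_distributions()].
#' @param seed Integer; when `cohort` is given, replaces its seed so one
#'   number controls the whole run.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = NULL, trajectories_path = NULL,
                       annotations_path = NULL, calibration_path = NULL,
                       contrasts = NULL, joints = NULL, sides = NULL,
                       axis = "y", alpha = 0.05,
                       tail = c("one_sided_auto", "two_sided"),
                       p_adjust = c("none", "BH"), animal_means = FALSE,
                       cross_condition = FALSE, seed = NULL) {
  tail <- match.arg(tail)
  p_adjust <- match.arg(p_adjust)
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(cohort)) {
    if (is.null(trajectories_path) || is.null(annotations_path)) {
      stop("either a cohort config or trajectory+annotation paths are required",
           call. = FALSE)
    }
  } else {
    stopifnot(inherits(cohort, "cohort_config"))
    if (!is.null(seed)) cohort$seed <- as.integer(seed)
  }
  if (!is.null(contrasts)) {
    for (ct in contrasts) {
      if (length(ct) != 2L) stop("each contrast must name two groups",
                                 call. = FALSE)
      lapply(ct, parse_group_label)
    }
  }
  structure(
    list(cohort = cohort, trajectories_path = trajectories_path,
         annotations_path = annotations_path,
         calibration_path = calibration_path, contrasts = contrasts,
         joints = joints, sides = sides, axis = axis, alpha = alpha,
         tail = tail, p_adjust = p_adjust, animal_means = animal_means,
         cross_condition = cross_condition, seed = seed),
    class = "run_config"
  )
}

default_contrasts <- function(groups_present) {
  out <- list()
  for (sp in SPECIES) for (sx in SEXES) {
    ctrl <- group_label(sp, sx, "control")
    les <- group_label(sp, sx, "lesioned")
    if (ctrl %in% groups_present && les %in% groups_present) {
      out[[length(out) + 1L]] <- c(ctrl, les)
    }
  }
  out
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes all stages under a single configuration: obtain trajectories
#' (synthesize a cohort or read files), optionally apply the four-point
#' homography correction, normalize every annotated step to the 100-bin
#' cycle, build per-group cross-animal DF distributions with
#' Kruskal-Wallis/Dunn comparison per joint and side, and run the
#' configured bin-wise contrasts. Deterministic given the configuration
#' (including its seed). Stage failures propagate with the stage name.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `curves.tsv`, `df.tsv`, `binwise.tsv` and `report.json` (and, for
#'   synthetic input, the cohort files).
#' @return Object of class `run_report`: a list with `provenance`
#'   (config hash, seed, package version, record counts), `binwise`
#'   (data frame: one row per joint/side/contrast with `percent_changed`),
#'   `binwise_detail` (per-bin tables), `df_summary` (data frame: median,
#'   IQR, n pairs per group/joint/side), and `df_tests` (per joint/side
#'   [kruskal_dunn()] results).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))

  if (!is.null(config$cohort)) {
    cohort <- pipeline_stage("simulate", generate_cohort(config$cohort))
    trajectories <- cohort$trajectories
    annotations <- cohort$annotations
    fps <- config$cohort$fps
  } else {
    cohort <- NULL
    inp <- pipeline_stage("ingest",
      read_trajectories(config$trajectories_path, config$annotations_path))
    trajectories <- inp$trajectories
    annotations <- inp$annotations
    fps <- attr(trajectories, "fps")
  }

  if (!is.null(config$calibration_path)) {
    trajectories <- pipeline_stage("calibrate", {
      cal <- read_calibration(config$calibration_path)
      H <- estimate_homography(cal$src, cal$dst)
      out <- apply_homography(H, trajectories)
      attr(out, "fps") <- fps
      out
    })
  }

  curves <- pipeline_stage("normalize",
    normalize_cohort(trajectories, annotations, fps = fps))

  joints <- if (is.null(config$joints)) unique(curves$joint) else config$joints
  sides <- if (is.null(config$sides)) unique(curves$side) else config$sides
  groups_present <- unique(curves$group)
  contrasts <- if (is.null(config$contrasts)) {
    default_contrasts(groups_present)
  } else config$contrasts
  for (ct in contrasts) {
    if (!all(ct %in% groups_present)) {
      stop("[stage contrasts] contrast ", paste(ct, collapse = ":"),
           " references a group absent from the data", call. = FALSE)
    }
  }

  df_records <- list()
  df_summary <- list()
  df_tests <- list()
  binwise_rows <- list()
  binwise_detail <- list()

  for (joint in joints) for (side in sides) {
    slice <- curves[curves$joint == joint & curves$side == side, ,
                    drop = FALSE]
    if (nrow(slice) == 0L) next
    key <- paste(joint, side, sep = ".")

    dists <- pipeline_stage("df",
      group_df_distributions(slice, cross_condition = config$cross_condition))
    for (g in names(dists)) {
      rec <- dists[[g]]
      df_records[[paste(key, g)]] <- rec
      df_summary[[paste(key, g)]] <- data.frame(
        joint = joint, side = side, group = g, n_pairs = nrow(rec),
        median = stats::median(rec$df), iqr = stats::IQR(rec$df),
        mean = mean(rec$df)
      )
    }
    within <- dists[names(dists) %in% groups_present]
    if (length(within) >= 2L) {
      df_tests[[key]] <- pipeline_stage("dfstats",
        kruskal_dunn(lapply(within, `[[`, "df"), alpha = config$alpha))
    }

    for (ct in contrasts) {
      ca <- slice[slice$group == ct[1], , drop = FALSE]
      cb <- slice[slice$group == ct[2], , drop = FALSE]
      if (nrow(ca) == 0L || nrow(cb) == 0L) next
      comp <- pipeline_stage("binwise",
        binwise_compare(ca, cb, axis = config$axis, alpha = config$alpha,
                        tail = config$tail, p_adjust = config$p_adjust,
                        animal_means = config$animal_means))
      ckey <- paste(key, paste(ct, collapse = ":"))
      binwise_detail[[ckey]] <- comp
      binwise_rows[[ckey]] <- data.frame(
        joint = joint, side = side,
        contrast = paste(ct, collapse = ":"), axis = config$axis,
        percent_changed = comp$percent_changed, n_a = comp$n_a,
        n_b = comp$n_b
      )
    }
  }

  binwise <- if (length(binwise_rows)) do.call(rbind, binwise_rows) else
    data.frame()
  dfsum <- if (length(df_summary)) do.call(rbind, df_summary) else
    data.frame()
  rownames(binwise) <- NULL
  rownames(dfsum) <- NULL

  cfg_json <- jsonlite::toJSON(strip_classes(config), auto_unbox = TRUE,
                               digits = NA, null = "null")
  report <- structure(
    list(
      provenance = list(
        config_hash = fnv1a(as.character(cfg_json)),
        seed = if (!is.null(config$cohort)) config$cohort$seed else config$seed,
        package_version = as.character(utils::packageVersion("gaitdf")),
        n_trajectories = nrow(unique(trajectories[, c("animal_id", "session",
                                                      "side", "joint")])),
        n_steps = nrow(annotations),
        n_curves = length(unique(curves$curve_id)),
        contrasts = vapply(contrasts, paste, "", collapse = ":")
      ),
      binwise = binwise, binwise_detail = binwise_detail,
      df_summary = dfsum, df_tests = df_tests
    ),
    class = "run_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(cohort)) write_cohort(cohort, out_dir)
    utils::write.table(curves, file.path(out_dir, "curves.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    all_df <- do.call(rbind, df_records)
    utils::write.table(all_df, file.path(out_dir, "df.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    bins_out <- do.call(rbind, lapply(names(binwise_detail), function(k) {
      d <- binwise_detail[[k]]
      cbind(joint = d$joint, side = d$side,
            contrast = paste(d$group_a, d$group_b, sep = ":"), d$bins)
    }))
    utils::write.table(bins_out, file.path(out_dir, "binwise.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_report_json(report, file.path(out_dir, "report.json"))
  }
  report
}

# serialize the report (without the bulky per-bin tables) to JSON
write_report_json <- function(report, path) {
  out <- list(
    provenance = report$provenance,
    binwise = report$binwise,
    df_summary = report$df_summary,
    df_tests = lapply(report$df_tests, function(tst) {
      list(kw_H = tst$kw_H, kw_p = tst$kw_p, dunn = tst$dunn,
           n = as.list(tst$n))
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d curves from %d steps (%d trajectories); config %s\n",
              x$provenance$n_curves, x$provenance$n_steps,
              x$provenance$n_trajectories, x$provenance$config_hash))
  if (nrow(x$binwise) > 0) {
    cat("  percent of step cycle changed:\n")
    print(x$binwise, row.names = FALSE)
  }
  invisible(x)
}
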