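#' Default joint waveform templates
#'
#' One template per (species, joint), reflecting the qualitative shapes of
#' walking rodents: in rats the metatarsus and ankle rise and fall once per
#' cycle (unidirectional) while the knee swings both ways (pendular); in
#' mice the pattern is reversed (pendular metatarsus and ankle,
#' unidirectional knee). Amplitudes scale with body size (rat ~10 AU,
#' mouse ~4 AU); baselines stack the joints vertically (metatarsus lowest,
#' knee highest). Both sides of the body share a template.
#'
#' @return Named list of [waveform_template()] objects keyed
#'   `"<species>.<joint>"`.
#' @export
default_templates <- function() {
  list(
    rat.metatarsus = waveform_template("unidirectional", amplitude = 10,
                                       baseline = 5, phase_peak = 65),
    rat.ankle = waveform_template("unidirectional", amplitude = 8,
                                  baseline = 15, phase_peak = 55),
    rat.knee = waveform_template("pendular", amplitude = 5, baseline = 30,
                                 phase_peak = 30, second_extremum_bin = 75),
    mouse.metatarsus = waveform_template("pendular", amplitude = 4,
                                         baseline = 2, phase_peak = 35,
                                         second_extremum_bin = 80),
    mouse.ankle = waveform_template("pendular", amplitude = 3, baseline = 6,
                                    phase_peak = 30, second_extremum_bin = 75),
    mouse.knee = waveform_template("unidirectional", amplitude = 2.5,
                                   baseline = 12, phase_peak = 50)
  )
}

# template lookup: side-specific key wins over the species.joint key
lookup_template <- function(templates, species, joint, side) {
  tpl <- templates[[paste(species, joint, side, sep = ".")]]
  if (is.null(tpl)) tpl <- templates[[paste(species, joint, sep = ".")]]
  if (is.null(tpl)) {
    stop("no template for ", paste(species, joint, side, sep = "/"),
         call. = FALSE)
  }
  tpl
}

lookup_effect <- function(effects, species, sex, joint, side) {
  if (is.null(effects) || length(effects) == 0L) return(NULL)
  effects[[paste(species, sex, joint, side, sep = ".")]]
}

#' Synthetic cohort configuration
#'
#' Describes a cohort of animals whose hindlimb landmark trajectories are to
#' be simulated: the group design (species x sex x condition), sampling rate,
#' step durations, noise levels, joint waveform templates, and the lesion
#' effects (if any) applied to the lesioned groups' waveforms.
#'
#' The defaults mirror a typical tunnel-walk study design: the eight groups
#' CMR, CFR, CMM, CFM, LMR, LFR, LMM, LFM with five animals each, six
#' analysed steps per animal, recorded at 240 frames per second. Step-cycle
#' durations are drawn uniformly per step (rats 0.65-0.85 s, mice
#' 0.35-0.55 s — slow overground walking). Noise is additive Gaussian:
#' `noise_sd_step` per cycle bin per step (within-animal variability) and
#' `noise_sd_animal` as a per-animal template offset (between-animal
#' variability), both in AU.
#'
#' @param groups Data frame with columns `species`, `sex`, `condition`; one
#'   row per group. Default: all eight combinations.
#' @param animals_per_group Animals per group, `>= 2` (cross-animal DF pairs
#'   need at least two animals). Default 5.
#' @param steps_per_animal Annotated steps per animal per limb. Default 6.
#' @param fps Sampling rate, frames per second. Default 240.
#' @param step_duration_range Named list (by species) of length-2 numeric
#'   ranges in seconds, or a single length-2 numeric applied to all species.
#' @param noise_sd_step Within-animal per-bin noise SD, AU, `>= 0`.
#' @param noise_sd_animal Between-animal offset SD, AU, `>= 0`.
#' @param stride_length Named numeric: forward distance covered per step
#'   cycle (AU) by species; sets the slope of the horizontal coordinate.
#' @param templates Named list of [waveform_template()]s keyed
#'   `"<species>.<joint>"` (optionally `"<species>.<joint>.<side>"`).
#' @param lesion_effects Named list of [lesion_effect()]s keyed
#'   `"<species>.<sex>.<joint>.<side>"`, applied only to lesioned groups.
#'   Default none (a null cohort).
#' @param seed Integer seed; the generated cohort is a pure function of the
#'   configuration including the seed.
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(groups = NULL,
                          animals_per_group = 5L,
                          steps_per_animal = 6L,
                          fps = 240,
                          step_duration_range = list(rat = c(0.65, 0.85),
                                                     mouse = c(0.35, 0.55)),
                          noise_sd_step = 0.5,
                          noise_sd_animal = 0.3,
                          stride_length = c(rat = 20, mouse = 8),
                          templates = default_templates(),
                          lesion_effects = list(),
                          seed = 1L) {
  if (is.null(groups)) {
    groups <- expand.grid(condition = CONDITIONS, sex = SEXES,
                          species = SPECIES, stringsAsFactors = FALSE)
    groups <- groups[, c("species", "sex", "condition")]
  }
  stopifnot(is.data.frame(groups),
            all(c("species", "sex", "condition") %in% names(groups)))
  if (!all(groups$species %in% SPECIES) || !all(groups$sex %in% SEXES) ||
      !all(groups$condition %in% CONDITIONS)) {
    stop("groups must use species rat/mouse, sex M/F, condition control/lesioned",
         call. = FALSE)
  }
  if (animals_per_group < 2) {
    stop("animals_per_group must be >= 2 (pairwise DF needs two animals)",
         call. = FALSE)
  }
  if (steps_per_animal < 1) stop("steps_per_animal must be >= 1", call. = FALSE)
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  if (noise_sd_step < 0 || noise_sd_animal < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  if (is.numeric(step_duration_range) && length(step_duration_range) == 2L) {
    step_duration_range <- stats::setNames(
      rep(list(step_duration_range), length(SPECIES)), SPECIES)
  }
  for (sp in unique(groups$species)) {
    r <- step_duration_range[[sp]]
    if (is.null(r) || length(r) != 2L || r[1] <= 0 || r[2] < r[1]) {
      stop("invalid step_duration_range for species ", sp, call. = FALSE)
    }
    if (is.na(stride_length[sp])) {
      stop("missing stride_length for species ", sp, call. = FALSE)
    }
  }
  for (eff in lesion_effects) stopifnot(inherits(eff, "lesion_effect"))
  structure(
    list(groups = groups, animals_per_group = as.integer(animals_per_group),
         steps_per_animal = as.integer(steps_per_animal), fps = fps,
         step_duration_range = step_duration_range,
         noise_sd_step = noise_sd_step, noise_sd_animal = noise_sd_animal,
         stride_length = stride_length, templates = templates,
         lesion_effects = lesion_effects, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(paste0("<cohort_config> %d groups x %d animals x %d steps, ",
                     "%g fps, noise SD step %.3g / animal %.3g AU, seed %d\n"),
              nrow(x$groups), x$animals_per_group, x$steps_per_animal, x$fps,
              x$noise_sd_step, x$noise_sd_animal, x$seed))
  invisible(x)
}

# bin-centre grid of the 100-bin cycle on normalized time
U_BINS <- (0:99) / 99

# noise realised as a natural cubic curve through per-bin values, so the
# per-bin noise survives frame sampling and re-normalization
noise_curve <- function(bin_noise, u) {
  stats::spline(U_BINS, bin_noise, xout = u, method = "natural")$y
}

#' Generate a synthetic gait cohort
#'
#' Simulates per-frame landmark trajectories (metatarsus, ankle, knee; both
#' sides) for every animal of the configured cohort, together with step
#' annotations and a ground-truth record. Each step is built in the 100-bin
#' cycle domain — template + per-animal offset + lesion effect (lesioned
#' groups only) + per-bin Gaussian noise — and then sampled at fps-spaced
#' time points over a randomly drawn step duration, so that downstream
#' spline time-normalization is genuinely exercised on non-uniform step
#' lengths. The horizontal coordinate advances linearly by the species
#' stride length, with the same per-bin noise model.
#'
#' The output is a pure function of the configuration (including its seed):
#' the same `config` always yields bit-identical results.
#'
#' @param config A [cohort_config()].
#' @return A list of class `gait_cohort`:
#'   * `trajectories` — data frame, one row per frame per joint per limb,
#'     columns `animal_id, session, species, sex, condition, side, joint,
#'     frame, x, y`;
#'   * `annotations` — data frame `animal_id, session, side, step_id,
#'     start_frame, end_frame` (half-open frame ranges, shared by the three
#'     joints of a limb);
#'   * `ground_truth` — per-group rendered templates, lesion effects, and
#'     the per-animal offsets actually drawn;
#'   * `config` — the input configuration.
#' @examples
#' cfg <- cohort_config(groups = data.frame(species = "rat", sex = "M",
#'                                          condition = "control"),
#'                      animals_per_group = 2, steps_per_animal = 2, seed = 7)
#' coh <- generate_cohort(cfg)
#' nrow(coh$annotations) # 2 animals x 2 sides x 2 steps = 8
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  traj_list <- list()
  ann_list <- list()
  offsets_list <- list()
  gt_groups <- list()

  for (g in seq_len(nrow(config$groups))) {
    species <- config$groups$species[g]
    sex <- config$groups$sex[g]
    condition <- config$groups$condition[g]
    label <- group_label(species, sex, condition)
    session <- session_for_condition(condition)
    dur_range <- config$step_duration_range[[species]]
    stride <- unname(config$stride_length[species])

    gt_templates <- list()
    for (joint in JOINTS) for (side in SIDES) {
      tpl <- lookup_template(config$templates, species, joint, side)
      eff <- if (condition == "lesioned") {
        lookup_effect(config$lesion_effects, species, sex, joint, side)
      } else NULL
      gt_templates[[paste(joint, side, sep = ".")]] <- list(
        template = tpl, lesion = eff,
        expected_bins = {
          v <- render_template(tpl, 100L)
          if (!is.null(eff)) v <- apply_lesion_effect(v, eff)
          v
        }
      )
    }
    gt_groups[[label]] <- gt_templates

    for (a in seq_len(config$animals_per_group)) {
      # animal identity is stable across sessions: control and lesioned
      # recordings of the same physical animal share the id stem
      animal_id <- sprintf("%s%s%02d", ifelse(species == "rat", "R", "M"),
                           sex, a)
      for (side in SIDES) {
        # per-animal template offsets, one per joint plus one horizontal
        y_off <- stats::rnorm(length(JOINTS), 0, config$noise_sd_animal)
        names(y_off) <- JOINTS
        x_off <- stats::rnorm(1, 0, config$noise_sd_animal)
        offsets_list[[length(offsets_list) + 1L]] <- data.frame(
          group = label, animal_id = animal_id, side = side,
          joint = c(JOINTS, "horizontal"), offset = c(y_off, x_off)
        )

        durations <- stats::runif(config$steps_per_animal, dur_range[1],
                                  dur_range[2])
        n_frames <- pmax(4L, as.integer(round(durations * config$fps)))
        starts <- cumsum(c(0L, n_frames[-length(n_frames)]))
        ends <- starts + n_frames

        ann_list[[length(ann_list) + 1L]] <- data.frame(
          animal_id = animal_id, session = session, side = side,
          step_id = seq_along(n_frames), start_frame = starts,
          end_frame = ends
        )

        for (s in seq_along(n_frames)) {
          nf <- n_frames[s]
          u <- (0:(nf - 1)) / (nf - 1)
          x_noise <- stats::rnorm(100, 0, config$noise_sd_step)
          x_vals <- stride * u + x_off +
            if (config$noise_sd_step > 0) noise_curve(x_noise, u) else 0
          frames <- starts[s]:(ends[s] - 1L)
          for (joint in JOINTS) {
            gt <- gt_groups[[label]][[paste(joint, side, sep = ".")]]
            y_noise <- stats::rnorm(100, 0, config$noise_sd_step)
            y_vals <- template_value(gt$template, u) + y_off[[joint]] +
              lesion_value(gt$lesion, u) +
              if (config$noise_sd_step > 0) noise_curve(y_noise, u) else 0
            traj_list[[length(traj_list) + 1L]] <- data.frame(
              animal_id = animal_id, session = session, species = species,
              sex = sex, condition = condition, side = side, joint = joint,
              frame = frames, x = x_vals, y = y_vals
            )
          }
        }
      }
    }
  }

  trajectories <- do.call(rbind, traj_list)
  rownames(trajectories) <- NULL
  annotations <- do.call(rbind, ann_list)
  rownames(annotations) <- NULL
  attr(trajectories, "fps") <- config$fps
  structure(
    list(trajectories = trajectories, annotations = annotations,
         ground_truth = list(groups = gt_groups,
                             animal_offsets = do.call(rbind, offsets_list),
                             seed = config$seed),
         config = config),
    class = "gait_cohort"
  )
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d trajectories (%d frames), %d annotated steps, seed %d\n",
              nrow(unique(x$trajectories[, c("animal_id", "session", "side", "joint")])),
              nrow(x$trajectories), nrow(x$annotations), x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes the trajectory and annotation tables in the package's tabular
#' format (see [write_trajectories()]) plus a `ground_truth.json` sidecar
#' holding the generating templates, lesion effects, per-animal offsets and
#' seed, so recovery can be scored without re-deriving the truth.
#'
#' @param cohort A `gait_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gait_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  traj_path <- file.path(dir, "trajectories.tsv")
  ann_path <- file.path(dir, "steps.tsv")
  gt_path <- file.path(dir, "ground_truth.json")
  write_trajectories(cohort$trajectories, traj_path,
                     fps = cohort$config$fps)
  write_annotations(cohort$annotations, ann_path)
  gt <- cohort$ground_truth
  gt_json <- list(
    seed = gt$seed,
    groups = lapply(gt$groups, function(gtpl) {
      lapply(gtpl, function(e) {
        list(template = unclass(e$template),
             lesion = if (is.null(e$lesion)) NULL else unclass(e$lesion),
             expected_bins = e$expected_bins)
      })
    }),
    animal_offsets = gt$animal_offsets
  )
  jsonlite::write_json(gt_json, gt_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(trajectories = traj_path, annotations = ann_path,
              ground_truth = gt_path))
}
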