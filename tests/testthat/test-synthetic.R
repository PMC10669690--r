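# Cohort generator: counts, determinism, and recovery of its own
# statistical structure through the normalization stage.

test_that("cohort counts follow the design", {
  cfg <- cohort_config(steps_per_animal = 1L, seed = 3L)
  coh <- generate_cohort(cfg)
  trajs <- unique(coh$trajectories[, c("animal_id", "session", "side", "joint")])
  # 8 groups x 5 animals x 3 joints x 2 sides
  expect_equal(nrow(trajs), 240)
  # annotated steps per (joint, side): 8 groups x 5 animals x steps
  ann_per_side <- table(coh$annotations$side)
  expect_equal(unname(ann_per_side[["left"]]), 40)
  cur <- normalize_cohort(coh$trajectories, coh$annotations)
  per_joint_side <- table(paste(cur$joint, cur$side))[["metatarsus left"]] / 100
  expect_equal(per_joint_side, 40)
})

test_that("identical seeds give bit-identical cohorts and files", {
  cfg <- tiny_cohort_config(seed = 7L)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$trajectories, c2$trajectories)
  expect_identical(c1$annotations, c2$annotations)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(c1, d1)
  write_cohort(c2, d2)
  for (f in c("trajectories.tsv", "steps.tsv", "ground_truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  c3 <- generate_cohort(tiny_cohort_config(seed = 8L))
  expect_false(identical(c1$trajectories$y, c3$trajectories$y))
})

test_that("noise-free cohort normalizes back to the rendered template", {
  cfg <- tiny_cohort_config(animals = 2L, steps = 3L, seed = 5L,
                            noise_sd_step = 0, noise_sd_animal = 0)
  coh <- generate_cohort(cfg)
  cur <- normalize_cohort(coh$trajectories, coh$annotations)
  for (joint in c("metatarsus", "knee")) {
    tpl <- render_template(default_templates()[[paste0("rat.", joint)]], 100)
    sub <- cur[cur$joint == joint & cur$side == "left", ]
    for (id in unique(sub$curve_id)) {
      y <- sub$y[sub$curve_id == id]
      # sampling at >= 156 frames then re-splining reproduces the smooth
      # template to well below measurement scale
      expect_lt(max(abs(y - tpl)), 1e-3)
    }
  }
})

test_that("lesioned groups carry the injected effect, controls do not", {
  eff <- lesion_effect(20, 54, delta = 5, taper = 0)
  cfg <- cohort_config(
    groups = data.frame(species = "rat", sex = "M",
                        condition = c("control", "lesioned")),
    animals_per_group = 2L, steps_per_animal = 1L,
    noise_sd_step = 0, noise_sd_animal = 0,
    lesion_effects = list(rat.M.metatarsus.left = eff), seed = 11L)
  coh <- generate_cohort(cfg)
  cur <- normalize_cohort(coh$trajectories, coh$annotations)
  base <- render_template(default_templates()$rat.metatarsus, 100)
  les <- cur[cur$joint == "metatarsus" & cur$side == "left" &
             cur$condition == "lesioned" & cur$step_id == 1, ]
  y <- les$y[les$animal_id == les$animal_id[1]]
  resid <- abs(y - apply_lesion_effect(base, eff))
  # spline resampling rings at the hard step edges of a taper-0 effect;
  # away from the two transitions the injected shift is reproduced
  interior <- setdiff(1:100, c(18:22, 52:56))
  expect_lt(max(resid[interior]), 2e-2)
  expect_lt(max(resid), abs(eff$delta) / 2)
  ctl <- cur[cur$joint == "metatarsus" & cur$side == "left" &
             cur$condition == "control" & cur$step_id == 1, ]
  y0 <- ctl$y[ctl$animal_id == ctl$animal_id[1]]
  expect_lt(max(abs(y0 - base)), 1e-3)
  # the right side and other joints are untouched
  right <- cur[cur$joint == "metatarsus" & cur$side == "right" &
               cur$condition == "lesioned" & cur$step_id == 1, ]
  yr <- right$y[right$animal_id == right$animal_id[1]]
  expect_lt(max(abs(yr - base)), 1e-3)
})

test_that("per-bin noise SD survives the pipeline within 15%", {
  # >= 500 steps of statistically identical animals, zero animal noise
  cfg <- tiny_cohort_config(animals = 2L, steps = 250L, seed = 21L,
                            noise_sd_step = 0.5, noise_sd_animal = 0)
  coh <- generate_cohort(cfg)
  cur <- normalize_cohort(coh$trajectories, coh$annotations)
  sub <- cur[cur$joint == "metatarsus" & cur$side == "left", ]
  Y <- matrix(sub$y[order(sub$curve_id, sub$bin)], nrow = 100)
  expect_equal(ncol(Y), 500)
  sds <- apply(Y, 1, sd)
  expect_true(all(sds / 0.5 > 0.85 & sds / 0.5 < 1.15))
})

test_that("config validation rejects degenerate designs", {
  expect_error(tiny_cohort_config(animals = 1L), "animals_per_group")
  expect_error(cohort_config(noise_sd_step = -1), "noise SDs")
  expect_error(cohort_config(step_duration_range = c(0.5, 0.2)),
               "step_duration_range")
  expect_error(cohort_config(groups = data.frame(species = "cat", sex = "M",
                                                 condition = "control")),
               "species")
})
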