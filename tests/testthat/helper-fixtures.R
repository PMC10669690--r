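# Shared fixtures: programmatically built curves and tiny cohort configs.

# a step_curve-like list with constant coordinates
const_curve <- function(y = 0, x = 0) {
  list(x = rep(x, 100), y = rep(y, 100))
}

rand_curve <- function(sd = 1) {
  list(x = rnorm(100, 0, sd), y = rnorm(100, 0, sd))
}

# long-format curve table from a 100 x n matrix of vertical values
# (horizontal defaults to zero), as produced by normalize_cohort()
curves_df_from_mat <- function(Y, X = NULL, animal_ids = NULL,
                               group = "CMR", joint = "metatarsus",
                               side = "left", id_prefix = group) {
  n <- ncol(Y)
  if (is.null(X)) X <- matrix(0, nrow(Y), n)
  if (is.null(animal_ids)) animal_ids <- paste0(id_prefix, "_a", seq_len(n))
  info <- gaitdf::parse_group_label(group)
  do.call(rbind, lapply(seq_len(n), function(j) {
    data.frame(
      curve_id = paste0(id_prefix, "_c", j), animal_id = animal_ids[j],
      session = if (info$condition == "control") "day0" else "day7",
      species = info$species, sex = info$sex, condition = info$condition,
      group = group, side = side, joint = joint, step_id = j,
      bin = 1:100, x = X[, j], y = Y[, j]
    )
  }))
}

# n iid-noise curves around a 100-bin base waveform (both axes noisy)
noisy_curves_df <- function(base_y, n, sd, base_x = NULL, ...) {
  Y <- matrix(rnorm(100 * n, 0, sd), 100, n) + base_y
  X <- matrix(rnorm(100 * n, 0, sd), 100, n)
  if (!is.null(base_x)) X <- X + base_x
  curves_df_from_mat(Y, X, ...)
}

# small one-group cohort configuration
tiny_cohort_config <- function(species = "rat", sex = "M",
                               condition = "control", animals = 2L,
                               steps = 2L, seed = 1L, ...) {
  gaitdf::cohort_config(
    groups = data.frame(species = species, sex = sex, condition = condition),
    animals_per_group = animals, steps_per_animal = steps, seed = seed, ...)
}
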