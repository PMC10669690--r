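# Bin-wise comparison, KS normality, and Kruskal-Wallis/Dunn against
# closed forms and independently coded oracles.

# independent tie-corrected Kruskal-Wallis H from the rank-sum formula
kw_oracle <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  N <- length(values)
  r <- rank(values)
  H <- 12 / (N * (N + 1)) * sum(tapply(r, g, sum)^2 / tabulate(g)) -
    3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# independent sup-distance of the ECDF from the fitted normal CDF
lilliefors_stat_oracle <- function(x) {
  n <- length(x)
  p <- pnorm(sort(x), mean(x), sd(x))
  max(pmax((1:n) / n - p, p - (0:(n - 1)) / n))
}

test_that("identical constant groups show no change anywhere", {
  a <- curves_df_from_mat(matrix(1, 100, 3))
  b <- curves_df_from_mat(matrix(1, 100, 3), group = "LMR")
  comp <- binwise_compare(a, b)
  expect_equal(comp$percent_changed, 0)
  expect_equal(comp$bins$p, rep(1, 100))
  expect_equal(comp$bins$t_stat, rep(0, 100))
})

test_that("identical samples give t = 0, one-sided p = 0.5, two-sided p = 1", {
  Y <- matrix(rep(c(1, 2, 3), each = 100), 100, 3)
  a <- curves_df_from_mat(Y)
  b <- curves_df_from_mat(Y, group = "LMR")
  one <- binwise_compare(a, b, tail = "one_sided_auto")
  expect_equal(one$bins$t_stat, rep(0, 100))
  expect_equal(one$bins$p, rep(0.5, 100))
  two <- binwise_compare(a, b, tail = "two_sided")
  expect_equal(two$bins$p, rep(1, 100))
})

test_that("per-bin t matches stats::t.test with pooled variance", {
  set.seed(20)
  a <- curves_df_from_mat(matrix(rnorm(500), 100, 5))
  b <- curves_df_from_mat(matrix(rnorm(700, 0.5), 100, 7), group = "LMR")
  comp <- binwise_compare(a, b, tail = "two_sided")
  ya <- matrix(a$y[order(a$curve_id, a$bin)], 100)
  yb <- matrix(b$y[order(b$curve_id, b$bin)], 100)
  for (bin in c(1, 17, 50, 100)) {
    ref <- t.test(ya[bin, ], yb[bin, ], var.equal = TRUE)
    expect_equal(comp$bins$t_stat[bin], unname(ref$statistic),
                 tolerance = 1e-12)
    expect_equal(comp$bins$p[bin], ref$p.value, tolerance = 1e-12)
  }
})

test_that("swapping groups flips t and preserves p and percent changed", {
  set.seed(21)
  a <- noisy_curves_df(rep(0, 100), 8, 1)
  b <- noisy_curves_df(c(rep(0, 40), rep(2, 30), rep(0, 30)), 8, 1,
                       group = "LMR")
  ab <- binwise_compare(a, b, tail = "two_sided")
  ba <- binwise_compare(b, a, tail = "two_sided")
  expect_equal(ab$bins$t_stat, -ba$bins$t_stat)
  expect_equal(ab$bins$p, ba$bins$p)
  expect_equal(ab$percent_changed, ba$percent_changed)
})

test_that("an overwhelming 35-bin shift is recovered as ~35% changed", {
  set.seed(22)
  base <- render_template(default_templates()$rat.metatarsus, 100)
  shifted <- apply_lesion_effect(base, lesion_effect(20, 54, delta = 5))
  a <- noisy_curves_df(base, 30, 0.5)
  b <- noisy_curves_df(shifted, 30, 0.5, group = "LMR")
  comp <- binwise_compare(a, b, tail = "two_sided", p_adjust = "BH")
  expect_true(abs(comp$percent_changed - 35) <= 3)
  expect_true(all(comp$bins$significant[20:54]))
})

test_that("animal-mean mode reduces n to the number of animals", {
  set.seed(23)
  a <- curves_df_from_mat(matrix(rnorm(600), 100, 6),
                          animal_ids = rep(c("a1", "a2", "a3"), each = 2))
  b <- curves_df_from_mat(matrix(rnorm(600), 100, 6),
                          animal_ids = rep(c("b1", "b2", "b3"), each = 2),
                          group = "LMR")
  comp <- binwise_compare(a, b, animal_means = TRUE)
  expect_equal(comp$n_a, 3)
  expect_equal(comp$bins$df[1], 4)
})

test_that("Lilliefors statistic equals the ECDF sup-distance oracle", {
  set.seed(24)
  for (n in c(10, 37, 200)) {
    x <- rnorm(n, 5, 2)
    expect_equal(ks_normality(x)$statistic, lilliefors_stat_oracle(x),
                 tolerance = 1e-10)
  }
  expect_error(ks_normality(c(1, 2, 3)), "at least 5")
  expect_error(ks_normality(rep(1, 10)), "degenerate")
})

test_that("KS normality is calibrated on normal data and rejects uniform", {
  set.seed(25)
  pvals <- replicate(100, ks_normality(rnorm(1000))$p)
  expect_gte(mean(pvals > 0.05), 0.9)
  expect_lt(ks_normality(runif(1e4))$p, 0.001)
})

test_that("Kruskal-Wallis H matches the closed form and oracle", {
  res <- kruskal_dunn(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(res$kw_H, 3.857, tolerance = 1e-3)
  # two identical groups: H = 0, p = 1 under tie correction
  same <- kruskal_dunn(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$kw_H, 0, tolerance = 1e-12)
  expect_equal(same$kw_p, 1)
  # random small instances against the independent rank-sum implementation
  set.seed(26)
  for (rep in 1:100) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(i)
      round(rnorm(sample(3:8, 1), sample(0:2, 1)), 1))
    names(groups) <- paste0("g", seq_len(k))
    expect_equal(kruskal_dunn(groups)$kw_H, kw_oracle(groups),
                 tolerance = 1e-10)
  }
})

test_that("all-identical values give H = 0 and unit p-values", {
  res <- kruskal_dunn(list(a = rep(2, 5), b = rep(2, 4)))
  expect_equal(res$kw_H, 0)
  expect_equal(res$kw_p, 1)
  expect_true(all(res$dunn == 1, na.rm = TRUE))
})

test_that("Dunn flags a strong location shift and respects Bonferroni", {
  set.seed(27)
  groups <- list(g1 = rnorm(30, 0, 1), g2 = rnorm(30, 10, 1),
                 g3 = rnorm(30, 0, 1))
  res <- kruskal_dunn(groups)
  expect_lt(res$dunn["g1", "g2"], 0.05)
  expect_lt(res$dunn["g2", "g3"], 0.05)
  expect_gt(res$dunn["g1", "g3"], 0.05)
  # symmetric matrix, NA diagonal
  expect_equal(res$dunn["g1", "g2"], res$dunn["g2", "g1"])
  expect_true(all(is.na(diag(res$dunn))))
  # Bonferroni never lowers a p-value
  raw <- kruskal_dunn(groups, p_adjust = "none")
  expect_true(all(res$dunn >= raw$dunn, na.rm = TRUE))
})

test_that("type-I rate of the bin-wise test is near alpha under the null", {
  set.seed(28)
  pcs <- replicate(50, {
    a <- noisy_curves_df(rep(0, 100), 10, 1)
    b <- noisy_curves_df(rep(0, 100), 10, 1, group = "LMR")
    binwise_compare(a, b, tail = "two_sided")$percent_changed
  })
  expect_gt(mean(pcs), 2.5)
  expect_lt(mean(pcs), 8)
})
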