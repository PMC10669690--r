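# Dissimilarity factor: closed forms, brute-force oracle equivalence,
# pairing combinatorics, and the Gaussian-null expectation.

# independently coded elementwise-loop oracle for the DF formula
df_loop_oracle <- function(a, b) {
  acc <- 0
  for (i in 1:100) {
    acc <- acc + (a$x[i] - b$x[i])^2
    acc <- acc + (a$y[i] - b$y[i])^2
  }
  acc / 200
}

test_that("identical curves have DF 0; constant offset gives c^2/2", {
  set.seed(10)
  a <- rand_curve()
  expect_identical(dissimilarity_factor(a, a), 0)
  b <- a; b$y <- a$y + 2
  expect_equal(dissimilarity_factor(a, b), 2) # c = 2 -> c^2/2
  for (c0 in c(0.1, 1, 3.7)) {
    b$y <- a$y + c0
    expect_equal(dissimilarity_factor(a, b), c0^2 / 2)
  }
})

test_that("DF equals the elementwise-loop oracle on random pairs", {
  set.seed(11)
  for (rep in 1:200) {
    a <- rand_curve(sd = runif(1, 0.1, 10))
    b <- rand_curve(sd = runif(1, 0.1, 10))
    expect_equal(dissimilarity_factor(a, b), df_loop_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("DF is symmetric, non-negative and scales quadratically", {
  set.seed(12)
  ref <- rand_curve()
  a <- rand_curve(); b <- rand_curve()
  expect_identical(dissimilarity_factor(a, b), dissimilarity_factor(b, a))
  expect_gte(dissimilarity_factor(a, b), 0)
  d1 <- dissimilarity_factor(a, b)
  for (k in c(0.5, 2, 10)) {
    ak <- list(x = ref$x + k * (a$x - ref$x), y = ref$y + k * (a$y - ref$y))
    bk <- list(x = ref$x + k * (b$x - ref$x), y = ref$y + k * (b$y - ref$y))
    expect_equal(dissimilarity_factor(ak, bk), k^2 * d1, tolerance = 1e-9)
  }
})

test_that("DF refuses mismatched joints or bin counts", {
  a <- c(const_curve(1), joint = "knee", side = "left")
  b <- c(const_curve(1), joint = "ankle", side = "left")
  expect_error(dissimilarity_factor(a, b), "joint")
  short <- list(x = rep(0, 50), y = rep(0, 50))
  expect_error(dissimilarity_factor(short, const_curve()), "length 100")
})

test_that("cross-animal pairing yields sum_{u<v} n_u n_v records", {
  set.seed(13)
  # 2 animals x 2 curves -> 4 records
  cur <- curves_df_from_mat(matrix(rnorm(400), 100, 4),
                            animal_ids = c("a1", "a1", "a2", "a2"))
  rec <- pairwise_df(cur)
  expect_equal(nrow(rec), 4)
  expect_true(all(rec$animal_id_a != rec$animal_id_b))
  # no duplicated unordered pairs
  key <- apply(rec[, c("curve_id_a", "curve_id_b")], 1,
               function(r) paste(sort(r), collapse = "|"))
  expect_equal(anyDuplicated(key), 0L)

  # 5 animals x 6 curves -> C(5,2) * 36 = 360 records
  cur2 <- curves_df_from_mat(matrix(rnorm(3000), 100, 30),
                             animal_ids = rep(paste0("a", 1:5), each = 6))
  expect_equal(nrow(pairwise_df(cur2)), 360)

  # all curves identical -> every df is 0
  cur3 <- curves_df_from_mat(matrix(1, 100, 4),
                             animal_ids = c("a1", "a1", "a2", "a2"))
  expect_equal(pairwise_df(cur3)$df, rep(0, 4))

  # single animal: no valid pairs
  cur4 <- curves_df_from_mat(matrix(rnorm(200), 100, 2),
                             animal_ids = c("a1", "a1"))
  expect_error(pairwise_df(cur4), "2 distinct animals")
})

test_that("pairwise_df matches dissimilarity_factor pair by pair", {
  set.seed(14)
  cur <- curves_df_from_mat(matrix(rnorm(600), 100, 6),
                            X = matrix(rnorm(600), 100, 6),
                            animal_ids = rep(c("a1", "a2", "a3"), each = 2))
  rec <- pairwise_df(cur)
  expect_equal(nrow(rec), 12)
  for (r in seq_len(nrow(rec))) {
    a <- cur[cur$curve_id == rec$curve_id_a[r], ]
    b <- cur[cur$curve_id == rec$curve_id_b[r], ]
    expect_equal(rec$df[r],
                 dissimilarity_factor(list(x = a$x, y = a$y),
                                      list(x = b$x, y = b$y)),
                 tolerance = 1e-12)
  }
})

test_that("Gaussian null: E[DF] = 2 sigma^2", {
  set.seed(15)
  sigma <- 0.7
  # 2 animals x 100 curves each -> 10^4 cross-animal pairs
  cur <- noisy_curves_df(rep(0, 100), n = 200, sd = sigma,
                         animal_ids = rep(c("a1", "a2"), each = 100))
  rec <- pairwise_df(cur)
  expect_equal(nrow(rec), 1e4)
  expect_equal(mean(rec$df), 2 * sigma^2, tolerance = 0.05)
})

test_that("group DF distributions include cross-condition pairs on request", {
  set.seed(16)
  ctl <- noisy_curves_df(rep(0, 100), n = 4, sd = 1, group = "CMR",
                         animal_ids = rep(c("r1", "r2"), each = 2))
  les <- noisy_curves_df(rep(0, 100), n = 4, sd = 1, group = "LMR",
                         animal_ids = rep(c("r3", "r4"), each = 2))
  cur <- rbind(ctl, les)
  within_only <- group_df_distributions(cur)
  expect_setequal(names(within_only), c("CMR", "LMR"))
  expect_equal(nrow(within_only$CMR), 4)
  both <- group_df_distributions(cur, cross_condition = TRUE)
  expect_true("LMR:CMR" %in% names(both))
  expect_equal(nrow(both$`LMR:CMR`), 16)
  expect_true(all(both$`LMR:CMR`$group_a != both$`LMR:CMR`$group_b))
})
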