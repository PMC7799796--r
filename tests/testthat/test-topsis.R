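test_that("normalization yields unit column norms", {
  expect_equal(topsis_normalize(cbind(c(3, 4))), cbind(c(0.6, 0.8)))
  set.seed(12)
  m <- matrix(runif(8, 1, 100), 4, 2)
  r <- topsis_normalize(m)
  expect_equal(unname(sqrt(colSums(r^2))), c(1, 1), tolerance = 1e-12)
  expect_warning(z <- topsis_normalize(cbind(c(1, 2), c(0, 0))), "all-zero")
  expect_equal(unname(z[, 2]), c(0, 0))
  expect_error(topsis(matrix(5, 1, 1), 1), "at least 2 alternatives")
})

test_that("weighting, ideal/base and distances follow the definitions", {
  r <- cbind(c(0.6, 0.8))
  expect_equal(unname(topsis_weight(r, 0.5)), cbind(c(0.3, 0.4)))
  expect_equal(topsis_weight(r, 1), r)
  expect_warning(topsis_weight(r, 0), "non-discriminating")
  v <- cbind(c(0.3, 0.4), c(0.1, 0.1))
  hb <- topsis_ideal_base(v)
  expect_equal(unname(hb$H), c(0.4, 0.1))
  expect_equal(unname(hb$D), c(0.3, 0.1))
  d <- topsis_distances(v, hb$H, hb$D)
  expect_equal(unname(d$d_plus[2]), 0)   # the row equal to H
  expect_equal(unname(d$d_minus[1]), 0)  # the row equal to D
  expect_equal(topsis_closeness(0, 0.5), 1)
  expect_equal(topsis_closeness(0.5, 0), 0)
  expect_warning(cc <- topsis_closeness(0, 0), "identical")
  expect_equal(cc, 0.5)
})

test_that("two-alternative dominance gives closeness 1 and 0 exactly", {
  m <- rbind(A = c(100, 100), B = c(0, 0))
  res <- topsis(m, c(0.6, 0.4))
  expect_identical(unname(res$c), c(1, 0))
  expect_equal(res$rank, c(1L, 2L))
})

test_that("the hand-worked 3x2 chain matches the step-by-step oracle", {
  m <- rbind(D1 = c(100, 100), D2 = c(50, 100), D3 = c(0, 0))
  w <- c(0.6, 0.4)
  res <- topsis(m, w)
  expect_equal(unname(res$c), oracle_topsis_closeness(m, w),
               tolerance = 1e-12)
  expect_equal(unname(res$c), c(1, 0.5923303169377979, 0),
               tolerance = 1e-12)
  expect_equal(res$rank, c(1L, 2L, 3L))
})

test_that("closeness is invariant to row permutation and column scaling", {
  set.seed(33)
  for (i in 1:50) {
    m <- matrix(runif(12, 0, 100), 6, 2,
                dimnames = list(paste0("D", 1:6), NULL))
    w <- c(0.6, 0.4)
    base <- topsis(m, w)$c
    p <- sample(6)
    expect_equal(unname(topsis(m[p, ], w)$c), unname(base[p]),
                 tolerance = 1e-12)
    m2 <- m; m2[, 1] <- m2[, 1] * runif(1, 0.1, 10)
    expect_equal(topsis(m2, w)$c, base, tolerance = 1e-12)
  }
})

test_that("dominance implies at least as high closeness", {
  set.seed(44)
  for (i in 1:100) {
    m <- matrix(runif(10, 0, 100), 5, 2)
    m[1, ] <- m[2, ] + runif(2, 0.1, 10)   # row 1 dominates row 2
    cc <- topsis(m, c(0.6, 0.4))$c
    expect_gte(cc[1], cc[2] - 1e-12)
  }
})

test_that("group runs and the mean total compose the pieces", {
  ds <- generate_region(small_region_config(seed = 19))
  ind <- compute_indicators(ds)
  res <- suppressWarnings(run_group_topsis(ind, "X4"))
  expect_true(all(res$c >= 0 & res$c <= 1))
  expect_equal(sort(res$rank), seq_along(res$c))
  # small areas can leave a coverage column all-zero; those warnings are
  # the degenerate-input handling under test elsewhere
  all4 <- suppressWarnings(topsis_all_groups(ind))
  expect_equal(all4$scores$MTci,
               rowMeans(all4$scores[, c("X4ci", "X5ci", "X6ci", "X7ci")]))
  expect_true(all(all4$scores$MTci >= 0 & all4$scores$MTci <= 1))
  # summary statistics recompute from the scores
  x4 <- all4$scores$X4ci
  s <- all4$summary[all4$summary$group == "X4", ]
  expect_equal(s$mean, mean(x4))
  expect_equal(s$sd, stats::sd(x4))
  expect_equal(s$skewness, e1071::skewness(x4, type = 2))
  expect_equal(s$kurtosis, e1071::kurtosis(x4, type = 2))
  # forced means
  expect_equal(unname(mean_total(rbind(c(1, 1, 1, 1)))), 1)
  expect_equal(unname(mean_total(rbind(c(0.8, 0.6, 0.4, 0.2)))), 0.5)
  expect_error(mean_total(rbind(c(0.5, NA, 0.2, 0.1))), "missing group score")
})

test_that("zero-recipient districts are dropped from rankings", {
  ds <- generate_region(small_region_config(seed = 23))
  ds$municipalities$recipients_65plus[
    ds$municipalities$district_id == ds$districts$id[1]] <- 0L
  ind <- suppressWarnings(compute_indicators(ds))
  expect_message(res <- suppressWarnings(run_group_topsis(ind, "X4")),
                 "zero-recipient")
  expect_false(ds$districts$id[1] %in% res$district_id)
})
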