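test_that("directional adjustment negates flagged columns exactly once", {
  vals <- data.frame(PN = c(1, 2), W_TDS = c(3, 5))
  ft <- tiny_function_table(vals,
                            categories = c("nitrogen_cycling", "water_quality"),
                            directions = c(1L, -1L))
  flipped <- apply_direction(ft)
  expect_equal(unname(flipped$values[, "W_TDS"]), c(-3, -5))
  expect_equal(flipped$values[, "PN"], ft$values[, "PN"])
  expect_true(all(flipped$schema$direction == 1L))
  # flags were reset: a second application is the identity
  expect_identical(apply_direction(flipped)$values, flipped$values)
})

test_that("min-max standardization matches the defining formula", {
  ft <- tiny_function_table(data.frame(TC = c(2, 4, 6)))
  std <- standardize_functions(ft)
  expect_equal(unname(std$values[, "TC"]), c(0, 0.5, 1))
  expect_equal(std$provenance$x_min, 2)
  expect_equal(std$provenance$x_max, 6)
})

test_that("a flipped function standardizes to one minus the unflipped STD", {
  set.seed(1)
  x <- rnorm(20)
  up <- standardize_functions(tiny_function_table(data.frame(W_TP = x)))
  dn <- standardize_functions(apply_direction(
    tiny_function_table(data.frame(W_TP = x),
                        categories = "water_quality", directions = -1L)))
  expect_true(all(abs(dn$values + up$values - 1) < 1e-12))
})

test_that("zero-range functions standardize to 0.5 with a warning", {
  ft <- tiny_function_table(data.frame(TC = c(7, 7, 7), TN = c(1, 2, 3)))
  expect_warning(std <- standardize_functions(ft), "zero range")
  expect_equal(unname(std$values[, "TC"]), c(0.5, 0.5, 0.5))
  expect_equal(unname(std$values[, "TN"]), c(0, 0.5, 1))
})

test_that("standardization refuses unflipped tables", {
  ft <- tiny_function_table(data.frame(W_TDS = c(1, 2)),
                            categories = "water_quality", directions = -1L)
  expect_error(standardize_functions(ft), "apply_direction")
})

test_that("EMF_average is the arithmetic mean of observed STD values", {
  ft <- tiny_function_table(
    data.frame(a = c(0.2, 1), b = c(0.4, 1), c = c(0.9, 1)))
  class(ft) <- c("standardized_table", "function_table")
  av <- emf_average(ft)
  expect_equal(unname(av), c(0.5, 1))
  # all-missing sample is an error naming it
  ft$values[1, ] <- NA
  expect_error(emf_average(ft), "s1:sediment")
})

test_that("EMF_average stays within the range of its inputs (property)", {
  set.seed(42)
  for (i in 1:50) {
    vals <- matrix(runif(8 * 5), 8, 5,
                   dimnames = list(NULL, paste0("f", 1:5)))
    ft <- tiny_function_table(as.data.frame(vals))
    class(ft) <- c("standardized_table", "function_table")
    av <- emf_average(ft)
    expect_true(all(av >= apply(vals, 1, min) - 1e-12))
    expect_true(all(av <= apply(vals, 1, max) + 1e-12))
    expect_equal(unname(av), unname(rowMeans(vals)))
  }
})

test_that("EMF_weighted averages category means with equal weight", {
  ft <- tiny_function_table(
    data.frame(f1 = 0.2, f2 = 0.4, f3 = 0.9),
    categories = c("nitrogen_cycling", "nitrogen_cycling", "water_quality"))
  class(ft) <- c("standardized_table", "function_table")
  expect_equal(unname(emf_weighted(ft)), (0.3 + 0.9) / 2)
})

test_that("EMF_weighted reduces to EMF_average for balanced categories", {
  set.seed(7)
  # one function per category
  ft1 <- tiny_function_table(
    as.data.frame(matrix(runif(12), 4, 3,
                         dimnames = list(NULL, c("x", "y", "z")))),
    categories = c("nitrogen_cycling", "nutrient_pool", "water_quality"))
  class(ft1) <- c("standardized_table", "function_table")
  expect_equal(emf_weighted(ft1), emf_average(ft1))
  # equal category sizes, random tables
  for (i in 1:20) {
    vals <- as.data.frame(matrix(runif(6 * 4), 6, 4,
                                 dimnames = list(NULL, paste0("f", 1:4))))
    ft <- tiny_function_table(vals,
      categories = rep(c("nutrient_pool", "water_quality"), each = 2))
    class(ft) <- c("standardized_table", "function_table")
    expect_equal(emf_weighted(ft), emf_average(ft), tolerance = 1e-12)
  }
})

test_that("threshold counts match their definition at the boundaries", {
  ft <- tiny_function_table(data.frame(a = c(1, 0.5), b = c(0.2, 0.6)))
  class(ft) <- c("standardized_table", "function_table")
  # per-function max over samples: a -> 1, b -> 0.6
  counts <- multi_threshold(ft, thresholds = c(5, 50, 95))
  expect_equal(unname(counts[1, "50"]), 1)  # 1.0 >= 0.5, 0.2 < 0.3
  expect_equal(unname(counts[1, "5"]), 2)
  expect_equal(unname(counts[1, "95"]), 1)  # only a reaches 95% of its max
  expect_error(multi_threshold(ft, thresholds = numeric(0)), "empty")
})

test_that("threshold counts equal a naive double loop and are monotone", {
  set.seed(13)
  grid <- 5:95
  for (rep in 1:10) {
    vals <- matrix(runif(20 * 18), 20, 18,
                   dimnames = list(NULL, paste0("f", 1:18)))
    ft <- tiny_function_table(as.data.frame(vals))
    class(ft) <- c("standardized_table", "function_table")
    counts <- multi_threshold(ft, thresholds = grid)
    maxs <- apply(vals, 2, max)
    naive <- matrix(0L, 20, length(grid))
    for (i in 1:20) for (ti in seq_along(grid)) {
      naive[i, ti] <- sum(vals[i, ] >= maxs * grid[ti] / 100)
    }
    expect_equal(unname(counts), naive)
    expect_true(all(t(apply(counts, 1, diff)) <= 0))
  }
})

test_that("robust top-k reference maxima soften single-sample peaks", {
  ft <- tiny_function_table(data.frame(a = c(1, 0.5, 0.5, 0.5)))
  class(ft) <- c("standardized_table", "function_table")
  k1 <- multi_threshold(ft, thresholds = 60, robust_max_k = 1)
  k2 <- multi_threshold(ft, thresholds = 60, robust_max_k = 2)
  expect_equal(unname(k1[, 1]), c(1, 0, 0, 0))   # cut 0.6
  expect_equal(unname(k2[, 1]), c(1, 1, 1, 1))   # cut 0.45
})

test_that("flipping one function leaves the other functions' part intact", {
  set.seed(3)
  vals <- data.frame(PN = runif(10), W_TDS = runif(10))
  cats <- c("nitrogen_cycling", "water_quality")
  ft_plus <- tiny_function_table(vals, cats, directions = c(1L, 1L))
  ft_minus <- tiny_function_table(vals, cats, directions = c(1L, -1L))
  s_plus <- standardize_functions(apply_direction(ft_plus))
  s_minus <- standardize_functions(apply_direction(ft_minus))
  expect_equal(s_plus$values[, "PN"], s_minus$values[, "PN"])
  contrib <- function(s) 2 * emf_average(s) - s$values[, "W_TDS"]
  expect_equal(contrib(s_plus), contrib(s_minus))
})

test_that("emf() ties the pieces together and reports functions used", {
  sim <- simulate_functions(simulation_config(n_sites = 6, seed = 2))
  tab <- sim$table
  tab$values[1, c("PN", "TC")] <- NA
  res <- emf(tab)
  expect_s3_class(res, "emf_result")
  expect_equal(res$scores$n_functions_used[1], 16)
  expect_true(all(res$scores$n_functions_used[-1] == 18))
  expect_true(all(res$scores$emf_average >= 0 & res$scores$emf_average <= 1))
  expect_true(all(res$scores$emf_weighted >= 0 & res$scores$emf_weighted <= 1))
  expect_identical(dim(res$threshold_counts),
                   c(nrow(tab$values), length(5:95)))
})
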