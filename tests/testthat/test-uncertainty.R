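summary_from_values <- function(value_sets, grid) {
  acc <- new_accumulator(grid)
  for (v in value_sets)
    acc <- accumulate(acc, scalar_volume(v, grid, probability = TRUE))
  finalize(acc)
}

test_that("total entropy matches analytic values at known probabilities", {
  grid <- image_grid(c(2, 2, 1))
  summ <- summary_from_values(list(c(0.5, 0, 1, 0.1)), grid)
  ht <- as.numeric(total_entropy(summ)$values)
  expect_equal(ht[1], log(2))
  expect_equal(ht[2], 0)
  expect_equal(ht[3], 0)
  expect_equal(ht[4], 0.325083, tolerance = 1e-6)
})

test_that("expected per-sample entropy averages sample entropies", {
  grid <- image_grid(c(1, 1, 1))
  expect_equal(as.numeric(expected_entropy(
    summary_from_values(list(0.5, 0.5), grid))$values), log(2))
  expect_equal(as.numeric(expected_entropy(
    summary_from_values(list(0, 1), grid))$values), 0)
  expect_equal(as.numeric(expected_entropy(
    summary_from_values(list(0.2, 0.4), grid))$values),
    0.586707, tolerance = 1e-6)
})

test_that("maximal-disagreement stack attains MI = ln 2", {
  grid <- image_grid(c(1, 1, 1))
  summ <- summary_from_values(list(0, 1), grid)
  ht <- total_entropy(summ)
  eh <- expected_entropy(summ)
  mi <- mutual_information(ht, eh)
  expect_equal(as.numeric(mi$values), log(2))
  expect_equal(as.numeric(predictive_std(summ)$values), 0.5)
})

test_that("identical samples give zero MI and zero std", {
  grid <- tiny_grid()
  v <- random_prob_volume(grid, 9)$values
  summ <- summary_from_values(list(v, v, v), grid)
  mi <- mutual_information(total_entropy(summ), expected_entropy(summ))
  expect_true(all(abs(mi$values) < 1e-12))
  expect_true(all(predictive_std(summ)$values < 1e-7))
})

test_that("decomposition and bounds hold on 100 random stacks", {
  grid <- image_grid(c(16, 16, 16))
  worst_neg <- 0
  for (seed in 1:100) {
    set.seed(seed)
    S <- sample(2:50, 1)
    summ <- summary_from_values(
      lapply(seq_len(S), function(i) runif(grid$n)), grid)
    ht <- total_entropy(summ)$values
    eh <- expected_entropy(summ)$values
    raw_mi <- ht - eh
    worst_neg <- min(worst_neg, min(raw_mi))
    sg <- predictive_std(summ)$values
    pbar <- summ$mean$values
    expect_true(all(ht >= 0 & ht <= log(2) + 1e-12))
    expect_true(all(eh >= 0 & eh <= log(2) + 1e-12))
    expect_true(all(sg >= 0 & sg <= 0.5 + 1e-12))
    # Jensen: mean entropy never exceeds entropy of the mean
    expect_true(min(raw_mi) >= -1e-12)
    # Bhatia-Davis bound on the variance of a [0,1] variable
    expect_true(all(sg^2 <= pbar * (1 - pbar) + 1e-12))
  }
  expect_gte(worst_neg, -1e-12)
})

test_that("single-sample stacks have exactly zero MI and std", {
  grid <- tiny_grid()
  summ <- summary_from_values(list(random_prob_volume(grid, 4)$values),
                              grid)
  mi <- mutual_information(total_entropy(summ), expected_entropy(summ))
  expect_true(all(mi$values == 0))
  expect_true(all(predictive_std(summ)$values == 0))
})

test_that("masked mean implements the mask-weighted aggregate", {
  grid <- tiny_grid()
  u_vals <- rep(0, grid$n)
  u_vals[1:3] <- 0.2
  u_vals[4] <- 0.8
  u <- scalar_volume(u_vals, grid)
  mask <- mask_from_indices(grid, 1:4)
  expect_equal(masked_mean(u, mask), 0.35)
  # constant map: C equals the constant
  const <- scalar_volume(rep(0.42, grid$n), grid)
  expect_equal(masked_mean(const, mask), 0.42)
  empty <- binary_mask(rep(0L, grid$n), grid)
  expect_error(masked_mean(u, empty), "empty")
})

test_that("compute_all on constant half-probability stack", {
  grid <- tiny_grid()
  summ <- summary_from_values(list(rep(0.5, grid$n), rep(0.5, grid$n)),
                              grid)
  mask <- mask_from_indices(grid, 1:10)
  res <- compute_all(summ, mask)
  expect_equal(res$subject$C[["h_total"]], log(2))
  expect_equal(res$subject$C[["e_h"]], log(2))
  expect_equal(res$subject$C[["mi"]], 0)
  expect_equal(res$subject$C[["std"]], 0)
  expect_equal(res$subject$mask_voxels, 10)
})

test_that("confident deterministic stacks give all-zero aggregates", {
  grid <- tiny_grid()
  v <- as.numeric(seq_len(grid$n) <= 8)   # exact 0/1 probabilities
  summ <- summary_from_values(list(v, v), grid)
  res <- compute_all(summ, mask_from_indices(grid, 1:8))
  expect_true(all(res$subject$C == 0))
})

test_that("streaming and stack-based uncertainty paths agree", {
  grid <- image_grid(c(8, 8, 8))
  for (seed in 1:5) {
    stack <- random_stack(grid, 2, 5, seed)
    summ <- summarize_stack(stack)
    eh_stream <- expected_entropy(summ)
    eh_stack <- expected_entropy(stack)
    expect_true(max(abs(eh_stream$values - eh_stack$values)) < 1e-10)
  }
})

test_that("uncertainty maps write and re-read as NIfTI", {
  grid <- tiny_grid(c(6, 6, 6))
  summ <- summary_from_values(list(random_prob_volume(grid, 1)$values,
                                   random_prob_volume(grid, 2)$values),
                              grid)
  res <- compute_all(summ, mask_from_indices(grid, 1:12))
  dir <- withr::local_tempdir()
  paths <- write_uncertainty_maps(res$maps, dir, "sub01")
  expect_true(all(file.exists(paths)))
  back <- read_volume(paths[["mi"]])
  expect_true(max(abs(back$values - res$maps$mi$values)) < 1e-6)
})

test_that("map operations reject grid-incompatible inputs", {
  g1 <- image_grid(c(4, 4, 4), c(1, 1, 1))
  g2 <- image_grid(c(4, 4, 4), c(1, 1, 1.3))
  u1 <- scalar_volume(rep(0.1, 64), g1)
  u2 <- scalar_volume(rep(0.1, 64), g2)
  expect_error(mutual_information(u1, u2), "grid mismatch")
  expect_error(masked_mean(u1, binary_mask(rep(1L, 64), g2)),
               "grid mismatch")
})
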