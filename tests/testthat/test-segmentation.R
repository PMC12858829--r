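test_that("binarization follows the >= threshold convention", {
  grid <- image_grid(c(3, 1, 1))
  vol <- scalar_volume(c(0.5, 0.49, 0.51), grid, probability = TRUE)
  mask <- binarize(vol, 0.5)
  expect_equal(as.integer(mask$values), c(1L, 0L, 1L))
  expect_error(binarize(vol, 1.5), "threshold")
})

test_that("binarized masks are nested in the threshold", {
  grid <- tiny_grid(c(8, 8, 8))
  for (seed in 1:5) {
    vol <- random_prob_volume(grid, seed)
    hi <- binarize(vol, 0.6)
    lo <- binarize(vol, 0.4)
    expect_true(all(hi$values <= lo$values))
  }
})

test_that("majority vote requires a strict majority", {
  grid <- tiny_grid()
  ones <- binary_mask(rep(1L, grid$n), grid)
  zeros <- binary_mask(rep(0L, grid$n), grid)
  expect_true(all(majority_vote(list(ones, ones, ones, zeros,
                                     zeros))$values == 1))
  expect_true(all(majority_vote(list(ones, ones, zeros, zeros,
                                     zeros))$values == 0))
  # even-count exact tie goes to background
  expect_true(all(majority_vote(list(ones, zeros))$values == 0))
  # single mask is the identity
  m <- mask_from_indices(grid, c(1, 5, 9))
  expect_identical(majority_vote(list(m))$values, m$values)
})

test_that("majority vote equals mean-binarization for odd stacks", {
  grid <- tiny_grid(c(6, 6, 6))
  for (seed in 1:10) {
    set.seed(seed)
    M <- sample(c(3, 5, 7), 1)
    masks <- lapply(seq_len(M), function(i)
      binary_mask(rbinom(grid$n, 1, 0.5), grid))
    mv <- majority_vote(masks)
    mean_vol <- scalar_volume(
      Reduce(`+`, lapply(masks, function(m) m$values)) / M, grid,
      probability = TRUE)
    expect_identical(mv$values, binarize(mean_vol, 0.5)$values)
  }
})

test_that("dice matches hand-counted overlap and handles empties", {
  grid <- tiny_grid()
  a <- mask_from_indices(grid, c(1, 2, 3))
  m <- mask_from_indices(grid, c(2, 3, 4, 5))
  expect_equal(dice(a, m), 4 / 7)
  expect_equal(dice(m, a), 4 / 7)   # symmetry
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, mask_from_indices(grid, 10:12)), 0)
  empty <- binary_mask(rep(0L, grid$n), grid)
  expect_equal(dice(a, empty), 0)
  expect_warning(d <- dice(empty, empty), "empty")
  expect_equal(d, 1)
})

test_that("hausdorff distance respects geometry and spacing", {
  grid <- image_grid(c(8, 8, 8))
  a <- mask_from_indices(grid, 1)                    # voxel (1,1,1)
  b_idx <- 1 + 3                                     # voxel (4,1,1)
  b <- mask_from_indices(grid, b_idx)
  expect_equal(hausdorff(a, b), 3)
  expect_equal(hausdorff(a, a), 0)
  grid_half <- image_grid(c(8, 8, 8), c(0.5, 1, 1))
  a2 <- mask_from_indices(grid_half, 1)
  b2 <- mask_from_indices(grid_half, 4)
  expect_equal(hausdorff(a2, b2), 1.5)
  expect_error(hausdorff(a, binary_mask(rep(0L, grid$n), grid)),
               "empty")
})

test_that("hausdorff is symmetric and HD95 never exceeds HD", {
  grid <- image_grid(c(10, 10, 10))
  for (seed in 1:20) {
    set.seed(seed)
    a <- mask_from_indices(grid, sample(grid$n, 15))
    b <- mask_from_indices(grid, sample(grid$n, 15))
    hd_ab <- hausdorff(a, b)
    expect_equal(hd_ab, hausdorff(b, a))
    expect_lte(hausdorff(a, b, 95), hd_ab + 1e-12)
    expect_equal(hausdorff(a, a), 0)
  }
})

test_that("volume similarity follows its formula", {
  grid <- tiny_grid()
  expect_equal(volume_similarity(mask_from_indices(grid, 1:3),
                                 mask_from_indices(grid, 10:12)), 1)
  expect_equal(volume_similarity(mask_from_indices(grid, 1:2),
                                 mask_from_indices(grid, 1:6)), 0.5)
  empty <- binary_mask(rep(0L, grid$n), grid)
  expect_equal(volume_similarity(mask_from_indices(grid, 1:4), empty), 0)
  expect_error(volume_similarity(empty, empty), "empty")
})

test_that("volume correlation matches the covariance formula", {
  truth <- c(1200, 1350, 980, 1500, 1100)
  auto <- c(1180, 1420, 1010, 1480, 1090)
  r_oracle <- sum((auto - mean(auto)) * (truth - mean(truth))) /
    sqrt(sum((auto - mean(auto))^2) * sum((truth - mean(truth))^2))
  expect_equal(volume_correlation(auto, truth), r_oracle,
               tolerance = 1e-12)
  expect_equal(volume_correlation(truth, truth), 1)
  expect_equal(volume_correlation(2 * truth + 5, truth), 1)
  expect_error(volume_correlation(rep(1, 5), truth), "variance")
  expect_error(volume_correlation(auto[1:2], truth[1:2]), "3 subjects")
})

test_that("threshold sweep is consistent and constant for binary maps", {
  grid <- tiny_grid(c(6, 6, 6))
  truth <- mask_from_indices(grid, 1:20)
  # degenerate 0/1 mean map: Dice flat across all thresholds
  degen <- scalar_volume(as.numeric(seq_len(grid$n) <= 20), grid,
                         probability = TRUE)
  sweep_tab <- threshold_sweep(list(degen), list(truth),
                               thresholds = c(0.2, 0.5, 0.8))
  expect_equal(length(unique(sweep_tab$dice)), 1)
  # tau = 0.5 column agrees with direct evaluation
  vol <- random_prob_volume(grid, 3)
  st <- threshold_sweep(list(vol), list(truth), thresholds = 0.5)
  direct <- dice(binarize(vol, 0.5), truth)
  expect_equal(st$dice[st$subject_id == "s1"], direct)
})

test_that("segmentation metrics reject grid-incompatible masks", {
  g1 <- image_grid(c(4, 4, 4), c(1, 1, 1))
  g2 <- image_grid(c(4, 4, 4), c(1.2, 1, 1))
  a <- binary_mask(rep(1L, 64), g1)
  b <- binary_mask(rep(1L, 64), g2)
  expect_error(dice(a, b), "grid mismatch")
  expect_error(hausdorff(a, b), "grid mismatch")
  expect_error(volume_similarity(a, b), "grid mismatch")
  expect_error(majority_vote(list(a, b)), "grid mismatch")
})
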