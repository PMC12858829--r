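test_that("phantom generation is deterministic and well-formed", {
  spec <- phantom_spec(seed = 0)
  p1 <- generate_phantom(spec)
  p2 <- generate_phantom(spec)
  expect_identical(p1$image$values, p2$image$values)
  expect_identical(p1$truth$values, p2$truth$values)
  n_truth <- mask_count(p1$truth)
  expect_gte(n_truth, 20)
  expect_lte(n_truth, 0.05 * p1$truth$grid$n)
  # plexus strictly inside the ventricles
  expect_true(all(p1$ventricles$values[p1$truth$values == 1] == 1))
})

test_that("noise-free phantom has exactly three intensity levels", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0, seed = 2))
  expect_setequal(unique(as.numeric(ph$image$values)), c(40, 100, 160))
})

test_that("intensity ordering is enforced", {
  expect_error(phantom_spec(intensity_plexus = 90), "ordering")
})

test_that("the noise-free simulator reproduces truth exactly end to end", {
  ph <- generate_phantom(phantom_spec(shape = c(24, 24, 24), seed = 1))
  pred <- simulate_predictor(ph$truth, simulator_spec_noise_free())
  sch <- sampling_scheme(members = 2, realizations = 3, base_seed = 9)
  stack <- run_sampling(pred, ph$image, sch, retain_stack = TRUE)
  # every sample identical
  for (s in stack$samples)
    expect_identical(s$values, stack$samples[[1]]$values)
  summ <- stack$summary
  cons <- binarize(summ$mean, 0.5)
  expect_equal(dice(cons, ph$truth), 1)
  res <- compute_all(summ, cons)
  expect_true(all(abs(res$subject$C) < 1e-12))
})

test_that("aleatoric-only noise leaves epistemic MI relatively small", {
  # independent large-sample oracle for the spec'd regime: with no
  # member offsets, inter-sample disagreement within the mask comes
  # only from realization noise, so masked MI stays well below E_H
  ph <- generate_phantom(phantom_spec(shape = c(24, 24, 24), seed = 4))
  pred <- simulate_predictor(
    ph$truth, simulator_spec(confidence = 2, sigma_epi = 0,
                             sigma_ale = 1, boundary_width = 0, seed = 5))
  summ <- run_sampling(pred, ph$image, sampling_scheme(5, 20,
                                                       base_seed = 6))
  res <- compute_all(summ, ph$truth)
  expect_lt(res$subject$C[["mi"]] / res$subject$C[["e_h"]], 0.2)
})

test_that("strong epistemic spread drives MI past the aleatoric term", {
  # regime verified with a large-sample logit-model oracle: Gaussian
  # member offsets overtake per-sample entropy once sigma_epi is well
  # above the base signal (5-member crossover near 3.7 at confidence 2)
  ph <- generate_phantom(phantom_spec(shape = c(24, 24, 24), seed = 4))
  pred <- simulate_predictor(
    ph$truth, simulator_spec(confidence = 2, sigma_epi = 5,
                             sigma_ale = 0, boundary_width = 0, seed = 5))
  summ <- run_sampling(pred, ph$image, sampling_scheme(5, 20,
                                                       base_seed = 6))
  res <- compute_all(summ, ph$truth)
  expect_gt(res$subject$C[["mi"]], res$subject$C[["e_h"]])
})

test_that("member offsets are constant across realizations", {
  ph <- generate_phantom(phantom_spec(shape = c(16, 16, 16), seed = 7))
  pred <- simulate_predictor(
    ph$truth, simulator_spec(confidence = 4, sigma_epi = 1,
                             sigma_ale = 0, boundary_width = 0, seed = 8))
  # sigma_ale = 0: all realizations of one member identical, members differ
  s11 <- pred(ph$image, 1, 101)
  s12 <- pred(ph$image, 1, 202)
  s21 <- pred(ph$image, 2, 101)
  expect_identical(s11$values, s12$values)
  expect_false(identical(s11$values, s21$values))
})

test_that("dropout-free toy predictor is deterministic across passes", {
  train <- lapply(1:2, function(s)
    generate_phantom(phantom_spec(shape = c(24, 24, 24), seed = s)))
  pred <- toy_dropout_predictor(train, dropout_rate = 0, seed = 3)
  ph <- train[[1]]
  a <- pred(ph$image, 1, 11)
  b <- pred(ph$image, 1, 99)
  expect_identical(a$values, b$values)
  summ <- run_sampling(pred, ph$image, sampling_scheme(1, 5,
                                                       base_seed = 2))
  expect_true(all(predictive_std(summ)$values < 1e-7))
})

test_that("stochastic dropout passes differ when p > 0", {
  train <- lapply(1:2, function(s)
    generate_phantom(phantom_spec(shape = c(24, 24, 24), seed = s)))
  pred <- toy_dropout_predictor(train, dropout_rate = 0.3, seed = 3)
  ph <- train[[1]]
  expect_false(identical(pred(ph$image, 1, 11)$values,
                         pred(ph$image, 1, 12)$values))
  expect_gte(min(attr(pred, "train_dice")), 0.9)
})

test_that("cohorts are reproducible and labels round-trip through CSV", {
  spec <- cohort_spec(n = 3, cohort = "local-like", seed = 21,
                      shape = c(16, 16, 16))
  c1 <- make_cohort(spec)
  c2 <- make_cohort(spec)
  expect_identical(c1[[2]]$image$values, c2[[2]]$image$values)
  expect_equal(length(c1), 3)
  tab <- data.frame(
    subject_id = vapply(c1, `[[`, "", "subject_id"),
    diagnosis = vapply(c1, `[[`, "", "diagnosis"),
    cohort = vapply(c1, `[[`, "", "cohort"),
    site = vapply(c1, `[[`, "", "site"))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_identical(back$subject_id, tab$subject_id)
  expect_identical(back$diagnosis, c("CON", "ASD", "CON"))
})

test_that("shifted-child cohorts carry higher epistemic uncertainty", {
  sch <- sampling_scheme(preset = "abide-light", base_seed = 5)
  local <- cohort_uncertainty(
    make_cohort(cohort_spec(10, "local-like", seed = 31,
                            shape = c(24, 24, 24))), sch)
  child <- cohort_uncertainty(
    make_cohort(cohort_spec(10, "shifted-child", seed = 32,
                            shape = c(24, 24, 24))), sch)
  expect_gt(mean(child$C_mi), mean(local$C_mi))
})
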