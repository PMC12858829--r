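# Shared fixture builders. Everything is generated in code; no binary
# fixtures on disk.

tiny_grid <- function(shape = c(4, 4, 4), spacing = c(1, 1, 1)) {
  image_grid(shape, spacing)
}

# Uniform random probability volume
random_prob_volume <- function(grid, seed) {
  set.seed(seed)
  scalar_volume(runif(grid$n), grid, probability = TRUE)
}

# A stack of S random probability volumes with (m, k) tags laid out
# m-major, built directly (bypassing run_sampling) for oracle tests.
random_stack <- function(grid, members, realizations, seed) {
  set.seed(seed)
  samples <- list(); mm <- integer(0); kk <- integer(0)
  for (m in seq_len(members)) for (k in seq_len(realizations)) {
    samples[[length(samples) + 1L]] <-
      scalar_volume(runif(grid$n), grid, probability = TRUE)
    mm <- c(mm, m); kk <- c(kk, k)
  }
  plexuq:::new_sample_stack(grid, samples, mm, kk)
}

# Mask from linear voxel indices
mask_from_indices <- function(grid, idx) {
  v <- integer(grid$n)
  v[idx] <- 1L
  binary_mask(v, grid)
}

# Predictor returning a fixed constant probability everywhere
constant_predictor <- function(value) {
  function(image, m, seed) {
    scalar_volume(rep(value, image$grid$n), image$grid, probability = TRUE)
  }
}

# Binary entropy oracle (nats), independent of the package internals
h_bin <- function(p) {
  ifelse(p <= 0 | p >= 1, 0, -p * log(p) - (1 - p) * log(1 - p))
}

# Reference BH step-up: reject H_(1..k*) where k* is the largest k with
# p_(k) <= k q / n; adjusted p by the step-up minimum formula.
bh_oracle <- function(p, q) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  k_ok <- which(ps <= seq_len(n) * q / n)
  reject_sorted <- rep(FALSE, n)
  if (length(k_ok)) reject_sorted[seq_len(max(k_ok))] <- TRUE
  adj_sorted <- rev(cummin(rev(pmin(1, n * ps / seq_len(n)))))
  reject <- adj <- rep(NA, n)
  reject[o] <- reject_sorted
  adj[o] <- adj_sorted
  list(p_adj = adj, reject = reject)
}

# Small local-like phantom + simulator pair for pipeline tests
small_subject <- function(seed = 1, shape = c(24, 24, 24), sim = NULL) {
  ph <- generate_phantom(phantom_spec(shape = shape, seed = seed))
  if (is.null(sim))
    sim <- simulator_spec(confidence = 5, sigma_epi = 0.4, sigma_ale = 0.4,
                          boundary_width = 1, seed = seed)
  list(phantom = ph, predictor = simulate_predictor(ph$truth, sim))
}
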