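#' Stochastic sampling scheme
#'
#' Defines the ensemble-by-dropout sampling design: M ensemble members,
#' K Monte Carlo dropout realizations per member (S = M*K stochastic
#' samples per subject), the dropout rate, and the base seed from which
#' all per-sample seeds are derived. The default scheme is the full
#' 5 x 20 = 100-sample design; `preset = "abide-light"` gives the
#' lighter 5 x 5 = 25-sample design used for large cohorts.
#'
#' @param members M, number of ensemble members (>= 1).
#' @param realizations K, dropout passes per member (>= 1).
#' @param dropout_rate dropout probability in [0, 1); consumed only by
#'   predictors that model dropout.
#' @param base_seed integer base seed.
#' @param preset `"full"` (5 x 20) or `"abide-light"` (5 x 5);
#'   overridden by explicit `members`/`realizations`.
#' @return an object of class `sampling_scheme`.
#' @export
sampling_scheme <- function(members = NULL, realizations = NULL,
                            dropout_rate = 0.1, base_seed = 1L,
                            preset = c("full", "abide-light")) {
  preset <- match.arg(preset)
  def <- switch(preset, "full" = c(5L, 20L), "abide-light" = c(5L, 5L))
  members <- if (is.null(members)) def[1] else as.integer(members)
  realizations <- if (is.null(realizations)) def[2] else as.integer(realizations)
  if (members < 1L || realizations < 1L)
    stop("members and realizations must be >= 1")
  if (!is.finite(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  structure(
    list(members = members, realizations = realizations,
         dropout_rate = dropout_rate, base_seed = as.integer(base_seed),
         S = members * realizations),
    class = "sampling_scheme"
  )
}

# 16-bit Feistel round function; constants are arbitrary odd mixers.
# All arithmetic stays below 2^53 so doubles are exact.
feistel_round <- function(x, key) {
  ((x * 40503 + key * 30011 + 12345) %% 65536)
}

#' Derive the seed for one stochastic sample
#'
#' Deterministic, call-order independent derivation of a per-(member,
#' realization) seed from the base seed, so samples can be generated in
#' any order (or in parallel) with identical results. A four-round
#' Feistel permutation over the 32-bit (m, k) index keeps distinct
#' (m, k) pairs on distinct orbits; the result is folded into the
#' positive signed 32-bit range accepted by `set.seed`.
#'
#' @param base_seed integer base seed.
#' @param m member index (>= 1).
#' @param k realization index (>= 1).
#' @return an integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(base_seed, m, k) {
  if (m < 1 || k < 1) stop("m and k must be >= 1")
  base <- as.numeric(base_seed) %% 65536
  left <- (m - 1) %% 65536
  right <- (k - 1) %% 65536
  keys <- c(base, (base * 3 + 7) %% 65536, (base * 5 + 13) %% 65536,
            (base * 11 + 29) %% 65536)
  for (key in keys) {
    tmp <- (left + feistel_round(right, key)) %% 65536
    left <- right
    right <- tmp
  }
  mixed <- left * 65536 + right             # bijective in (m-1, k-1) mod 2^16
  as.integer(1 + (mixed + floor(as.numeric(base_seed) / 65536)) %%
               (2147483647 - 1))
}

new_sample_stack <- function(grid, samples, members, realizations) {
  tags <- paste(members, realizations, sep = ":")
  if (anyDuplicated(tags)) stop("duplicate (member, realization) tags")
  structure(
    list(grid = grid, samples = samples, members = members,
         realizations = realizations, S = length(samples)),
    class = "sample_stack"
  )
}

#' @export
print.sample_stack <- function(x, ...) {
  cat("<sample_stack> S = ", x$S, " samples (",
      length(unique(x$members)), " members x ",
      length(unique(x$realizations)), " realizations) on ",
      paste(x$grid$shape, collapse = "x"), "\n", sep = "")
  invisible(x)
}

#' Create an empty moment accumulator
#'
#' Holds the streaming sufficient statistics for all four uncertainty
#' maps: per-voxel running sums of p, p^2 and the per-sample binary
#' entropy H(p) in nats, plus the sample count. Memory stays at three
#' volumes regardless of the number of samples accumulated.
#'
#' @param grid an `image_grid`.
#' @return an object of class `moment_accumulator`.
#' @export
new_accumulator <- function(grid) {
  stopifnot(inherits(grid, "image_grid"))
  zero <- array(0, dim = grid$shape)
  structure(
    list(grid = grid, S = 0L, sum_p = zero, sum_p2 = zero, sum_h = zero),
    class = "moment_accumulator"
  )
}

#' Fold one probability sample into an accumulator
#'
#' Order of accumulation does not matter: the update is associative and
#' commutative over samples.
#'
#' @param acc a `moment_accumulator`.
#' @param sample a probability `scalar_volume` on the same grid.
#' @return the updated accumulator.
#' @export
accumulate <- function(acc, sample) {
  stopifnot(inherits(acc, "moment_accumulator"),
            inherits(sample, "scalar_volume"))
  stop_if_incompatible(acc$grid, sample$grid, "accumulator and sample")
  p <- sample$values
  if (min(p) < 0 || max(p) > 1)
    stop("sample values outside [0, 1]")
  acc$S <- acc$S + 1L
  acc$sum_p <- acc$sum_p + p
  acc$sum_p2 <- acc$sum_p2 + p * p
  acc$sum_h <- acc$sum_h + binary_entropy_values(p)
  acc
}

#' Finalize an accumulator into a predictive summary
#'
#' @param acc a `moment_accumulator` with at least one sample.
#' @return an object of class `predictive_summary` with per-voxel mean
#'   probability `mean` (a probability `scalar_volume`), raw second
#'   moment `m2`, mean per-sample entropy `mean_h` (nats), and `S`.
#' @export
finalize <- function(acc) {
  stopifnot(inherits(acc, "moment_accumulator"))
  if (acc$S < 1L) stop("cannot finalize an accumulator with 0 samples")
  mean_p <- pmin(pmax(acc$sum_p / acc$S, 0), 1)
  structure(
    list(grid = acc$grid, S = acc$S,
         mean = scalar_volume(mean_p, acc$grid, probability = TRUE),
         m2 = array(acc$sum_p2 / acc$S, dim = acc$grid$shape),
         mean_h = array(acc$sum_h / acc$S, dim = acc$grid$shape)),
    class = "predictive_summary"
  )
}

#' Summarize a retained sample stack directly
#'
#' Brute-force (non-streaming) computation of the predictive summary
#' from a full stack; numerically equivalent to accumulating every
#' sample and finalizing.
#'
#' @param stack a `sample_stack`.
#' @return a `predictive_summary`.
#' @export
summarize_stack <- function(stack) {
  stopifnot(inherits(stack, "sample_stack"))
  acc <- new_accumulator(stack$grid)
  for (s in stack$samples) acc <- accumulate(acc, s)
  finalize(acc)
}

#' Run the stochastic sampling loop
#'
#' Calls `predictor(image, m, seed)` once per (member m, realization k)
#' with the seed from [derive_seed()], validating that each returned
#' volume is a probability volume on the image grid. With
#' `retain_stack = TRUE` the full `sample_stack` is returned (with the
#' finalized summary attached as `$summary`); otherwise only the
#' streaming `predictive_summary` is returned, keeping memory bounded
#' regardless of S.
#'
#' @param predictor function `(image, m, seed) -> scalar_volume` whose
#'   output is deterministic in its arguments.
#' @param image input `scalar_volume` passed through to the predictor.
#' @param scheme a [sampling_scheme()].
#' @param retain_stack keep all S sample volumes in memory.
#' @return a `sample_stack` (retained) or `predictive_summary`
#'   (streaming).
#' @export
run_sampling <- function(predictor, image, scheme, retain_stack = FALSE) {
  stopifnot(is.function(predictor), inherits(image, "scalar_volume"),
            inherits(scheme, "sampling_scheme"))
  acc <- new_accumulator(image$grid)
  samples <- if (retain_stack) vector("list", scheme$S) else NULL
  members <- integer(0); realizations <- integer(0)
  idx <- 0L
  for (m in seq_len(scheme$members)) {
    for (k in seq_len(scheme$realizations)) {
      idx <- idx + 1L
      seed <- derive_seed(scheme$base_seed, m, k)
      out <- predictor(image, m, seed)
      if (!inherits(out, "scalar_volume"))
        stop(sprintf("predictor contract violation at (m=%d, k=%d): %s",
                     m, k, "output is not a scalar_volume"))
      if (!grids_compatible(image$grid, out$grid))
        stop(sprintf("predictor contract violation at (m=%d, k=%d): %s",
                     m, k, "output grid differs from the input grid"))
      rng <- range(out$values)
      if (rng[1] < 0 || rng[2] > 1)
        stop(sprintf(
          "predictor contract violation at (m=%d, k=%d): values in [%.4g, %.4g]",
          m, k, rng[1], rng[2]))
      acc <- accumulate(acc, out)
      if (retain_stack) {
        samples[[idx]] <- out
        members[idx] <- m; realizations[idx] <- k
      }
    }
  }
  if (retain_stack) {
    stack <- new_sample_stack(image$grid, samples, members, realizations)
    stack$summary <- finalize(acc)
    stack
  } else {
    finalize(acc)
  }
}
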