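#' Parametric stochastic predictor specification
#'
#' Generative model for stochastic segmentation probabilities with
#' separable epistemic and aleatoric components, on the logit scale:
#'
#'   logit p_mk(v) = mu(v) + delta_m(v) + eps_mk(v)
#'
#' where mu(v) = +a on the truth mask and -a elsewhere (softened within
#' `boundary_width` voxels of the truth boundary to emulate
#' partial-volume ambiguity), delta_m is a Gaussian field drawn once per
#' ensemble member (SD `sigma_epi`; constant across dropout
#' realizations — this is what makes it epistemic: inter-model
#' disagreement), and eps_mk is a fresh Gaussian field per realization
#' (SD `sigma_ale`: within-model dispersion, the aleatoric proxy's
#' target). Optional smoothing at correlation length `ell` makes the
#' noise fields spatially coherent; fields are rescaled to their
#' nominal SD after smoothing.
#'
#' @param confidence a > 0, logit-scale class signal.
#' @param sigma_epi per-member logit offset SD (>= 0).
#' @param sigma_ale per-realization logit noise SD (>= 0).
#' @param boundary_width softening width w in voxels (>= 0).
#' @param ell spatial correlation length in voxels (>= 0; 0 = white).
#' @param seed base seed for the member offsets delta_m.
#' @return object of class `simulator_spec`.
#' @export
simulator_spec <- function(confidence = 4, sigma_epi = 0.5,
                           sigma_ale = 0.5, boundary_width = 1,
                           ell = 0, seed = 1L) {
  if (!is.finite(confidence) || confidence <= 0)
    stop("confidence must be a positive real")
  if (sigma_epi < 0 || sigma_ale < 0 || boundary_width < 0 || ell < 0)
    stop("spreads, boundary_width and ell must be >= 0")
  structure(
    list(confidence = confidence, sigma_epi = sigma_epi,
         sigma_ale = sigma_ale, boundary_width = boundary_width,
         ell = ell, seed = as.integer(seed)),
    class = "simulator_spec")
}

# Circular FFT convolution with a separable Gaussian kernel; adequate
# for stationary noise fields (wrap-around is just more noise).
gaussian_smooth3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  d <- dim(arr)
  kern1 <- function(n) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) # circular distances
    k <- exp(-x^2 / (2 * sigma^2))
    k / sum(k)
  }
  K <- outer(outer(kern1(d[1]), kern1(d[2])), kern1(d[3]))
  dim(K) <- d
  Re(stats::fft(stats::fft(arr) * stats::fft(K), inverse = TRUE)) / prod(d)
}

# Signed distance (voxel units) from each voxel center to the
# foreground/background interface: positive inside the mask, negative
# outside, magnitude |d - 0.5| where d is the Euclidean distance to the
# nearest voxel of the opposite class (the 0.5 shift puts the zero
# level between the two voxel layers). Outside voxels beyond the
# mask's bounding box + margin are assigned a large negative value
# without computing distances, since the caller clamps the ramp.
signed_boundary_distance <- function(mask, margin = 4) {
  v <- mask$values
  d <- dim(v)
  inside_idx <- which(v == 1L, arr.ind = TRUE)
  if (nrow(inside_idx) == 0L)
    return(array(-margin, dim = d))
  outside <- array(TRUE, dim = d)
  outside[v == 1L] <- FALSE
  lo <- pmax(apply(inside_idx, 2, min) - margin, 1)
  hi <- pmin(apply(inside_idx, 2, max) + margin, d)
  coords <- voxel_coords(d)
  near <- coords[, 1] >= lo[1] & coords[, 1] <= hi[1] &
    coords[, 2] >= lo[2] & coords[, 2] <= hi[2] &
    coords[, 3] >= lo[3] & coords[, 3] <= hi[3]
  out <- array(-margin, dim = d)
  min_dist_to <- function(pts, set) {
    # chunked nearest-neighbor distance (voxel units)
    res <- rep(Inf, nrow(pts))
    chunk <- max(1L, floor(4e6 / nrow(set)))
    i <- 1L
    while (i <= nrow(pts)) {
      j <- min(nrow(pts), i + chunk - 1L)
      P <- pts[i:j, , drop = FALSE]
      d2 <- outer(rowSums(P^2), rowSums(set^2), "+") - 2 * P %*% t(set)
      res[i:j] <- sqrt(pmax(apply(d2, 1, min), 0))
      i <- j + 1L
    }
    res
  }
  out_near_idx <- which(near & as.vector(outside))
  if (length(out_near_idx))
    out[out_near_idx] <- -(min_dist_to(coords[out_near_idx, , drop = FALSE],
                                       inside_idx) - 0.5)
  # nearest outside voxel to any inside voxel lies within the box
  outside_near <- coords[near & as.vector(outside), , drop = FALSE]
  out[v == 1L] <- min_dist_to(inside_idx, outside_near) - 0.5
  out
}

# Seeded Gaussian field with target marginal SD, optionally smoothed
# and rescaled back to that SD.
noise_field <- function(shape, sd, ell, seed) {
  if (sd == 0) return(array(0, dim = shape))
  with_seed(seed, {
    f <- array(stats::rnorm(prod(shape)), dim = shape)
    if (ell > 0) {
      f <- gaussian_smooth3(f, ell)
      f <- f / stats::sd(f)
    }
    f * sd
  })
}

#' Noise-free simulator limit
#'
#' Both noise spreads zero, no boundary softening, and a saturating
#' logit signal so predictions are exactly 0/1: every stochastic sample
#' is identical and equal to the truth. The whole pipeline then returns
#' Dice 1 and all four masked uncertainty aggregates 0 (up to floating
#' point on the background logit).
#'
#' @param seed seed (unused by a deterministic simulator, kept for
#'   interface symmetry).
#' @return a `simulator_spec`.
#' @export
simulator_spec_noise_free <- function(seed = 1L) {
  simulator_spec(confidence = 40, sigma_epi = 0, sigma_ale = 0,
                 boundary_width = 0, ell = 0, seed = seed)
}

#' Build a parametric stochastic predictor from a truth mask
#'
#' Returns a function `(image, m, seed) -> scalar_volume` satisfying
#' the [run_sampling()] predictor contract: output is deterministic in
#' `(m, seed)`, the member offset delta_m depends only on
#' `(spec$seed, m)` (cached across calls), and the realization noise is
#' drawn from the per-call seed. The `image` argument is accepted for
#' contract compatibility but ignored: the simulator is driven by the
#' truth geometry.
#'
#' @param truth a `binary_mask`, the ground-truth structure.
#' @param spec a [simulator_spec()].
#' @return a predictor function.
#' @export
simulate_predictor <- function(truth, spec) {
  stopifnot(inherits(truth, "binary_mask"), inherits(spec, "simulator_spec"))
  grid <- truth$grid
  a <- spec$confidence
  tv <- truth$values
  mu <- if (spec$boundary_width > 0) {
    a * pmin(pmax(signed_boundary_distance(truth) /
                    spec$boundary_width, -1), 1)
  } else {
    a * (2 * tv - 1)
  }
  delta_cache <- new.env(parent = emptyenv())
  member_offset <- function(m) {
    key <- as.character(m)
    if (!is.null(delta_cache[[key]])) return(delta_cache[[key]])
    # distinct seed stream from the sampling loop's per-(m,k) seeds
    dseed <- derive_seed(spec$seed * 31 + 17, m, 1)
    delta <- noise_field(grid$shape, spec$sigma_epi, spec$ell, dseed)
    delta_cache[[key]] <- delta
    delta
  }
  function(image, m, seed) {
    delta <- member_offset(m)
    eps <- noise_field(grid$shape, spec$sigma_ale, spec$ell, seed)
    scalar_volume(stats::plogis(mu + delta + eps), grid,
                  probability = TRUE)
  }
}
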