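# Run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards so generation never perturbs user RNG use.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Phantom specification
#'
#' Describes a self-contained 3D test image emulating the anatomy the
#' segmentation task targets: two low-intensity ellipsoidal "ventricles"
#' in a mid-intensity background, each containing a thin bright
#' curvilinear "plexus" tube (the segmentation target). The intensity
#' ordering plexus > background > ventricle mimics the T1 contrast of a
#' bright choroid plexus inside dark CSF.
#'
#' @param shape grid shape, default 48^3 voxels.
#' @param spacing voxel spacing in mm, default 1 mm isotropic.
#' @param ventricle_centers 2x3 matrix of ellipsoid centers in voxel
#'   fractions of the grid.
#' @param ventricle_semiaxes 2x3 matrix of semi-axes in voxels.
#' @param plexus_radius tube radius in voxels (1-2).
#' @param n_control control points per tube (>= 3); their transverse
#'   offsets are drawn from the spec seed, giving per-subject anatomy.
#' @param intensity_ventricle,intensity_background,intensity_plexus
#'   tissue mean intensities; must satisfy plexus > background >
#'   ventricle.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48, 48, 48), spacing = c(1, 1, 1),
                         ventricle_centers = rbind(c(0.34, 0.5, 0.5),
                                                   c(0.66, 0.5, 0.5)),
                         ventricle_semiaxes = rbind(c(8, 13, 8),
                                                   c(8, 13, 8)) *
                           min(shape) / 48,
                         plexus_radius = 1.6,
                         n_control = 5,
                         intensity_ventricle = 40,
                         intensity_background = 100,
                         intensity_plexus = 160,
                         noise_sd = 10,
                         seed = 1L) {
  if (!(intensity_plexus > intensity_background &&
        intensity_background > intensity_ventricle))
    stop("intensity ordering must be plexus > background > ventricle")
  if (plexus_radius <= 0) stop("plexus_radius must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(
    list(shape = as.integer(shape), spacing = as.numeric(spacing),
         ventricle_centers = ventricle_centers,
         ventricle_semiaxes = ventricle_semiaxes,
         plexus_radius = plexus_radius, n_control = as.integer(n_control),
         intensity_ventricle = intensity_ventricle,
         intensity_background = intensity_background,
         intensity_plexus = intensity_plexus,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec")
}

# Normalized ellipsoid radius^2 of voxel coordinates (1-based index
# space) relative to center (voxels) and semi-axes.
ellipsoid_r2 <- function(coords, center, semi) {
  ((coords[, 1] - center[1]) / semi[1])^2 +
    ((coords[, 2] - center[2]) / semi[2])^2 +
    ((coords[, 3] - center[3]) / semi[3])^2
}

voxel_coords <- function(shape) {
  as.matrix(expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                        z = seq_len(shape[3])))
}

# Smooth random tube inside one ellipsoid: control points along the
# long (y) axis with seeded transverse offsets, spline-interpolated.
# The curve is contracted toward the center if it leaves the safety
# ellipsoid (semi-axes reduced by the tube radius plus a voxelization
# margin), so the rasterized tube stays strictly inside the ventricle
# at any grid scale.
tube_curve <- function(center, semi, n_control, radius, n_dense = 160) {
  tt <- seq(-0.62, 0.62, length.out = n_control)
  off_x <- stats::runif(n_control, -0.30, 0.30) * semi[1]
  off_z <- stats::runif(n_control, -0.30, 0.30) * semi[3]
  td <- seq(-0.62, 0.62, length.out = n_dense)
  curve <- cbind(center[1] + stats::spline(tt, off_x, xout = td)$y,
                 center[2] + td * semi[2],
                 center[3] + stats::spline(tt, off_z, xout = td)$y)
  semi_eff <- pmax(semi - (radius + 0.8), 0.5)
  r <- sqrt(ellipsoid_r2(curve, center, semi_eff))
  scale <- max(1, max(r))
  sweep(sweep(curve, 2, center, "-") / scale, 2, center, "+")
}

#' Generate a phantom image and its ground truth
#'
#' Deterministic given the spec (including its seed). The truth mask is
#' the rasterized plexus tube; the intensity image is the piecewise
#' tissue means plus additive Gaussian noise. The tube is required to
#' stay strictly inside its ventricle; a spec whose tube escapes is an
#' error.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (a `scalar_volume`), `truth` (a
#'   `binary_mask`) and `ventricles` (a `binary_mask`, CSF region).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- image_grid(spec$shape, spec$spacing)
  coords <- voxel_coords(spec$shape)
  n <- nrow(coords)
  ventricle <- rep(FALSE, n)
  plexus <- rep(FALSE, n)
  with_seed(spec$seed, {
    for (v in seq_len(nrow(spec$ventricle_centers))) {
      center <- spec$ventricle_centers[v, ] * spec$shape
      semi <- spec$ventricle_semiaxes[v, ]
      inside <- ellipsoid_r2(coords, center, semi) <= 1
      ventricle <- ventricle | inside
      curve <- tube_curve(center, semi, spec$n_control, spec$plexus_radius)
      # candidate voxels: bounding box of the curve dilated by radius+1
      lo <- apply(curve, 2, min) - spec$plexus_radius - 1
      hi <- apply(curve, 2, max) + spec$plexus_radius + 1
      cand <- which(coords[, 1] >= lo[1] & coords[, 1] <= hi[1] &
                    coords[, 2] >= lo[2] & coords[, 2] <= hi[2] &
                    coords[, 3] >= lo[3] & coords[, 3] <= hi[3])
      cc <- coords[cand, , drop = FALSE]
      d2min <- rep(Inf, length(cand))
      for (j in seq_len(nrow(curve))) {
        d2 <- (cc[, 1] - curve[j, 1])^2 + (cc[, 2] - curve[j, 2])^2 +
          (cc[, 3] - curve[j, 3])^2
        d2min <- pmin(d2min, d2)
      }
      tube <- cand[d2min <= spec$plexus_radius^2]
      if (any(!inside[tube]))
        stop("phantom spec error: plexus tube escapes its ventricle")
      plexus[tube] <- TRUE
    }
    if (sum(plexus) < 20L)
      stop("phantom spec error: plexus has fewer than 20 voxels")
    intensity <- rep(spec$intensity_background, n)
    intensity[ventricle] <- spec$intensity_ventricle
    intensity[plexus] <- spec$intensity_plexus
    if (spec$noise_sd > 0)
      intensity <- intensity + stats::rnorm(n, 0, spec$noise_sd)
    list(image = scalar_volume(intensity, grid),
         truth = binary_mask(as.integer(plexus), grid),
         ventricles = binary_mask(as.integer(ventricle), grid))
  })
}
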