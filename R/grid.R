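#' Image grid geometry
#'
#' An `image_grid` records the geometry shared by all volumes of one
#' subject: the voxel counts along each axis, the physical voxel spacing
#' in millimetres, and the 4x4 voxel-to-world affine. All physical-space
#' computations (Hausdorff distances, volumes in mm^3) go through the
#' grid, so axis order in the underlying array never affects results.
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 1).
#' @param spacing numeric vector of length 3, mm per voxel (each > 0).
#'   Defaults to 1 mm isotropic.
#' @param affine 4x4 voxel-to-world matrix (mm). Defaults to a diagonal
#'   scaling by `spacing` (0-based voxel indices map to world mm).
#' @return An object of class `image_grid` with fields `shape`,
#'   `spacing`, `affine` and the voxel count `n`.
#' @export
image_grid <- function(shape, spacing = c(1, 1, 1), affine = NULL) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("shape must be three integers >= 1")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive reals (mm)")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine)))
    stop("affine must be a finite 4x4 matrix")
  d <- det(affine)
  if (!is.finite(d) || abs(d) < .Machine$double.eps)
    stop("affine must be invertible")
  structure(
    list(shape = shape, spacing = spacing, affine = affine,
         n = prod(shape)),
    class = "image_grid"
  )
}

#' @export
print.image_grid <- function(x, ...) {
  cat("<image_grid> ", paste(x$shape, collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "x"),
      " mm (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Test whether two grids are compatible
#'
#' Two grids are compatible when their shapes are identical and their
#' spacing and affine agree within a relative tolerance. Every
#' multi-volume operation in the package requires compatible grids.
#'
#' @param a,b `image_grid` objects.
#' @param tol relative tolerance on spacing and affine entries.
#' @return `TRUE` or `FALSE`.
#' @export
grids_compatible <- function(a, b, tol = 1e-4) {
  stopifnot(inherits(a, "image_grid"), inherits(b, "image_grid"))
  if (!identical(a$shape, b$shape)) return(FALSE)
  rel_ok <- function(x, y) {
    scale <- pmax(abs(x), abs(y), 1)
    all(abs(x - y) <= tol * scale)
  }
  rel_ok(a$spacing, b$spacing) && rel_ok(a$affine, b$affine)
}

stop_if_incompatible <- function(a, b, what = "volumes") {
  if (!grids_compatible(a, b))
    stop("grid mismatch: ", what, " must share shape, spacing and affine")
  invisible(TRUE)
}

#' Scalar volume on an image grid
#'
#' Wraps a 3D numeric array together with its grid. When
#' `probability = TRUE` the values are validated to lie in [0, 1];
#' probability volumes hold the per-sample predictions p_s(v) and the
#' predictive mean.
#'
#' @param values numeric 3D array (or vector of length `grid$n`).
#' @param grid an `image_grid`.
#' @param probability validate values as probabilities in [0, 1].
#' @return Object of class `scalar_volume` with fields `grid`, `values`
#'   (a 3D array) and `probability`.
#' @export
scalar_volume <- function(values, grid, probability = FALSE) {
  stopifnot(inherits(grid, "image_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$n)
    stop("value array length (", length(values),
         ") does not match grid voxel count (", grid$n, ")")
  if (any(!is.finite(values)))
    stop("volume contains non-finite values")
  if (probability) {
    rng <- range(values)
    if (rng[1] < 0 || rng[2] > 1)
      stop(sprintf(
        "probability volume out of range [0,1]: min %.6g, max %.6g",
        rng[1], rng[2]))
  }
  structure(
    list(grid = grid, values = array(values, dim = grid$shape),
         probability = isTRUE(probability)),
    class = "scalar_volume"
  )
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat("<scalar_volume> ", paste(x$grid$shape, collapse = "x"),
      if (x$probability) " [probability]" else "",
      ", range [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

#' Binary mask on an image grid
#'
#' A {0,1} volume: a consensus segmentation, a ground-truth label, or
#' the aggregation mask b_i used for per-subject uncertainty. Input
#' values within `tol` of 0 or 1 are coerced to exact 0/1; anything
#' farther from both is rejected.
#'
#' @param values numeric/integer 3D array or vector.
#' @param grid an `image_grid`.
#' @param tol coercion tolerance around 0 and 1.
#' @return Object of class `binary_mask`; `values` is an integer array.
#' @export
binary_mask <- function(values, grid, tol = 1e-3) {
  stopifnot(inherits(grid, "image_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$n)
    stop("mask length does not match grid voxel count")
  near0 <- abs(values) <= tol
  near1 <- abs(values - 1) <= tol
  bad <- !(near0 | near1)
  if (any(bad))
    stop(sprintf(
      "mask contains %d value(s) not within %g of 0 or 1 (e.g. %.6g)",
      sum(bad), tol, values[which(bad)[1]]))
  structure(
    list(grid = grid, values = array(as.integer(near1), dim = grid$shape)),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(x$grid$shape, collapse = "x"),
      ", ", sum(x$values), " foreground voxel(s)\n", sep = "")
  invisible(x)
}

#' Number of foreground voxels in a mask
#' @param mask a `binary_mask`.
#' @return integer count.
#' @export
mask_count <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$values)
}

#' Physical volume of a mask in mm^3
#' @param mask a `binary_mask`.
#' @return foreground voxel count times the voxel volume from the grid
#'   affine (absolute determinant of the 3x3 block).
#' @export
mask_volume_mm3 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  vox_mm3 <- abs(det(mask$grid$affine[1:3, 1:3]))
  sum(mask$values) * vox_mm3
}
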