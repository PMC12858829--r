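# Binary (Bernoulli) entropy in nats, with the x*ln(x) -> 0 limit
# handled analytically rather than by epsilon-clamping, so voxels at
# p = 0 or 1 contribute exactly 0.
binary_entropy_values <- function(p) {
  h <- array(0, dim = dim(p) %||% length(p))
  inner <- p > 0 & p < 1
  pi_ <- p[inner]
  h[inner] <- -pi_ * log(pi_) - (1 - pi_) * log(1 - pi_)
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total predictive entropy map
#'
#' The binary entropy of the mean predicted probability,
#' H_total(v) = -p_bar ln p_bar - (1 - p_bar) ln(1 - p_bar), in nats.
#' This is the combined (aleatoric + epistemic) uncertainty; its ceiling
#' is ln 2 at p_bar = 0.5 and it is exactly 0 where p_bar is 0 or 1.
#'
#' @param summary a `predictive_summary` from [finalize()] or
#'   [summarize_stack()].
#' @return a `scalar_volume` of entropies (nats).
#' @export
total_entropy <- function(summary) {
  stopifnot(inherits(summary, "predictive_summary"))
  scalar_volume(binary_entropy_values(summary$mean$values), summary$grid)
}

#' Expected per-sample entropy map (aleatoric proxy)
#'
#' The mean over samples of the per-sample binary entropy,
#' E_s[H_s](v) = (1/S) sum_s H(p_s(v)), in nats. Under the BALD
#' decomposition this is the aleatoric component: uncertainty each
#' stochastic model instance reports on its own, irreducible under the
#' learned model.
#'
#' @param x a `predictive_summary` (streaming path) or a `sample_stack`
#'   (direct recomputation from the retained samples).
#' @return a `scalar_volume` of entropies (nats).
#' @export
expected_entropy <- function(x) {
  if (inherits(x, "predictive_summary")) {
    return(scalar_volume(x$mean_h, x$grid))
  }
  if (inherits(x, "sample_stack")) {
    acc <- array(0, dim = x$grid$shape)
    for (s in x$samples) acc <- acc + binary_entropy_values(s$values)
    return(scalar_volume(acc / x$S, x$grid))
  }
  stop("x must be a predictive_summary or sample_stack")
}

#' Mutual information map (epistemic uncertainty, BALD)
#'
#' MI(v) = H_total(v) - E_s[H_s](v): the disagreement between
#' stochastic model instances, i.e. the epistemic component. MI is
#' analytically non-negative (Jensen); tiny negative values arise only
#' from floating point and are clamped to 0. Raw values below
#' `-warn_below` trigger a warning because they indicate inconsistent
#' inputs (maps not computed from the same stack).
#'
#' @param h_total total-entropy `scalar_volume`.
#' @param e_h expected-per-sample-entropy `scalar_volume` on the same
#'   grid.
#' @param warn_below magnitude of negative raw MI that triggers a
#'   diagnostic warning.
#' @return a `scalar_volume`, clamped below at 0.
#' @export
mutual_information <- function(h_total, e_h, warn_below = 1e-9) {
  stopifnot(inherits(h_total, "scalar_volume"),
            inherits(e_h, "scalar_volume"))
  stop_if_incompatible(h_total$grid, e_h$grid, "uncertainty maps")
  raw <- h_total$values - e_h$values
  worst <- min(raw)
  if (worst < -warn_below)
    warning(sprintf(
      "raw mutual information reaches %.3g; inputs may be inconsistent",
      worst))
  scalar_volume(pmax(raw, 0), h_total$grid)
}

#' Predictive standard deviation map
#'
#' The population standard deviation of the sampled probabilities,
#' sigma(v) = sqrt((1/S) sum_s (p_s - p_bar)^2), computed from the
#' streaming moments as sqrt(max(0, E[p^2] - p_bar^2)). A dispersion
#' index without the aleatoric/epistemic separation; bounded by 0.5.
#'
#' @param summary a `predictive_summary`.
#' @return a `scalar_volume` in probability units.
#' @export
predictive_std <- function(summary) {
  stopifnot(inherits(summary, "predictive_summary"))
  v <- pmax(summary$m2 - summary$mean$values^2, 0)
  scalar_volume(sqrt(v), summary$grid)
}

#' Mask-restricted mean of an uncertainty map
#'
#' The per-subject scalar C = sum_i U(p_i) b_i / sum_i b_i: the mean of
#' the uncertainty map over the voxels of a binary mask (typically the
#' subject's own binarized consensus segmentation). An empty mask is an
#' explicit error: C is undefined, never silently zero.
#'
#' @param u uncertainty `scalar_volume`.
#' @param mask a `binary_mask` on the same grid with >= 1 foreground
#'   voxel.
#' @return scalar C.
#' @export
masked_mean <- function(u, mask) {
  stopifnot(inherits(u, "scalar_volume"), inherits(mask, "binary_mask"))
  stop_if_incompatible(u$grid, mask$grid, "map and mask")
  nb <- sum(mask$values)
  if (nb < 1L) stop("empty aggregation mask: masked mean C is undefined")
  sum(u$values * mask$values) / nb
}

#' Compute all four uncertainty maps and their masked aggregates
#'
#' One pass producing the voxel-wise total entropy, expected per-sample
#' entropy, mutual information and predictive standard deviation, plus
#' the four mask-restricted per-subject aggregates C. When `mask` is
#' omitted it defaults to the subject's own consensus segmentation
#' (mean probability binarized at 0.5).
#'
#' @param summary a `predictive_summary`.
#' @param mask optional `binary_mask`; default: binarized consensus.
#' @param subject_id identifier carried into the subject summary.
#' @return a list of class `uncertainty_result` with `maps` (class
#'   `uncertainty_maps`: `h_total`, `e_h`, `mi`, `std`) and `subject`
#'   (class `subject_uncertainty`: the four C values and the mask voxel
#'   count).
#' @export
compute_all <- function(summary, mask = NULL, subject_id = "subject") {
  stopifnot(inherits(summary, "predictive_summary"))
  if (is.null(mask)) mask <- binarize(summary$mean, 0.5)
  h_total <- total_entropy(summary)
  e_h <- expected_entropy(summary)
  mi <- mutual_information(h_total, e_h)
  std <- predictive_std(summary)
  maps <- structure(
    list(grid = summary$grid, h_total = h_total, e_h = e_h,
         mi = mi, std = std),
    class = "uncertainty_maps")
  subject <- structure(
    list(subject_id = subject_id,
         C = c(h_total = masked_mean(h_total, mask),
               e_h = masked_mean(e_h, mask),
               mi = masked_mean(mi, mask),
               std = masked_mean(std, mask)),
         mask_voxels = sum(mask$values)),
    class = "subject_uncertainty")
  structure(list(maps = maps, subject = subject),
            class = "uncertainty_result")
}

#' Write the four uncertainty maps as NIfTI files
#'
#' Files are named `<subject>_htotal.nii.gz`, `_ehs`, `_mi`, `_std`.
#'
#' @param maps an `uncertainty_maps` object.
#' @param dir output directory (created if absent).
#' @param subject_id file-name prefix.
#' @return named character vector of the four paths, invisibly.
#' @export
write_uncertainty_maps <- function(maps, dir, subject_id = "subject") {
  stopifnot(inherits(maps, "uncertainty_maps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    htotal = file.path(dir, paste0(subject_id, "_htotal.nii.gz")),
    ehs = file.path(dir, paste0(subject_id, "_ehs.nii.gz")),
    mi = file.path(dir, paste0(subject_id, "_mi.nii.gz")),
    std = file.path(dir, paste0(subject_id, "_std.nii.gz")))
  write_volume(maps$h_total, paths["htotal"])
  write_volume(maps$e_h, paths["ehs"])
  write_volume(maps$mi, paths["mi"])
  write_volume(maps$std, paths["std"])
  invisible(paths)
}
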