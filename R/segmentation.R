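#' Binarize a mean probability map
#'
#' Voxels with mean probability >= tau become foreground. The tie at
#' exactly tau goes to foreground; the conventional default tau = 0.5
#' gives the consensus segmentation of a stochastic stack.
#'
#' @param mean_map probability `scalar_volume`.
#' @param threshold tau in (0, 1).
#' @return a `binary_mask`.
#' @export
binarize <- function(mean_map, threshold = 0.5) {
  stopifnot(inherits(mean_map, "scalar_volume"))
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  binary_mask(as.integer(mean_map$values >= threshold), mean_map$grid)
}

#' Majority-vote consensus of binary masks
#'
#' A voxel is foreground when strictly more than half the masks label
#' it foreground; for an even number of masks an exact tie goes to
#' background (conservative under-segmentation). For an odd number of
#' masks this equals binarizing the voxel-wise mean at 0.5.
#'
#' @param masks list of `binary_mask` on a shared grid (>= 1).
#' @return a `binary_mask`.
#' @export
majority_vote <- function(masks) {
  if (!is.list(masks) || length(masks) == 0L)
    stop("need at least one mask")
  stopifnot(all(vapply(masks, inherits, logical(1), "binary_mask")))
  grid <- masks[[1]]$grid
  votes <- array(0L, dim = grid$shape)
  for (m in masks) {
    stop_if_incompatible(grid, m$grid, "masks")
    votes <- votes + m$values
  }
  binary_mask(as.integer(votes > length(masks) / 2), grid)
}

#' Dice similarity coefficient
#'
#' Dice = 2 sum(a_i m_i) / (sum a_i + sum m_i) between an automated
#' mask `a` and a reference mask `m`. Two empty masks give 1 (perfect
#' agreement on absence) with a warning; exactly one empty gives 0.
#'
#' @param a,m `binary_mask` objects on a shared grid.
#' @return Dice in [0, 1].
#' @export
dice <- function(a, m) {
  stopifnot(inherits(a, "binary_mask"), inherits(m, "binary_mask"))
  stop_if_incompatible(a$grid, m$grid, "masks")
  na <- sum(a$values); nm <- sum(m$values)
  if (na == 0L && nm == 0L) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(a$values * m$values) / (na + nm)
}

# Boundary voxels: foreground with at least one 6-neighbor (or image
# edge) in background.
boundary_indices <- function(mask) {
  v <- mask$values
  d <- dim(v)
  pad <- array(0L, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  core <- function(sx, sy, sz)
    pad[(2:(d[1] + 1)) + sx, (2:(d[2] + 1)) + sy, (2:(d[3] + 1)) + sz]
  nb <- core(-1, 0, 0) & core(1, 0, 0) & core(0, -1, 0) & core(0, 1, 0) &
    core(0, 0, -1) & core(0, 0, 1)
  which(v == 1L & !nb, arr.ind = TRUE)
}

world_coords <- function(idx, grid) {
  # 0-based voxel indices through the affine
  homog <- cbind(idx - 1, 1)
  xyz <- homog %*% t(grid$affine)
  xyz[, 1:3, drop = FALSE]
}

# For each row of A (world mm), distance to the nearest row of B,
# chunked so the distance matrix never exceeds ~4e6 entries.
directed_surface_distances <- function(A, B) {
  nA <- nrow(A)
  out <- numeric(nA)
  chunk <- max(1L, floor(4e6 / nrow(B)))
  i <- 1L
  while (i <= nA) {
    j <- min(nA, i + chunk - 1L)
    Ai <- A[i:j, , drop = FALSE]
    d2 <- outer(rowSums(Ai^2), rowSums(B^2), "+") - 2 * Ai %*% t(B)
    out[i:j] <- sqrt(pmax(apply(d2, 1, min), 0))
    i <- j + 1L
  }
  out
}

#' Hausdorff distance between two masks
#'
#' Symmetric Hausdorff distance between the boundary voxel sets of two
#' masks, measured between voxel centers in world millimetres through
#' the grid affine. `percentile = 100` gives the classical maximum of
#' the two directed distances; `percentile = 95` gives HD95, the 95th
#' percentile of the pooled directed surface distances (robust to
#' boundary outliers).
#'
#' @param a,m non-empty `binary_mask` objects on a shared grid.
#' @param percentile 100 (maximum) or a percentile in (0, 100].
#' @return distance in mm.
#' @export
hausdorff <- function(a, m, percentile = 100) {
  stopifnot(inherits(a, "binary_mask"), inherits(m, "binary_mask"))
  stop_if_incompatible(a$grid, m$grid, "masks")
  if (sum(a$values) == 0L || sum(m$values) == 0L)
    stop("Hausdorff distance undefined for an empty mask")
  if (!is.finite(percentile) || percentile <= 0 || percentile > 100)
    stop("percentile must lie in (0, 100]")
  A <- world_coords(boundary_indices(a), a$grid)
  B <- world_coords(boundary_indices(m), m$grid)
  dAB <- directed_surface_distances(A, B)
  dBA <- directed_surface_distances(B, A)
  if (percentile == 100) {
    max(max(dAB), max(dBA))
  } else {
    as.numeric(stats::quantile(c(dAB, dBA), percentile / 100, names = FALSE))
  }
}

#' Volume similarity
#'
#' VS = 1 - |V_a - V_m| / (V_a + V_m), agreement of segmented volumes
#' regardless of overlap. Both masks empty is an error (0/0); exactly
#' one empty gives 0 by the formula.
#'
#' @param a,m `binary_mask` objects on a shared grid.
#' @return VS in [0, 1] (1 for equal volumes).
#' @export
volume_similarity <- function(a, m) {
  stopifnot(inherits(a, "binary_mask"), inherits(m, "binary_mask"))
  stop_if_incompatible(a$grid, m$grid, "masks")
  na <- sum(a$values); nm <- sum(m$values)
  if (na + nm == 0L) stop("volume similarity undefined for two empty masks")
  1 - abs(na - nm) / (na + nm)
}

#' Pearson correlation of automated vs reference volumes
#'
#' @param auto_volumes,truth_volumes numeric vectors of equal length
#'   >= 3 with non-zero variance.
#' @return Pearson r.
#' @export
volume_correlation <- function(auto_volumes, truth_volumes) {
  if (length(auto_volumes) != length(truth_volumes))
    stop("volume vectors must have equal length")
  if (length(auto_volumes) < 3L) stop("need at least 3 subjects")
  if (stats::sd(auto_volumes) == 0 || stats::sd(truth_volumes) == 0)
    stop("zero variance in a volume vector; correlation undefined")
  stats::cor(auto_volumes, truth_volumes, method = "pearson")
}

#' Evaluate one consensus segmentation against ground truth
#'
#' @param auto automated `binary_mask`.
#' @param truth reference `binary_mask`.
#' @param subject_id identifier for the output row.
#' @return one-row data.frame: subject_id, dice, hd_mm, hd95_mm, vs,
#'   vol_auto_mm3, vol_truth_mm3. Hausdorff columns are NA when either
#'   mask is empty.
#' @export
evaluate_segmentation <- function(auto, truth, subject_id = "subject") {
  hd <- hd95 <- NA_real_
  if (sum(auto$values) > 0L && sum(truth$values) > 0L) {
    hd <- hausdorff(auto, truth, 100)
    hd95 <- hausdorff(auto, truth, 95)
  }
  data.frame(
    subject_id = subject_id,
    dice = dice(auto, truth),
    hd_mm = hd,
    hd95_mm = hd95,
    vs = volume_similarity(auto, truth),
    vol_auto_mm3 = mask_volume_mm3(auto),
    vol_truth_mm3 = mask_volume_mm3(truth),
    stringsAsFactors = FALSE)
}

#' Dice as a function of the binarization threshold
#'
#' For each subject's mean probability map, binarizes at every
#' threshold of the grid and scores Dice against the subject's truth;
#' used to check that accuracy is insensitive to the choice of
#' threshold on well-separated predictions.
#'
#' @param mean_maps list of probability `scalar_volume`s.
#' @param truths list of `binary_mask`s (same order/length).
#' @param thresholds numeric vector of thresholds in (0, 1).
#' @param subject_ids optional identifiers.
#' @return data.frame with columns subject_id, threshold, dice; mean
#'   rows (`subject_id == ".mean"`) give the across-subject mean Dice
#'   per threshold.
#' @export
threshold_sweep <- function(mean_maps, truths,
                            thresholds = seq(0.2, 0.8, by = 0.1),
                            subject_ids = NULL) {
  if (length(mean_maps) != length(truths))
    stop("mean_maps and truths must have equal length")
  if (is.null(subject_ids))
    subject_ids <- paste0("s", seq_along(mean_maps))
  rows <- list()
  for (i in seq_along(mean_maps)) {
    for (tau in thresholds) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subject_ids[i], threshold = tau,
        dice = dice(binarize(mean_maps[[i]], tau), truths[[i]]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  means <- stats::aggregate(dice ~ threshold, data = out, FUN = mean)
  means <- data.frame(subject_id = ".mean", threshold = means$threshold,
                      dice = means$dice, stringsAsFactors = FALSE)
  rbind(out, means)
}
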