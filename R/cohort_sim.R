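#' Cohort presets
#'
#' Phantom and simulator settings for the three synthetic cohorts the
#' package ships:
#' \describe{
#'   \item{local-like}{in-distribution adults: high contrast, low
#'     epistemic and aleatoric spread — a model evaluated on data like
#'     its training set.}
#'   \item{shifted-adult}{a moderate distribution shift: same anatomy,
#'     raised epistemic spread (inter-member disagreement) — a model
#'     on out-of-distribution adult data.}
#'   \item{shifted-child}{a strong shift: smaller ventricles, thinner
#'     plexus and reduced contrast (the pediatric pattern of small CSF
#'     spaces and amplified partial-volume effects), with the largest
#'     epistemic spread and wider boundary softening.}
#' }
#'
#' @param preset one of `"local-like"`, `"shifted-adult"`,
#'   `"shifted-child"`.
#' @return list with `phantom` (template [phantom_spec()] arguments)
#'   and `simulator` (template [simulator_spec()] arguments).
#' @export
cohort_preset <- function(preset = c("local-like", "shifted-adult",
                                     "shifted-child")) {
  preset <- match.arg(preset)
  switch(preset,
    "local-like" = list(
      phantom = list(),
      simulator = list(confidence = 5, sigma_epi = 0.4, sigma_ale = 0.4,
                       boundary_width = 1),
      age_group = "adult"),
    "shifted-adult" = list(
      phantom = list(),
      simulator = list(confidence = 4, sigma_epi = 1.2, sigma_ale = 0.5,
                       boundary_width = 1),
      age_group = "adult"),
    "shifted-child" = list(
      phantom = list(
        ventricle_semiaxes = rbind(c(6.5, 10, 6.5), c(6.5, 10, 6.5)),
        plexus_radius = 1.3,
        intensity_plexus = 135),
      simulator = list(confidence = 3, sigma_epi = 2.2, sigma_ale = 0.6,
                       boundary_width = 1.5),
      age_group = "child"))
}

#' Cohort specification
#'
#' Defines one group of synthetic subjects: how many, which preset (or
#' explicit phantom/simulator overrides), and the labels carried into
#' the cohort table. Diagnosis labels alternate ASD/CON unless given.
#'
#' @param n subjects (>= 2).
#' @param cohort cohort label; when it names a preset
#'   ([cohort_preset()]) that preset supplies defaults.
#' @param diagnosis character vector recycled to length n.
#' @param site site label(s) recycled to length n.
#' @param phantom_args,simulator_args overrides merged over the preset.
#' @param shape phantom grid shape for every subject.
#' @param seed group seed; per-subject seeds are derived injectively.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, cohort = "local-like",
                        diagnosis = c("CON", "ASD"), site = "site1",
                        phantom_args = list(), simulator_args = list(),
                        shape = c(32, 32, 32), seed = 1L) {
  if (n < 2L) stop("need n >= 2 subjects per group")
  preset <- tryCatch(cohort_preset(cohort), error = function(e) NULL)
  if (!is.null(preset)) {
    phantom_args <- utils::modifyList(preset$phantom, phantom_args)
    simulator_args <- utils::modifyList(preset$simulator, simulator_args)
    age_group <- preset$age_group
  } else {
    age_group <- "adult"
  }
  structure(
    list(n = as.integer(n), cohort = cohort,
         diagnosis = rep_len(diagnosis, n), site = rep_len(site, n),
         age_group = age_group,
         phantom_args = phantom_args, simulator_args = simulator_args,
         shape = as.integer(shape), seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Builds `n` subjects, each with its own phantom anatomy (control
#' points and noise drawn from an injectively derived per-subject
#' seed), ground truth, and stochastic predictor. Deterministic given
#' the spec.
#'
#' @param spec a [cohort_spec()].
#' @return list of subjects; each is a list with `subject_id`,
#'   `diagnosis`, `cohort`, `site`, `age_group`, `seed`, `image`,
#'   `truth`, `predictor`.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  lapply(seq_len(spec$n), function(i) {
    sseed <- derive_seed(spec$seed, i, 1)
    pargs <- utils::modifyList(
      list(shape = spec$shape, seed = sseed), spec$phantom_args)
    ph <- generate_phantom(do.call(phantom_spec, pargs))
    sargs <- utils::modifyList(list(seed = sseed), spec$simulator_args)
    sim <- do.call(simulator_spec, sargs)
    list(subject_id = sprintf("%s_%03d", spec$cohort, i),
         diagnosis = spec$diagnosis[i], cohort = spec$cohort,
         site = spec$site[i], age_group = spec$age_group, seed = sseed,
         image = ph$image, truth = ph$truth,
         predictor = simulate_predictor(ph$truth, sim))
  })
}

#' Run the uncertainty pipeline over a cohort
#'
#' For each subject: run the stochastic sampling scheme (streaming),
#' binarize the predictive mean into the consensus segmentation,
#' compute the four uncertainty maps and their mask-restricted
#' aggregates (mask = the subject's own consensus, falling back to the
#' truth mask when the consensus is empty), and optionally score the
#' consensus against the truth.
#'
#' @param subjects list from [make_cohort()].
#' @param scheme a [sampling_scheme()]; its `base_seed` is combined
#'   with each subject's seed so subjects get independent streams.
#' @param threshold consensus binarization threshold.
#' @param evaluate also compute Dice/Hausdorff/volume columns against
#'   the subject truths.
#' @return a cohort table: data.frame with one row per subject
#'   (subject_id, diagnosis, cohort, site, age_group, C_h_total,
#'   C_e_h, C_mi, C_std, mask_voxels, volume_mm3, and evaluation
#'   columns when requested).
#' @export
cohort_uncertainty <- function(subjects, scheme = sampling_scheme(),
                               threshold = 0.5, evaluate = FALSE) {
  rows <- lapply(subjects, function(subj) {
    sch <- scheme
    sch$base_seed <- derive_seed(subj$seed + scheme$base_seed, 1, 2)
    summary <- run_sampling(subj$predictor, subj$image, sch)
    consensus <- binarize(summary$mean, threshold)
    mask <- if (sum(consensus$values) > 0L) consensus else subj$truth
    res <- compute_all(summary, mask, subject_id = subj$subject_id)
    row <- data.frame(
      subject_id = subj$subject_id, diagnosis = subj$diagnosis,
      cohort = subj$cohort, site = subj$site, age_group = subj$age_group,
      C_h_total = res$subject$C[["h_total"]],
      C_e_h = res$subject$C[["e_h"]],
      C_mi = res$subject$C[["mi"]],
      C_std = res$subject$C[["std"]],
      mask_voxels = res$subject$mask_voxels,
      volume_mm3 = mask_volume_mm3(consensus),
      stringsAsFactors = FALSE)
    if (evaluate) {
      ev <- evaluate_segmentation(consensus, subj$truth, subj$subject_id)
      row <- cbind(row, ev[, c("dice", "hd_mm", "hd95_mm", "vs",
                               "vol_truth_mm3")])
    }
    row
  })
  do.call(rbind, rows)
}
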