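#' Read a NIfTI volume
#'
#' Reads a 3D NIfTI-1 file (.nii or .nii.gz) into a [scalar_volume()],
#' populating the grid from the header (pixdim and the sform/qform
#' affine). With `expect_probability = TRUE` the values must already lie
#' in [0, 1].
#'
#' @param path path to a NIfTI file.
#' @param expect_probability validate the value range as [0, 1].
#' @return a `scalar_volume`.
#' @export
read_volume <- function(path, expect_probability = FALSE) {
  img <- read_nifti_checked(path)
  grid <- grid_from_nifti(img)
  scalar_volume(as.numeric(img), grid, probability = expect_probability)
}

#' Read a NIfTI binary mask
#'
#' Values within 1e-3 of 0 or 1 are coerced to exact 0/1 (tolerating
#' float storage and lossy intensity scaling); anything else is a
#' validation error.
#'
#' @param path path to a NIfTI file.
#' @return a `binary_mask`.
#' @export
read_mask <- function(path) {
  img <- read_nifti_checked(path)
  grid <- grid_from_nifti(img)
  binary_mask(as.numeric(img), grid)
}

read_nifti_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) dim(img) <- d[1:3]
  if (length(dim(img)) != 3L)
    stop("expected a 3D volume, got ", length(dim(img)), " dimensions: ", path)
  img
}

grid_from_nifti <- function(img) {
  affine <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(affine) <- list(dim = c(4L, 4L))
  image_grid(dim(img)[1:3],
             spacing = abs(RNifti::pixdim(img)[1:3]),
             affine = affine)
}

#' Write a volume or mask to NIfTI
#'
#' Probabilities and other scalar volumes are stored as 32-bit float,
#' masks as unsigned 8-bit. The grid spacing and affine go into pixdim
#' and the sform. A round-trip read returns the grid within 1e-4
#' relative tolerance and values within 1e-6 (float storage).
#'
#' @param volume a `scalar_volume` or `binary_mask`.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "binary_mask")) {
    values <- volume$values
    datatype <- "uint8"
  } else if (inherits(volume, "scalar_volume")) {
    values <- volume$values
    datatype <- "float"
  } else stop("volume must be a scalar_volume or binary_mask")
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- volume$grid$spacing
  RNifti::`sform<-`(img, structure(volume$grid$affine, code = 2L))
  dir <- dirname(path)
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tryCatch(RNifti::writeNifti(img, path, datatype = datatype),
           error = function(e) stop("cannot write '", path, "': ",
                                    conditionMessage(e)))
  # the NIfTI writer reports some failures only on its own stderr
  if (!file.exists(path)) stop("cannot write '", path, "'")
  invisible(path)
}

#' Load a sample stack from a manifest
#'
#' The manifest is a CSV with columns `subject_id`, `member`,
#' `realization`, `path` listing one probability NIfTI per stochastic
#' sample. Paths are resolved relative to the manifest's directory when
#' not absolute. All volumes must share a compatible grid and the
#' (member, realization) tags must be unique.
#'
#' @param manifest path to the manifest CSV.
#' @param subject_id subject to load; defaults to the only subject
#'   present (error if the manifest holds several and none is named).
#' @return a `sample_stack` (see [run_sampling()]).
#' @export
load_stack <- function(manifest, subject_id = NULL) {
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("subject_id", "member", "realization", "path")
  if (!all(need %in% names(tab)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (is.null(subject_id)) {
    ids <- unique(tab$subject_id)
    if (length(ids) != 1L)
      stop("manifest holds ", length(ids),
           " subjects; pass subject_id explicitly")
    subject_id <- ids
  }
  tab <- tab[tab$subject_id == subject_id, , drop = FALSE]
  if (nrow(tab) == 0L) stop("subject '", subject_id, "' not in manifest")
  if (anyDuplicated(tab[c("member", "realization")]))
    stop("duplicate (member, realization) tags for subject ", subject_id)
  base <- dirname(manifest)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  samples <- vector("list", nrow(tab))
  grid <- NULL
  for (i in seq_len(nrow(tab))) {
    vol <- read_volume(resolve(tab$path[i]), expect_probability = TRUE)
    if (is.null(grid)) grid <- vol$grid
    else stop_if_incompatible(grid, vol$grid, "stack samples")
    samples[[i]] <- vol
  }
  new_sample_stack(grid, samples,
                   members = as.integer(tab$member),
                   realizations = as.integer(tab$realization))
}
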