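#' @importFrom stats cor coef glm binomial median pnorm qnorm quantile rbinom
#'   rnorm runif rexp rbeta sd t.test chisq.test fisher.test setNames
#'   complete.cases as.formula optim plogis qlogis uniroot
#' @importFrom utils read.csv write.csv head
NULL

# Tolerance for voxel-spacing agreement across volumes of one study (mm).
# Shapes must match exactly; spacing may differ by header rounding only.
.SPACING_TOL <- 1e-3

#' Construct a DCE-MRI study object
#'
#' A `dce_study` holds one patient-timepoint of a dynamic contrast-enhanced
#' acquisition: an ordered list of co-registered 3-D volumes in which index 1
#' is the pre-contrast phase and indices 2..n are post-contrast phases, plus
#' the voxel spacing in mm.
#'
#' @param phases list of 3-D numeric arrays, all the same dimension; the
#'   first element is the pre-contrast volume.
#' @param spacing numeric length-3 vector of voxel edge lengths in mm.
#' @param patient_id character scalar identifier.
#' @param timepoint `"T0"` (pre-treatment) or `"T3"` (post-treatment).
#' @return An object of class `dce_study` with elements `patient_id`,
#'   `timepoint`, `phases`, `spacing` and `shape`.
#' @export
dce_study <- function(phases, spacing, patient_id = "anon", timepoint = c("T0", "T3")) {
  timepoint <- match.arg(timepoint)
  if (!is.list(phases) || length(phases) < 2L)
    stop("a DCE study needs at least 2 phases (pre-contrast + >=1 post-contrast)")
  shape <- dim(phases[[1L]])
  if (length(shape) != 3L)
    stop("phase volumes must be 3-D arrays")
  for (i in seq_along(phases)) {
    di <- dim(phases[[i]])
    if (length(di) != 3L || !all(di == shape))
      stop(sprintf("phase %d has shape (%s); expected (%s)",
                   i, paste(di, collapse = ","), paste(shape, collapse = ",")))
    if (!all(is.finite(phases[[i]])))
      stop(sprintf("phase %d contains non-finite voxels", i))
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite values (mm)")
  structure(
    list(patient_id = as.character(patient_id), timepoint = timepoint,
         phases = phases, spacing = spacing, shape = as.integer(shape)),
    class = "dce_study")
}

#' @export
print.dce_study <- function(x, ...) {
  cat(sprintf("<dce_study> %s @ %s: %d phases, grid %s, spacing %s mm\n",
              x$patient_id, x$timepoint, length(x$phases),
              paste(x$shape, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' Load a DCE-MRI study from NIfTI files
#'
#' Reads an ordered set of NIfTI volumes (first = pre-contrast) into a
#' [dce_study()]. The voxel grid is taken from the first volume; any later
#' volume whose shape differs, or whose spacing differs by more than
#' `1e-3` mm, is a hard error.
#'
#' @param paths character vector of NIfTI file paths in phase order.
#' @param timepoint `"T0"` or `"T3"`.
#' @param patient_id identifier stored on the study.
#' @return A [dce_study()].
#' @export
load_dce_study <- function(paths, timepoint = "T0", patient_id = "anon") {
  if (length(paths) < 2L)
    stop("need at least 2 volumes (pre-contrast + >=1 post-contrast)")
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing file(s): ", paste(missing, collapse = ", "))
  vols <- lapply(paths, RNifti::readNifti)
  spacing <- .nifti_spacing(vols[[1L]])
  shape <- dim(vols[[1L]])
  for (i in seq_along(vols)) {
    if (!all(dim(vols[[i]]) == shape))
      stop(sprintf("grid mismatch: %s has shape (%s), expected (%s)",
                   paths[i], paste(dim(vols[[i]]), collapse = ","),
                   paste(shape, collapse = ",")))
    sp <- .nifti_spacing(vols[[i]])
    if (any(abs(sp - spacing) > .SPACING_TOL))
      stop(sprintf("grid mismatch: %s spacing (%s) differs from (%s) by > %g mm",
                   paths[i], paste(sp, collapse = ","),
                   paste(spacing, collapse = ","), .SPACING_TOL))
  }
  phases <- lapply(vols, function(v) array(as.numeric(v), dim = shape))
  dce_study(phases, spacing, patient_id = patient_id, timepoint = timepoint)
}

.nifti_spacing <- function(vol) {
  px <- RNifti::pixdim(vol)
  as.numeric(px[seq_len(3L)])
}

#' Load a binary mask on the grid of a reference study
#'
#' Values must be finite; any value greater than zero is coerced to 1 (with a
#' warning when coercion actually changes values, as segmentation tools
#' sometimes emit label values > 1).
#'
#' @param path NIfTI file path.
#' @param reference a [dce_study()] defining the expected grid.
#' @return A 3-D integer array of 0/1 on the reference grid.
#' @export
load_mask <- function(path, reference) {
  stopifnot(inherits(reference, "dce_study"))
  if (!file.exists(path)) stop("missing file: ", path)
  vol <- RNifti::readNifti(path)
  if (!all(dim(vol) == reference$shape))
    stop(sprintf("grid mismatch: mask %s has shape (%s), expected (%s)", path,
                 paste(dim(vol), collapse = ","),
                 paste(reference$shape, collapse = ",")))
  sp <- .nifti_spacing(vol)
  if (any(abs(sp - reference$spacing) > .SPACING_TOL))
    stop("grid mismatch: mask spacing differs from study spacing")
  v <- as.numeric(vol)
  if (any(!is.finite(v))) stop("mask contains non-finite voxels: ", path)
  out <- as.integer(v > 0)
  n_coerced <- sum(v > 0 & v != 1)
  if (n_coerced > 0L)
    warning(sprintf("mask %s: %d voxel(s) with value != 1 coerced to 1",
                    path, n_coerced))
  array(out, dim = reference$shape)
}

#' Write a volume or mask as NIfTI
#'
#' @param vol 3-D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing voxel spacing, mm.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, spacing = c(1, 1, 1)) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- as.numeric(spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Volume of one voxel in mm^3
#'
#' @param study a [dce_study()] (or a numeric length-3 spacing vector).
#' @return Scalar voxel volume in mm^3, the product of the spacing components.
#' @export
voxel_volume <- function(study) {
  spacing <- if (inherits(study, "dce_study")) study$spacing else as.numeric(study)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  prod(spacing)
}

#' Bundle breast / FGT / tumor masks for one study
#'
#' Validates nesting: fibroglandular tissue (FGT) must lie inside the breast
#' mask. FGT voxels outside the breast are clipped to the breast with a
#' message (segmentation outputs commonly leak by a few voxels) rather than
#' an error.
#'
#' @param breast,fgt 0/1 arrays on a common grid.
#' @param tumor optional 0/1 array; `NULL` for tumor-free studies.
#' @param spacing voxel spacing, mm.
#' @return An object of class `mask_set` with elements `breast`, `fgt`,
#'   `tumor` (possibly `NULL`), `spacing`; `refined_fgt` is added by
#'   [refine_fgt()].
#' @export
mask_set <- function(breast, fgt, tumor = NULL, spacing = c(1, 1, 1)) {
  shape <- dim(breast)
  if (length(shape) != 3L) stop("masks must be 3-D arrays")
  for (m in list(fgt, tumor)) {
    if (!is.null(m) && !all(dim(m) == shape))
      stop("all masks must share one grid")
  }
  breast <- .as_binary(breast); fgt <- .as_binary(fgt)
  if (!is.null(tumor)) tumor <- .as_binary(tumor)
  leaked <- sum(fgt == 1L & breast == 0L)
  if (leaked > 0L) {
    message(sprintf("mask_set: clipped %d FGT voxel(s) outside the breast mask", leaked))
    fgt <- fgt * breast
  }
  structure(list(breast = breast, fgt = fgt, tumor = tumor,
                 refined_fgt = NULL, spacing = as.numeric(spacing)),
            class = "mask_set")
}

.as_binary <- function(m) {
  if (any(!is.finite(m))) stop("mask contains non-finite voxels")
  array(as.integer(m > 0), dim = dim(m))
}

#' Physical volume of a mask region in mm^3
#'
#' @param mask 0/1 array.
#' @param spacing voxel spacing (mm) or a [dce_study()].
#' @return voxel count times voxel volume; additive over disjoint masks.
#' @export
region_volume <- function(mask, spacing) {
  sum(mask > 0) * voxel_volume(spacing)
}

#' Read a per-patient volume manifest
#'
#' The manifest CSV lists every file of a cohort with columns `patient_id`,
#' `timepoint`, `phase_index` (0 = pre-contrast; `NA` for masks), `path` and
#' `mask_role` (empty/`NA` for phase volumes; `breast`, `fgt` or `tumor` for
#' masks). Relative paths are resolved against the manifest's directory.
#'
#' @param path CSV file path.
#' @return data.frame with the columns above and resolved paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("missing manifest: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "timepoint", "phase_index", "path", "mask_role")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}

#' Load one patient-timepoint (study + masks) from a manifest
#'
#' @param manifest data.frame from [read_manifest()].
#' @param patient_id,timepoint which rows to load.
#' @return list with elements `study` ([dce_study()]) and `masks`
#'   ([mask_set()]).
#' @export
load_from_manifest <- function(manifest, patient_id, timepoint = "T0") {
  rows <- manifest[manifest$patient_id == patient_id &
                   manifest$timepoint == timepoint, , drop = FALSE]
  if (!nrow(rows)) stop("no manifest rows for ", patient_id, " @ ", timepoint)
  is_phase <- is.na(rows$mask_role) | rows$mask_role == ""
  ph <- rows[is_phase, , drop = FALSE]
  ph <- ph[order(ph$phase_index), , drop = FALSE]
  study <- load_dce_study(ph$path, timepoint = timepoint, patient_id = patient_id)
  mk <- rows[!is_phase, , drop = FALSE]
  get_mask <- function(role) {
    p <- mk$path[mk$mask_role == role]
    if (!length(p)) return(NULL)
    load_mask(p[[1L]], study)
  }
  breast <- get_mask("breast"); fgt <- get_mask("fgt")
  if (is.null(breast) || is.null(fgt))
    stop("manifest must provide breast and fgt masks for ", patient_id)
  masks <- mask_set(breast, fgt, tumor = get_mask("tumor"),
                    spacing = study$spacing)
  list(study = study, masks = masks)
}
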