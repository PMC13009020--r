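# Laterality handling and FGT refinement.
#
# BPE is measured on the contralateral (tumor-free, or smaller-tumor) breast,
# so the breast mask has to be split into sides and tumor voxels removed from
# the FGT mask before any enhancement statistics are computed.

#' Split a mask set into left/right sides
#'
#' Every breast voxel is assigned to one side by comparing its coordinate
#' along the laterality axis with the midpoint of the breast mask's bounding
#' box along that axis. Voxels at or below the midpoint go to the lower-index
#' side (reported as `"left"`); the rest to `"right"`. No anatomical
#' reorientation is attempted — "left"/"right" are array-order labels.
#'
#' @param masks a [mask_set()].
#' @param axis laterality axis (1, 2 or 3; default 1 = first array axis).
#' @return An object of class `lateralized_masks`: list with per-side 0/1
#'   side masks (`left`, `right`), the `axis`, and the parent `masks`.
#' @export
split_laterality <- function(masks, axis = 1L) {
  stopifnot(inherits(masks, "mask_set"), axis %in% 1:3)
  if (sum(masks$breast) == 0L) stop("empty breast mask")
  idx <- which(masks$breast == 1L, arr.ind = TRUE)
  coords <- idx[, axis]
  mid <- (min(coords) + max(coords)) / 2
  left <- array(0L, dim = dim(masks$breast))
  right <- left
  is_left <- coords <= mid
  left[idx[is_left, , drop = FALSE]] <- 1L
  right[idx[!is_left, , drop = FALSE]] <- 1L
  structure(list(left = left, right = right, axis = as.integer(axis),
                 masks = masks, analysis_side = NULL, selection_mode = NULL),
            class = "lateralized_masks")
}

#' Select the analysis side (contralateral or ipsilateral)
#'
#' In `contralateral` mode the side with less tumor is chosen: the side with
#' zero tumor voxels, or — for bilateral disease — the side with the smaller
#' tumor volume; exact ties go to the lower-index side with a warning. If no
#' tumor mask is present (or it is empty) the study is treated as tumor-free
#' and the side with more FGT is chosen. `ipsilateral` mode returns the
#' complementary side.
#'
#' @param lat a `lateralized_masks` from [split_laterality()].
#' @param mode `"contralateral"` (default) or `"ipsilateral"`.
#' @return `lat` with `analysis_side` (`"left"`/`"right"`) and
#'   `selection_mode` filled in.
#' @export
select_analysis_side <- function(lat, mode = c("contralateral", "ipsilateral")) {
  stopifnot(inherits(lat, "lateralized_masks"))
  mode <- match.arg(mode)
  tumor <- lat$masks$tumor
  if (is.null(tumor) || sum(tumor) == 0L) {
    message("no tumor voxels: treating study as tumor-free, choosing larger-FGT side")
    fgt_l <- sum(lat$masks$fgt * lat$left)
    fgt_r <- sum(lat$masks$fgt * lat$right)
    contra <- if (fgt_r > fgt_l) "right" else "left"
  } else {
    t_l <- sum(tumor * lat$left)
    t_r <- sum(tumor * lat$right)
    if (t_l == t_r) {
      warning("equal tumor volume on both sides; taking lower-index side as contralateral")
      contra <- "left"
    } else {
      contra <- if (t_l < t_r) "left" else "right"
    }
  }
  side <- if (mode == "contralateral") contra else setdiff(c("left", "right"), contra)
  lat$analysis_side <- side
  lat$selection_mode <- mode
  lat
}

#' Side mask of the selected analysis side
#'
#' @param lat a `lateralized_masks` with `analysis_side` set.
#' @return The 0/1 side mask.
#' @export
analysis_side_mask <- function(lat) {
  stopifnot(inherits(lat, "lateralized_masks"))
  if (is.null(lat$analysis_side))
    stop("analysis side not selected; call select_analysis_side() first")
  lat[[lat$analysis_side]]
}

#' Refine the FGT mask by tumor exclusion
#'
#' Subtracts the tumor mask — optionally dilated by a physical margin — from
#' the FGT mask, so tumor voxels never count as enhancing parenchyma. With
#' the default margin of 0 mm this is a strict voxel-wise subtraction.
#'
#' @param masks a [mask_set()].
#' @param margin_mm non-negative dilation margin applied to the tumor before
#'   subtraction, in mm (anisotropic spacing respected).
#' @return The input `mask_set` with `refined_fgt` filled in.
#' @export
refine_fgt <- function(masks, margin_mm = 0) {
  stopifnot(inherits(masks, "mask_set"), margin_mm >= 0)
  tumor <- masks$tumor
  if (is.null(tumor) || sum(tumor) == 0L) {
    masks$refined_fgt <- masks$fgt
    return(masks)
  }
  excl <- if (margin_mm > 0) dilate_mask(tumor, margin_mm, masks$spacing) else tumor
  refined <- array(as.integer(masks$fgt == 1L & excl == 0L), dim = dim(masks$fgt))
  if (sum(refined) == 0L)
    message("refine_fgt: refined FGT mask is empty (tumor covers all FGT)")
  masks$refined_fgt <- refined
  masks
}

#' Dilate a binary mask by a physical margin
#'
#' Euclidean dilation: a voxel is set if any mask voxel lies within
#' `margin_mm` of its centre, using the voxel spacing to convert offsets to
#' mm. Implemented by shifting the mask over the ball of integer offsets
#' whose physical length is at most the margin.
#'
#' @param mask 0/1 array.
#' @param margin_mm dilation radius, mm.
#' @param spacing voxel spacing, mm.
#' @return Dilated 0/1 array.
#' @export
dilate_mask <- function(mask, margin_mm, spacing = c(1, 1, 1)) {
  if (margin_mm <= 0) return(mask)
  r <- pmax(0L, floor(margin_mm / spacing))
  offs <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d <- sqrt((offs$dx * spacing[1])^2 + (offs$dy * spacing[2])^2 +
            (offs$dz * spacing[3])^2)
  offs <- offs[d <= margin_mm, , drop = FALSE]
  dims <- dim(mask)
  out <- array(0L, dim = dims)
  for (i in seq_len(nrow(offs))) {
    sh <- .shift3d(mask, offs$dx[i], offs$dy[i], offs$dz[i])
    out <- out | sh
  }
  array(as.integer(out), dim = dims)
}

# shift an array by integer offsets, zero-filling at the borders
.shift3d <- function(a, dx, dy, dz) {
  dims <- dim(a)
  out <- array(0L, dim = dims)
  src <- function(d, n) max(1L, 1L - d):min(n, n - d)
  xs <- src(dx, dims[1]); ys <- src(dy, dims[2]); zs <- src(dz, dims[3])
  out[xs + dx, ys + dy, zs + dz] <- a[xs, ys, zs]
  out
}
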