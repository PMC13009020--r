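# Quantitative BPE.
#
# Per-voxel relative enhancement of the i-th post-contrast phase is
#   E_ij = (S_ij - S_0j) / S_0j * 100  [percent],
# defined only where the pre-contrast signal S_0j exceeds a positivity floor.
# The volume-based BPE at enhancement threshold k is the volume of refined-FGT
# voxels with E_ij >= k%, normalized by the breast volume of the analysis
# side:
#   BPE_ik = |{ j in FGT : E_ij >= k }| * V_voxel / V_breast.
# It is a fraction in [0, V_FGT / V_breast] and, being a ratio of volumes of
# a ratio image, is invariant to global intensity scaling.

#' Per-voxel relative enhancement map
#'
#' @param study a [dce_study()].
#' @param phase_index post-contrast phase to use (1 = first post-contrast,
#'   the peak-contrast default; 3 = delayed phase where acquired).
#' @param positivity_floor voxels whose pre-contrast signal is at or below
#'   this floor (signal units; default `1e-6`) have undefined enhancement and
#'   are marked invalid; they are excluded from the enhancing-voxel count but
#'   still count toward breast volume.
#' @return An object of class `enhancement_map`: list with `values` (percent
#'   enhancement, 0 where invalid), `valid` (0/1 array), `phase_index`,
#'   `spacing`.
#' @export
enhancement_map <- function(study, phase_index = 1L, positivity_floor = 1e-6) {
  stopifnot(inherits(study, "dce_study"))
  n_post <- length(study$phases) - 1L
  if (phase_index < 1L || phase_index > n_post)
    stop(sprintf("phase_index %d out of range (study has %d post-contrast phases)",
                 phase_index, n_post))
  s0 <- study$phases[[1L]]
  si <- study$phases[[phase_index + 1L]]
  valid <- s0 > positivity_floor
  vals <- array(0, dim = dim(s0))
  vals[valid] <- 100 * (si[valid] - s0[valid]) / s0[valid]
  structure(list(values = vals,
                 valid = array(as.integer(valid), dim = dim(s0)),
                 phase_index = as.integer(phase_index),
                 spacing = study$spacing),
            class = "enhancement_map")
}

#' Volume-based BPE at one enhancement threshold
#'
#' Counts refined-FGT voxels whose relative enhancement is at least
#' `threshold_k` percent (closed comparison) and normalizes their volume by
#' the breast volume. Voxels with undefined enhancement (pre-contrast signal
#' at or below the positivity floor) never count as enhancing but remain in
#' the breast-volume denominator.
#'
#' @param enh an [enhancement_map()].
#' @param refined_fgt 0/1 tumor-free FGT mask (analysis side).
#' @param breast 0/1 breast mask of the analysis side (the normalizer).
#' @param threshold_k enhancement threshold, percent.
#' @param voxel_vol voxel volume in mm^3 (defaults to the map's spacing).
#' @param side optional label (`"left"`/`"right"`) recorded on the result.
#' @return An object of class `bpe_measurement`: list with `value` (fraction
#'   in \[0, 1\]), `method = "volume"`, `threshold_k`, `phase_index`, `side`,
#'   `fgt_voxels_used`, `v_breast_mm3`, `v_fgt_mm3`.
#' @export
bpe_volume <- function(enh, refined_fgt, breast, threshold_k,
                       voxel_vol = NULL, side = NA_character_) {
  stopifnot(inherits(enh, "enhancement_map"))
  if (is.null(voxel_vol)) voxel_vol <- voxel_volume(enh$spacing)
  n_breast <- sum(breast > 0)
  if (n_breast == 0L) stop("empty breast mask")
  fgt_valid <- refined_fgt > 0 & enh$valid == 1L
  n_fgt_valid <- sum(fgt_valid)
  if (sum(refined_fgt > 0) == 0L)
    warning("empty refined FGT mask: BPE is 0")
  n_enh <- sum(fgt_valid & enh$values >= threshold_k)
  structure(list(value = (n_enh * voxel_vol) / (n_breast * voxel_vol),
                 method = "volume",
                 threshold_k = threshold_k,
                 phase_index = enh$phase_index,
                 side = side,
                 fgt_voxels_used = n_fgt_valid,
                 v_breast_mm3 = n_breast * voxel_vol,
                 v_fgt_mm3 = sum(refined_fgt > 0) * voxel_vol),
            class = "bpe_measurement")
}

#' Intensity-based BPE (mean relative enhancement)
#'
#' Mean relative enhancement over valid refined-FGT voxels, expressed as a
#' fraction (percent / 100). This is a thresholdless summary of enhancement
#' amplitude rather than enhancing volume; it is not bounded by 1 and is not
#' the canonical volume-based statistic used in the main analyses — it is
#' provided as a labelled variant for comparison.
#'
#' @inheritParams bpe_volume
#' @return A `bpe_measurement` with `method = "intensity"` and
#'   `threshold_k = NA`.
#' @export
bpe_intensity <- function(enh, refined_fgt, breast = NULL, side = NA_character_) {
  stopifnot(inherits(enh, "enhancement_map"))
  fgt_valid <- refined_fgt > 0 & enh$valid == 1L
  n <- sum(fgt_valid)
  if (n == 0L) stop("no valid FGT voxels for intensity-based BPE")
  voxel_vol <- voxel_volume(enh$spacing)
  n_breast <- if (is.null(breast)) NA_real_ else sum(breast > 0)
  structure(list(value = mean(enh$values[fgt_valid]) / 100,
                 method = "intensity",
                 threshold_k = NA_real_,
                 phase_index = enh$phase_index,
                 side = side,
                 fgt_voxels_used = n,
                 v_breast_mm3 = n_breast * voxel_vol,
                 v_fgt_mm3 = sum(refined_fgt > 0) * voxel_vol),
            class = "bpe_measurement")
}

#' @export
print.bpe_measurement <- function(x, ...) {
  cat(sprintf("<bpe_measurement> %s BPE = %.4f (phase %d%s%s)\n",
              x$method, x$value, x$phase_index,
              if (!is.na(x$threshold_k)) sprintf(", k = %g%%", x$threshold_k) else "",
              if (!is.na(x$side)) paste0(", side ", x$side) else ""))
  invisible(x)
}

#' Sweep the volume-based BPE over a threshold grid
#'
#' Computes the full BPE-vs-threshold curve for one study (one row per phase
#' and threshold). For a fixed phase the curve is non-increasing in the
#' threshold. The default grid (0 to 200% in steps of 5) brackets the
#' clinically useful 20–80% band with margin on both sides.
#'
#' @param study a [dce_study()].
#' @param lat a `lateralized_masks` with the analysis side selected and the
#'   parent mask set refined ([refine_fgt()]); alternatively pass `breast`
#'   and `refined_fgt` masks directly.
#' @param thresholds numeric vector of thresholds, percent.
#' @param phase_indices post-contrast phases to sweep.
#' @param positivity_floor see [enhancement_map()].
#' @param breast,refined_fgt direct mask override (both or neither).
#' @return data.frame with columns `patient_id`, `timepoint`, `side`,
#'   `method`, `phase_index`, `threshold_k`, `bpe_value`, `v_breast_mm3`,
#'   `v_fgt_mm3`, `fgt_voxels_used`.
#' @export
bpe_sweep <- function(study, lat = NULL, thresholds = seq(0, 200, by = 5),
                      phase_indices = 1L, positivity_floor = 1e-6,
                      breast = NULL, refined_fgt = NULL) {
  stopifnot(inherits(study, "dce_study"), length(thresholds) >= 1L)
  side <- NA_character_
  if (!is.null(lat)) {
    stopifnot(inherits(lat, "lateralized_masks"))
    if (is.null(lat$masks$refined_fgt))
      stop("mask set not refined; call refine_fgt() before bpe_sweep()")
    sm <- analysis_side_mask(lat)
    breast <- lat$masks$breast * sm
    refined_fgt <- lat$masks$refined_fgt * sm
    side <- lat$analysis_side
  }
  if (is.null(breast) || is.null(refined_fgt))
    stop("provide either `lat` or both `breast` and `refined_fgt`")
  vv <- voxel_volume(study)
  rows <- vector("list", length(phase_indices) * length(thresholds))
  r <- 0L
  for (ph in phase_indices) {
    enh <- enhancement_map(study, ph, positivity_floor)
    for (k in thresholds) {
      m <- bpe_volume(enh, refined_fgt, breast, k, voxel_vol = vv, side = side)
      r <- r + 1L
      rows[[r]] <- data.frame(patient_id = study$patient_id,
                              timepoint = study$timepoint,
                              side = side, method = "volume",
                              phase_index = ph, threshold_k = k,
                              bpe_value = m$value,
                              v_breast_mm3 = m$v_breast_mm3,
                              v_fgt_mm3 = m$v_fgt_mm3,
                              fgt_voxels_used = m$fgt_voxels_used,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
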