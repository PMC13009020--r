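# Synthetic data: a 3-D digital breast phantom with exact ground truth, and
# a cohort simulator whose ordinal grades derive from BPE at a known
# generative threshold and whose outcomes carry stated effect sizes. These
# make every stage of the pipeline testable without patient data.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so
#' generators are deterministic without disturbing the session.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Specification of a two-breast DCE phantom
#'
#' Two ellipsoidal "breasts" along the laterality axis (first array axis); a
#' seeded random subset of breast voxels is fibroglandular tissue (FGT), and
#' a seeded subset of FGT enhances by `enhancement_amplitude` percent on the
#' post-contrast phases. With `exact_counts = TRUE` (default) each side's
#' breast mask is trimmed by a few deterministically chosen voxels so that
#' the FGT and enhancing-voxel counts are exact integers, making the
#' designed BPE `enhancing_fraction * fgt_fraction` attainable exactly.
#'
#' @param shape grid size (3 integers).
#' @param spacing voxel spacing, mm.
#' @param centers 2x3 matrix of ellipsoid centres (voxel coordinates); rows =
#'   left, right. Default: centred in each half of axis 1.
#' @param radii 2x3 matrix of ellipsoid radii (voxels).
#' @param fgt_fraction fraction of breast voxels that are FGT.
#' @param enhancing_fraction fraction of FGT voxels that enhance.
#' @param enhancement_amplitude percent signal increase of enhancing voxels
#'   on the first post-contrast phase.
#' @param phase_amplitudes per-post-phase multiplier on the enhancement
#'   amplitude (kinetics); length = number of post-contrast phases.
#' @param tumor_spec `NULL`, or list with `side` (`"left"`/`"right"`),
#'   `center` (voxel coords), `radius` (voxels), `amplitude` (percent).
#' @param noise_sd additive Gaussian noise SD, signal units.
#' @param baseline_signal pre-contrast signal level.
#' @param seed integer seed.
#' @param exact_counts trim breast masks for exact fraction arithmetic.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32L, 24L, 16L), spacing = c(1, 1, 1),
                         centers = NULL, radii = NULL,
                         fgt_fraction = 0.5, enhancing_fraction = 0.4,
                         enhancement_amplitude = 80,
                         phase_amplitudes = c(1, 0.9, 0.75),
                         tumor_spec = NULL, noise_sd = 0,
                         baseline_signal = 100, seed = 1L,
                         exact_counts = TRUE) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 4L),
            fgt_fraction >= 0, fgt_fraction <= 1,
            enhancing_fraction >= 0, enhancing_fraction <= 1,
            is.finite(enhancement_amplitude), noise_sd >= 0,
            baseline_signal > 0, length(phase_amplitudes) >= 1L)
  if (is.null(centers))
    centers <- rbind(c(shape[1] * 0.27, shape[2] / 2, shape[3] / 2),
                     c(shape[1] * 0.73, shape[2] / 2, shape[3] / 2))
  if (is.null(radii)) {
    r <- c(shape[1] * 0.18, shape[2] * 0.33, shape[3] * 0.33)
    radii <- rbind(r, r)
  }
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 centers = centers, radii = radii,
                 fgt_fraction = fgt_fraction,
                 enhancing_fraction = enhancing_fraction,
                 enhancement_amplitude = enhancement_amplitude,
                 phase_amplitudes = as.numeric(phase_amplitudes),
                 tumor_spec = tumor_spec, noise_sd = noise_sd,
                 baseline_signal = baseline_signal, seed = as.integer(seed),
                 exact_counts = exact_counts),
            class = "phantom_spec")
}

.ellipsoid_mask <- function(shape, center, radius) {
  x <- (seq_len(shape[1]) - center[1]) / radius[1]
  y <- (seq_len(shape[2]) - center[2]) / radius[2]
  z <- (seq_len(shape[3]) - center[3]) / radius[3]
  d <- outer(outer(x^2, y^2, "+"), z^2, "+")
  array(as.integer(d <= 1), dim = shape)
}

# largest n' <= n for which both f1*n' and f2*f1*n' are integers (within fp
# tolerance); falls back to n if none found nearby
.exact_count <- function(n, f1, f2) {
  is_int <- function(x) abs(x - round(x)) < 1e-9
  for (np in n:max(1L, n - 2000L))
    if (is_int(f1 * np) && is_int(f2 * f1 * np)) return(np)
  n
}

#' Generate a DCE phantom with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return list with `study` ([dce_study()]), `masks` ([mask_set()]) and
#'   `truth` — a record of exact per-side voxel counts, the enhancing
#'   fraction and amplitude, and the designed noise-free BPE value
#'   (`bpe_true`, valid at any threshold below the amplitude).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  sides <- list(left = .ellipsoid_mask(shape, spec$centers[1, ], spec$radii[1, ]),
                right = .ellipsoid_mask(shape, spec$centers[2, ], spec$radii[2, ]))
  if (any(sides$left & sides$right))
    stop("breast ellipsoids overlap; adjust centers/radii")
  for (s in sides) if (sum(s) == 0L) stop("ellipsoid lies outside the grid")
  bbox_ok <- function(c0, r0) all(c0 - r0 >= 1 - 1e-9) && all(c0 + r0 <= shape + 1e-9)
  for (i in 1:2) if (!bbox_ok(spec$centers[i, ], spec$radii[i, ]))
    stop("ellipsoid exceeds the grid")

  truth_side <- list()
  fgt <- array(0L, dim = shape)
  enh_mask <- array(0L, dim = shape)
  breast <- array(0L, dim = shape)
  with_seed(spec$seed, {
    for (sn in c("left", "right")) {
      side <- sides[[sn]]
      vox <- which(side == 1L)
      n <- length(vox)
      if (spec$exact_counts) {
        np <- .exact_count(n, spec$fgt_fraction, spec$enhancing_fraction)
        if (np < n) {
          # trim voxels farthest from the ellipsoid centre (deterministic)
          ci <- spec$centers[if (sn == "left") 1 else 2, ]
          idx <- which(side == 1L, arr.ind = TRUE)
          d2 <- (idx[, 1] - ci[1])^2 + (idx[, 2] - ci[2])^2 + (idx[, 3] - ci[3])^2
          keep <- order(d2, vox)[seq_len(np)]
          vox <- vox[keep]
          n <- np
        }
      }
      side2 <- array(0L, dim = shape); side2[vox] <- 1L
      breast[vox] <- 1L
      n_fgt <- round(spec$fgt_fraction * n)
      n_enh <- round(spec$enhancing_fraction * n_fgt)
      fgt_vox <- sort(sample(vox, n_fgt))
      enh_vox <- sort(sample(fgt_vox, n_enh))
      fgt[fgt_vox] <- 1L
      enh_mask[enh_vox] <- 1L
      truth_side[[sn]] <- list(n_breast = n, n_fgt = n_fgt, n_enh = n_enh,
                               bpe_true = if (n > 0) n_enh / n else NA_real_)
    }

    tumor <- NULL
    if (!is.null(spec$tumor_spec)) {
      ts <- spec$tumor_spec
      tumor <- .ellipsoid_mask(shape, ts$center, rep(ts$radius, 3)) * breast
      if (sum(tumor) == 0L) stop("tumor ellipsoid contains no breast voxels")
    }

    n_phase <- length(spec$phase_amplitudes)
    base <- array(spec$baseline_signal, dim = shape)
    phases <- vector("list", n_phase + 1L)
    rel <- enh_mask * (spec$enhancement_amplitude / 100)
    if (!is.null(tumor))
      rel <- pmax(rel, tumor * (spec$tumor_spec$amplitude / 100))
    phases[[1L]] <- base
    for (i in seq_len(n_phase))
      phases[[i + 1L]] <- base * (1 + rel * spec$phase_amplitudes[i])
    if (spec$noise_sd > 0)
      for (i in seq_along(phases))
        phases[[i]] <- phases[[i]] + array(rnorm(prod(shape), 0, spec$noise_sd),
                                           dim = shape)
  })

  study <- dce_study(phases, spec$spacing, patient_id = "phantom", timepoint = "T0")
  masks <- mask_set(breast, fgt, tumor = tumor, spacing = spec$spacing)
  truth <- list(per_side = truth_side,
                enhancing_fraction = spec$enhancing_fraction,
                fgt_fraction = spec$fgt_fraction,
                amplitude = spec$enhancement_amplitude,
                designed_bpe = spec$enhancing_fraction * spec$fgt_fraction,
                enh_mask = enh_mask)
  list(study = study, masks = masks, truth = truth)
}

#' Write a phantom to NIfTI files plus a manifest
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @param patient_id,timepoint identifiers used in filenames and manifest.
#' @return data.frame of manifest rows (not yet written to disk).
#' @export
write_phantom <- function(phantom, dir, patient_id = "phantom", timepoint = "T0") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- phantom$study$spacing
  rows <- list()
  for (i in seq_along(phantom$study$phases)) {
    f <- file.path(dir, sprintf("%s_%s_phase%d.nii.gz", patient_id, timepoint, i - 1L))
    write_volume(phantom$study$phases[[i]], f, sp)
    rows[[length(rows) + 1L]] <- data.frame(patient_id = patient_id,
      timepoint = timepoint, phase_index = i - 1L, path = f, mask_role = "",
      stringsAsFactors = FALSE)
  }
  roles <- list(breast = phantom$masks$breast, fgt = phantom$masks$fgt,
                tumor = phantom$masks$tumor)
  for (role in names(roles)) {
    if (is.null(roles[[role]])) next
    f <- file.path(dir, sprintf("%s_%s_%s.nii.gz", patient_id, timepoint, role))
    write_volume(roles[[role]], f, sp)
    rows[[length(rows) + 1L]] <- data.frame(patient_id = patient_id,
      timepoint = timepoint, phase_index = NA_integer_, path = f,
      mask_role = role, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Specification of a simulated patient cohort
#'
#' Each patient carries a latent enhancement model: an FGT volume fraction
#' `r` and a Gaussian distribution of voxel enhancement amplitudes
#' (mean `mu`, SD `sigma`), so the BPE-vs-threshold curve is
#' `bpe(k) = r * P(amplitude >= k)`. Ordinal grades are obtained by binning
#' the BPE computed at the generative threshold `k_star` at prevalence-based
#' cutpoints, then flipping to an adjacent grade with probability
#' `flip_prob` (radiologist variability). Survival times follow an
#' exponential proportional-hazards model with the stated log-HR on the
#' dichotomized (grade 3/4 vs 1/2) indicator, censored administratively at
#' the time that yields the target event rate; pCR follows a logistic model
#' with the stated log-OR on a drop in quantitative grade after NAC.
#'
#' @param n number of patients.
#' @param k_star generative enhancement threshold, percent.
#' @param grade_prevalence length-4 probabilities of grades 1..4 (defaults
#'   to the 471/299/205/99 split of a 1074-patient reference cohort).
#' @param grade_cutpoints optional explicit cutpoints on BPE at `k_star`
#'   (length 3, increasing); default: prevalence quantiles of the sample.
#' @param flip_prob adjacent-grade misclassification probability.
#' @param log_hr_os,log_hr_rfs log hazard ratios of the high-BPE indicator.
#' @param log_or_drop log odds ratio of a post-NAC grade drop for pCR.
#' @param pcr_base_rate pCR probability without a grade drop.
#' @param event_rate_os,event_rate_rfs target event fractions.
#' @param nac_fraction fraction of patients receiving NAC (these get T3
#'   measurements and pCR outcomes).
#' @param seed integer seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n, k_star = 55, grade_prevalence = c(471, 299, 205, 99) / 1074,
                        grade_cutpoints = NULL, flip_prob = 0.1,
                        log_hr_os = log(0.58), log_hr_rfs = log(0.85),
                        log_or_drop = log(6), pcr_base_rate = 0.2,
                        event_rate_os = 0.35, event_rate_rfs = 0.45,
                        nac_fraction = 0.3, seed = 1L) {
  stopifnot(n >= 1, length(grade_prevalence) == 4L,
            abs(sum(grade_prevalence) - 1) < 1e-8,
            flip_prob >= 0, flip_prob <= 0.5,
            event_rate_os > 0, event_rate_os < 1,
            event_rate_rfs > 0, event_rate_rfs < 1,
            nac_fraction >= 0, nac_fraction <= 1)
  if (!is.null(grade_cutpoints))
    stopifnot(length(grade_cutpoints) == 3L, all(diff(grade_cutpoints) > 0))
  structure(as.list(environment()), class = "cohort_spec")
}

# per-patient BPE-vs-threshold curve of the latent enhancement model
.bpe_curve <- function(r, mu, sigma, k) r * pnorm((mu - k) / sigma)

#' Generate a simulated cohort
#'
#' @param spec a [cohort_spec()].
#' @return data.frame of per-patient records (one row each) with latent
#'   enhancement parameters (`enh_r`, `enh_mu`, `enh_sigma`), quantitative
#'   BPE at `k_star` (`bpe_t0`, and `bpe_t3` for NAC patients), true and
#'   observed grades, demographics, OS/RFS times and events, and `pcr`.
#'   Attributes: `cutpoints` (the generative grade cutpoints), `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  with_seed(spec$seed, {
    # latent enhancement model
    enh_r <- stats::rbeta(n, 2, 8)            # FGT fraction of breast volume
    enh_mu <- rnorm(n, 60, 25)                # mean voxel amplitude, percent
    enh_sigma <- runif(n, 15, 40)             # amplitude spread, percent
    bpe_t0 <- .bpe_curve(enh_r, enh_mu, enh_sigma, spec$k_star)

    cp <- spec$grade_cutpoints
    if (is.null(cp)) {
      pr <- cumsum(spec$grade_prevalence)[1:3]
      cp <- quantile(bpe_t0, pr, names = FALSE)
    }
    grade_true <- 1L + vapply(bpe_t0, function(b) sum(cp <= b), integer(1))
    flip <- runif(n) < spec$flip_prob
    dirn <- ifelse(runif(n) < 0.5, -1L, 1L)
    radiologist_grade <- pmin(4L, pmax(1L, grade_true + ifelse(flip, dirn, 0L)))
    bpe_high <- as.integer(grade_true >= 3L)

    # demographics: higher grades trend younger / premenopausal
    age <- rnorm(n, 55.5 - 3 * (grade_true - 1), 11)
    p_post <- plogis((age - 51) / 4)
    meno <- ifelse(runif(n) < 0.03, "unknown",
                   ifelse(runif(n) < p_post, "post", "pre"))
    race <- sample(c("White", "Black", "Asian", "Hispanic", "AIAN", "NHPI",
                     "Multi"), n, replace = TRUE,
                   prob = c(759, 213, 24, 41, 23, 4, 9) / 1073)
    subtype <- sample(c("HR+HER2-", "HR+HER2+", "HR-HER2+", "TN"), n,
                      replace = TRUE, prob = c(648, 123, 75, 228) / 1074)
    hr_status <- as.integer(subtype %in% c("HR+HER2-", "HR+HER2+"))
    her2_status <- as.integer(subtype %in% c("HR+HER2+", "HR-HER2+"))
    tumor_stage <- sample(1:4, n, replace = TRUE, prob = c(0.3, 0.4, 0.2, 0.1))
    histologic_grade <- sample(1:3, n, replace = TRUE, prob = c(0.2, 0.45, 0.35))
    node_positive <- rbinom(n, 1, 0.35)
    nac <- rbinom(n, 1, spec$nac_fraction)

    # survival: exponential PH on the high-BPE indicator, administrative
    # censoring at the time giving the target event rate
    sim_surv <- function(log_hr, target) {
      lam <- 2e-4 * exp(log_hr * bpe_high)    # per day
      tt <- rexp(n, lam)
      f <- function(C) mean(1 - exp(-lam * C)) - target
      C <- tryCatch(uniroot(f, c(1, 1e6))$root,
                    error = function(e) stop("infeasible event rate"))
      list(time = pmin(tt, C), event = as.integer(tt <= C))
    }
    os <- sim_surv(spec$log_hr_os, spec$event_rate_os)
    rfs <- sim_surv(spec$log_hr_rfs, spec$event_rate_rfs)

    # post-NAC BPE: multiplicative shrink, stronger for higher grades
    shrink <- pmin(1.1, pmax(0.05, rnorm(n, 0.9 - 0.1 * (grade_true - 1), 0.15)))
    bpe_t3 <- ifelse(nac == 1L, bpe_t0 * shrink, NA_real_)
    grade_t3 <- ifelse(nac == 1L,
                       1L + vapply(bpe_t3, function(b)
                         if (is.na(b)) NA_integer_ else sum(cp <= b), integer(1)),
                       NA_integer_)
    drop_grade <- ifelse(nac == 1L, as.integer(grade_t3 < grade_true), NA_integer_)
    pcr <- rep(NA_integer_, n)
    i_nac <- which(nac == 1L)
    if (length(i_nac))
      pcr[i_nac] <- rbinom(length(i_nac), 1,
                           plogis(qlogis(spec$pcr_base_rate) +
                                  spec$log_or_drop * drop_grade[i_nac]))

    cohort <- data.frame(
      patient_id = sprintf("sim%05d", seq_len(n)),
      age_years = age, menopausal_status = meno, race_ethnicity = race,
      hr_status = hr_status, her2_status = her2_status,
      molecular_subtype = subtype, tumor_stage = tumor_stage,
      histologic_grade = histologic_grade, node_positive = node_positive,
      nac = nac, enh_r = enh_r, enh_mu = enh_mu, enh_sigma = enh_sigma,
      bpe_t0 = bpe_t0, bpe_t3 = bpe_t3, grade_true = grade_true,
      radiologist_grade = radiologist_grade, grade_t3 = grade_t3,
      bpe_high = bpe_high, grade_drop = drop_grade,
      os_time = os$time, os_event = os$event,
      rfs_time = rfs$time, rfs_event = rfs$event, pcr = pcr,
      stringsAsFactors = FALSE)
  })
  attr(cohort, "cutpoints") <- cp
  attr(cohort, "spec") <- spec
  cohort
}

#' Per-patient BPE at every threshold of a grid
#'
#' Evaluates each simulated patient's latent BPE-vs-threshold curve on a
#' grid, in the long format [optimize_threshold()] consumes.
#'
#' @param cohort a [generate_cohort()] result.
#' @param grid threshold grid, percent.
#' @return data.frame with `patient_id`, `threshold_k`, `bpe_value`.
#' @export
cohort_sweep_table <- function(cohort, grid = seq(0, 200, by = 5)) {
  stopifnot(all(c("enh_r", "enh_mu", "enh_sigma") %in% names(cohort)))
  out <- expand.grid(patient_id = cohort$patient_id, threshold_k = grid,
                     stringsAsFactors = FALSE)
  i <- match(out$patient_id, cohort$patient_id)
  out$bpe_value <- .bpe_curve(cohort$enh_r[i], cohort$enh_mu[i],
                              cohort$enh_sigma[i], out$threshold_k)
  out
}
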