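# End-to-end orchestration: simulate -> quantify -> calibrate -> grade ->
# outcomes, with a resolved-config record and per-stage file outputs so a
# run is auditable and reproducible.

#' Build a run configuration
#'
#' @param out_dir output directory for all stage artifacts.
#' @param stages subset of `c("simulate", "quantify", "calibrate", "grade",
#'   "outcomes")`, executed in pipeline order.
#' @param manifest path to a volume manifest CSV ([read_manifest()]);
#'   written by the simulate stage when it runs.
#' @param grades_csv path to a CSV with `patient_id`, `radiologist_grade`.
#' @param cohort_csv path to a cohort CSV (outcomes stage).
#' @param side `"contralateral"` or `"ipsilateral"`.
#' @param lat_axis laterality axis (1–3).
#' @param thresholds numeric threshold grid, percent.
#' @param phases post-contrast phase indices to quantify.
#' @param positivity_floor pre-contrast signal floor.
#' @param tumor_margin_mm tumor dilation margin for FGT refinement.
#' @param alpha univariate screening level.
#' @param n_sim simulate stage: cohort size.
#' @param n_phantoms simulate stage: number of phantom studies to write.
#' @param seed integer seed for all randomness in the run.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, stages = c("quantify", "calibrate", "grade",
                                           "outcomes"),
                       manifest = NULL, grades_csv = NULL, cohort_csv = NULL,
                       side = "contralateral", lat_axis = 1L,
                       thresholds = seq(0, 200, by = 5), phases = 1L,
                       positivity_floor = 1e-6, tumor_margin_mm = 0,
                       alpha = 0.05, n_sim = 300L, n_phantoms = 2L,
                       seed = 1L) {
  all_stages <- c("simulate", "quantify", "calibrate", "grade", "outcomes")
  stages <- all_stages[all_stages %in% stages]
  if (!length(stages)) stop("no valid stages requested")
  stopifnot(length(thresholds) >= 1L, side %in% c("contralateral", "ipsilateral"))
  structure(list(out_dir = out_dir, stages = stages, manifest = manifest,
                 grades_csv = grades_csv, cohort_csv = cohort_csv,
                 side = side, lat_axis = as.integer(lat_axis),
                 thresholds = thresholds, phases = as.integer(phases),
                 positivity_floor = positivity_floor,
                 tumor_margin_mm = tumor_margin_mm, alpha = alpha,
                 n_sim = as.integer(n_sim), n_phantoms = as.integer(n_phantoms),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys as in [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("missing config: ", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$thresholds) && length(y$thresholds) == 3L &&
      !is.null(names(y$thresholds)))
    y$thresholds <- seq(y$thresholds[["from"]], y$thresholds[["to"]],
                        by = y$thresholds[["by"]])
  do.call(run_config, y)
}

#' Run the BPE pipeline
#'
#' Executes the configured stages in order, writing every intermediate table
#' to `out_dir`: `manifest.csv` + NIfTI phantoms and `cohort.csv` (simulate),
#' `sweep.csv` (quantify), `threshold_curve.csv` + `calibration.json`
#' (calibrate), `grade_model.json` + `predicted_grades.csv` (grade), and
#' `table1.csv` / `table2_os.csv` / `table2_rfs.csv` / `table3_pcr.csv` +
#' `screening_log.json` (outcomes). The resolved configuration is written as
#' `run_config.json`. Identical config + inputs + seed reproduce identical
#' numbers.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  # validate declared inputs before any computation
  for (f in c(config$manifest, config$grades_csv, config$cohort_csv))
    if (!is.null(f) && !("simulate" %in% config$stages) && !file.exists(f))
      stop("validation error: missing input file ", f)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- config; cfg_json$thresholds <- as.numeric(cfg_json$thresholds)
  jsonlite::write_json(unclass(cfg_json),
                       file.path(config$out_dir, "run_config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  res <- list()

  for (stage in config$stages) {
    res <- switch(stage,
      simulate  = .stage_simulate(config, res),
      quantify  = .stage_quantify(config, res),
      calibrate = .stage_calibrate(config, res),
      grade     = .stage_grade(config, res),
      outcomes  = .stage_outcomes(config, res))
  }
  invisible(res)
}

.stage_simulate <- function(config, res) {
  sim_dir <- file.path(config$out_dir, "sim")
  dir.create(sim_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(config$n_phantoms)) {
    ps <- phantom_spec(seed = config$seed + i,
                       tumor_spec = list(side = "right", center = c(24, 12, 8),
                                         radius = 2.5, amplitude = 150))
    ph <- generate_phantom(ps)
    pid <- sprintf("phantom%03d", i)
    rows[[i]] <- write_phantom(ph, sim_dir, patient_id = pid, timepoint = "T0")
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(config$out_dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  cohort <- generate_cohort(cohort_spec(n = config$n_sim, seed = config$seed))
  cpath <- file.path(config$out_dir, "cohort.csv")
  write.csv(cohort, cpath, row.names = FALSE)
  gpath <- file.path(config$out_dir, "grades.csv")
  write.csv(cohort[, c("patient_id", "radiologist_grade")], gpath,
            row.names = FALSE)
  config_env <- res
  config_env$manifest_path <- mpath
  config_env$cohort_path <- cpath
  config_env$grades_path <- gpath
  config_env
}

.stage_quantify <- function(config, res) {
  mpath <- res$manifest_path %||% config$manifest
  if (is.null(mpath)) stop("quantify stage needs a manifest")
  manifest <- read_manifest(mpath)
  keys <- unique(manifest[, c("patient_id", "timepoint")])
  sweeps <- list()
  for (i in seq_len(nrow(keys))) {
    loaded <- load_from_manifest(manifest, keys$patient_id[i], keys$timepoint[i])
    masks <- refine_fgt(loaded$masks, config$tumor_margin_mm)
    lat <- split_laterality(masks, axis = config$lat_axis)
    lat <- select_analysis_side(lat, mode = config$side)
    sweeps[[i]] <- bpe_sweep(loaded$study, lat, thresholds = config$thresholds,
                             phase_indices = config$phases,
                             positivity_floor = config$positivity_floor)
  }
  sweep <- do.call(rbind, sweeps)
  write.csv(sweep, file.path(config$out_dir, "sweep.csv"), row.names = FALSE)
  res$sweep <- sweep
  res
}

.stage_calibrate <- function(config, res) {
  gpath <- res$grades_path %||% config$grades_csv
  if (is.null(gpath)) stop("calibrate stage needs a grades CSV")
  grades <- read.csv(gpath, stringsAsFactors = FALSE)
  sweep <- res$sweep
  if (!is.null(sweep) &&
      !all(sweep$patient_id %in% grades$patient_id)) {
    message("calibrate: imaging sweep patients have no grades; using the cohort's analytic sweep")
    sweep <- NULL
  }
  if (is.null(sweep)) {
    # calibrate can run from a simulated cohort's analytic sweep
    cpath <- res$cohort_path %||% config$cohort_csv
    if (is.null(cpath)) stop("calibrate stage needs a graded sweep or a cohort")
    cohort <- read.csv(cpath, stringsAsFactors = FALSE)
    sweep <- cohort_sweep_table(cohort, config$thresholds)
  }
  tc <- optimize_threshold(sweep, grades, grid = config$thresholds)
  write.csv(tc$curve, file.path(config$out_dir, "threshold_curve.csv"),
            row.names = FALSE)
  i <- which(tc$curve$threshold_k == tc$optimal_k)
  jsonlite::write_json(list(optimal_k = tc$optimal_k,
                            rho = tc$curve$rho[i],
                            auc_1_v_234 = tc$curve$auc_1_v_234[i],
                            auc_12_v_34 = tc$curve$auc_12_v_34[i],
                            auc_123_v_4 = tc$curve$auc_123_v_4[i]),
                       file.path(config$out_dir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA)
  res$threshold_curve <- tc
  res$sweep_used <- sweep
  res$grades <- grades
  res
}

.stage_grade <- function(config, res) {
  tc <- res$threshold_curve
  if (is.null(tc)) stop("grade stage needs calibration results (run calibrate)")
  sweep <- res$sweep_used
  rows <- sweep[sweep$threshold_k == tc$optimal_k, , drop = FALSE]
  g <- setNames(res$grades$radiologist_grade, res$grades$patient_id)
  gi <- as.integer(g[as.character(rows$patient_id)])
  gm <- fit_grade_model(rows$bpe_value, gi, threshold_k = tc$optimal_k,
                        levels = if (all(1:4 %in% gi)) "both" else "2")
  jsonlite::write_json(list(threshold_k = gm$threshold_k,
                            criterion = gm$criterion,
                            cutpoints_2level = gm$cutpoints_2level,
                            cutpoints_4level = gm$cutpoints_4level),
                       file.path(config$out_dir, "grade_model.json"),
                       auto_unbox = TRUE, digits = NA)
  pred <- data.frame(patient_id = rows$patient_id,
                     bpe_value = rows$bpe_value,
                     predicted_2level = as.character(assign_grade(gm, rows$bpe_value, "2")),
                     stringsAsFactors = FALSE)
  if (!is.null(gm$cutpoints_4level))
    pred$predicted_grade <- assign_grade(gm, rows$bpe_value, "4")
  write.csv(pred, file.path(config$out_dir, "predicted_grades.csv"),
            row.names = FALSE)
  res$grade_model <- gm
  res$predicted_grades <- pred
  res
}

.stage_outcomes <- function(config, res) {
  cpath <- res$cohort_path %||% config$cohort_csv
  if (is.null(cpath)) stop("outcomes stage needs a cohort CSV")
  cohort <- validate_cohort(read.csv(cpath, stringsAsFactors = FALSE))
  t1 <- cohort_summary(cohort)
  write.csv(t1, file.path(config$out_dir, "table1.csv"), row.names = FALSE)
  candidates <- intersect(c("age_years", "menopausal_status", "node_positive",
                            "tumor_stage", "histologic_grade", "hr_status",
                            "her2_status", "nac"), names(cohort))
  screening <- list()
  tables <- list()
  for (oc in c("OS", "RFS")) {
    scr <- univariate_screen(cohort, oc, candidates, alpha = config$alpha,
                             primary = "bpe_high")
    screening[[oc]] <- scr[c("selected", "p_values", "log")]
    est <- fit_cox(cohort, oc, predictor = "bpe_high",
                   covariates = setdiff(scr$selected, "bpe_high"))
    tables[[oc]] <- data.frame(outcome = oc, predictor = "bpe_high",
                               hr = est$point, ci_low = est$ci_low,
                               ci_high = est$ci_high, p = est$p_value,
                               n = est$n_used, stringsAsFactors = FALSE)
    write.csv(tables[[oc]],
              file.path(config$out_dir, sprintf("table2_%s.csv", tolower(oc))),
              row.names = FALSE)
  }
  if ("pcr" %in% names(cohort) && any(!is.na(cohort$pcr))) {
    sub <- cohort[!is.na(cohort$pcr) & !is.na(cohort$grade_drop), , drop = FALSE]
    if (length(unique(sub$grade_drop)) == 2L && sum(sub$pcr) >= 1L) {
      scr <- univariate_screen(sub, "pCR", intersect(candidates,
               c("age_years", "menopausal_status", "hr_status", "her2_status")),
               alpha = config$alpha, primary = "grade_drop")
      screening$pCR <- scr[c("selected", "p_values", "log")]
      est <- fit_pcr_logistic(sub, "grade_drop",
                              covariates = setdiff(scr$selected, "grade_drop"))
      t3 <- data.frame(predictor = "grade_drop", or = est$point,
                       ci_low = est$ci_low, ci_high = est$ci_high,
                       p = est$p_value, n = est$n_used, stringsAsFactors = FALSE)
      write.csv(t3, file.path(config$out_dir, "table3_pcr.csv"), row.names = FALSE)
      res$table3 <- t3
    }
  }
  jsonlite::write_json(screening, file.path(config$out_dir, "screening_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  res$table1 <- t1
  res$table2 <- tables
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
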