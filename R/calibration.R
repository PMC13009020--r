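# Calibration of the enhancement threshold against radiologist BPE grades,
# grade-separation AUCs, monotone grade cutpoints, and longitudinal change.

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, as used to compare a
#' continuous BPE measurement with the ordinal radiologist grade. A constant
#' vector has no rank ordering and is an error.
#'
#' @param x,y numeric vectors of equal length (>= 3), finite.
#' @return correlation in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (sd(x) == 0 || sd(y) == 0)
    stop("Spearman correlation undefined for a constant vector")
  cor(x, y, method = "spearman")
}

#' Rank-sum AUC for a grade dichotomy
#'
#' The area under the ROC curve of a continuous score for the high-grade
#' class, computed as the Mann–Whitney concordance probability with ties
#' counted one half. Equal to the AUC of a single-covariate logistic model,
#' since AUC is invariant to monotone transforms of the score.
#'
#' @param bpe numeric score vector.
#' @param grades ordinal grades 1..4 (or any integer-valued ordinal).
#' @param split which dichotomy: `"1_v_234"` (grade 1 vs 2–4),
#'   `"12_v_34"` (1–2 vs 3–4) or `"123_v_4"` (1–3 vs 4).
#' @return AUC in \[0, 1\].
#' @export
dichotomy_auc <- function(bpe, grades, split = c("12_v_34", "1_v_234", "123_v_4")) {
  split <- match.arg(split)
  cut <- switch(split, "1_v_234" = 2L, "12_v_34" = 3L, "123_v_4" = 4L)
  auc_binary(bpe, as.integer(grades >= cut))
}

#' Rank-sum AUC for a binary label
#'
#' @param score numeric vector.
#' @param label 0/1 vector (1 = positive class); both classes must be
#'   nonempty.
#' @return AUC in \[0, 1\].
#' @export
auc_binary <- function(score, label) {
  stopifnot(length(score) == length(label))
  label <- as.integer(label)
  n1 <- sum(label == 1L); n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be nonempty")
  r <- rank(score)                       # average ranks handle ties as 1/2
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Optimize the enhancement threshold against radiologist grades
#'
#' For every threshold on the grid, correlates the per-patient BPE with the
#' ordinal grade (Spearman) and computes the three grade-separation AUCs.
#' The optimal threshold maximizes the correlation; ties break to the
#' smallest threshold.
#'
#' @param sweep data.frame with columns `patient_id`, `threshold_k`,
#'   `bpe_value` (one phase at a time), e.g. from [bpe_sweep()] or
#'   [cohort_sweep_table()].
#' @param grades data.frame with columns `patient_id`, `radiologist_grade`
#'   (1–4), or a named vector.
#' @param grid thresholds to evaluate (default: all present in `sweep`).
#' @return An object of class `threshold_curve`: data.frame-backed list with
#'   `curve` (threshold, rho, auc_1_v_234, auc_12_v_34, auc_123_v_4) and
#'   `optimal_k`.
#' @export
optimize_threshold <- function(sweep, grades, grid = NULL) {
  if (is.data.frame(grades)) {
    g <- setNames(grades$radiologist_grade, grades$patient_id)
  } else g <- grades
  if (length(unique(g)) < 2L) stop("need at least 2 distinct grades")
  if (is.null(grid)) grid <- sort(unique(sweep$threshold_k))
  if (!length(grid)) stop("empty threshold grid")
  curve <- data.frame(threshold_k = grid, rho = NA_real_,
                      auc_1_v_234 = NA_real_, auc_12_v_34 = NA_real_,
                      auc_123_v_4 = NA_real_)
  for (i in seq_along(grid)) {
    rows <- sweep[sweep$threshold_k == grid[i], , drop = FALSE]
    gi <- as.numeric(g[as.character(rows$patient_id)])
    if (any(is.na(gi))) stop("grades missing for some patients in the sweep")
    b <- rows$bpe_value
    curve$rho[i] <- if (sd(b) == 0) 0 else spearman_rho(b, gi)
    for (sp in c("1_v_234", "12_v_34", "123_v_4")) {
      cutg <- switch(sp, "1_v_234" = 2L, "12_v_34" = 3L, "123_v_4" = 4L)
      col <- paste0("auc_", sp)
      if (any(gi >= cutg) && any(gi < cutg))
        curve[[col]][i] <- auc_binary(b, as.integer(gi >= cutg))
    }
  }
  best <- max(curve$rho)
  optimal_k <- min(curve$threshold_k[curve$rho == best])
  structure(list(curve = curve, optimal_k = optimal_k), class = "threshold_curve")
}

#' @export
print.threshold_curve <- function(x, ...) {
  i <- which(x$curve$threshold_k == x$optimal_k)
  cat(sprintf("<threshold_curve> %d thresholds; optimal k = %g%% (rho = %.3f)\n",
              nrow(x$curve), x$optimal_k, x$curve$rho[i]))
  cat(sprintf("  AUC at optimum: 1 vs 2-4 = %.3f, 1-2 vs 3-4 = %.3f, 1-3 vs 4 = %.3f\n",
              x$curve$auc_1_v_234[i], x$curve$auc_12_v_34[i], x$curve$auc_123_v_4[i]))
  invisible(x)
}

# Youden-optimal cutpoint for score >= c => positive. Candidates are
# midpoints between consecutive distinct scores (plus outer sentinels);
# ties in J break to the smallest cutpoint.
youden_cutpoint <- function(score, label) {
  label <- as.integer(label)
  stopifnot(any(label == 1L), any(label == 0L))
  u <- sort(unique(score))
  cand <- if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2 else u
  j <- vapply(cand, function(c) {
    mean(score[label == 1L] >= c) - mean(score[label == 0L] >= c)
  }, numeric(1))
  cand[which.max(j)]                      # which.max takes the first (smallest)
}

#' Fit monotone grade cutpoints from quantitative BPE
#'
#' Learns cutpoints on the quantitative BPE scale that reproduce the ordinal
#' radiologist grade. The 2-level cutpoint separates grades 1/2 from 3/4;
#' the 4-level model stacks the Youden-optimal cutpoints of the three
#' cumulative dichotomies (grade >= 2, >= 3, = 4), with an isotonic repair
#' (logged) if the raw cutpoints are not increasing.
#'
#' @param bpe numeric BPE vector.
#' @param grades ordinal grades 1..4; the 4-level fit needs all four present.
#' @param threshold_k the enhancement threshold the BPE values were computed
#'   at (recorded on the model).
#' @param levels `"both"` (default), `"2"` or `"4"`.
#' @return An object of class `grade_model` with `cutpoints_2level` (scalar),
#'   `cutpoints_4level` (length 3, strictly increasing) and `threshold_k`.
#' @export
fit_grade_model <- function(bpe, grades, threshold_k = NA_real_,
                            levels = c("both", "2", "4")) {
  levels <- match.arg(levels)
  grades <- as.integer(grades)
  if (length(unique(grades)) < 2L) stop("need at least 2 distinct grades")
  cut2 <- cut4 <- NULL
  if (levels %in% c("both", "2"))
    cut2 <- youden_cutpoint(bpe, as.integer(grades >= 3L))
  if (levels %in% c("both", "4")) {
    if (!all(1:4 %in% grades)) stop("4-level fit needs all four grades present")
    raw <- vapply(2:4, function(gc) youden_cutpoint(bpe, as.integer(grades >= gc)),
                  numeric(1))
    cut4 <- cummax(raw)
    if (any(cut4 != raw))
      message("fit_grade_model: isotonic repair applied to 4-level cutpoints")
    eps <- max(1e-12, 1e-9 * max(abs(bpe)))
    for (i in 2:3) if (cut4[i] <= cut4[i - 1]) cut4[i] <- cut4[i - 1] + eps
  }
  structure(list(cutpoints_2level = cut2, cutpoints_4level = cut4,
                 threshold_k = threshold_k, criterion = "youden"),
            class = "grade_model")
}

#' Assign a grade from a fitted grade model
#'
#' A BPE value maps to 1 plus the number of cutpoints at or below it
#' (closed on the right: a value exactly at a cutpoint takes the higher
#' grade). Monotone in BPE by construction.
#'
#' @param model a [fit_grade_model()] result.
#' @param bpe numeric vector of BPE values.
#' @param levels `"4"` (default, grades 1–4) or `"2"` (`"low"`/`"high"`).
#' @return integer grades (4-level) or factor low/high (2-level).
#' @export
assign_grade <- function(model, bpe, levels = c("4", "2")) {
  stopifnot(inherits(model, "grade_model"))
  levels <- match.arg(levels)
  if (levels == "2") {
    if (is.null(model$cutpoints_2level)) stop("model has no 2-level cutpoint")
    return(factor(ifelse(bpe >= model$cutpoints_2level, "high", "low"),
                  levels = c("low", "high")))
  }
  if (is.null(model$cutpoints_4level)) stop("model has no 4-level cutpoints")
  vapply(bpe, function(b) 1L + sum(model$cutpoints_4level <= b), integer(1))
}

#' Classify longitudinal grade change
#'
#' Maps the sign of the post- minus pre-treatment grade to
#' `drop` / `stable` / `increase`. A drop in quantitative BPE grade across
#' neoadjuvant chemotherapy is the primary pCR predictor.
#'
#' @param grade_t0,grade_t3 grades in 1..4 (vectorized).
#' @return factor with levels `drop`, `stable`, `increase`.
#' @export
grade_change <- function(grade_t0, grade_t3) {
  stopifnot(all(grade_t0 %in% 1:4), all(grade_t3 %in% 1:4),
            length(grade_t0) == length(grade_t3))
  d <- sign(as.integer(grade_t3) - as.integer(grade_t0))
  factor(c("drop", "stable", "increase")[d + 2L],
         levels = c("drop", "stable", "increase"))
}

#' Paired test of pre- vs post-treatment BPE
#'
#' One-sample t test on the per-patient differences (post minus pre),
#' optionally stratified by baseline radiologist grade.
#'
#' @param bpe_t0,bpe_t3 paired BPE vectors (same patients, same order).
#' @param strata optional stratification vector (e.g. baseline grade).
#' @return data.frame with one row per stratum (or a single `"all"` row):
#'   `stratum`, `n`, `mean_diff`, `t`, `df`, `p`.
#' @export
paired_change_test <- function(bpe_t0, bpe_t3, strata = NULL) {
  stopifnot(length(bpe_t0) == length(bpe_t3), length(bpe_t0) >= 2L)
  if (is.null(strata)) strata <- rep("all", length(bpe_t0))
  out <- lapply(unique(strata), function(s) {
    i <- strata == s
    d <- bpe_t3[i] - bpe_t0[i]
    if (length(d) < 2L)
      return(data.frame(stratum = s, n = length(d), mean_diff = mean(d),
                        t = NA_real_, df = NA_real_, p = NA_real_))
    if (sd(d) < 1e-10 * (1 + abs(mean(d)))) {
      if (all(abs(d) < 1e-12))
        return(data.frame(stratum = s, n = length(d), mean_diff = 0,
                          t = 0, df = length(d) - 1, p = 1))
      stop("zero variance of nonzero differences in stratum ", s)
    }
    tt <- t.test(d)
    data.frame(stratum = s, n = length(d), mean_diff = mean(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  do.call(rbind, out)
}
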