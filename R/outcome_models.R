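# Outcome statistics: cohort summary table, univariate screening,
# multivariate proportional-hazards OS/RFS models, stratified analyses, and
# pCR logistic odds ratios. Model fitting goes through survival::coxph
# (Efron ties) and stats::glm; this module owns the screening logic,
# effect-estimate extraction (Wald CIs on the log scale) and table shaping.

#' Derive the molecular subtype from HR/HER2 status
#'
#' @param hr_status,her2_status 0/1 vectors.
#' @return factor with levels `HR+HER2-`, `HR+HER2+`, `HR-HER2+`, `TN`
#'   (triple negative = both negative).
#' @export
molecular_subtype <- function(hr_status, her2_status) {
  stopifnot(length(hr_status) == length(her2_status),
            all(hr_status %in% 0:1), all(her2_status %in% 0:1))
  lv <- c("HR+HER2-", "HR+HER2+", "HR-HER2+", "TN")
  out <- ifelse(hr_status == 1 & her2_status == 0, lv[1],
         ifelse(hr_status == 1 & her2_status == 1, lv[2],
         ifelse(hr_status == 0 & her2_status == 1, lv[3], lv[4])))
  factor(out, levels = lv)
}

#' Validate a cohort data.frame
#'
#' Checks the invariants of the per-patient record: nonnegative follow-up
#' times, 0/1 events, grades in 1..4, and — when both a `molecular_subtype`
#' column and HR/HER2 fields are present — their mutual consistency (a
#' discrepancy is an error, never a silent overwrite).
#'
#' @param cohort data.frame of per-patient records.
#' @return `cohort`, invisibly, with `molecular_subtype` derived if absent.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1L)
  for (col in intersect(c("os_time", "rfs_time"), names(cohort)))
    if (any(cohort[[col]] < 0, na.rm = TRUE)) stop(col, " must be >= 0")
  for (col in intersect(c("os_event", "rfs_event", "pcr", "nac",
                          "node_positive", "hr_status", "her2_status"),
                        names(cohort)))
    if (!all(cohort[[col]] %in% c(0, 1, NA))) stop(col, " must be 0/1")
  if ("radiologist_grade" %in% names(cohort) &&
      !all(cohort$radiologist_grade %in% c(1:4, NA)))
    stop("radiologist_grade must be in 1..4")
  if (all(c("hr_status", "her2_status") %in% names(cohort))) {
    derived <- molecular_subtype(cohort$hr_status, cohort$her2_status)
    if ("molecular_subtype" %in% names(cohort)) {
      if (!all(as.character(cohort$molecular_subtype) == as.character(derived)))
        stop("molecular_subtype inconsistent with hr_status/her2_status")
    } else cohort$molecular_subtype <- derived
  }
  invisible(cohort)
}

.p_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Baseline cohort summary by BPE grade
#'
#' Builds a demographics table in the style of a clinical baseline table:
#' per radiologist grade, the group size, age as mean +/- SD and
#' median \[IQR\], and counts with column percentages for each categorical
#' variable; each grade is compared with grade 1 (two-sample t test for age,
#' chi-square — or Fisher where any expected cell is < 5 — for categoricals)
#' with significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param cohort data.frame with `radiologist_grade`, `age_years` and any of
#'   `race_ethnicity`, `molecular_subtype`, `menopausal_status`.
#' @param categorical names of categorical columns to summarize.
#' @return data.frame with columns `variable`, `level`, one summary column
#'   per grade (`grade_1`..), `p_vs_grade1`, `stars`, plus numeric helper
#'   columns `<grade>_n` / `<grade>_pct` for categorical rows.
#' @export
cohort_summary <- function(cohort,
                           categorical = intersect(c("race_ethnicity",
                                                     "molecular_subtype",
                                                     "menopausal_status"),
                                                   names(cohort))) {
  cohort <- validate_cohort(cohort)
  grades <- sort(unique(cohort$radiologist_grade))
  empty <- setdiff(1:4, grades)
  if (length(empty) && length(grades) < 4L)
    warning("grade(s) with n = 0 omitted: ", paste(empty, collapse = ", "))
  gcol <- function(g) paste0("grade_", g)
  split_by_g <- lapply(grades, function(g)
    cohort[cohort$radiologist_grade == g, , drop = FALSE])
  names(split_by_g) <- grades
  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df
  base_row <- function(variable, level) {
    r <- data.frame(variable = variable, level = level,
                    stringsAsFactors = FALSE)
    for (g in grades) r[[gcol(g)]] <- NA_character_
    r$p_vs_grade1 <- NA_real_; r$stars <- ""
    r
  }
  # group sizes
  r <- base_row("n", "")
  for (g in grades) r[[gcol(g)]] <- sprintf("%d", nrow(split_by_g[[as.character(g)]]))
  add(r)
  # age
  if ("age_years" %in% names(cohort)) {
    r1 <- base_row("age", "mean_sd"); r2 <- base_row("age", "median_iqr")
    for (g in grades) {
      a <- split_by_g[[as.character(g)]]$age_years
      r1[[gcol(g)]] <- sprintf("%.2f ± %.2f", mean(a), sd(a))
      q <- quantile(a, c(0.25, 0.5, 0.75), names = FALSE)
      r2[[gcol(g)]] <- sprintf("%.2f [%.2f, %.2f]", q[2], q[1], q[3])
      if (g != grades[1] && 1 %in% grades) {
        p <- t.test(a, split_by_g[["1"]]$age_years)$p.value
        r1[[gcol(g)]] <- paste0(r1[[gcol(g)]], " ", .p_stars(p))
        r2[[gcol(g)]] <- paste0(r2[[gcol(g)]], " ", .p_stars(p))
      }
    }
    add(r1); add(r2)
  }
  # categorical blocks: counts and column percentages
  for (v in categorical) {
    lv <- if (is.factor(cohort[[v]])) levels(cohort[[v]]) else
      sort(unique(as.character(cohort[[v]])))
    for (l in lv) {
      r <- base_row(v, l)
      for (g in grades) {
        sub <- split_by_g[[as.character(g)]]
        n <- sum(as.character(sub[[v]]) == l)
        pct <- 100 * n / nrow(sub)
        r[[gcol(g)]] <- sprintf("%d (%.2f%%)", n, pct)
        r[[paste0(gcol(g), "_n")]] <- n
        r[[paste0(gcol(g), "_pct")]] <- pct
        if (g != grades[1] && 1 %in% grades) {
          tab <- table(factor(as.character(sub[[v]]) == l, levels = c(FALSE, TRUE)))
          tab1 <- table(factor(as.character(split_by_g[["1"]][[v]]) == l,
                               levels = c(FALSE, TRUE)))
          m <- rbind(as.numeric(tab), as.numeric(tab1))
          p <- tryCatch({
            exp_cells <- outer(rowSums(m), colSums(m)) / sum(m)
            if (any(exp_cells < 5)) fisher.test(m)$p.value
            else chisq.test(m, correct = FALSE)$p.value
          }, error = function(e) NA_real_)
          r[[gcol(g)]] <- paste0(r[[gcol(g)]], " ", .p_stars(p))
          r[[paste0(gcol(g), "_p")]] <- p
        }
      }
      add(r)
    }
  }
  merge_rows(rows)
}

# rbind data.frames with unequal columns, filling NA
merge_rows <- function(lst) {
  cols <- unique(unlist(lapply(lst, names)))
  do.call(rbind, lapply(lst, function(d) {
    for (c in setdiff(cols, names(d))) d[[c]] <- NA
    d[cols]
  }))
}

# Wald effect estimate (exp scale) for one coefficient of a fitted model
.effect_from_fit <- function(fit, term, effect_type, n_used, model_terms) {
  sm <- summary(fit)
  co <- if (inherits(fit, "coxph")) sm$coefficients else sm$coefficients
  rn <- rownames(co)
  hit <- grep(term, rn, fixed = TRUE)
  if (!length(hit)) stop("term not found in model: ", term)
  i <- hit[1L]
  beta <- co[i, 1L]
  se <- if (inherits(fit, "coxph")) co[i, "se(coef)"] else co[i, "Std. Error"]
  pcol <- grep("^Pr\\(|^p$", colnames(co))
  p <- co[i, pcol[length(pcol)]]
  structure(list(effect_type = effect_type, term = rn[i],
                 point = exp(beta), ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se), p_value = unname(p),
                 beta = unname(beta), se = unname(se),
                 n_used = n_used, model_terms = model_terms),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate> %s[%s] = %.2f [%.2f, %.2f], p = %.3g (n = %d)\n",
              x$effect_type, x$term, x$point, x$ci_low, x$ci_high,
              x$p_value, x$n_used))
  invisible(x)
}

#' Univariate screening of candidate covariates
#'
#' Fits a one-covariate model per candidate (proportional hazards for OS/RFS,
#' logistic for pCR) and keeps those with Wald p below `alpha`. The primary
#' BPE predictor is always retained regardless of its univariate p value.
#' Candidates whose fit fails to converge are logged and excluded.
#'
#' @param cohort validated cohort data.frame.
#' @param outcome `"OS"`, `"RFS"` or `"pCR"`.
#' @param candidates character vector of covariate column names.
#' @param alpha screening level (default 0.05).
#' @param primary name of the primary predictor column (always kept); `NULL`
#'   to screen candidates only.
#' @return list with `selected` (character vector, primary first),
#'   `p_values` (named numeric) and `log` (character messages).
#' @export
univariate_screen <- function(cohort, outcome = c("OS", "RFS", "pCR"),
                              candidates, alpha = 0.05, primary = NULL) {
  outcome <- match.arg(outcome)
  cohort <- validate_cohort(cohort)
  pv <- setNames(rep(NA_real_, length(candidates)), candidates)
  log <- character()
  for (v in candidates) {
    p <- tryCatch({
      fit <- .fit_outcome(cohort, outcome, v, character())
      co <- summary(fit)$coefficients
      pcol <- grep("^Pr\\(|^p$", colnames(co))
      # overall term p: take the smallest coefficient p for multi-level factors
      min(co[grep(v, rownames(co), fixed = TRUE), pcol[length(pcol)]])
    }, error = function(e) NA_real_, warning = function(w) NA_real_)
    if (is.na(p)) log <- c(log, sprintf("candidate %s excluded (fit failed)", v))
    pv[v] <- p
  }
  selected <- names(pv)[!is.na(pv) & pv < alpha]
  if (!is.null(primary)) selected <- unique(c(primary, setdiff(selected, primary)))
  list(selected = selected, p_values = pv, log = log)
}

# shared model constructor for screening and final fits
.fit_outcome <- function(cohort, outcome, predictor, covariates) {
  rhs <- paste(c(predictor, covariates), collapse = " + ")
  if (outcome %in% c("OS", "RFS")) {
    tcol <- if (outcome == "OS") "os_time" else "rfs_time"
    ecol <- if (outcome == "OS") "os_event" else "rfs_event"
    f <- as.formula(sprintf("survival::Surv(%s, %s) ~ %s", tcol, ecol, rhs))
    survival::coxph(f, data = cohort, ties = "efron")
  } else {
    f <- as.formula(paste("pcr ~", rhs))
    glm(f, data = cohort, family = binomial())
  }
}

#' Cox proportional-hazards model for OS or RFS
#'
#' Partial-likelihood fit with Efron tie handling; the hazard ratio for the
#' primary predictor is reported with a Wald 95% CI computed on the log
#' scale.
#'
#' @param cohort validated cohort data.frame.
#' @param outcome `"OS"` or `"RFS"`.
#' @param predictor column name of the primary predictor (e.g. the
#'   dichotomized `bpe_high` grade indicator).
#' @param covariates further adjustment covariates (typically the output of
#'   [univariate_screen()]).
#' @return An `effect_estimate` (HR) with the fitted model in `$fit`.
#' @export
fit_cox <- function(cohort, outcome = c("OS", "RFS"), predictor,
                    covariates = character()) {
  outcome <- match.arg(outcome)
  cohort <- validate_cohort(cohort)
  ecol <- if (outcome == "OS") "os_event" else "rfs_event"
  if (sum(cohort[[ecol]], na.rm = TRUE) < 1L)
    stop("no events: all subjects censored for ", outcome)
  pvals <- cohort[[predictor]]
  if (length(unique(pvals[!is.na(pvals)])) < 2L)
    stop("predictor has a single level")
  fit <- .fit_outcome(cohort, outcome, predictor, setdiff(covariates, predictor))
  est <- .effect_from_fit(fit, predictor, "HR", n_used = fit$n,
                          model_terms = c(predictor, covariates))
  est$fit <- fit
  est
}

#' Logistic model for pathological complete response
#'
#' Maximum-likelihood logistic fit; the odds ratio for the predictor is
#' reported with a Wald 95% CI. Quasi-separation (divergent coefficients) is
#' signalled as a warning via the glm machinery.
#'
#' @param cohort validated cohort data.frame with a 0/1 `pcr` column.
#' @param predictor predictor column name (e.g. `grade_drop`).
#' @param covariates adjustment covariates.
#' @return An `effect_estimate` (OR) with the fitted model in `$fit`.
#' @export
fit_pcr_logistic <- function(cohort, predictor, covariates = character()) {
  cohort <- validate_cohort(cohort)
  if (!"pcr" %in% names(cohort)) stop("cohort lacks a pcr column")
  pvals <- cohort[[predictor]]
  if (length(unique(pvals[!is.na(pvals)])) < 2L)
    stop("predictor has a single level")
  fit <- .fit_outcome(cohort, "pCR", predictor, setdiff(covariates, predictor))
  if (any(abs(coef(fit)) > 15, na.rm = TRUE))
    warning("possible quasi-separation: very large logistic coefficients")
  est <- .effect_from_fit(fit, predictor, "OR",
                          n_used = sum(complete.cases(
                            cohort[, c("pcr", predictor, covariates), drop = FALSE])),
                          model_terms = c(predictor, covariates))
  est$fit <- fit
  est
}

#' Unadjusted odds ratio of a 2x2 table
#'
#' Cross-product ratio `(a d) / (b c)` for exposure rows and outcome columns.
#'
#' @param a,b,c,d cell counts: `a` exposed/outcome, `b` exposed/no-outcome,
#'   `c` unexposed/outcome, `d` unexposed/no-outcome.
#' @return scalar odds ratio.
#' @export
odds_ratio_2x2 <- function(a, b, c, d) (a * d) / (b * c)

#' Refit an outcome model within strata
#'
#' Refits the model within each stratum, dropping the stratifying covariate
#' from that stratum's adjustment set, and re-running univariate screening
#' per stratum. Strata too small to fit are marked not-estimable rather than
#' failing the whole analysis.
#'
#' @param cohort validated cohort data.frame.
#' @param strata_col column defining the strata (each level refit separately).
#' @param outcome `"OS"`, `"RFS"` or `"pCR"`.
#' @param predictor primary predictor column.
#' @param candidates covariates eligible for per-stratum screening (the
#'   stratifying column is removed automatically).
#' @param alpha screening level.
#' @return data.frame with one row per stratum: `stratum`, `n`, `estimable`,
#'   `point`, `ci_low`, `ci_high`, `p_value`, `covariates`.
#' @export
stratified_analysis <- function(cohort, strata_col, outcome, predictor,
                                candidates = character(), alpha = 0.05) {
  cohort <- validate_cohort(cohort)
  cands <- setdiff(candidates, c(strata_col, predictor))
  out <- lapply(sort(unique(cohort[[strata_col]])), function(s) {
    sub <- cohort[cohort[[strata_col]] == s, , drop = FALSE]
    res <- tryCatch({
      scr <- if (length(cands))
        univariate_screen(sub, outcome, cands, alpha, primary = NULL)$selected
      else character()
      est <- if (outcome == "pCR") fit_pcr_logistic(sub, predictor, scr)
             else fit_cox(sub, outcome, predictor, scr)
      data.frame(stratum = as.character(s), n = nrow(sub), estimable = TRUE,
                 point = est$point, ci_low = est$ci_low, ci_high = est$ci_high,
                 p_value = est$p_value,
                 covariates = paste(scr, collapse = "+"),
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(stratum = as.character(s), n = nrow(sub), estimable = FALSE,
                 point = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 p_value = NA_real_, covariates = "", stringsAsFactors = FALSE))
    res
  })
  do.call(rbind, out)
}

#' Split a cohort at the sample median age
#'
#' @param age numeric vector.
#' @return factor `"le_median"` / `"gt_median"`; group sizes differ by at
#'   most the number of ties at the median.
#' @export
median_age_split <- function(age) {
  m <- median(age)
  factor(ifelse(age > m, "gt_median", "le_median"),
         levels = c("le_median", "gt_median"))
}
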