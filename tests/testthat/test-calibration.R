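test_that("Spearman correlation handles monotone, reversed, tied and degenerate input", {
  expect_equal(spearman_rho(c(1, 2, 3), c(10, 20, 30)), 1.0)
  expect_equal(spearman_rho(c(1, 2, 3), c(30, 20, 10)), -1.0)
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  expect_equal(spearman_rho(x, y), brute_spearman(x, y))
  set.seed(8)
  for (i in 1:10) {
    a <- sample(1:6, 8, replace = TRUE); b <- sample(1:6, 8, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(spearman_rho(a, b), brute_spearman(a, b))
  }
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:3, 1:4), "equal length")
})

test_that("dichotomy AUC equals exhaustive pair counting and hits the limits", {
  # separable and all-tied limits
  expect_equal(dichotomy_auc(c(0.1, 0.2, 0.6, 0.9), c(1, 2, 3, 4), "12_v_34"), 1.0)
  expect_equal(dichotomy_auc(rep(0.5, 6), c(1, 1, 2, 3, 4, 4), "12_v_34"), 0.5)
  set.seed(19)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    score <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    grades <- sample(1:4, n, replace = TRUE)
    for (sp in c("1_v_234", "12_v_34", "123_v_4")) {
      cutg <- switch(sp, "1_v_234" = 2L, "12_v_34" = 3L, "123_v_4" = 4L)
      lab <- as.integer(grades >= cutg)
      if (all(lab == 0) || all(lab == 1)) next
      expect_equal(dichotomy_auc(score, grades, sp), brute_auc(score, lab))
    }
  }
  expect_error(dichotomy_auc(1:3, c(1, 1, 2), "12_v_34"), "nonempty")
})

test_that("AUC is invariant under strictly monotone transforms of the score", {
  set.seed(77)
  score <- runif(30); grades <- sample(1:4, 30, replace = TRUE)
  base <- dichotomy_auc(score, grades, "12_v_34")
  for (f in list(function(x) 10 * x - 3, exp, function(x) x^3 + x))
    expect_equal(dichotomy_auc(f(score), grades, "12_v_34"), base)
})

test_that("threshold optimization recovers a generative threshold and flags the null", {
  co <- generate_cohort(cohort_spec(n = 300, k_star = 55, seed = 31))
  sw <- cohort_sweep_table(co, seq(0, 200, 5))
  tc <- optimize_threshold(sw, co[, c("patient_id", "radiologist_grade")])
  expect_lte(abs(tc$optimal_k - 55), 5)
  expect_true(all(tc$curve$auc_12_v_34 >= 0 & tc$curve$auc_12_v_34 <= 1, na.rm = TRUE))
  # grades independent of BPE: correlation near zero everywhere
  co2 <- co
  co2$radiologist_grade <- with_seed(99, sample(co$radiologist_grade))
  tc2 <- optimize_threshold(cohort_sweep_table(co2, seq(20, 80, 20)),
                            co2[, c("patient_id", "radiologist_grade")])
  expect_true(all(abs(tc2$curve$rho) < 3 / sqrt(300)))
  # single-threshold grid returns that threshold
  tc3 <- optimize_threshold(sw[sw$threshold_k == 40, ],
                            co[, c("patient_id", "radiologist_grade")], grid = 40)
  expect_equal(tc3$optimal_k, 40)
  expect_error(optimize_threshold(sw, setNames(rep(2, 300), co$patient_id)),
               "distinct grades")
})

test_that("grade cutpoints separate a separable cohort exactly and recover a noisy one", {
  grades <- rep(1:4, each = 10)
  bpe <- grades / 4
  gm <- fit_grade_model(bpe, grades, threshold_k = 55)
  expect_true(all(diff(gm$cutpoints_4level) > 0))
  expect_true(all(gm$cutpoints_4level > c(0.25, 0.5, 0.75) &
                  gm$cutpoints_4level < c(0.5, 0.75, 1)))
  expect_equal(assign_grade(gm, bpe), grades)
  expect_equal(as.character(assign_grade(gm, c(0.2, 0.9), "2")), c("low", "high"))
  # noisy 2-level recovery around a known generative cutpoint
  set.seed(5)
  b <- runif(400)
  g <- ifelse(b + rnorm(400, 0, 0.04) >= 0.6, 3L, 2L)
  if (length(unique(g)) == 2L) {
    gm2 <- fit_grade_model(b, g, levels = "2")
    expect_lt(abs(gm2$cutpoints_2level - 0.6), 0.08)
  }
  expect_error(fit_grade_model(rep(0.5, 5), rep(2L, 5)), "distinct grades")
  expect_error(fit_grade_model(runif(10), rep(c(1L, 3L), 5), levels = "4"),
               "all four grades")
})

test_that("grade assignment is closed on the right and monotone", {
  gm <- structure(list(cutpoints_2level = 0.3,
                       cutpoints_4level = c(0.1, 0.3, 0.6),
                       threshold_k = 55, criterion = "youden"),
                  class = "grade_model")
  expect_equal(assign_grade(gm, c(0.05, 0.1, 0.3, 0.59, 0.6, 0.9)),
               c(1L, 2L, 3L, 3L, 4L, 4L))
  b <- sort(runif(50))
  expect_true(all(diff(assign_grade(gm, b)) >= 0))
})

test_that("grade change maps the sign of the difference", {
  expect_equal(as.character(grade_change(3, 1)), "drop")
  expect_equal(as.character(grade_change(2, 2)), "stable")
  expect_equal(as.character(grade_change(1, 3)), "increase")
  expect_equal(as.character(grade_change(c(4, 2, 1), c(2, 2, 4))),
               c("drop", "stable", "increase"))
  expect_error(grade_change(0, 2))
})

test_that("paired change test matches the closed-form t statistic", {
  t0 <- c(0.2, 0.3, 0.4)
  expect_equal(paired_change_test(t0, t0)$t, 0)
  expect_equal(paired_change_test(t0, t0)$mean_diff, 0)
  d <- c(0.1, 0.2, 0.3)
  res <- paired_change_test(rep(0, 3), d)
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(3)))
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * stats::pt(-abs(res$t), 2))
  # stratified output, one row per stratum
  res2 <- paired_change_test(c(t0, t0), c(t0, t0 - c(0.05, 0.1, 0.15)),
                             strata = rep(1:2, each = 3))
  expect_equal(nrow(res2), 2)
  expect_equal(res2$mean_diff, c(0, -0.1))
  # constant nonzero differences have no t distribution: signalled
  expect_error(paired_change_test(t0, t0 - 0.1), "zero variance")
})

test_that("paired test power tracks the noncentral-t prediction", {
  n <- 50; delta <- 0.03; s <- 0.08
  ncp <- delta / (s / sqrt(n))
  crit <- stats::qt(0.975, n - 1)
  predicted <- stats::pt(-crit, n - 1, ncp) + 1 - stats::pt(crit, n - 1, ncp)
  rej <- with_seed(123, mean(replicate(300, {
    d0 <- runif(n, 0.1, 0.5)
    paired_change_test(d0, d0 - rnorm(n, delta, s))$p < 0.05
  })))
  expect_lt(abs(rej - predicted), 3 * sqrt(predicted * (1 - predicted) / 300) + 0.01)
})

test_that("paired test keeps its nominal size under the null, stratified", {
  n <- 20
  rej <- with_seed(321, unlist(replicate(1000, {
    d0 <- runif(n, 0.1, 0.5)
    strat <- rep(1:2, each = n / 2)
    paired_change_test(d0, d0 + rnorm(n, 0, 0.05), strata = strat)$p < 0.05
  }, simplify = FALSE)))
  # per-stratum rejection rate over 2000 null tests
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / length(rej)))
})
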