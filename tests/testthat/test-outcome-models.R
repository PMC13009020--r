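test_that("molecular subtype derivation and cohort validation", {
  st <- molecular_subtype(c(1, 1, 0, 0), c(0, 1, 1, 0))
  expect_equal(as.character(st), c("HR+HER2-", "HR+HER2+", "HR-HER2+", "TN"))
  co <- data.frame(patient_id = "a", hr_status = 1, her2_status = 0,
                   molecular_subtype = "TN", radiologist_grade = 2)
  expect_error(validate_cohort(co), "inconsistent")
  co$molecular_subtype <- "HR+HER2-"
  expect_silent(validate_cohort(co))
  expect_error(validate_cohort(data.frame(os_time = -1)), "os_time")
  expect_error(validate_cohort(data.frame(os_event = 2)), "0/1")
})

test_that("cohort summary reproduces printed counts and percentages", {
  meno <- matrix(c(157, 149, 120, 72,
                   304, 138, 76, 23,
                   10, 12, 9, 4), nrow = 3, byrow = TRUE,
                 dimnames = list(c("pre", "post", "unknown"), NULL))
  co <- cohort_from_counts("menopausal_status", meno, c(471, 299, 205, 99))
  expect_equal(nrow(co), 1074)
  s <- cohort_summary(co, categorical = "menopausal_status")
  pre4 <- s[s$variable == "menopausal_status" & s$level == "pre", ]
  expect_equal(pre4$grade_4_n, 72)
  expect_equal(pre4$grade_4_pct, 72.73, tolerance = 1e-3)
  expect_equal(pre4$grade_1_pct, 33.33, tolerance = 1e-3)
  # percentages of each grade column sum to 100
  blk <- s[s$variable == "menopausal_status", ]
  for (g in 1:4)
    expect_equal(sum(blk[[sprintf("grade_%d_pct", g)]]), 100, tolerance = 1e-6)
  # premenopausal fraction differs strongly from grade 1 in grades 2-4
  expect_true(all(grepl("\\*\\*\\*$", pre4[paste0("grade_", 2:4)])))
})

test_that("cohort summary includes age statistics and omits empty grades", {
  set.seed(12)
  co <- data.frame(patient_id = as.character(1:60),
                   radiologist_grade = rep(c(1, 3), each = 30),
                   age_years = c(rnorm(30, 55, 5), rnorm(30, 45, 5)))
  expect_warning(s <- cohort_summary(co), "omitted")
  age_row <- s[s$variable == "age" & s$level == "mean_sd", ]
  m1 <- mean(co$age_years[co$radiologist_grade == 1])
  expect_match(age_row$grade_1, sprintf("%.2f", m1), fixed = TRUE)
  expect_match(age_row$grade_3, "\\*")   # clearly separated means
  # single-grade cohort: comparisons suppressed, table still built
  expect_warning(s1 <- cohort_summary(co[co$radiologist_grade == 1, ]), "omitted")
  expect_false(any(grepl("\\*", s1$grade_1)))
})

test_that("unadjusted odds ratio is the cross-product ratio", {
  expect_identical(odds_ratio_2x2(10, 5, 4, 20), 10.0)
  set.seed(2)
  for (i in 1:20) {
    t <- sample(1:30, 4)
    expect_equal(odds_ratio_2x2(t[1], t[2], t[3], t[4]),
                 (t[1] * t[4]) / (t[2] * t[3]), tolerance = 1e-12)
  }
})

test_that("Cox fit agrees with an independently maximized Efron partial likelihood", {
  set.seed(42)
  n <- 40
  x1 <- rbinom(n, 1, 0.5); x2 <- rnorm(n)
  tt <- round(rexp(n, 0.1 * exp(-0.6 * x1 + 0.3 * x2)), 1)  # rounding makes ties
  ev <- rbinom(n, 1, 0.8)
  co <- data.frame(patient_id = as.character(1:n), bpe_high = x1, z = x2,
                   os_time = tt, os_event = ev)
  est <- fit_cox(co, "OS", "bpe_high", covariates = "z")
  ora <- optim(c(0, 0), efron_nll, time = tt, event = ev, x = cbind(x1, x2),
               method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(unname(coef(est$fit)), ora$par, tolerance = 1e-6)
  # CI transformation consistency: exp of the coefficient CI, exactly
  expect_identical(est$ci_low, exp(est$beta - 1.96 * est$se))
  expect_identical(est$ci_high, exp(est$beta + 1.96 * est$se))
  expect_identical(est$point, exp(est$beta))
  expect_error(fit_cox(transform(co, os_event = 0), "OS", "bpe_high"), "no events")
  expect_error(fit_cox(transform(co, bpe_high = 1), "OS", "bpe_high"),
               "single level")
})

test_that("logistic fit agrees with an independently maximized Bernoulli likelihood", {
  set.seed(9)
  n <- 50
  x <- rbinom(n, 1, 0.4); z <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 1.2 * x + 0.4 * z))
  co <- data.frame(patient_id = as.character(1:n), grade_drop = x, z = z, pcr = y)
  est <- fit_pcr_logistic(co, "grade_drop", covariates = "z")
  ora <- optim(c(0, 0, 0), logistic_nll, y = y, x = cbind(x, z),
               method = "BFGS", control = list(reltol = 1e-15))
  expect_equal(unname(coef(est$fit)), ora$par, tolerance = 1e-6)
  # unadjusted fit on a 2x2 layout equals the cross-product OR
  a <- 10L; b <- 5L; c_ <- 4L; d <- 20L
  co2 <- data.frame(
    patient_id = as.character(1:(a + b + c_ + d)),
    grade_drop = rep(c(1L, 1L, 0L, 0L), c(a, b, c_, d)),
    pcr = rep(c(1L, 0L, 1L, 0L), c(a, b, c_, d)))
  est2 <- fit_pcr_logistic(co2, "grade_drop")
  expect_equal(est2$point, odds_ratio_2x2(a, b, c_, d), tolerance = 1e-7)
})

test_that("univariate screening keeps significant candidates plus the primary predictor", {
  co <- generate_cohort(cohort_spec(n = 600, seed = 77))
  scr <- univariate_screen(co, "OS", c("age_years", "node_positive"),
                           primary = "bpe_high")
  expect_equal(scr$selected[1], "bpe_high")
  expect_true(all(scr$p_values[setdiff(scr$selected, "bpe_high")] < 0.05,
                  na.rm = TRUE))
  # empty candidate list: only the primary predictor
  scr2 <- univariate_screen(co, "OS", character(), primary = "bpe_high")
  expect_equal(scr2$selected, "bpe_high")
  # a strongly prognostic covariate is detected
  co$strong <- with_seed(5, rbinom(nrow(co), 1, 0.5))
  co$os_time <- co$os_time * exp(-1.0 * co$strong)
  scr3 <- univariate_screen(co, "OS", "strong")
  expect_equal(scr3$selected, "strong")
})

test_that("stratified analysis refits per stratum and tolerates small strata", {
  co <- generate_cohort(cohort_spec(n = 800, seed = 13))
  co$stratum2 <- rep(c("a", "b"), length.out = nrow(co))
  res <- stratified_analysis(co, "stratum2", "OS", "bpe_high")
  expect_equal(nrow(res), 2)
  expect_true(all(res$estimable))
  # two identical strata give identical estimates
  co2 <- rbind(co, co)
  co2$stratum3 <- rep(c("x", "y"), each = nrow(co))
  res2 <- stratified_analysis(co2, "stratum3", "OS", "bpe_high")
  expect_equal(res2$point[1], res2$point[2])
  # a degenerate stratum (single predictor level) is flagged, not fatal
  co$tiny <- "rest"
  co$tiny[which(co$bpe_high == 0)[1:2]] <- "t"
  res3 <- stratified_analysis(co, "tiny", "OS", "bpe_high")
  expect_false(res3$estimable[res3$stratum == "t"])
  # median age split is near-balanced
  sp <- median_age_split(co$age_years)
  expect_lte(abs(diff(table(sp))), 1)
})
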