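test_that("summary-statistic t tests reproduce known demographic contrasts", {
  # eye-level group sizes (each subject contributes both eyes)
  g1 <- t_test_from_summary(22.896, 1.525, 96, 22.778, 1.278, 108)
  expect_equal(g1$statistic, 0.601, tolerance = 1e-3)
  expect_identical(g1$df, 202)
  g2 <- t_test_from_summary(30.488, 2.848, 86, 30.904, 2.851, 104)
  expect_equal(g2$statistic, -1.000, tolerance = 2e-3)
  g3 <- t_test_from_summary(40.083, 3.560, 48, 41.121, 2.847, 66,
                            variant = "welch")
  expect_equal(g3$statistic, -1.669, tolerance = 1e-3)
  expect_lt(g3$df, 48 + 66 - 2)                    # Welch df below pooled df
  g4 <- t_test_from_summary(51.238, 4.808, 42, 52.167, 5.063, 60)
  expect_equal(g4$statistic, -0.931, tolerance = 1e-3)
})

test_that("t-test edge cases and variant agreement", {
  expect_identical(t_test_from_summary(5, 1, 10, 5, 2, 12)$statistic, 0)
  z <- t_test_from_summary(5, 0, 10, 5, 0, 12)
  expect_identical(z$statistic, 0)
  z2 <- t_test_from_summary(6, 0, 10, 5, 0, 12)
  expect_true(is.infinite(z2$statistic) && z2$degenerate)
  # pooled and Welch coincide with equal SDs and equal n
  p <- t_test_from_summary(3, 1.2, 30, 2.5, 1.2, 30)
  w <- t_test_from_summary(3, 1.2, 30, 2.5, 1.2, 30, variant = "welch")
  expect_equal(p$statistic, w$statistic, tolerance = 1e-12)
  expect_equal(p$df, w$df, tolerance = 1e-9)
  expect_error(t_test_from_summary(1, 1, 1, 2, 1, 5),
               class = "macvasc_validation_error")
})

test_that("chi-square sex-ratio test matches the direct formula", {
  eq <- chi_square_sex_ratio(matrix(c(10, 10, 20, 20, 7, 7), 2))
  expect_equal(eq$statistic, 0, tolerance = 1e-12)
  counts <- matrix(c(48, 54, 43, 52, 24, 33, 21, 30), 2)
  ct <- chi_square_sex_ratio(counts)
  expect_equal(ct$df, 3)
  expect_gt(ct$p, 0.05)
  # brute-force expected-count oracle on a 2x2 table
  tb <- matrix(c(12, 30, 25, 17), 2)
  exp_tb <- outer(rowSums(tb), colSums(tb)) / sum(tb)
  expect_equal(chi_square_sex_ratio(tb)$statistic,
               sum((tb - exp_tb)^2 / exp_tb), tolerance = 1e-10)
  expect_error(chi_square_sex_ratio(matrix(c(0, 0, 1, 2), 2)),
               class = "macvasc_validation_error")
})

test_that("Shapiro-Wilk wrapper behaves on normal and skewed samples", {
  set.seed(19)
  ps_norm <- vapply(1:10, function(i) shapiro_wilk(rnorm(500))$p, numeric(1))
  ws <- vapply(1:10, function(i) shapiro_wilk(rnorm(500))$statistic, numeric(1))
  expect_true(all(ws > 0.97 & ws <= 1))
  expect_gt(mean(ps_norm > 0.05), 0.7)             # null p-values mostly large
  ps_exp <- vapply(1:10, function(i) shapiro_wilk(rexp(500))$p, numeric(1))
  expect_true(all(ps_exp < 0.05))
  expect_error(shapiro_wilk(rep(2, 10)), class = "macvasc_validation_error")
  expect_error(shapiro_wilk(c(1, 2)), class = "macvasc_validation_error")
})

test_that("age grouping floors fractional ages at the study boundaries", {
  expect_identical(as.character(age_group(c(18, 25.9, 26, 35.5, 36, 45.9, 46, 70))),
                   c("G1", "G1", "G2", "G2", "G3", "G3", "G4", "G4"))
})

test_that("sex-difference analysis recovers effects and validates input", {
  eff <- cohort_effect_defaults()
  eff$b_age <- 0                                   # isolate the sex effect
  tab <- generate_cohort(cohort_params(n_subjects = 50, effects = eff,
                                       noise_scale = 0), seed = 2)
  rep <- sex_difference_analysis(tab, regions = "whole")
  expect_equal(rep$beta[rep$metric == "Df"], 0.010, tolerance = 1e-8)
  expect_equal(rep$beta[rep$metric == "tau"], 0, tolerance = 1e-8)
  # beta equals the raw mean difference (up to the fit's 1e-8 tolerance)
  expect_equal(rep$beta, rep$mean_male - rep$mean_female, tolerance = 1e-8)
  tab$sex <- "F"
  expect_error(sex_difference_analysis(tab), class = "macvasc_validation_error")
})

test_that("age-association analysis recovers the generating slopes exactly", {
  eff <- cohort_effect_defaults()
  eff$b_sex <- 0                                   # isolate the age effect
  tab <- generate_cohort(cohort_params(n_subjects = 50, effects = eff,
                                       noise_scale = 0), seed = 3)
  rep <- age_association_analysis(tab, regions = c("whole", "inner_ring"))
  eff <- cohort_effect_defaults()
  for (i in seq_len(nrow(rep))) {
    truth <- eff$b_age[eff$metric == rep$metric[i] & eff$region == rep$region[i]]
    expect_equal(rep$beta[i], truth, tolerance = 1e-8)
  }
  tab$age_years <- 30
  expect_error(age_association_analysis(tab), class = "macvasc_validation_error")
})

test_that("age-group contrasts detect a step decrease and adjust for sex", {
  set.seed(91)
  n_per <- 60
  ages <- c(runif(n_per, 18, 25), runif(n_per, 26, 35),
            runif(n_per, 36, 45), runif(n_per, 46, 70))
  sex <- sample(c("M", "F"), 4 * n_per, replace = TRUE)
  subj <- sprintf("P%03d", seq_len(4 * n_per))
  mu <- ifelse(ages >= 36, 0.9, 1.0)               # step decrease from G3 on
  tab <- data.frame(subject_id = rep(subj, each = 2),
                    eye = rep(c("OD", "OS"), 4 * n_per),
                    sex = rep(sex, each = 2), age_years = rep(ages, each = 2))
  tab$Df_whole <- rep(mu, each = 2) + rnorm(8 * n_per, 0, 0.03)
  res <- age_group_comparison(tab, metrics = "Df", regions = "whole")
  p <- setNames(res$p, res$contrast)
  expect_gt(p[["G1-G2"]], 0.05)
  expect_true(all(p[c("G1-G3", "G1-G4", "G2-G3", "G2-G4")] < 0.05))
  expect_gt(p[["G3-G4"]], 0.05)
  # Bonferroni never reports smaller p than the unadjusted analysis
  res_b <- age_group_comparison(tab, metrics = "Df", regions = "whole",
                                adjust = "bonferroni")
  expect_true(all(res_b$p >= res$p))

  # sex-confounded groups: adjusted contrast differs from the raw difference
  tab2 <- tab
  sex_subj <- ifelse(runif(length(ages)) < ifelse(ages <= 25, 0.85, 0.25),
                     "M", "F")
  tab2$sex <- rep(sex_subj, each = 2)
  tab2$Df_whole <- tab2$Df_whole + 0.05 * (tab2$sex == "M")
  res2 <- age_group_comparison(tab2, metrics = "Df", regions = "whole")
  raw12 <- mean(tab2$Df_whole[age_group(tab2$age_years) == "G1"]) -
    mean(tab2$Df_whole[age_group(tab2$age_years) == "G2"])
  adj12 <- res2$estimate[res2$contrast == "G1-G2"]
  expect_gt(abs(raw12 - adj12), 0.01)
})

test_that("baseline table matches the noise-free linear predictor per stratum", {
  tab <- generate_cohort(cohort_params(n_subjects = 80, noise_scale = 0),
                         seed = 6)
  bt <- baseline_table(tab, metrics = "Df", regions = "whole")
  eff <- cohort_effect_defaults()
  e <- eff[eff$metric == "Df" & eff$region == "whole", ]
  tab$age_group <- age_group(tab$age_years)
  for (i in seq_len(nrow(bt))) {
    stratum <- tab[tab$sex == bt$sex[i] & tab$age_group == bt$age_group[i], ]
    pred <- e$base + e$b_sex * (bt$sex[i] == "M") + e$b_age * mean(stratum$age_years)
    expect_equal(bt$mean[i], pred, tolerance = 1e-10)
  }
  # strata counts add up to the table rows
  bt_all <- baseline_table(tab)
  expect_identical(sum(bt_all$n[bt_all$metric == "Df" & bt_all$region == "whole"]),
                   nrow(tab))
  # single-eye stratum: SD flagged undefined
  one <- tab[1, ]
  one$age_years <- 20
  bt1 <- baseline_table(rbind(one, tab[tab$age_years > 26, ]),
                        metrics = "Df", regions = "whole")
  g1row <- bt1[bt1$age_group == "G1" & bt1$sex == one$sex, ]
  expect_false(g1row$sd_defined)
})
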