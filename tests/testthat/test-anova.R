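test_that("split-plot ANOVA matches a brute-force strata oracle and aov", {
  set.seed(51)
  for (rep in 1:5) {
    tab <- synthetic_rms_table(n_per_cell = 3, cond_effect = runif(1, 0, 1),
                               age_effect = runif(1, 0, 1),
                               sex_effect = runif(1, -1, 1), seed = 50 + rep)
    res <- split_plot_anova(tab, "mastoid")
    wide <- tidyr::pivot_wider(tab[, c("subject_id", "age_group", "sex",
                                       "condition", "mean_rms")],
                               names_from = "condition",
                               values_from = "mean_rms")
    bf <- brute_force_split_plot(wide)
    expect_equal(res$F, unname(bf$F[res$effect]), tolerance = 1e-8)
    expect_true(all(res$df_den == bf$df_den))

    # independent route: univariate mixed ANOVA via aov + Error(subject)
    long <- tab
    long$subject_id <- factor(long$subject_id)
    fit <- stats::aov(mean_rms ~ age_group * sex * condition +
                        Error(subject_id), data = long)
    sm <- summary(fit)
    between <- sm[["Error: subject_id"]][[1]]
    within <- sm[["Error: Within"]][[1]]
    rownames(between) <- trimws(rownames(between))
    rownames(within) <- trimws(rownames(within))
    expect_equal(res$F[res$effect == "age"],
                 between["age_group", "F value"], tolerance = 1e-8)
    expect_equal(res$F[res$effect == "age:sex"],
                 between["age_group:sex", "F value"], tolerance = 1e-8)
    expect_equal(res$F[res$effect == "condition"],
                 within["condition", "F value"], tolerance = 1e-8)
    expect_equal(res$F[res$effect == "age:sex:condition"],
                 within["age_group:sex:condition", "F value"],
                 tolerance = 1e-8)
    expect_equal(res$p[res$effect == "condition"],
                 within["condition", "Pr(>F)"], tolerance = 1e-8)
  }
})

test_that("a balanced 40-subject table gives df_den 36 for every effect", {
  tab <- synthetic_rms_table(n_per_cell = 10, cond_effect = 0.3, seed = 60)
  res <- split_plot_anova(tab, "mastoid")
  expect_true(all(res$df_den == 36L))
  expect_true(all(res$df_num == 1L))
  expect_equal(attr(res, "n_subjects"), 40L)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_equal(res$stratum,
               c(rep("between", 3), rep("within", 4)))
})

test_that("an exactly balanced zero condition contrast gives F = 0", {
  tab <- synthetic_rms_table(n_per_cell = 4, cond_effect = 0, seed = 61)
  wide <- tidyr::pivot_wider(tab[, c("subject_id", "age_group", "sex",
                                     "condition", "mean_rms")],
                             names_from = "condition",
                             values_from = "mean_rms")
  # force per-cell condition differences that cancel exactly
  wide <- wide[order(wide$age_group, wide$sex), ]
  dif <- rep(c(0.2, -0.2), length.out = nrow(wide))
  wide$unpredictable <- wide$predictable + dif
  long <- tidyr::pivot_longer(wide, c("unpredictable", "predictable"),
                              names_to = "condition",
                              values_to = "mean_rms")
  long$n_epochs <- 6L
  long$channel <- "mastoid"
  long$mean_peak <- 0
  res <- split_plot_anova(long, "mastoid")
  expect_equal(res$F[res$effect == "condition"], 0, tolerance = 1e-20)
})

test_that("designs with empty or tiny cells are rejected", {
  tab <- synthetic_rms_table(n_per_cell = 3, seed = 62)
  tab <- tab[!(tab$age_group == "elder" & tab$sex == "male"), ]
  expect_error(split_plot_anova(tab, "mastoid"), "invalid design")
  expect_error(split_plot_anova(synthetic_rms_table(seed = 1), "Cz"),
               "no rows")
})

test_that("Tukey HSD reduces to the two-sided t test for two groups", {
  means <- c(a = 1.3, b = 0.4)
  mse <- 0.8
  df <- 18
  n <- 10
  out <- tukey_hsd(means, mse, df, n)
  tstat <- (means["a"] - means["b"]) / sqrt(2 * mse / n)
  p_t <- 2 * stats::pt(-abs(tstat), df)
  expect_equal(out$p_adj, unname(p_t), tolerance = 1e-10)
  expect_equal(out$q, unname(abs(tstat) * sqrt(2)), tolerance = 1e-12)
})

test_that("identical cell means give q = 0 and adjusted p = 1", {
  out <- tukey_hsd(c(a = 2, b = 2, c = 2), mse = 1, df = 12, n = 5)
  expect_true(all(out$q == 0))
  expect_true(all(out$p_adj == 1))
  expect_false(any(out$significant))
  expect_error(tukey_hsd(c(a = 1, b = 2), 0, 10, 5), "degenerate")
})

test_that("Cohen's d follows the documented definitions and signs", {
  tab <- synthetic_rms_table(n_per_cell = 6, cond_effect = 0, seed = 63)
  wide <- tidyr::pivot_wider(tab[, c("subject_id", "age_group", "sex",
                                     "condition", "mean_rms")],
                             names_from = "condition",
                             values_from = "mean_rms")
  wide$unpredictable <- wide$predictable       # identical columns
  long <- tidyr::pivot_longer(wide, c("unpredictable", "predictable"),
                              names_to = "condition", values_to = "mean_rms")
  long$channel <- "mastoid"; long$mean_peak <- 0; long$n_epochs <- 6L
  expect_equal(cohens_d(long, "condition", "mastoid")$cohens_d, 0)

  # means 1 vs 0, common SD 1 -> d = 1 (between, age contrast elder - young)
  set.seed(64)
  z <- rnorm(40)
  z <- (z - mean(z)) / sd(z)                   # exact mean 0, SD 1
  tab2 <- synthetic_rms_table(n_per_cell = 10, seed = 65)
  wide2 <- tidyr::pivot_wider(tab2[, c("subject_id", "age_group", "sex",
                                       "condition", "mean_rms")],
                              names_from = "condition",
                              values_from = "mean_rms")
  avg <- z + ifelse(wide2$age_group == "elder", 1, 0)
  wide2$unpredictable <- avg
  wide2$predictable <- avg                     # condition-mean = avg
  z_e <- avg[wide2$age_group == "elder"]
  z_y <- avg[wide2$age_group == "young"]
  long2 <- tidyr::pivot_longer(wide2, c("unpredictable", "predictable"),
                               names_to = "condition",
                               values_to = "mean_rms")
  long2$channel <- "mastoid"; long2$mean_peak <- 0; long2$n_epochs <- 6L
  d <- cohens_d(long2, "age", "mastoid")
  sp <- sqrt(((length(z_e) - 1) * var(z_e) + (length(z_y) - 1) * var(z_y)) /
               (length(z_e) + length(z_y) - 2))
  expect_equal(d$cohens_d, (mean(z_e) - mean(z_y)) / sp)
  expect_gt(d$cohens_d, 0)                     # elder - young convention
  expect_equal(d$definition, "between-pooled")
})

test_that("the ANOVA's type-I error for the condition effect is ~5%", {
  set.seed(66)
  n_rep <- 500
  rej <- 0L
  for (r in seq_len(n_rep)) {
    tab <- synthetic_rms_table(n_per_cell = 5, cond_effect = 0,
                               seed = 1000 + r)
    res <- split_plot_anova(tab, "mastoid")
    if (res$p[res$effect == "condition"] < 0.05) rej <- rej + 1L
  }
  rate <- rej / n_rep
  band <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_gt(rate, 0.05 - band)
  expect_lt(rate, 0.05 + band)
})
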