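#' Split-plot (repeated-measures mixed) three-way ANOVA
#'
#' Tests age group, sex and perturbation type (condition) on the per-subject
#' mean RMS of one channel, with age and sex between subjects and condition
#' within subjects. With a two-level within factor the split-plot model
#' reduces exactly to two between-subject analyses: the between stratum is a
#' two-way ANOVA on the per-subject condition means (error: subjects within
#' groups), and the within stratum is a two-way ANOVA, intercept included,
#' on the per-subject condition differences (unpredictable - predictable;
#' error: condition x subject). Both use sum-to-zero coding, so each 1-df F
#' is the partial (Type III) test and unbalanced group sizes are handled.
#' Each effect is tested on (1, N - 4) degrees of freedom, N the number of
#' subjects with both condition cells at that channel; subjects missing a
#' condition cell are dropped listwise.
#'
#' @param table An RMS summary table from [summarize_rms()].
#' @param channel Channel to analyze (e.g. `"Cz"`, `"Fz"`, `"mastoid"`).
#' @param response Response column, `"mean_rms"` (default) or `"mean_peak"`.
#' @return A tibble of class `pep_anova` with one row per effect: `effect`,
#'   `stratum` (`between`/`within`), `F`, `df_num`, `df_den`, `p`, plus
#'   attributes `n_subjects`, `channel`, and the stratum error mean squares
#'   (`ms_error_between`, `ms_error_within`).
#' @export
split_plot_anova <- function(table, channel, response = "mean_rms") {
  wide <- anova_wide(table, channel, response)
  n <- nrow(wide)
  counts <- table(wide$age_group, wide$sex)
  if (any(counts < 2)) {
    stop("invalid design: need at least 2 subjects per age x sex cell ",
         "with both conditions at channel ", channel)
  }
  opts <- list(contrasts = c("contr.sum", "contr.poly"))
  old <- options(opts)
  on.exit(options(old))
  wide$age_group <- factor(wide$age_group, c("elder", "young"))
  wide$sex <- factor(wide$sex, c("male", "female"))
  wide$avg <- (wide$unpredictable + wide$predictable) / 2
  wide$dif <- wide$unpredictable - wide$predictable

  fit_b <- stats::lm(avg ~ age_group * sex, data = wide)
  fit_w <- stats::lm(dif ~ age_group * sex, data = wide)
  t_b <- summary(fit_b)$coefficients
  t_w <- summary(fit_w)$coefficients
  df_den <- n - 4L

  eff <- function(label, stratum, tval) {
    tibble::tibble(effect = label, stratum = stratum, F = tval^2,
                   df_num = 1L, df_den = df_den,
                   p = stats::pf(tval^2, 1, df_den, lower.tail = FALSE))
  }
  out <- dplyr::bind_rows(
    eff("age", "between", t_b["age_group1", "t value"]),
    eff("sex", "between", t_b["sex1", "t value"]),
    eff("age:sex", "between", t_b["age_group1:sex1", "t value"]),
    eff("condition", "within", t_w["(Intercept)", "t value"]),
    eff("age:condition", "within", t_w["age_group1", "t value"]),
    eff("sex:condition", "within", t_w["sex1", "t value"]),
    eff("age:sex:condition", "within", t_w["age_group1:sex1", "t value"]))
  # note: subject-mean stratum; multiply by 2 for the subject-total scale
  attr(out, "ms_error_between") <- sum(stats::residuals(fit_b)^2) / df_den
  attr(out, "ms_error_within") <- sum(stats::residuals(fit_w)^2) / df_den
  attr(out, "n_subjects") <- n
  attr(out, "channel") <- channel
  class(out) <- c("pep_anova", class(out))
  out
}

# wide subject x condition layout for one channel, listwise-complete
anova_wide <- function(table, channel, response = "mean_rms") {
  sub <- table[table$channel == channel, ]
  if (!nrow(sub)) stop("no rows for channel ", channel)
  wide <- tidyr::pivot_wider(
    sub[, c("subject_id", "age_group", "sex", "condition", response)],
    names_from = "condition", values_from = dplyr::all_of(response))
  for (cond in c("unpredictable", "predictable")) {
    if (is.null(wide[[cond]])) wide[[cond]] <- NA_real_
  }
  wide[stats::complete.cases(wide[, c("unpredictable", "predictable")]), ]
}

#' Tukey HSD pairwise comparisons
#'
#' All-pairs comparisons of cell means against an ANOVA error stratum using
#' the studentized-range distribution: for means `i`, `j`,
#' `q = |m_i - m_j| / sqrt(MSE / n_h)` with `n_h` the harmonic mean of the
#' two cell sizes (Tukey-Kramer), and the adjusted p-value is the upper tail
#' of the studentized range with `k` means and `df` error degrees of
#' freedom.
#'
#' @param means Named numeric vector of cell means.
#' @param mse Error mean square from the ANOVA stratum the cells live in.
#' @param df Error degrees of freedom.
#' @param n Cell sizes: scalar or named vector matching `means`.
#' @param alpha Significance level.
#' @return A tibble: `pair`, `diff`, `q`, `p_adj`, `significant`.
#' @export
tukey_hsd <- function(means, mse, df, n, alpha = 0.05) {
  k <- length(means)
  stopifnot(k >= 2, df >= 1)
  if (mse <= 0) stop("degenerate data: zero error mean square")
  if (length(n) == 1) n <- stats::setNames(rep(n, k), names(means))
  pairs <- utils::combn(names(means), 2)
  res <- apply(pairs, 2, function(pr) {
    nh <- 2 / (1 / n[pr[1]] + 1 / n[pr[2]])
    d <- means[pr[1]] - means[pr[2]]
    q <- abs(d) / sqrt(mse / nh)
    p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    tibble::tibble(pair = paste(pr[1], "-", pr[2]), diff = unname(d),
                   q = unname(q), p_adj = unname(p),
                   significant = unname(p < alpha))
  })
  dplyr::bind_rows(res)
}

#' Age x sex follow-up at one channel
#'
#' Tukey HSD over the four age x sex cells of subject-level RMS (averaged
#' over conditions), using the between-subject error stratum of the
#' split-plot ANOVA -- the follow-up used to ask which cells drive an age or
#' sex main effect.
#'
#' @inheritParams split_plot_anova
#' @param alpha Significance level.
#' @return A [tukey_hsd()] tibble over cells named `age.sex`.
#' @export
posthoc_age_sex <- function(table, channel, response = "mean_rms",
                            alpha = 0.05) {
  wide <- anova_wide(table, channel, response)
  wide$avg <- (wide$unpredictable + wide$predictable) / 2
  cell <- interaction(wide$age_group, wide$sex, drop = TRUE)
  means <- tapply(wide$avg, cell, mean)
  ns <- tapply(wide$avg, cell, length)
  aov_tab <- split_plot_anova(table, channel, response)
  tukey_hsd(means, attr(aov_tab, "ms_error_between"),
            attr(aov_tab, "n_subjects") - 4L, ns, alpha = alpha)
}

#' Cohen's d effect sizes
#'
#' Standardized mean differences for the three main effects, on the scale of
#' the RMS summary table. The condition effect uses the classical
#' between-condition pooled SD (not the difference-score dz): mean
#' (unpredictable - predictable) divided by the pooled SD of the two
#' condition columns. Age and sex effects pool the SD of subject-level RMS
#' (averaged over conditions) across the two groups. Sign conventions:
#' unpredictable - predictable, elder - young, male - female.
#'
#' @inheritParams split_plot_anova
#' @param effect `"condition"`, `"age"` or `"sex"`.
#' @return A tibble: `effect`, `channel`, `cohens_d`, `definition`.
#' @export
cohens_d <- function(table, effect = c("condition", "age", "sex"), channel,
                     response = "mean_rms") {
  effect <- match.arg(effect)
  wide <- anova_wide(table, channel, response)
  if (effect == "condition") {
    x <- wide$unpredictable
    y <- wide$predictable
    if (length(x) < 2) stop("need >= 2 subjects")
    sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
                 (length(x) + length(y) - 2))
    if (sp <= 0) stop("degenerate data: zero pooled SD")
    d <- mean(x - y) / sp
    def <- "within-subject"
  } else {
    wide$avg <- (wide$unpredictable + wide$predictable) / 2
    g <- if (effect == "age") wide$age_group else wide$sex
    lv <- if (effect == "age") c("elder", "young") else c("male", "female")
    x <- wide$avg[g == lv[1]]
    y <- wide$avg[g == lv[2]]
    if (length(x) < 2 || length(y) < 2) stop("need >= 2 subjects per group")
    sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
                 (length(x) + length(y) - 2))
    if (sp <= 0) stop("degenerate data: zero pooled SD")
    d <- (mean(x) - mean(y)) / sp
    def <- "between-pooled"
  }
  tibble::tibble(effect = effect, channel = channel, cohens_d = d,
                 definition = def)
}
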