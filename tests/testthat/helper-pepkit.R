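# Shared fixtures, built in code.

# a short custom protocol (valid under the protocol invariants) for tests
# that do not need the full 34-trial sequence
small_protocol <- function() {
  pep_protocol(1:6,
               c("posterior", "posterior", "posterior", "anterior",
                 "posterior", "anterior"),
               c("unpredictable", "excluded", "predictable", "unpredictable",
                 "predictable", "unpredictable"),
               name = "small-6")
}

# a light generator configuration: 8 subjects (2 per age x sex cell, the
# smallest cohort the split-plot design accepts)
small_config <- function(seed = 1, n_per_cell = 2, dropout_events = 0, ...) {
  generator_config(n_per_cell = n_per_cell, dropout_events = dropout_events,
                   seed = seed, ...)
}

one_subject <- function(age_group = "young", sex = "female", gain = 1) {
  tibble::tibble(subject_id = "S01", age_group = age_group, sex = sex,
                 subject_gain = gain)
}

# deterministic RMS-table generator for ANOVA-level tests: balanced
# age x sex x condition layout with configurable effects
synthetic_rms_table <- function(n_per_cell = 5, cond_effect = 0,
                                age_effect = 0, sex_effect = 0, sd = 1,
                                seed = 1, channel = "mastoid") {
  set.seed(seed)
  grid <- expand.grid(age_group = c("young", "elder"),
                      sex = c("male", "female"),
                      idx = seq_len(n_per_cell), stringsAsFactors = FALSE)
  grid$subject_id <- sprintf("T%02d", seq_len(nrow(grid)))
  base <- 1 +
    age_effect * (grid$age_group == "elder") +
    sex_effect * (grid$sex == "male") +
    stats::rnorm(nrow(grid), sd = sd)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    tibble::tibble(subject_id = grid$subject_id[i],
                   age_group = grid$age_group[i], sex = grid$sex[i],
                   channel = channel,
                   condition = c("unpredictable", "predictable"),
                   mean_rms = c(base[i] + cond_effect +
                                  stats::rnorm(1, sd = sd / 2),
                                base[i] + stats::rnorm(1, sd = sd / 2)),
                   mean_peak = 0, n_epochs = c(6L, 24L))
  })
  dplyr::bind_rows(rows)
}

# brute-force split-plot sums of squares for a 2 x 2 x (2 within) design,
# computed straight from the textbook decomposition on subject totals and
# condition differences -- independent of the package's implementation
brute_force_split_plot <- function(wide) {
  # wide: subject_id, age_group, sex, unpredictable, predictable (balanced)
  n <- nrow(wide)
  a <- factor(wide$age_group)
  s <- factor(wide$sex)
  celln <- table(a, s)
  stopifnot(length(unique(celln)) == 1)           # balanced only
  m <- unique(celln)[1]
  y <- cbind(wide$unpredictable, wide$predictable)
  tot <- rowSums(y)                               # subject totals (k = 2)
  dif <- y[, 1] - y[, 2]

  ss <- function(v, g) {                          # between-groups SS of v
    gm <- mean(v)
    sum(tapply(v, g, function(x) length(x) * (mean(x) - gm)^2))
  }
  # between stratum (divide by k = 2: totals over 2 condition measurements)
  ss_age <- ss(tot, a) / 2
  ss_sex <- ss(tot, s) / 2
  ss_cells <- ss(tot, interaction(a, s)) / 2
  ss_as <- ss_cells - ss_age - ss_sex
  ss_sub <- sum(tapply(tot, interaction(a, s),
                       function(x) sum((x - mean(x))^2))) / 2
  # within stratum from condition differences
  ss_cond <- n * mean(dif)^2 / 2
  ss_cond_cells <- ss(dif, interaction(a, s)) / 2
  ss_ca <- ss(dif, a) / 2
  ss_cs <- ss(dif, s) / 2
  ss_cas <- ss_cond_cells - ss_ca - ss_cs
  ss_err_w <- sum(tapply(dif, interaction(a, s),
                         function(x) sum((x - mean(x))^2))) / 2
  df_den <- n - 4
  f <- function(ss_eff, ss_err) (ss_eff / 1) / (ss_err / df_den)
  list(F = c(age = f(ss_age, ss_sub), sex = f(ss_sex, ss_sub),
             `age:sex` = f(ss_as, ss_sub),
             condition = f(ss_cond, ss_err_w),
             `age:condition` = f(ss_ca, ss_err_w),
             `sex:condition` = f(ss_cs, ss_err_w),
             `age:sex:condition` = f(ss_cas, ss_err_w)),
       df_den = df_den)
}
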