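test_that("change rates are percent changes from baseline with sign", {
  expect_equal(change_rate(25, 25), 0)
  expect_equal(change_rate(24.5, 25), -2)
  expect_equal(change_rate(26, 25), 4)
  expect_error(change_rate(24, 0), "positive")
  expect_error(change_rate(24, -1), "positive")
})

test_that("change rate is invariant to rescaling both measurements", {
  set.seed(21)
  for (i in 1:20) {
    eb <- runif(1, 20, 40)
    et <- eb * runif(1, 0.8, 1.2)
    k <- runif(1, 0.1, 10)
    expect_equal(change_rate(k * et, k * eb), change_rate(et, eb))
  }
})

arm_df <- function(study, times, effects, n) {
  data.frame(study_id = study, time_weeks = times, effect_pct = effects,
             n = n, stringsAsFactors = FALSE)
}

test_that("placebo adjustment subtracts the control arm at matched times", {
  int <- arm_df("s", 12, -3, 30)
  ctl <- arm_df("s", 12, -1, 25)
  adj <- placebo_adjust(int, ctl)
  expect_equal(adj$effect_pct, -2)
  expect_equal(adj$n_eff, 25)  # conservative: the smaller arm
  expect_true(all(adj$adjusted))

  same <- placebo_adjust(arm_df("s", c(4, 12), c(-1, -2), 30),
                         arm_df("s", c(4, 12), c(-1, -2), 30))
  expect_equal(same$effect_pct, c(0, 0))
})

test_that("placebo adjustment is antisymmetric in the two arms", {
  set.seed(31)
  for (i in 1:10) {
    tms <- sort(runif(3, 1, 52))
    a <- arm_df("s", tms, rnorm(3), 40)
    b <- arm_df("s", tms, rnorm(3), 30)
    expect_equal(placebo_adjust(a, b)$effect_pct,
                 -placebo_adjust(b, a)$effect_pct)
  }
})

test_that("placebo adjustment rejects mismatched studies and disjoint times", {
  expect_error(placebo_adjust(arm_df("s1", 12, -1, 30),
                              arm_df("s2", 12, -1, 30)),
               "single common study")
  expect_error(placebo_adjust(arm_df("s", 12, -1, 30),
                              arm_df("s", 26, -1, 30)),
               "no overlapping time points")
})

test_that("assembly computes adjusted effects from raw BMI arms", {
  df <- data.frame(
    study_id = "s1",
    arm = rep(c("intervention", "control"), each = 2),
    n = 30L, time = c(0, 12, 0, 12), time_unit = "weeks",
    bmi = c(30, 29.1, 30, 29.7))
  tab <- read_study_table(write_temp_csv(df))
  es <- assemble_effect_series(tab)
  expect_equal(nrow(es), 1)
  # intervention -3%, control -1% -> adjusted -2%
  expect_equal(es$effect_pct, -2)
  expect_equal(es$time_weeks, 12)
  expect_equal(es$n_eff, 30)
})

test_that("assembly accepts pre-computed change rates without time-0 rows", {
  df <- data.frame(
    study_id = "s1", arm = c("intervention", "control"),
    n = c(30L, 28L), time = 12, time_unit = "weeks",
    change_rate_pct = c(-3, -1))
  es <- assemble_effect_series(read_study_table(write_temp_csv(df)))
  expect_equal(es$effect_pct, -2)
  expect_equal(es$n_eff, 28)
})

test_that("assembly guards: no outcomes, missing control, missing baseline", {
  expect_error(assemble_effect_series(carnitine_trials()), "no outcome")

  df <- data.frame(
    study_id = c("s1", "s1", "s1", "s1", "s2", "s2"),
    arm = c("intervention", "intervention", "control", "control",
            "intervention", "intervention"),
    n = 30L, time = c(0, 12, 0, 12, 0, 12), time_unit = "weeks",
    bmi = c(30, 29.1, 30, 29.7, 31, 30.2))
  expect_warning(es <- assemble_effect_series(read_study_table(write_temp_csv(df))),
                 "without a control arm")
  expect_equal(unique(es$study_id), "s1")

  nobase <- data.frame(
    study_id = "s1", arm = c("intervention", "control"),
    n = 30L, time = 12, time_unit = "weeks", bmi = c(29.1, 29.7))
  expect_error(assemble_effect_series(read_study_table(write_temp_csv(nobase))),
               "time-0")
})

test_that("assembled effects recover the generator's noiseless truth", {
  # with omega = 0 the only deviation is residual noise; each adjusted point
  # must fall within 3 SDs of the difference of two arm-level residuals
  for (seed in c(2, 7, 19)) {
    cfg <- carnitine_design(truth = emax_params(-1.51, 0.5, 0, 0, 0.414),
                            re_emax = "none", re_et50 = "none", seed = seed)
    b <- simulate_trials(cfg)
    es <- assemble_effect_series(b$table)
    truth <- b$noiseless_adjusted
    m <- merge(as.data.frame(es), as.data.frame(truth),
               by = c("study_id", "time_weeks"))
    expect_equal(nrow(m), nrow(truth))
    des <- cfg$design
    i <- match(m$study_id, des$study_id)
    sd_adj <- 0.414 * sqrt(1 / (des$n_intervention[i] / 100) +
                             1 / (des$n_control[i] / 100))
    expect_true(all(abs(m$effect_pct.x - m$effect_pct.y) < 3 * sd_adj))
  }
})

test_that("effect series round-trips through its CSV writer", {
  cfg <- carnitine_design(truth = emax_params(-1.51, 0.5, 0, 0, 0.414),
                          re_emax = "none", re_et50 = "none", seed = 3)
  es <- assemble_effect_series(simulate_trials(cfg)$table)
  path <- tempfile(fileext = ".csv")
  write_effect_series(es, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(es))
  expect_identical(back$effect_pct, es$effect_pct)
  expect_identical(back$n_eff, es$n_eff)
})
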