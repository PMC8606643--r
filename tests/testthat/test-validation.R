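wls_spec <- function(init = emax_params(-1, 1, 0, 0, 0.3)) {
  model_spec(init = init, re_emax = "none", re_et50 = "none")
}

sim_series <- function(seed, n_studies = 8, truth = emax_params(-1.51, 0.5, 0, 0, 0.414)) {
  cfg <- if (n_studies == 8)
    carnitine_design(truth = truth, re_emax = "none", re_et50 = "none",
                     seed = seed)
  else
    sim_config(n_studies = n_studies, truth = truth, re_emax = "none",
               re_et50 = "none", seed = seed)
  assemble_effect_series(simulate_trials(cfg)$table)
}

test_that("an identity resample reproduces the estimate with zero bias", {
  es <- sim_series(5)
  bs <- bootstrap_emax(es, wls_spec(), n_reps = 1, seed = 1,
                       .resample = function(ids, r) ids)
  expect_equal(bs$summary$median, bs$summary$estimate)
  expect_equal(bs$summary$bias_pct, rep(0, nrow(bs$summary)))
  expect_equal(bs$n_failed, 0L)
})

test_that("bootstrap percentiles bracket the median and the estimate brackets hold", {
  es <- sim_series(11)
  bs <- bootstrap_emax(es, wls_spec(), n_reps = 40, seed = 2, n_starts = 2)
  with(bs$summary, {
    expect_true(all(ci_low <= median + 1e-12))
    expect_true(all(median <= ci_high + 1e-12))
  })
  expect_false(bs$unreliable)

  # self-consistency: over repeated experiments the 95% interval for emax
  # should cover the original estimate nearly always
  hits <- vapply(1:10, function(k) {
    es_k <- sim_series(200 + k)
    b <- bootstrap_emax(es_k, wls_spec(), n_reps = 40, seed = k,
                        n_starts = 1)
    row <- b$summary[b$summary$parameter == "emax", ]
    row$ci_low <= row$estimate && row$estimate <= row$ci_high
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("bootstrap interval widths shrink roughly as 1/sqrt(study count)", {
  es8 <- sim_series(31, n_studies = 8)
  es32 <- sim_series(31, n_studies = 32)
  b8 <- bootstrap_emax(es8, wls_spec(), n_reps = 150, seed = 3, n_starts = 1)
  b32 <- bootstrap_emax(es32, wls_spec(), n_reps = 150, seed = 3, n_starts = 1)
  # the scaling is checked on sigma: at 8 endpoint-only studies the emax
  # interval is inflated by replicates that wander along the flat ET50
  # ridge, so emax is far from its asymptotic regime there
  w <- function(b) {
    r <- b$summary[b$summary$parameter == "sigma", ]
    r$ci_high - r$ci_low
  }
  ratio <- w(b8) / w(b32)  # expect about sqrt(4) = 2
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.6)
})

test_that("the VPC envelope collapses onto the curve in the noise-free limit", {
  es <- sim_series(7)
  f <- fit_emax(wls_spec(), es, seed = 1)
  f0 <- f
  f0$params$sigma <- 1e-12
  v <- pcvpc(es, f0, n_sims = 50, seed = 1)
  expect_lt(max(v$table$sim_hi - v$table$sim_lo), 1e-9)
  # envelope sits on the population prediction at each design time
  ki <- order(v$table$time)
  pred <- emax_effect(f0$params$emax, f0$params$et50, v$table$time[ki])
  expect_equal(v$table$sim_median[ki], pred, tolerance = 1e-6)
})

test_that("prediction correction is the identity at a single shared design point", {
  es <- effect_series(c("a", "b", "c"), c(12, 12, 12), c(-1.0, -1.6, -1.2),
                      c(50, 80, 40))
  f <- suppressWarnings(fit_emax(wls_spec(), es, seed = 1))
  v <- pcvpc(es, f, n_sims = 30, seed = 1)
  expect_equal(nrow(v$table), 1)
  expect_equal(v$table$obs_median, stats::median(es$effect_pct))
})

test_that("the VPC covers self-simulated data and flags a wrong model", {
  des <- data.frame(study_id = sprintf("v%02d", 1:30),
                    n_intervention = rep(c(40L, 80L, 120L), 10),
                    n_control = rep(c(40L, 80L, 120L), 10),
                    time_weeks = rep(c(1, 2, 4, 8, 16, 32), 5))
  cfg <- sim_config(truth = emax_params(-1.51, 0.5, 0, 0, 0.414),
                    re_emax = "none", re_et50 = "none", design = des,
                    seed = 17)
  es <- assemble_effect_series(simulate_trials(cfg)$table)
  f <- fit_emax(wls_spec(), es, seed = 1)
  expect_true(f$converged)
  cov_self <- vapply(1:5, function(k) {
    obs <- embma:::with_seed(1000 + k, embma:::simulate_effects(f, es))
    pcvpc(obs, f, n_sims = 150, seed = k)$coverage
  }, numeric(1))
  expect_gte(mean(cov_self), 0.9)

  # same design generated with a tenfold ET50 is caught
  cfg_bad <- sim_config(truth = emax_params(-1.51, 5, 0, 0, 0.414),
                        re_emax = "none", re_et50 = "none", design = des,
                        seed = 18)
  es_bad <- assemble_effect_series(simulate_trials(cfg_bad)$table)
  v_bad <- pcvpc(es_bad, f, n_sims = 150, seed = 2)
  expect_lt(v_bad$coverage, 0.9)
})

test_that("efficacy prediction reduces to the deterministic curve without heterogeneity", {
  p <- emax_params(-1.51, 0.5, 0, 0, 0.414)
  pr <- predict_efficacy(p, horizon = 20, n_sims = 50, seed = 1)
  expect_equal(pr$median, emax_effect(-1.51, 0.5, pr$time))
  expect_equal(pr$lo, pr$median)
  expect_equal(pr$hi, pr$median)
  expect_true(all(diff(abs(pr$median)) >= 0))
  expect_equal(pr$fraction_of_emax, pr$time / (0.5 + pr$time))

  ms <- attr(pr, "milestones")
  expect_equal(ms$fraction, c(0.5, 0.8, 0.9, 0.95))
  expect_equal(ms$time_weeks, c(0.5, 2, 4.5, 9.5))
  # fraction of emax at et50 is one half by definition
  expect_equal(pr$fraction_of_emax[which.min(abs(pr$time - 0.5))], 0.5,
               tolerance = 0.01)
})

test_that("heterogeneity widens the prediction band around a monotone median", {
  p <- emax_params(-1.51, 0.5, 0.4, 0.1, 0.414)
  pr <- predict_efficacy(p, horizon = 20, n_sims = 400, seed = 2)
  late <- pr$time > 1
  expect_true(all(pr$lo[late] < pr$median[late]))
  expect_true(all(pr$hi[late] > pr$median[late]))
  # reproducible under the same seed
  pr2 <- predict_efficacy(p, horizon = 20, n_sims = 400, seed = 2)
  expect_identical(pr$lo, pr2$lo)
})
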