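base_spec <- function(init = emax_params(-1, 1, 0, 0, 0.3)) {
  model_spec(init = init, re_emax = "none", re_et50 = "none")
}

test_that("the objective has its closed-form value on trivial instances", {
  p <- emax_params(-1.51, 0.5, 0, 0, 1)
  # one observation exactly on the curve, n = 100 -> variance 1
  es <- effect_series("s", 2, emax_effect(-1.51, 0.5, 2), 100)
  expect_equal(emax_objective(p, base_spec(), es), log(2 * pi))
  # doubling n halves the variance: residual term stays 0, the
  # normalization term drops by log 2
  es2 <- effect_series("s", 2, emax_effect(-1.51, 0.5, 2), 200)
  expect_equal(emax_objective(p, base_spec(), es2), log(2 * pi) - log(2))
})

test_that("without random effects the objective equals an independent WLS oracle", {
  es <- tiny_series()
  for (pars in list(c(-1.5, 1.2, 0.5), c(-0.8, 5, 1.1), c(2, 20, 0.3))) {
    p <- emax_params(pars[1], pars[2], 0, 0, pars[3])
    v <- pars[3]^2 / (es$n_eff / 100)
    mu <- emax_effect(pars[1], pars[2], es$time_weeks)
    expect_equal(emax_objective(p, base_spec(), es),
                 wls_m2ll(es$effect_pct, mu, v), tolerance = 1e-10)
  }
})

test_that("the Laplace marginal is exact for an additive effect on Emax", {
  # with an additive random effect on emax the model is linear in eta and
  # the marginal likelihood has a closed multivariate-normal form
  es <- tiny_series()
  p <- emax_params(-1.5, 1.2, 0.6, 0, 0.5)
  spec <- model_spec(init = p, re_emax = "additive", re_et50 = "none")
  tot <- 0
  for (s in unique(es$study_id)) {
    i <- es$study_id == s
    k <- es$time_weeks[i] / (p$et50 + es$time_weeks[i])
    V <- diag(p$sigma^2 / (es$n_eff[i] / 100), sum(i)) +
      p$omega_emax^2 * outer(k, k)
    tot <- tot + mvn_m2ll(es$effect_pct[i], p$emax * k, V)
  }
  expect_equal(emax_objective(p, spec, es), tot, tolerance = 1e-8)
})

test_that("the Laplace marginal tracks numerical integration for an exponential effect", {
  es <- tiny_series()
  p <- emax_params(-1.5, 1.2, 0.4, 0, 0.5)
  spec <- model_spec(init = p, re_emax = "exponential", re_et50 = "none")
  tot <- 0
  for (s in unique(es$study_id)) {
    i <- es$study_id == s
    k <- es$time_weeks[i] / (p$et50 + es$time_weeks[i])
    vv <- p$sigma^2 / (es$n_eff[i] / 100)
    integrand <- Vectorize(function(eta) {
      mu <- p$emax * exp(eta) * k
      exp(sum(stats::dnorm(es$effect_pct[i], mu, sqrt(vv), log = TRUE)) +
            stats::dnorm(eta, 0, p$omega_emax, log = TRUE))
    })
    L <- stats::integrate(integrand, -8 * p$omega_emax, 8 * p$omega_emax,
                          rel.tol = 1e-12)$value
    tot <- tot - 2 * log(L)
  }
  # Laplace is an approximation; agreement to ~0.05 OFV units on this
  # mildly nonlinear instance
  expect_equal(emax_objective(p, spec, es), tot, tolerance = 0.05)
})

test_that("noiseless data are recovered to numerical precision", {
  cfg <- carnitine_design(truth = emax_params(-1.51, 0.5, 0, 0, 0),
                          re_emax = "none", re_et50 = "none", seed = 2)
  es <- assemble_effect_series(simulate_trials(cfg)$table)
  f <- fit_emax(base_spec(), es, seed = 1)
  expect_true(f$converged)
  expect_lt(abs(f$params$emax + 1.51) / 1.51, 1e-4)
  expect_lt(abs(f$params$et50 - 0.5) / 0.5, 1e-4)
})

test_that("identifiability guards: single study, single time point", {
  es1 <- effect_series(c("only", "only"), c(12, 26), c(-1.2, -1.4), c(50, 50))
  spec <- model_spec(init = emax_params(-1, 1, 0.2, 0.1, 0.3),
                     re_emax = "exponential", re_et50 = "exponential")
  expect_warning(f <- fit_emax(spec, es1, seed = 1), "fewer than 2 studies")
  expect_equal(f$params$omega_emax, 0)
  expect_equal(f$params$omega_et50, 0)

  es2 <- effect_series(c("a", "b", "c"), c(12, 12, 12), c(-1.2, -1.4, -1),
                       c(50, 50, 50))
  expect_warning(f2 <- fit_emax(base_spec(), es2, seed = 1),
                 "fewer than 2 distinct time points")
  expect_true(f2$et50_fixed)
  expect_equal(f2$params$et50, 1)  # held at the initial value
  expect_false(is.null(f2$params$emax))
})

test_that("the fit is invariant to row and study permutations", {
  cfg <- carnitine_design(truth = emax_params(-1.51, 0.5, 0, 0, 0.414),
                          re_emax = "none", re_et50 = "none", seed = 9)
  es <- assemble_effect_series(simulate_trials(cfg)$table)
  f1 <- fit_emax(base_spec(), es, seed = 4)
  set.seed(77)
  perm <- sample(nrow(es))
  es_shuffled <- effect_series(es$study_id[perm], es$time_weeks[perm],
                               es$effect_pct[perm], es$n_eff[perm])
  f2 <- fit_emax(base_spec(), es_shuffled, seed = 4)
  expect_equal(f1$ofv, f2$ofv, tolerance = 1e-10)
  expect_equal(unclass(f1$params), unclass(f2$params), tolerance = 1e-8)
})

test_that("adding a parameter never increases the optimized OFV", {
  cfg <- sim_config(n_studies = 12,
                    truth = emax_params(-1.51, 0.5, 0, 0, 0.414),
                    re_emax = "none", re_et50 = "none",
                    covariate_effects = list(
                      covariate_spec("emax", "age", "linear_shift",
                                     theta = 0, reference = 50)),
                    seed = 13)
  es <- assemble_effect_series(simulate_trials(cfg)$table)
  f0 <- fit_emax(base_spec(), es, seed = 1)
  spec_cov <- base_spec()
  spec_cov$covariates <- list(covariate_spec("emax", "age", "linear_shift"))
  f1 <- fit_emax(spec_cov, es, init = f0$params, seed = 1)
  expect_lte(f1$ofv, f0$ofv + 1e-4)
})

test_that("inter-study variability is recovered from a large study set", {
  des <- data.frame(study_id = sprintf("s%03d", 1:200),
                    n_intervention = rep(c(30L, 60L, 120L, 45L), 50),
                    n_control = rep(c(30L, 60L, 120L, 45L), 50),
                    time_weeks = rep(c(12, 26, 52, 17), 50))
  cfg <- sim_config(truth = emax_params(-1.51, 0.5, 0.3, 0, 0.414),
                    re_emax = "exponential", re_et50 = "none",
                    design = des, seed = 99)
  es <- assemble_effect_series(simulate_trials(cfg)$table)
  spec <- model_spec(init = emax_params(-1, 1, 0.2, 0, 0.3),
                     re_emax = "exponential", re_et50 = "none")
  f <- fit_emax(spec, es, seed = 1, n_starts = 1)
  expect_true(f$converged)
  expect_lt(abs(f$params$omega_emax - 0.3) / 0.3, 0.25)
})

test_that("covariate search includes a real effect and keeps it", {
  cfg <- sim_config(n_studies = 20,
                    truth = emax_params(-1.51, 0.5, 0, 0, 0.414),
                    re_emax = "none", re_et50 = "none",
                    covariate_effects = list(
                      covariate_spec("emax", "age", "linear_shift",
                                     theta = 0.15, reference = 50)),
                    seed = 42)
  es <- assemble_effect_series(simulate_trials(cfg)$table)
  base <- fit_emax(base_spec(), es, seed = 1)
  res <- covariate_search(base, list(
    covariate_spec("emax", "age", "linear_shift")), seed = 1)
  expect_equal(res$steps$decision, c("included", "retained"))
  expect_gt(res$steps$delta[1], 3.84)
  expect_gt(res$steps$delta[2], 6.63)
  # the generating coefficient is recovered in sign and rough magnitude
  expect_gt(res$fit$thetas[["age"]], 0.05)
})

test_that("covariate search leaves the base model alone without candidates", {
  es <- tiny_series()
  base <- fit_emax(base_spec(), es, seed = 1)
  res <- covariate_search(base, list())
  expect_identical(res$fit$ofv, base$ofv)
  expect_equal(nrow(res$steps), 0)
})

test_that("covariate search skips candidates with missing study values", {
  cfg <- sim_config(n_studies = 8,
                    truth = emax_params(-1.51, 0.5, 0, 0, 0.414),
                    re_emax = "none", re_et50 = "none", seed = 3)
  es <- assemble_effect_series(simulate_trials(cfg)$table)
  base <- fit_emax(base_spec(), es, seed = 1)
  expect_message(
    res <- covariate_search(base, list(
      covariate_spec("emax", "not_recorded", "linear_shift"))),
    "skipped")
  expect_equal(nrow(res$steps), 0)
  expect_identical(res$fit$ofv, base$ofv)
})

test_that("CWRES vanish on noiseless data and are standard normal under the model", {
  cfg0 <- carnitine_design(truth = emax_params(-1.51, 0.5, 0, 0, 0),
                           re_emax = "none", re_et50 = "none", seed = 2)
  es0 <- assemble_effect_series(simulate_trials(cfg0)$table)
  f0 <- fit_emax(base_spec(), es0, seed = 1)
  expect_lt(max(abs(cwres(f0)$cwres)), 1e-5)

  des <- data.frame(study_id = sprintf("s%03d", 1:120),
                    n_intervention = rep(c(30L, 60L, 120L), 40),
                    n_control = rep(c(30L, 60L, 120L), 40),
                    time_weeks = rep(c(12, 26, 52), 40))
  cfg <- sim_config(truth = emax_params(-1.51, 0.5, 0.3, 0, 0.5857),
                    re_emax = "exponential", re_et50 = "none",
                    design = des, seed = 5)
  es <- assemble_effect_series(simulate_trials(cfg)$table)
  spec <- model_spec(init = emax_params(-1.5, 0.5, 0.3, 0, 0.5),
                     re_emax = "exponential", re_et50 = "none")
  f <- fit_emax(spec, es, seed = 1, n_starts = 1)
  cw <- cwres(f)
  expect_lt(abs(mean(cw$cwres)), 0.1)
  expect_gt(stats::var(cw$cwres), 0.8)
  expect_lt(stats::var(cw$cwres), 1.2)

  # a residual scale fixed far too small inflates CWRES spread
  f_bad <- f
  f_bad$params$sigma <- f$params$sigma / 2
  expect_gt(stats::var(cwres(f_bad)$cwres), 2)
})
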