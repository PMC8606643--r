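# Maximum-likelihood estimation of the Emax meta-analysis model.
#
# The marginal likelihood integrates the study-level random effects out by a
# per-study Laplace approximation: an inner optimization finds the mode of
# the joint deviance in eta for each study, and the curvature there supplies
# the Gaussian correction. With all omegas zero the objective reduces
# exactly to weighted least squares with residual variances
# sigma^2 / (n_eff / 100), plus the normal constant.

# override covariate thetas with estimated values
effective_covspecs <- function(spec, thetas) {
  specs <- spec$covariates
  if (!is.null(thetas)) {
    for (k in seq_along(specs)) specs[[k]]$theta <- unname(thetas[k])
  }
  specs
}

# fill in NULL reference values (population medians) for continuous forms
resolve_references <- function(spec, data) {
  covs <- attr(data, "covariates")
  for (k in seq_along(spec$covariates)) {
    sp <- spec$covariates[[k]]
    if (sp$form %in% c("linear_shift", "power") && is.null(sp$reference)) {
      if (is.null(covs) || !sp$name %in% names(covs))
        stop("covariate '", sp$name, "' not found in the data", call. = FALSE)
      spec$covariates[[k]]$reference <-
        stats::median(as.numeric(covs[[sp$name]]), na.rm = TRUE)
    }
  }
  spec
}

# Laplace term for a single study. forms/omegas are length-2 (emax, et50);
# `active` marks which random effects are live (form != none and omega > 0).
# The inner mode is found by damped Newton with analytic gradient and
# Hessian of the joint deviance; the search always starts at eta = 0 (the
# prior mode) so the marginal objective is a deterministic function of the
# parameters.
study_laplace <- function(y, t, v, emax_t, et50_t, forms, omegas, active) {
  d <- sum(active)
  w <- 1 / v
  const <- sum(log(2 * pi * v)) +
    sum(log(2 * pi * omegas[active]^2))
  devfun <- function(eta) {
    full <- numeric(2)
    full[active] <- eta
    e1 <- if (forms[1] == "none") emax_t else
      apply_random_effect(emax_t, full[1], forms[1])
    t5 <- if (forms[2] == "none") et50_t else
      apply_random_effect(et50_t, full[2], forms[2])
    if (!is.finite(e1) || !is.finite(t5) || t5 <= 0) return(Inf)
    f <- e1 * t / (t5 + t)
    val <- sum((y - f)^2 * w) + sum(eta^2 / omegas[active]^2) + const
    if (is.finite(val)) val else Inf
  }
  # analytic gradient and Hessian of the joint deviance in the active etas
  grad_hess <- function(eta) {
    full <- numeric(2)
    full[active] <- eta
    if (forms[1] == "none") { e1 <- emax_t; de1 <- 0; d2e1 <- 0 }
    else if (forms[1] == "exponential") { e1 <- emax_t * exp(full[1]); de1 <- e1; d2e1 <- e1 }
    else { e1 <- emax_t + full[1]; de1 <- 1; d2e1 <- 0 }
    if (forms[2] == "none") { t5 <- et50_t; dt5 <- 0; d2t5 <- 0 }
    else if (forms[2] == "exponential") { t5 <- et50_t * exp(full[2]); dt5 <- t5; d2t5 <- t5 }
    else { t5 <- et50_t + full[2]; dt5 <- 1; d2t5 <- 0 }
    k <- t / (t5 + t)
    dk <- -t / (t5 + t)^2
    d2k <- 2 * t / (t5 + t)^3
    f <- e1 * k
    r <- y - f
    df1 <- de1 * k
    df2 <- e1 * dk * dt5
    d2f11 <- d2e1 * k
    d2f12 <- de1 * dk * dt5
    d2f22 <- e1 * (d2k * dt5^2 + dk * d2t5)
    g_full <- c(-2 * sum(w * r * df1), -2 * sum(w * r * df2))
    H_full <- matrix(c(
      2 * sum(w * (df1^2 - r * d2f11)), 2 * sum(w * (df1 * df2 - r * d2f12)),
      2 * sum(w * (df1 * df2 - r * d2f12)), 2 * sum(w * (df2^2 - r * d2f22))),
      2, 2)
    Hgn_full <- matrix(c(
      2 * sum(w * df1^2), 2 * sum(w * df1 * df2),
      2 * sum(w * df1 * df2), 2 * sum(w * df2^2)), 2, 2)
    pr <- 2 / omegas^2
    pr[!active] <- 0
    g_full <- g_full + pr * full
    H_full <- H_full + diag(pr)
    Hgn_full <- Hgn_full + diag(pr)
    list(g = g_full[active],
         H = H_full[active, active, drop = FALSE],
         Hgn = Hgn_full[active, active, drop = FALSE])
  }

  eta <- numeric(d)
  m_cur <- devfun(eta)
  for (it in seq_len(60)) {
    G <- grad_hess(eta)
    if (max(abs(G$g)) < 1e-9 * (1 + abs(m_cur))) break
    lam <- 0
    ch <- NULL
    H <- G$H
    repeat {
      ch <- tryCatch(chol(H + diag(lam, d)), error = function(e) NULL)
      if (!is.null(ch)) break
      lam <- if (lam == 0) 1e-6 * (1 + max(abs(diag(H)))) else lam * 10
      if (lam > 1e12) { ch <- chol(G$Hgn); break }
    }
    step <- -backsolve(ch, forwardsolve(t(ch), G$g))
    alpha <- 1
    improved <- FALSE
    for (ls in seq_len(40)) {
      m_new <- devfun(eta + alpha * step)
      if (is.finite(m_new) && m_new < m_cur - 1e-13) { improved <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!improved) break
    eta <- eta + alpha * step
    m_cur <- m_new
    if (max(abs(alpha * step)) < 1e-10) break
  }

  G <- grad_hess(eta)
  detG <- det(G$H / 2)
  if (!is.finite(detG) || detG <= 0) detG <- max(det(G$Hgn / 2), 1e-12)
  full <- numeric(2)
  full[active] <- eta
  list(ofv = m_cur + log(detG) - d * log(2 * pi), eta = full)
}

# per-study typical parameter values after covariate submodels
typical_values <- function(params, covspecs, data) {
  studies <- unique(data$study_id)
  covs <- attr(data, "covariates")
  emax_t <- et50_t <- numeric(length(studies))
  for (k in seq_along(studies)) {
    cov_row <- list()
    if (!is.null(covs)) {
      row <- covs[covs$study_id == studies[k], , drop = FALSE]
      if (nrow(row) >= 1) cov_row <- as.list(row[1, ])
    }
    emax_t[k] <- apply_covariates(params$emax, "emax", covspecs, cov_row)
    et50_t[k] <- apply_covariates(params$et50, "et50", covspecs, cov_row)
  }
  list(studies = studies, emax = emax_t, et50 = et50_t)
}

objective_core <- function(params, spec, data, thetas = NULL,
                           return_eta = FALSE) {
  covspecs <- effective_covspecs(spec, thetas)
  tv <- typical_values(params, covspecs, data)
  if (any(!is.finite(tv$emax)) || any(!is.finite(tv$et50)) || any(tv$et50 <= 0))
    stop("non-finite or nonpositive typical parameter value for study '",
         tv$studies[which(!is.finite(tv$emax) | !is.finite(tv$et50) |
                            tv$et50 <= 0)[1]], "'", call. = FALSE)
  v <- params$sigma^2 / (data$n_eff / 100)
  forms <- c(spec$re_emax, spec$re_et50)
  omegas <- c(params$omega_emax, params$omega_et50)
  active <- forms != "none" & omegas > 0

  if (!any(active)) {
    ki <- match(data$study_id, tv$studies)
    pred <- tv$emax[ki] * data$time_weeks / (tv$et50[ki] + data$time_weeks)
    if (any(!is.finite(pred))) {
      bad <- which(!is.finite(pred))[1]
      stop("non-finite model prediction (study '", data$study_id[bad],
           "', time ", data$time_weeks[bad], ")", call. = FALSE)
    }
    ofv <- sum((data$effect_pct - pred)^2 / v + log(2 * pi * v))
    eta <- if (return_eta)
      data.frame(study_id = tv$studies,
                 eta_emax = 0, eta_et50 = 0)[, c(TRUE, active), drop = FALSE]
    return(list(ofv = ofv, eta = eta))
  }

  total <- 0
  etas <- matrix(0, length(tv$studies), 2)
  for (k in seq_along(tv$studies)) {
    idx <- which(data$study_id == tv$studies[k])
    res <- study_laplace(data$effect_pct[idx], data$time_weeks[idx], v[idx],
                         tv$emax[k], tv$et50[k], forms, omegas, active)
    total <- total + res$ofv
    etas[k, ] <- res$eta
  }
  eta <- NULL
  if (return_eta) {
    eta <- data.frame(study_id = tv$studies, eta_emax = etas[, 1],
                      eta_et50 = etas[, 2])
    eta <- eta[, c(TRUE, active), drop = FALSE]
  }
  list(ofv = total, eta = eta)
}

#' Objective function (-2 log marginal likelihood) of the Emax MBMA model
#'
#' Evaluates minus twice the log marginal likelihood of an effect series
#' under given parameters. Residual variance for an observation backed by
#' `n_eff` subjects is `sigma^2 / (n_eff / 100)`. Study-level random
#' effects, when present (`re_*` form not `"none"` and the matching omega
#' positive), are integrated out by a per-study Laplace approximation; with
#' all omegas zero the value is the exact weighted-least-squares deviance
#' `sum((y - f)^2 / v + log(2 pi v))`.
#'
#' @param params An [emax_params()] object.
#' @param spec A [model_spec()]; its covariate `theta` values are used
#'   unless overridden by `thetas`.
#' @param data An `effect_series` with all times > 0.
#' @param thetas Optional named vector of covariate coefficients overriding
#'   those in `spec`.
#' @return The objective function value (OFV), a single number.
#' @export
emax_objective <- function(params, spec, data, thetas = NULL) {
  stopifnot(inherits(params, "emax_params"), inherits(spec, "model_spec"),
            inherits(data, "effect_series"))
  if (nrow(data) == 0) stop("'data' is empty", call. = FALSE)
  if (any(data$time_weeks <= 0))
    stop("all observation times must be > 0 (baseline points carry no information)",
         call. = FALSE)
  spec <- resolve_references(spec, data)
  objective_core(params, spec, data, thetas = thetas)$ofv
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i] - 1e-12) return(TRUE)
    if (a[i] > b[i] + 1e-12) return(FALSE)
  }
  FALSE
}

#' Fit the Emax meta-analysis model by maximum likelihood
#'
#' Minimizes the [emax_objective()] over the fixed effects, with `et50`,
#' the omegas, and `sigma` estimated on the log scale (enforcing
#' positivity; omegas and sigma are bounded below at 1e-3, `et50` is kept
#' in `[1e-3, 1e4]` weeks). A small multi-start (default 3 starts, the
#' initial values plus seeded jitter) guards against local minima;
#' ties are broken by lowest OFV, then lexicographic parameter order. The
#' result is deterministic given `(data, init, seed)`.
#'
#' Identifiability guards: with fewer than 2 studies the inter-study
#' variabilities are dropped (with a warning); with fewer than 2 distinct
#' observation times `et50` is fixed at its initial value (with a warning).
#' Non-convergence is reported through `converged = FALSE`, not an error.
#'
#' @param spec A [model_spec()].
#' @param data An `effect_series` (all times > 0).
#' @param init Starting [emax_params()]; defaults to `spec$init`.
#' @param seed Integer seed controlling the multi-start jitter.
#' @param n_starts Number of optimizer starts.
#' @return An object of class `emax_fit` with elements `params`, `thetas`,
#'   `ofv`, `eta_by_study` (empirical-Bayes modes for active random
#'   effects), `converged`, `n_obs`, `n_studies`, `spec` (with fitted
#'   covariate coefficients), and the data used.
#' @export
fit_emax <- function(spec, data, init = NULL, seed = 1L, n_starts = 3L) {
  stopifnot(inherits(spec, "model_spec"), inherits(data, "effect_series"))
  if (nrow(data) == 0) stop("'data' is empty", call. = FALSE)
  if (any(data$time_weeks <= 0))
    stop("all observation times must be > 0", call. = FALSE)
  data <- new_effect_series(as.data.frame(data), attr(data, "covariates"))
  init <- init %||% spec$init
  spec <- resolve_references(spec, data)

  n_studies <- length(unique(data$study_id))
  n_times <- length(unique(round(data$time_weeks, 6)))
  if (n_studies < 2 && (spec$re_emax != "none" || spec$re_et50 != "none")) {
    warning("fewer than 2 studies: inter-study variability not estimable; ",
            "random effects dropped", call. = FALSE)
    spec$re_emax <- "none"
    spec$re_et50 <- "none"
  }
  et50_fixed <- FALSE
  if (n_times < 2) {
    warning("fewer than 2 distinct time points: ET50 not identifiable; ",
            "fixed at ", init$et50, " weeks", call. = FALSE)
    et50_fixed <- TRUE
  }
  est_om1 <- spec$re_emax != "none"
  est_om2 <- spec$re_et50 != "none"
  cnames <- vapply(spec$covariates, `[[`, character(1), "name")

  p0 <- c(emax = init$emax)
  if (!et50_fixed) p0 <- c(p0, let50 = log(init$et50))
  if (est_om1) p0 <- c(p0, lom1 = log(max(init$omega_emax, 0.05)))
  if (est_om2) p0 <- c(p0, lom2 = log(max(init$omega_et50, 0.05)))
  p0 <- c(p0, lsig = log(max(init$sigma, 0.05)))
  if (length(cnames)) {
    th0 <- vapply(spec$covariates, `[[`, numeric(1), "theta")
    p0 <- c(p0, stats::setNames(th0, paste0("th_", cnames)))
  }
  ix <- stats::setNames(seq_along(p0), names(p0))
  lower <- rep(-Inf, length(p0))
  upper <- rep(Inf, length(p0))
  if (!et50_fixed) {
    lower[ix["let50"]] <- log(1e-3)
    upper[ix["let50"]] <- log(1e4)
  }
  for (nm in c("lom1", "lom2", "lsig"))
    if (nm %in% names(ix)) lower[ix[nm]] <- log(1e-3)

  unpack <- function(p) {
    params <- emax_params(
      emax = p[ix[["emax"]]],
      et50 = if (et50_fixed) init$et50 else exp(p[ix[["let50"]]]),
      omega_emax = if (est_om1) exp(p[ix[["lom1"]]]) else 0,
      omega_et50 = if (est_om2) exp(p[ix[["lom2"]]]) else 0,
      sigma = exp(p[ix[["lsig"]]]))
    thetas <- NULL
    if (length(cnames))
      thetas <- stats::setNames(p[ix[paste0("th_", cnames)]], cnames)
    list(params = params, thetas = thetas)
  }
  objfun <- function(p) {
    u <- tryCatch(unpack(p), error = function(e) NULL)
    if (is.null(u)) return(1e10)
    val <- tryCatch(objective_core(u$params, spec, data, thetas = u$thetas)$ofv,
                    error = function(e) NA_real_)
    if (is.finite(val)) val else 1e10
  }

  starts <- list(p0)
  if (n_starts > 1) {
    jit <- with_seed(derive_seed(seed, 11L),
                     lapply(seq_len(n_starts - 1),
                            function(i) stats::rnorm(length(p0), 0, 0.3)))
    starts <- c(starts, lapply(jit, function(j) p0 + j))
  }
  best <- NULL
  for (st in starts) {
    o <- tryCatch(
      stats::nlminb(st, objfun, lower = lower, upper = upper,
                    control = list(rel.tol = 1e-10, x.tol = 1e-8,
                                   iter.max = 500, eval.max = 2000)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$objective < best$objective - 1e-9 ||
        (abs(o$objective - best$objective) <= 1e-9 && lex_less(o$par, best$par)))
      best <- o
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)
  # polish restart from the best solution; on flat likelihood surfaces the
  # first pass often stops with a "false convergence" code even at the
  # optimum, and a restart settles the diagnostic
  polish <- tryCatch(
    stats::nlminb(best$par, objfun, lower = lower, upper = upper,
                  control = list(rel.tol = 1e-10, x.tol = 1e-8,
                                 iter.max = 500, eval.max = 2000)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$objective <= best$objective + 1e-9)
    best <- polish

  # nlminb reports "false convergence" both at active bounds and on flat
  # plateaus; accept the solution as converged when no small coordinate
  # move inside the bounds improves the objective
  converged <- best$convergence == 0
  if (!converged && is.finite(best$objective)) {
    improvable <- FALSE
    for (j in seq_along(best$par)) {
      for (sgn in c(-1, 1)) {
        pj <- best$par
        pj[j] <- min(max(pj[j] + sgn * 1e-4 * max(1, abs(pj[j])), lower[j]),
                     upper[j])
        if (objfun(pj) < best$objective - 1e-6) { improvable <- TRUE; break }
      }
      if (improvable) break
    }
    converged <- !improvable
  }

  u <- unpack(best$par)
  core <- objective_core(u$params, spec, data, thetas = u$thetas,
                         return_eta = TRUE)
  spec_out <- spec
  if (length(cnames))
    for (k in seq_along(spec_out$covariates))
      spec_out$covariates[[k]]$theta <- unname(u$thetas[k])

  structure(
    list(params = u$params, thetas = u$thetas, ofv = core$ofv,
         eta_by_study = core$eta,
         converged = converged && is.finite(core$ofv),
         n_obs = nrow(data), n_studies = n_studies, spec = spec_out,
         data = data, et50_fixed = et50_fixed,
         message = best$message, seed = seed, n_starts = n_starts),
    class = "emax_fit")
}

#' @export
print.emax_fit <- function(x, ...) {
  cat("Emax MBMA fit",
      if (!x$converged) " (DID NOT CONVERGE)" else "", "\n", sep = "")
  cat(sprintf("  %d studies, %d observations; OFV = %.4f\n",
              x$n_studies, x$n_obs, x$ofv))
  print(x$params)
  if (!is.null(x$thetas) && length(x$thetas)) {
    cat("  covariate coefficients:\n")
    for (nm in names(x$thetas))
      cat(sprintf("    theta[%s] = %.4g\n", nm, x$thetas[[nm]]))
  }
  if (x$et50_fixed) cat("  (et50 fixed: < 2 distinct times)\n")
  invisible(x)
}

#' Stepwise covariate selection on the objective function value
#'
#' Forward step: each candidate covariate is added (to `emax` by
#' convention) and the best candidate is included when it lowers the OFV by
#' more than `include_dofv` (3.84, the 5% chi-square critical value on 1
#' d.f.); iterated until no candidate qualifies. Backward step: each
#' included covariate is removed in turn and retained only when its removal
#' raises the OFV by more than `remove_dofv` (6.63, the 1% critical value).
#' Candidates with missing covariate values for any study are skipped with
#' a message. The full decision trail is returned.
#'
#' @param base A converged `emax_fit` (the covariate-free base model).
#' @param candidates List of [covariate_spec()] objects to test.
#' @param data Effect series; defaults to the base fit's data.
#' @param include_dofv,remove_dofv OFV-change thresholds for inclusion and
#'   retention.
#' @param seed Integer seed (passed to the refits).
#' @param n_starts Optimizer starts per refit.
#' @return A list with `fit` (the final model) and `steps` (a data.frame
#'   trail: phase, covariate, ofv_with, ofv_without, delta, decision).
#' @export
covariate_search <- function(base, candidates, data = base$data,
                             include_dofv = 3.84, remove_dofv = 6.63,
                             seed = 1L, n_starts = 2L) {
  stopifnot(inherits(base, "emax_fit"))
  if (!base$converged) stop("base fit did not converge", call. = FALSE)
  covs <- attr(data, "covariates")
  studies <- unique(data$study_id)
  usable <- vapply(candidates, function(cd) {
    ok <- !is.null(covs) && cd$name %in% names(covs) &&
      all(studies %in% covs$study_id) &&
      !any(is.na(covs[[cd$name]][match(studies, covs$study_id)]))
    if (!ok) message("candidate covariate '", cd$name,
                     "' missing for some study; skipped")
    ok
  }, logical(1))
  pool <- candidates[usable]

  steps <- data.frame(phase = character(), covariate = character(),
                      ofv_with = numeric(), ofv_without = numeric(),
                      delta = numeric(), decision = character(),
                      stringsAsFactors = FALSE)
  current <- base
  round_id <- 0L
  while (length(pool) > 0) {
    round_id <- round_id + 1L
    fits <- vector("list", length(pool))
    deltas <- rep(-Inf, length(pool))
    for (k in seq_along(pool)) {
      spec_try <- current$spec
      spec_try$covariates <- c(spec_try$covariates, list(pool[[k]]))
      f <- tryCatch(
        fit_emax(spec_try, data, init = current$params,
                 seed = derive_seed(seed, round_id * 100L + k),
                 n_starts = n_starts),
        error = function(e) NULL)
      if (!is.null(f) && f$converged) {
        fits[[k]] <- f
        deltas[k] <- current$ofv - f$ofv
      }
    }
    best_k <- which.max(deltas)
    for (k in seq_along(pool)) {
      steps <- rbind(steps, data.frame(
        phase = "forward", covariate = pool[[k]]$name,
        ofv_with = if (is.null(fits[[k]])) NA_real_ else fits[[k]]$ofv,
        ofv_without = current$ofv, delta = deltas[k],
        decision = if (k == best_k && deltas[k] > include_dofv)
          "included" else "rejected",
        stringsAsFactors = FALSE))
    }
    if (deltas[best_k] > include_dofv) {
      current <- fits[[best_k]]
      pool <- pool[-best_k]
    } else break
  }

  included <- setdiff(vapply(current$spec$covariates, `[[`, character(1), "name"),
                      vapply(base$spec$covariates, `[[`, character(1), "name"))
  for (nm in included) {
    spec_wo <- current$spec
    keep <- vapply(spec_wo$covariates, function(sp) sp$name != nm, logical(1))
    spec_wo$covariates <- spec_wo$covariates[keep]
    f <- tryCatch(
      fit_emax(spec_wo, data, init = current$params,
               seed = derive_seed(seed, 9000L + match(nm, included)),
               n_starts = n_starts),
      error = function(e) NULL)
    if (is.null(f) || !f$converged) next
    inc <- f$ofv - current$ofv
    retained <- inc > remove_dofv
    steps <- rbind(steps, data.frame(
      phase = "backward", covariate = nm, ofv_with = current$ofv,
      ofv_without = f$ofv, delta = inc,
      decision = if (retained) "retained" else "removed",
      stringsAsFactors = FALSE))
    if (!retained) current <- f
  }
  list(fit = current, steps = steps)
}

#' Conditional weighted residuals
#'
#' Residual diagnostics conditioned on the empirical-Bayes random-effect
#' modes: the model prediction is linearized around each study's eta mode
#' (first-order expansion), giving observation covariance
#' `F Omega F' + diag(v)`; the residuals are whitened by the Cholesky
#' factor of that covariance. Under a correctly specified model CWRES are
#' approximately standard normal. Without random effects they reduce to
#' `(y - f) / sd`.
#'
#' @param fit A converged `emax_fit`.
#' @param data Effect series (defaults to the fit's data).
#' @return A data.frame with one row per observation: `study_id`,
#'   `time_weeks`, `observed`, `pred` (population prediction, eta = 0),
#'   `ipred` (prediction at the eta mode), `cwres`.
#' @export
cwres <- function(fit, data = fit$data) {
  stopifnot(inherits(fit, "emax_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  params <- fit$params
  spec <- fit$spec
  covspecs <- effective_covspecs(spec, fit$thetas)
  tv <- typical_values(params, covspecs, data)
  v <- params$sigma^2 / (data$n_eff / 100)
  forms <- c(spec$re_emax, spec$re_et50)
  omegas <- c(params$omega_emax, params$omega_et50)
  active <- forms != "none" & omegas > 0
  d <- sum(active)

  out <- data.frame(study_id = data$study_id, time_weeks = data$time_weeks,
                    observed = data$effect_pct, pred = NA_real_,
                    ipred = NA_real_, cwres = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(tv$studies)) {
    idx <- which(data$study_id == tv$studies[k])
    t <- data$time_weeks[idx]
    y <- data$effect_pct[idx]
    predfun <- function(eta) {
      full <- numeric(2)
      full[active] <- eta
      e1 <- if (forms[1] == "none") tv$emax[k] else
        apply_random_effect(tv$emax[k], full[1], forms[1])
      t5 <- if (forms[2] == "none") tv$et50[k] else
        apply_random_effect(tv$et50[k], full[2], forms[2])
      e1 * t / (t5 + t)
    }
    out$pred[idx] <- predfun(numeric(d))
    if (d == 0) {
      out$ipred[idx] <- out$pred[idx]
      out$cwres[idx] <- (y - out$pred[idx]) / sqrt(v[idx])
      next
    }
    res_l <- study_laplace(y, t, v[idx], tv$emax[k], tv$et50[k],
                           forms, omegas, active)
    eta_hat <- res_l$eta[active]
    f_hat <- predfun(eta_hat)
    Fj <- num_jacobian(predfun, eta_hat)
    Om <- diag(omegas[active]^2, d)
    V <- Fj %*% Om %*% t(Fj) + diag(v[idx], length(idx))
    r <- y - f_hat + as.vector(Fj %*% eta_hat)
    U <- chol(V)
    out$ipred[idx] <- f_hat
    out$cwres[idx] <- forwardsolve(t(U), r)
  }
  out
}
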