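---
title: "Methods: an Emax model-based meta-analysis of aggregate BMI time courses"
author: "embma package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an Emax model-based meta-analysis of aggregate BMI time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embma)
```

## The problem

Randomized trials of nutritional supplements such as l-carnitine in type 2
diabetes report only aggregate results: per-arm sample sizes, doses,
durations, and summary BMI values. Classical meta-analysis pools one effect
size per study and discards the time dimension. Model-based meta-analysis
(MBMA) instead fits a parametric time-course model to the arm-level
aggregates across trials, which lets heterogeneous durations (12 weeks to
12 months in the carnitine trials) inform a single onset curve, and lets
the fitted curve answer design questions — most usefully, how long
treatment must continue before the effect plateaus.

`embma` implements that workflow end to end for BMI change rates:
preprocessing of arm-level outcomes, maximum-likelihood estimation of an
Emax time-course model with inter-study random effects, covariate
selection on the objective function value, bootstrap uncertainty, residual
and simulation-based diagnostics, and Monte-Carlo prediction. Because the
per-study time courses behind published analyses of this kind are not
deposited anywhere, the package also ships a first-class synthetic-data
generator with stored ground truth; every claim the test suite makes about
estimator behaviour is established on data from that generator.

## The model

The unit of effect is the percent BMI change from baseline,
$E\% = (E_t - E_b)/E_b \times 100$. Shared trial effects are removed by
differencing the arms of each study at matched times,
$E_{D,i,j} = E_{I,i,j} - E_{C,i,j}$, giving one placebo-adjusted
observation per study $i$ and time $j$. The structural model is a
time-driven Emax curve,

$$E_{D,i,j} = \frac{E_{\max,i}\; t_{ij}}{ET_{50,i} + t_{ij}} +
  \varepsilon_{ij}, \qquad
  \varepsilon_{ij} \sim N\!\big(0,\; \sigma^2 / (N_{ij}/100)\big),$$

where $E_{\max}$ is the asymptotic maximal change (negative for weight
loss), $ET_{50}$ the duration at half-maximal effect in weeks, and the
residual variance shrinks with the sample size behind each aggregate
observation — $\sigma$ is the residual SD for an arm of 100 subjects.
Study-level parameters carry inter-study random effects in exponential
($p\,e^\eta$) or additive ($p + \eta$) form, with
$\eta \sim N(0, \omega^2)$, independently selectable per parameter.
Covariate submodels on the typical values support a centred linear shift,
a power law, and a 0/1 categorical shift.

## Estimation

The marginal likelihood integrates the study-level random effects out by a
per-study Laplace approximation: a damped-Newton inner search (analytic
gradient and Hessian of the joint deviance) finds each study's conditional
mode $\hat\eta_i$, and the curvature there supplies the Gaussian
correction. With all $\omega = 0$ the objective reduces *exactly* to
weighted least squares with variances $\sigma^2/(N/100)$ plus the normal
constant; the test suite pins this down against an independently coded
oracle, against the closed multivariate-normal form of the additive-linear
case (where Laplace is exact), and against adaptive quadrature for the
exponential case.

Numerical choices, fixed once:

* $ET_{50}$, the $\omega$s and $\sigma$ are estimated on the log scale.
  $\omega$ and $\sigma$ are bounded below at $10^{-3}$ (mirroring the
  boundary-adjacent $\omega_{ET50}$ the carnitine analysis itself reports)
  and $ET_{50}$ is kept in $[10^{-3}, 10^4]$ weeks — times are in weeks,
  so values outside that range are physically meaningless and only arise
  when the likelihood is flat.
* The outer optimizer is `nlminb` with a small multi-start (3 by default:
  the initial values plus seeded jitter of SD 0.3 on the working scale),
  ties broken by lowest OFV then lexicographic parameter order, followed
  by a polish restart. Convergence uses relative tolerance $10^{-10}$.
  Because the ET50 profile can be genuinely flat, a "false convergence"
  return is accepted as converged only when no small coordinate move
  inside the bounds improves the objective.
* The inner search always starts at $\eta = 0$ (the prior mode); with
  sparse per-study data the inner surface can be multimodal, and a fixed
  start keeps the marginal objective a deterministic function of the
  parameters.
* Identifiability guards: one study $\Rightarrow$ random effects dropped
  with a warning; one distinct time $\Rightarrow$ $ET_{50}$ fixed at its
  initial value with a warning. Drugs represented by a single study are
  thereby handled as "too few studies to model" rather than silently
  over-fitted.

Covariate selection follows the standard OFV stepwise procedure: forward
inclusion at $\Delta\mathrm{OFV} > 3.84$ ($\chi^2_1$, $\alpha = 0.05$),
backward retention at $\Delta\mathrm{OFV} > 6.63$ ($\alpha = 0.01$),
candidates acting on $E_{\max}$ by convention. When several covariates
target one parameter they compose in declaration order, a fixed rule that
makes multi-covariate models reproducible.

## Preprocessing decisions

* Months convert to weeks at $52/12$; 12 weeks and 3 months (13.0 weeks)
  are deliberately distinct design points. Time matching between arms uses
  a 0.5-week tolerance that absorbs floating error only.
* The effective sample size of an adjusted point is
  $\min(N_I, N_C)$ — a conservative choice, since a single $N_{ij}$ is
  not well defined for a differenced series.
* Baseline (time-0) adjusted effects are identically zero, carry no
  information for a curve through the origin, and are excluded from the
  likelihood; they would otherwise make the weighted residual degenerate.
* Studies without a control arm are excluded with a counted warning.
  Reported variances/SDs are never imputed: the likelihood weights only by
  sample size.

## Validation and prediction

**Bootstrap.** The resampling unit is the study — the level at which the
modeled heterogeneity lives. Each replicate is refitted from the original
estimates; failures are dropped and counted, and a summary with more than
50% failures is flagged unreliable. Intervals are percentile (2.5th to
97.5th), bias is $(\text{median} - \text{estimate})/\text{estimate}
\times 100$.

**CWRES.** Conditional weighted residuals linearize the model around each
study's empirical-Bayes mode; under a correct model they are approximately
standard normal, which the tests verify on a 120-study simulation (mean
within $\pm 0.1$, variance in $[0.8, 1.2]$), along with their power to
flag a misspecified residual scale.

**pcVPC.** The prediction-corrected visual predictive check simulates the
observed design from the fitted model, rescales observed and simulated
values by the ratio of bin-median population prediction to each point's
own population prediction, and compares observed bin medians with the
2.5th–97.5th percentile envelope of simulated bin medians. Aggregate-trial
data are too sparse for automatic binning, so the default is one bin per
distinct design time, with explicit edges as an override.

**Prediction.** Monte-Carlo simulation of the population curve under the
fitted inter-study variability yields a median curve with a 95% band; the
parameter-free fraction of maximal effect $t/(ET_{50}+t)$ is annotated at
50, 80, 90, and 95% of $E_{\max}$. With $ET_{50} = 0.5$ weeks these
milestones fall at 0.5, 2, 4.5, and 9.5 weeks; the 80% point is the
conventional plateau criterion.

## The synthetic-data generator

`simulate_trials()` emulates what the analysis assumes: two-arm studies
whose control arms follow an optional placebo Emax curve (default zero —
the placebo response cancels in the adjustment but exercises the
subtraction step), intervention arms adding a study-level drug curve, and
arm-level residual noise with SD $\sigma/\sqrt{N/100}$. Baseline BMI is
drawn per arm from a normal distribution (default mean 30, SD 2, floored
at 15 — an obese type-2-diabetes population) and raw BMI values are
back-computed so that the change-rate step recovers the generated rates
exactly. Dose is carried as inert metadata (2–3 g/day), matching the
absence of dose dependence in the motivating analysis. The default design,
and `carnitine_design()` exactly, mirror the packaged fixture: 8 two-arm
studies, arm sizes 23–132, endpoint durations 12–52 weeks.

What the generator does *not* emulate — and what passing tests therefore
cannot show about real data: publication bias, outcome reporting at
unscheduled interim visits, non-normal residuals, correlated multi-arm
designs, and measurement error in the published aggregates themselves.

Note one deliberate asymmetry: the generator applies residual noise per
*arm*, so a differenced observation carries roughly twice the residual
variance that its $N$-based weight implies ($\sigma_{\text{fit}} \approx
\sqrt{2}\,\sigma_{\text{gen}}$ with equal arms). The fitted $\sigma$
absorbs this factor; relative weighting across observations, and hence
the structural estimates, are unaffected.

## Problem sizes used by the tests

The parameter-recovery experiment runs 50 replicates of the 8-study
fixture design (truth $E_{\max} = -1.51$%, $ET_{50} = 0.5$ weeks,
$\sigma = 0.414$, $\omega = 0$) through the full pipeline with the
mixed-effects base model and a single optimizer start; the covariate
type-I experiment uses 100 replicates of a 20-study design; variance
recovery uses one 200-study set; the pcVPC self-consistency check pools
20 replicate datasets at 200 simulations each. These sizes give stable
medians and rates while keeping the default suite quick to run.

## Known limitations

* $ET_{50}$ is weakly identified from endpoint-only designs whose
  earliest observation (12 weeks) lies far above the half-maximal
  duration: its profile likelihood is nearly flat, estimates pile up at
  the boundary or wander large, and bootstrap intervals for $ET_{50}$ —
  and, through the curve's ridge, for $E_{\max}$ at small study counts —
  are very wide. This mirrors the wide published bootstrap interval for
  $ET_{50}$ ([0.5, 37.2] weeks) in the motivating analysis. Estimating
  the mixed-effects model regularizes but does not cure this; conclusions
  about onset earlier than the earliest observed time rest on the Emax
  form itself.
* The Laplace approximation is exact only in the additive-linear case;
  for exponential random effects on sparse studies it deviates from the
  true marginal by a small amount (about 0.03 OFV units on the test
  instances), which is negligible next to the 3.84/6.63 decision
  thresholds but is not controlled in general.
* Which random-effect form (exponential vs additive) the motivating
  analysis retained is not recoverable from its report; both are
  implemented and selectable, with exponential as the default for its
  sign-preserving behaviour.
* The bootstrap label in such reports is ambiguous between a data
  bootstrap and a simulation-based interval; the package implements the
  study-resampling data bootstrap.
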