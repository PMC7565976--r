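---
title: "Population modelling of preclinical tumour growth with tumgrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population modelling of preclinical tumour growth with tumgrowth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`tumgrowth` analyses longitudinal tumour-volume data from preclinical
experiments in which treatment starts when a tumour reaches an enrollment
threshold (80 mm³ by default) and volumes are caliper-measured — volume
approximated as $L l^2 / 2$ from two perpendicular diameters — twice a
week thereafter.

The structural model is a generalized Gompertz law for the volume $V(t)$
of one tumour,

$$\frac{dV}{dt} = k_{\mathrm{eff}}(t)\, V \left[\log\frac{V_{\max}}{V}\right]^{\gamma},
\qquad V(0) = V_0,$$

with growth rate constant $k$ (1/day), plateau volume $V_{\max}$ (mm³)
and power coefficient $\gamma$. At $\gamma = 1$ this is the classic
Gompertz law. Treatment acts multiplicatively on the rate:
$k_{\mathrm{eff}} = k(1 - \mathit{EFF})$ while treatment is active, so
$1/(1-\mathit{EFF})$ is the factor by which growth slows. $\mathit{EFF} = 0$
means no effect; $\mathit{EFF} \ge 1$ (growth arrest or shrinkage) is
supported only when shrinkage mode is requested explicitly.

Substituting $u = \log(V_{\max}/V)$ turns the ODE into $du/dt = -k u^\gamma$,
which has a closed-form solution for every $\gamma > 0$. `predict_volume()`
therefore evaluates trajectories analytically by default; a numerical
adaptive-step integration (`method = "ode"`, absolute/relative tolerance
1e-8, with the treatment start forced as a step boundary) is kept as an
independent cross-check and agrees with the analytic path to better than
1e-6 relative error in the test suite. One modelling consequence of
$\gamma < 1$ worth knowing: the plateau is reached in *finite* time, so
trajectories are non-decreasing rather than strictly increasing once
there.

Two structural choices were genuinely open and are package decisions:
$\gamma$ powers the $\log(V_{\max}/V)$ term (so that $\gamma = 1$
recovers classic Gompertz with exactly the three named parameters), and
treatment is modelled as continuously active from its start time — the
every-two-days dosing interval is carried as design metadata only, since
no pharmacokinetic model is fitted. The time origin is the treatment
start, and each animal's initial volume $V_0$ is fixed at its first
observed volume rather than estimated, keeping the parameter count down;
the anchoring observation is consequently excluded from the residual
likelihood.

## Population model and estimation

Individual parameters are log-normally distributed around population
typical values: $\log k_i \sim N(\log k_{\mathrm{pop}}, \omega_k^2)$ and
likewise for $V_{\max}$ and (in treated arms only) $\mathit{EFF}$;
$\gamma$ is a fixed effect shared by all animals, and inter-individual
variabilities quoted as percentages are the $\omega$'s (the sd of the
log-scale random effect), e.g. "39%" is $\omega = 0.39$. The residual
model is combined proportional + additive:
$y = f + \varepsilon$, $\mathrm{sd}(\varepsilon) =
\sqrt{\sigma_{\mathrm{add}}^2 + (\sigma_{\mathrm{prop}} f)^2}$.

`saem_fit()` implements stochastic approximation EM from scratch. Each
iteration alternates:

1. **Simulation** — Metropolis sampling of every animal's log-scale
   individual parameters from their conditional posterior: one
   independent proposal from the current population law, component-wise
   random walks (scales adapted towards ~30% acceptance during burn-in),
   and a dedicated kernel that moves $(\log k_i, \log \mathit{EFF}_i)$
   along the ridge of constant $k_i(1-\mathit{EFF}_i)$. The treated-arm
   likelihood depends on those two parameters only through the effective
   rate, so this last kernel — exact Jacobian, no likelihood evaluation —
   is what decorrelates the otherwise ridge-locked pair; without it the
   rate/effect split mixes far too slowly.
2. **Stochastic approximation / M-step** — closed-form weighted
   least-squares updates of the population coefficients and $\omega$'s
   from smoothed sufficient statistics; a one-dimensional profile step
   for $\gamma$; and a damped conditional maximization for the residual
   parameters. The step size is 1 during burn-in (with
   simulated-annealing style damping that limits how fast variance
   components may shrink) and decays as $(i - n_{\mathrm{burnin}})^{-a}$,
   $a = 0.7$ by default, afterwards. The reported estimate is the
   average of the parameter state over the final quarter of the
   smoothing phase, which removes most of the chain's residual
   Monte-Carlo jitter.

Two safeguards matter in practice. The generalized Gompertz family
contains a degenerate ridge — $\gamma \to 0$ with $V_{\max} \to \infty$
is indistinguishable from exponential growth — so individual plateaus
are bounded at 50 times the largest observed volume (with matching broad
support bounds on the other parameters), and initial $\omega$'s are
capped at 1.5. Initialization uses `two_stage_fit()`, a per-animal
least-squares fit with a globally profiled $\gamma$ that also serves as
an independent oracle: on rich data (dense sampling, moderate
variability so that every animal identifies its own parameters) SAEM and
the two-stage estimator agree to within a few percent, which the test
suite asserts at a 5% tolerance.

Covariates are multiplicative arm coefficients on the log-scale
parameters (vehicle arm as reference; for `eff`, the first treated arm).
`log_likelihood()` estimates the observed-data log-likelihood by
importance sampling — per-animal proposals centred at the conditional
mode with curvature-based covariance inflated by 1.5 — and reports a
Monte-Carlo standard error. `lrt()` compares nested fits against a
chi-square reference; only fixed-effect covariates are tested, so no
boundary mixture correction is applied. Negative statistics beyond three
standard errors trigger a warning and are clamped to zero.

Convergence discipline matters more for the LRT than for point
estimates: the likelihood surface is flat along a $k$–$\gamma$–$\omega_k$
ridge, and under-converged fits can differ by several nats — enough to
fabricate or destroy a likelihood-ratio signal. The calibration study in
the test suite therefore runs generous iteration budgets (500 burn-in +
300 smoothing) and fits null and alternative models with common random
numbers so that residual convergence error largely cancels in the
difference. Under those conditions the type-I error of the
arm-covariate LRT at $\alpha = 0.05$ was 5/100 over 100 null
simulations.

## The cohort simulator

`simulate_cohort()` emulates the in vivo design: per-animal parameters
drawn from the population law; true initial volume equal to the
enrollment threshold perturbed by one realization of the measurement
error model; noise-free trajectories observed at the design grid
(default twice weekly over 28 days) under combined residual error,
floored at 1 mm³ so that log-scale machinery stays defined; and a
humane-endpoint survival time — the first crossing of the endpoint
volume (default 1500 mm³) by the noise-free trajectory, censored at the
study end (default day 60). Defaults follow the emulated study where it
states them (enrollment at 80 mm³, twice-weekly caliper measurements,
three arms) and otherwise use values a preclinical modeller would
consider realistic: 10 animals per arm, $\sigma_{\mathrm{prop}} = 0.15$,
$\sigma_{\mathrm{add}} = 5$ mm³, since group sizes and the residual
model are not published. The treatment effect is drawn log-normally, so
a reported 82% variability implies a fifth of treated animals with
$\mathit{EFF} > 1$, i.e. shrinking tumours — the simulator and estimator
both support this.

What the simulator does *not* emulate: enrollment on discrete
measurement days (enrollment is exact up to measurement error), dropout
other than the volume endpoint, drug pharmacokinetics, body-weight or
metastasis dynamics. Passing recovery tests on these cohorts therefore
demonstrates estimator correctness under the stated statistical model,
not robustness to every real-data pathology.

Because the first observation doubles as the anchor for $V_0$ while the
simulator perturbs both the true initial volume and its observation, the
fit sees a slightly misspecified anchor — deliberately so, as a mild
realism stress; recovery tolerances absorb it.

## What the recovery tests assert

At the study's published population values ($k = 0.64$/day with
$\omega = 0.39$, $V_{\max} = 1620$ mm³ with $\omega = 0.64$,
$\mathit{EFF} = 0.52$ with $\omega = 0.82$, $\gamma = 0.17$), a single
cohort of 3 × 20 animals is a *small* experiment: the maximum-likelihood
estimate of $\mathit{EFF}_{\mathrm{pop}}$ itself scatters with a
standard deviation near 18% across cohorts (with $\omega_{\mathrm{eff}}
= 0.82$ and 40 treated animals, that is mostly irreducible sampling
noise; we verified on deviating cohorts that the importance-sampling
log-likelihood at the SAEM estimate exceeds the one at the generating
truth). Estimator accuracy is therefore assessed on estimates averaged
over five replicate cohorts, where the 15% tolerance (±0.1 for
$\gamma$) binds on bias rather than on single-cohort noise. The same
averaging defines the reported treatment growth-slowing factor
$1/(1-\widehat{\mathit{EFF}})$, which rounds to the published factor
of 2.

The 90% prediction band (`predict_intervals()`) is checked by
Monte-Carlo coverage on the arm with a continuous observation
distribution (vehicle); treated arms carry a point mass at the 1 mm³
floor, where an equal-tailed band can only over-cover.

## Dose-response and survival components

`fit_hill()` estimates $r(c) = \mathrm{top} \cdot c^n/(c^n +
EC_{50}^n)$ by least squares with a deterministic multi-start
(log-spaced $EC_{50}$ in [0.1, 30] mM crossed with $n \in \{0.5, 1, 1.5,
2, 3\}$) and a Gauss-Newton polish. Because responses are normalized to
the reference (highest) concentration rather than to the fitted maximum,
`top` is estimated but bounded in (0, 1.5]; whether the original
analysis constrained it is not recoverable, and on noiseless data the
unconstrained optimum is recovered exactly either way. On noisy
replicates (6 cells, 5% noise) the estimator is median-unbiased with a
heavy right tail driven by the strong $EC_{50}$–top correlation at the
top of the grid.

`gehan_breslow_wilcoxon()` is the weighted log-rank test with pooled
number-at-risk weights (Breslow convention; ties reduce the risk set
simultaneously). Its asymptotic chi-square(1) p-value is complemented by
a permutation option, exhaustive for small groups — the 4+4 permutation
distribution reproduces the exact Mann-Whitney p-value when no
observation is censored, and matches a brute-force pairwise-scoring
implementation of Gehan's statistic in general. Three-arm survival
figures are handled as pairwise comparisons against vehicle without
multiplicity correction, matching how a single pairwise p-value is
usually quoted.

## Problem sizes and reproducibility

Every stochastic operation takes an explicit seed, and the pipeline
writes it into its report. The simulation studies in the test suite use
deliberately chosen sizes — five replicate 60-animal cohorts for
recovery, 100 null replicates of a 16-animal two-arm design for LRT
calibration, 4000 virtual animals per arm for bands — so the entire
suite runs in minutes on a single core while keeping Monte-Carlo error
well inside each assertion's tolerance.
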