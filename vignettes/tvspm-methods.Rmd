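---
title: "Time-varying surplus production models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-varying surplus production models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`tvspm` implements a continuous-time state-space surplus production model
for data-moderate stock assessment, in the maximum-net-productivity
parameterization. Exploitable biomass $B_t$ follows the stochastic
differential equation

$$
dB_t = \left(\gamma m_t \frac{B_t}{K_t}
       - \gamma m_t \Big[\frac{B_t}{K_t}\Big]^{n}
       - F_t B_t\right) dt + \sigma_B B_t \, dW_t,
$$

where $m_t$ is maximum net productivity (tonnes/yr), $K_t$ carrying
capacity (tonnes), $F_t$ fishing mortality (1/yr), $\sigma_B$ the biomass
process SD, and $n > 0$ a dimensionless shape exponent with normalizer
$\gamma = n^{n/(n-1)}/(n-1)$. The familiar intrinsic growth rate is the
derived quantity $r_t = m_t\, n^{n/(n-1)} / K_t$. Three members of the
family are supported: Schaefer ($n = 2$, $\gamma = 4$, $m = rK/4$), the Fox
limit ($n \to 1$, handled analytically: production
$e\, m\, (B/K)\log(K/B)$, $m = rK/e$), and Pella-Tomlinson (free $n$,
estimated on the log scale). The Fox curve is never evaluated as
$n = 1 + \epsilon$; the closed-form limit avoids catastrophic cancellation
and is guarded by an $\epsilon$-consistency test.

MSY-based reference points are closed forms of the same parameters, and
therefore inherit any time variation:

$$
B_{MSY,t} = K_t (1/n)^{1/(n-1)}, \qquad
MSY_t = m_t, \qquad
F_{MSY,t} = MSY_t / B_{MSY,t}.
$$

At the Fox limit $B_{MSY} = K/e$ and $F_{MSY} = r$; under Schaefer
$B_{MSY} = K/2$ and $F_{MSY} = r/2$. The identity
$MSY_t = F_{MSY,t} B_{MSY,t}$ holds exactly at the point estimates and is
asserted in the tests.

# Time-varying productivity

Temporal variation enters through multiplicative deviations
$m_t = \bar m\, G_t(m)$ and $K_t = \bar K\, G_t(K)$ whose logarithms follow
mean-reverting Ornstein-Uhlenbeck (OU) diffusions,

$$
d\log G_t = -\psi \log G_t\, dt + \sigma\, dW_t,
$$

with stationary variance $\sigma^2/(2\psi)$. The OU choice (rather than a
random walk) bounds parameter drift, and — because the process is
stationary and fully specified by $(\psi, \sigma)$ — gives the initial
deviation state a proper distribution, which matters for one-step-ahead
residuals of early observations. Discretization uses the *exact* Gaussian
OU transition even though the biomass equation is Euler-discretized: the
exact transition is free, removes one source of discretization error, and
coincides with Euler as $dt \to 0$.

Six scenarios control which deviations are active and how they are coupled
(`scenario_spec()`): CM (none), RM (OU on $m$, $K$ constant), KM (one OU
driver shared by $m$ and $K$, so $r$ stays constant while $K$ varies),
PKRM ($G(r) = G(K)$, i.e. $\log G(m) = 2 \log G(K)$ from a single driver),
LKRM ($G(r) = G(K)^\lambda$ with $\lambda$ a free fixed effect, initial
value 1; $\lambda = 1$ reproduces PKRM exactly), and IKRM (independent OU
processes on $m$ and $K$). The implied growth-rate deviation is always
$G(r) = G(m)/G(K)$. During estimation $\lambda$ is box-constrained to
$[-1, 4]$: below $-1$ productivity would *fall* as carrying capacity
rises, a regime that is biologically implausible and, under the fixed OU
volatility, numerically unstable (the inner Laplace optimization loses
convexity). $\lambda = -1$, the boundary, is the "constant $m$" edge case.

The OU hyper-parameters $(\psi_m, \sigma_m, \psi_K, \sigma_K)$ are fixed at
0.2 by default — the moderately persistent setting used for the assessed
stock — and can instead be estimated via `spm_control()`. With them fixed,
CM is *not* nested in RM, and a more flexible scenario can legitimately
attain a lower marginal likelihood than CM on data without productivity
variation; this is exactly the mechanism by which AICc favours
parsimonious scenarios in the comparison suite.

# Observation model and likelihood

Annual catch is the integral of $F_t B_t$ over the year (trapezoid rule on
the Euler grid) with lognormal observation error; each fleet's abundance
index observes its catchability $q_i$ times the annual mean of biomass on
the grid (a start-of-year snapshot is available as a config switch), also
with lognormal error. Lognormal errors are mean-corrected ($-\sigma^2/2$)
so the expected observation equals the truth; the correction can be turned
off (median convention) via `spm_control(mean_correct = FALSE)`.

The latent vector comprises log-biomass on the $dt = 1/8$ yr Euler grid
(Ito-corrected log-scale transitions, guaranteeing positivity), *annual*
log fishing mortality as a random walk, and the active OU paths. Modelling
$F$ at annual rather than grid resolution matches the annual catch data
and the simulator's "constant within year" convention, and cuts the latent
dimension by roughly a third at no cost to the annual quantities the
analysis reports. Initial depletion $B_0/K_0$ is fixed at 0.46, the value
adopted from existing assessments of the emulated stock.

Fixed effects carry the priors used in the original analysis: lognormal
priors on $r$ (median 0.49, log-SD 0.2) and $K$ (median 11,230,000 t,
log-SD 0.5). Two weakly informative ratio priors, $N(0, 2^2)$ on
$\log(\sigma_{I,i}/\sigma_B)$ and $\log(\sigma_C/\sigma_F)$, stabilize the
classic observation/process noise decomposition — the same convention the
upstream assessment engine ships as its default. Without them the maximum
likelihood estimate of $\sigma_B$ (and $\sigma_C$) routinely collapses to
the zero boundary on 30-year series. All priors are switchable in
`prior_spec()`.

Latent states are integrated out by the Laplace approximation (sparse
inner Newton optimization plus a Gaussian log-determinant correction),
implemented in a compiled TMB template; the marginal likelihood is
maximized with `nlminb`. A fit is declared converged when the optimizer
reports success, the projected gradient infinity-norm is below $10^{-3}$,
and the fixed-effect Hessian is positive definite. (A tighter $10^{-6}$
gradient norm is not reliably attainable with quasi-Newton optimization at
this problem scale; the $10^{-3}$ threshold was adopted as the package's
convergence contract and is reported alongside every fit.) The Laplace
approximation itself is validated against dense grid-based integration
over the latent biomass chain on a five-year problem, agreeing within 1%
on the likelihood scale.

# Diagnostics, selection and uncertainty

Model comparison uses AICc with $p$ the number of *free fixed effects*
(latents are marginalized, fixed/mapped parameters excluded) and $n$ the
total count of catch plus index observations. One-step-ahead residuals
are computed by sequential conditioning with fixed effects frozen at their
estimates (`TMB::oneStepPredict`); the very first catch observation is
conditioned on rather than predicted because the initial fishing mortality
is diffuse and that observation has no proper predictive law. Serial
independence is tested with the Ljung-Box statistic (default lag
$\min(10, \lfloor n/7\rfloor)$, i.e. 4 for a 30-year annual series).
Retrospective peels refit the model dropping terminal years and summarize
with Mohn's rho. Uncertainty intervals are delta-method on the log scale,
$\exp(\hat\theta \pm 1.96\,SE)$, for fixed effects, latent states, and the
annual reference-point series alike; annualization of grid-resolution
quantities is the within-year trapezoid mean, consistent with the index
observation convention. For time-varying fits the headline estimates are
terminal-year values.

# The synthetic-data generator

No real catch, CPUE or environmental series ships with the package; the
generator (`sim_config()`, `simulate_population()`, `observe()`,
`simulate_env_table()`) emulates the study system with known truth:

* 30 annual time steps (1992-2021 labelling), Euler step 1/8 yr;
* mean carrying capacity 11.23 million t, $r = 0.49$/yr (so
  $\bar m = rK/4 \approx 1.376$ million t/yr under Schaefer), initial
  depletion 0.46 — the prior means of the original analysis, used as the
  generating truth;
* process noise $\sigma_B = 0.05$; four CPUE fleets with distinct
  catchabilities ($0.5, 1, 2, 4 \times 10^{-6}$ per tonne) and index SD
  0.2 each; catch observation SD 0.05;
* fishing mortality follows an annual log-scale random walk (SD 0.1) with
  deterministic drift 0.05/yr from $F = 0.05$: a one-way trip ending just
  below $F_{MSY} \approx 0.245$, giving the contrast a production model
  needs and, on average, a terminal state in the sustainable Kobe
  quadrant. The random-walk component makes individual realizations range
  from lightly fished to overfished, which is deliberate: recovery studies
  should span informative and less informative histories.

The environmental table draws ten standardized covariates (SST, SSS, SSO,
SSCA, MLT, SSH, ENSO, PDO, IPO, WPSTA) from three latent, temporally
persistent climate factors — interannual (AR(1) $\phi = 0.5$), decadal
($\phi = 0.85$) and upper-ocean ($\phi = 0.6$) — with factor loadings that
make the ENSO-like block (SST, SSH, ENSO) nearly collinear, so iterative
VIF screening has something to remove, while PDO, IPO, MLT and the rest
survive at moderate VIFs. Temporal persistence matters: a productivity
signal planted through an iid covariate is invisible to the OU smoother,
exactly as a white-noise climate proxy would be in a real assessment. A
known response can be planted either in the covariate table
(`response_link`) or directly in the population's productivity path
(`logGm_custom`), which is how the end-to-end linkage experiment wires a
PDO effect into $m_t$.

What the generator does *not* emulate: age/size structure, spatial
heterogeneity, effort economics, CPUE standardization artifacts, and
lagged environmental effects. Passing tests therefore demonstrate that the
estimation and linkage machinery recovers truth under the model's own
assumptions at realistic noise levels — not that those assumptions hold
for any particular real fishery.

# Environmental linkage

The post hoc analysis regresses the annual point-estimate series
$\hat m_t$ (equal to $MSY_t$) from a time-varying fit on environmental
covariates, ignoring the estimation uncertainty of $\hat m_t$ — a
deliberate mirror of the two-stage design it reproduces. Covariates are
first screened by iterative VIF removal (threshold 10, always removing the
current maximum, full audit trail retained; perfectly collinear columns
get infinite VIF and fall first). The additive models are penalized
thin-plate regression splines fitted by REML through `mgcv`, with a year
smooth ($k = 3$) always included to absorb background temporal structure.
Candidate subsets are searched exhaustively up to 8 covariates (AIC
ranking), greedily forward beyond that. Basis dimensions default to
$k = 5$ for covariate smooths — with 30 annual observations, larger bases
mostly add ways to overfit — and are per-term configurable. Smooth-term
p-values are the standard penalized-Wald approximations; their null
calibration (a few percent false-positive rate at $\alpha = 0.05$) is
verified by simulation in the test suite.

# Problem sizes and numerical choices

The validation suite runs, per study: 50 replicates for fixed-effect
coverage, 20 for trend recovery (summarized by the median across-replicate
correlation), 30 for the AICc scenario comparison, 20 seeds for the
end-to-end linkage experiment, 2000 series for Ljung-Box calibration and
500 for smooth-term calibration. These sizes give stable pass/fail
behaviour for the properties tested while keeping a full run of the suite
in the tens of minutes on one core. Other numerical choices: optimizer
iteration cap 500; inner (Laplace) Newton tolerance is TMB's default
$10^{-8}$; the biomass floor $10^{-6}\bar K$ aborts a simulated collapse
with a diagnostic rather than silently underflowing; box bounds keep the
Pella-Tomlinson exponent in $[1.01, 14]$ during estimation (the left-skew
region below 1 is served by the Fox limit, and the bound keeps the
$\gamma$ normalizer away from its $n = 1$ singularity).

# Known limitations

* $\lambda$ (LKRM) and $n$ (Pella-Tomlinson) are weakly identified on
  30-year series; their fits can end on a box bound and are then flagged
  as non-converged rather than silently accepted.
* Recovering *interannual* productivity variation from four noisy indices
  is information-limited: across replicates the true-versus-estimated
  $m_t$ correlation is typically 0.6-0.9 but occasional realizations carry
  essentially no recoverable signal, a property of the data, not the
  optimizer.
* The environmental stage inherits all caveats of post hoc regression on
  estimated quantities: the year smooth can absorb low-frequency covariate
  signal, and contemporaneous-only effects are assumed.

# A worked example

```{r example}
library(tvspm)

cfg  <- sim_config(scenario = scenario_spec("RM"), seed = 1)
traj <- simulate_population(cfg)
dat  <- observe(traj, cfg)

fit <- fit_spm(dat, scenario = "RM")
fit$estimates
reference_point_series(fit)
stock_status(fit)

cmp <- compare_scenarios(dat, c("CM", "RM", "KM"))
cmp$table

res <- osa_residuals(fit)
ljung_box(res$residual[res$stream == "catch"])

env <- simulate_env_table(dat$catch$year, seed = 2)
vr  <- vif_screen(env$env)
sel <- select_model(data.frame(year = dat$catch$year,
                               m = reference_point_series(fit)$m),
                    env$env, vr$retained)
sel$ranking
```
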